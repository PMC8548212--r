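# shared fixture cache: the mini-locus is deterministic per seed, build once
.fx_cache <- new.env(parent = emptyenv())

get_fixture <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- build_fixture_genome(fixture_spec(seed = seed))
  .fx_cache[[key]]
}

default_profiles_test <- function() {
  groups <- c("M.WT.Cb", "F.WT.Cb", "M.KO.Cb", "F.KO.Cb",
              "M.WT.Br", "F.WT.Br", "M.KO.Br", "F.KO.Br")
  matrix(0, 1, 8, dimnames = list("flat", groups))
}

# a small sequence-backed model with n exons of given lengths on one strand
toy_model <- function(lengths, strand = "+", roles = NULL, spacer = 20,
                      seed = 1) {
  set.seed(seed)
  n <- length(lengths)
  ids <- paste0("X", seq_len(n))
  if (is.null(roles)) roles <- c("novel_start", rep("internal", max(0, n - 2)),
                                 if (n > 1) "terminal")
  seqs <- vapply(lengths, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  gaps <- replicate(n + 1, paste(sample(c("A", "C", "G", "T"), spacer,
                                        replace = TRUE), collapse = ""))
  chromseq <- paste0(gaps[1], paste0(seqs, gaps[-1], collapse = ""))
  starts <- spacer + cumsum(c(0, head(lengths + spacer, -1))) + 1
  ends <- starts + lengths - 1
  ord <- if (strand == "+") seq_len(n) else rev(seq_len(n))
  exons <- lapply(ord, function(i)
    exon(ids[i], genomic_interval("chrT", starts[i], ends[i], strand),
         role = roles[match(i, ord)]))
  gene_model_from_sequence(exons, c(chrT = chromseq))
}
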