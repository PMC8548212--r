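#' Fixture specification for the synthetic mini-locus and its datasets
#'
#' Bundles the seed and the per-dataset parameters for all generators. The
#' defaults encode the study conditions: a 448-nt SSR start exon with a
#' putative ATG at 362-364 (29 codons flush to the exon end), a 65-nt SINE
#' cassette exon carrying an in-frame TGA at 19-21 relative to the upstream
#' SSR frame and an ATG at 48-50 opening a 6-codon block (MDEGYF) flush to
#' the exon end, a reference first exon with a 48-nt CDS prefix (16
#' residues), and a shared downstream CDS of 781 codons, so the reference
#' protein is 797 aa and the SSR fusion protein 810 aa. Real inter-exon
#' distances (hundreds of kb) are scaled to 5-kb spacers; the scale is
#' recorded in the emitted truth.
#'
#' @param seed Integer seed; fully determines every output byte.
#' @param locus,long_reads,expression,promoters Named lists overriding the
#'   per-dataset defaults (see the package vignette for the full parameter
#'   table).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, locus = list(), long_reads = list(),
                         expression = list(), promoters = list()) {
  merge_defaults <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown fixture parameter(s): ",
                          paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  locus <- merge_defaults(list(
    chrom = "chrL",
    ssr_len = 448, ssr_atg = 362,
    sine_len = 65, sine_stop = 19, sine_atg = 48,
    e1_len = 200, e1_atg = 153,
    internal_exon_len = 200, n_internal = 11,   # E2..E12
    last_exon_len = 400,
    cds_aa_after_e1 = 781,                      # shared codons from E2 onward
    spacer = 5000, flank = 1000,
    real_gaps_kb = c(ssr_sine = 566.7, sine_e1 = 200)), locus)
  long_reads <- merge_defaults(list(
    n_reads = 500,
    mixture = c("SSR-SINE-ref" = 0.7, "SSR-ref" = 0.2, "E1-ref" = 0.1),
    error_rate = 0, min_len = 500, max_len = 5500,
    adapter_len = 50, mean_quality = 30, low_quality_frac = 0.05,
    low_quality_phred = 8), long_reads)
  expression <- merge_defaults(list(
    replicates = 2, probes_per_cluster = 50, n_null = 200,
    sigma = 0.25, baseline = c(6, 12),
    profiles = NULL), expression)   # NULL -> default 4 one-group patterns
  promoters <- merge_defaults(list(
    set_sizes = c(setA = 200, setB = 200),
    prevalence = c(setA = 0.6, setB = 0.2),
    flank = 1000, consensus = "AGGTCACAGTGACCT", motif_id = "ERE-like",
    gc = 0.5), promoters)
  structure(list(seed = seed, locus = locus, long_reads = long_reads,
                 expression = expression, promoters = promoters),
            class = "fixture_spec")
}

# n random codons from the standard code with no stop codons
random_nonstop_codons <- function(n) {
  if (n == 0) return(character(0))
  all_codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                      paste0), c("A", "C", "G", "T"), paste0))
  ok <- setdiff(all_codons, STOP_CODONS)
  sample(ok, n, replace = TRUE)
}

# random sequence of length n containing no ATG triplet
random_no_atg <- function(n) {
  s <- random_dna(n)
  while (grepl("ATG", s, fixed = TRUE))
    s <- sub("ATG", random_dna(3), s, fixed = TRUE)
  s
}

#' Build the synthetic mini-locus genome, gene model and truth record
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, writes `genome.fa`,
#'   `model.gff3` and `truth.json` (the latter requires jsonlite) into it.
#' @return List: `genome` (named character vector), `model` (a
#'   [gene_model()]), `truth` (exon table, annotated codon checks, scale
#'   notes, reference and fusion proteins).
#' @export
build_fixture_genome <- function(spec = fixture_spec(), dir = NULL) {
  lc <- spec$locus
  if (lc$ssr_atg > lc$ssr_len - 2 || lc$sine_atg > lc$sine_len - 2 ||
      lc$sine_stop > lc$sine_len - 2 || lc$e1_atg > lc$e1_len - 2)
    stop("inconsistent locus geometry: annotated codon outside its exon")
  if ((lc$ssr_len - lc$ssr_atg + 1) %% 3 != 0 ||
      (lc$sine_len - lc$sine_atg + 1) %% 3 != 0 ||
      (lc$e1_len - lc$e1_atg + 1) %% 3 != 0)
    stop("inconsistent locus geometry: start codons must sit flush with exon ends")
  set.seed(spec$seed)

  # SSR: random 5' part without ATG, then ATG + non-stop codons to the end
  n_ssr_cod <- (lc$ssr_len - lc$ssr_atg + 1) %/% 3
  ssr <- paste0(random_no_atg(lc$ssr_atg - 1), "ATG",
                paste(random_nonstop_codons(n_ssr_cod - 1), collapse = ""))

  # SINE: upstream-frame codons (SSR frame = frame 1 of the exon) non-stop up
  # to the planted TGA; no stray ATG before the annotated one; the annotated
  # ATG block encodes MDEGYF and runs flush to the exon end
  n_sine_cod <- (lc$sine_len - lc$sine_atg + 1) %/% 3
  sine_tail <- c("ATG", "GAT", "GAA", "GGG", "TAC", "TTT")  # M D E G Y F
  if (n_sine_cod != length(sine_tail))
    sine_tail <- c("ATG", random_nonstop_codons(n_sine_cod - 1))
  repeat {
    head_cod <- random_nonstop_codons((lc$sine_stop - 1) %/% 3)
    mid <- random_dna(lc$sine_atg - 1 - (lc$sine_stop + 2))
    sine <- paste0(paste(head_cod, collapse = ""), "TGA", mid,
                   paste(sine_tail, collapse = ""))
    if (!grepl("ATG", substr(sine, 1, lc$sine_atg - 1), fixed = TRUE)) break
  }
  stopifnot(nchar(sine) == lc$sine_len)

  # shared CDS from E2 onward (781 codons + stop), then split across exons
  shared_cds <- paste(random_nonstop_codons(lc$cds_aa_after_e1), collapse = "")
  # the final E1 residue must differ from the final SSR and SINE residues,
  # otherwise the shared C-terminal block would extend into the N-terminal
  # prefixes and the novel/replaced counts would not reflect the junction
  junction_aa <- translate_codons(c(substr(ssr, lc$ssr_len - 2, lc$ssr_len),
                                    substr(sine, lc$sine_len - 2, lc$sine_len)))
  junction_aa <- strsplit(junction_aa, "")[[1]]
  repeat {
    e1_cod <- c("ATG", random_nonstop_codons((lc$e1_len - lc$e1_atg + 1) %/% 3 - 1))
    last_aa <- translate_codons(e1_cod[length(e1_cod)])
    if (!last_aa %in% junction_aa) break
  }
  e1 <- paste0(random_no_atg(lc$e1_atg - 1), paste(e1_cod, collapse = ""))
  cds_len <- nchar(shared_cds) + 3
  internal_total <- lc$n_internal * lc$internal_exon_len
  if (cds_len <= internal_total || cds_len > internal_total + lc$last_exon_len)
    stop("inconsistent locus geometry: shared CDS must end inside the last exon")
  body <- paste0(shared_cds, "TAA")
  internals <- substring(body,
                         seq(1, internal_total, by = lc$internal_exon_len),
                         seq(lc$internal_exon_len, internal_total,
                             by = lc$internal_exon_len))
  last_exon <- paste0(substring(body, internal_total + 1),
                      random_dna(lc$last_exon_len - (cds_len - internal_total)))

  exon_seqs <- c(SSR = ssr, SINE = sine, E1 = e1,
                 stats::setNames(internals, paste0("E", 1 + seq_along(internals))),
                 stats::setNames(last_exon, paste0("E", 2 + length(internals))))
  roles <- c("novel_start", "novel_start", "reference_first",
             rep("internal", length(internals)), "terminal")

  # assemble the chromosome: leading flank, exons with fixed spacers
  pieces <- character(0); pos <- lc$flank
  starts <- numeric(length(exon_seqs)); ends <- numeric(length(exon_seqs))
  pieces <- random_dna(lc$flank)
  for (i in seq_along(exon_seqs)) {
    starts[i] <- pos + 1
    ends[i] <- pos + nchar(exon_seqs[i])
    pieces <- paste0(pieces, exon_seqs[i])
    pos <- ends[i]
    spacer_seq <- random_dna(if (i < length(exon_seqs)) lc$spacer else lc$flank)
    pieces <- paste0(pieces, spacer_seq)
    pos <- pos + nchar(spacer_seq)
  }
  genome <- stats::setNames(pieces, lc$chrom)

  ann_start <- c(SSR = lc$ssr_atg, SINE = lc$sine_atg, E1 = lc$e1_atg)
  ann_stop <- c(SINE = lc$sine_stop)
  exons <- lapply(seq_along(exon_seqs), function(i) {
    id <- names(exon_seqs)[i]
    exon(id, genomic_interval(lc$chrom, starts[i], ends[i], "+"),
         role = roles[i],
         annotated_start = if (id %in% names(ann_start)) ann_start[[id]] else NA_real_,
         annotated_stop = if (id %in% names(ann_stop)) ann_stop[[id]] else NA_real_)
  })
  model <- gene_model_from_sequence(exons, genome)

  ref_chain <- c("E1", paste0("E", 2:(2 + length(internals))))
  ref_orf <- find_orfs(annotate_isoform(ref_chain, model), "annotated_starts")[[1]]
  truth <- list(
    exons = data.frame(id = names(exon_seqs), start = starts, end = ends,
                       length = nchar(exon_seqs), role = roles,
                       stringsAsFactors = FALSE),
    annotated = list(ssr_atg = lc$ssr_atg, sine_atg = lc$sine_atg,
                     sine_stop = lc$sine_stop, e1_atg = lc$e1_atg),
    spacer_scale = list(fixture_spacer = lc$spacer,
                        real_gaps_kb = lc$real_gaps_kb),
    reference_chain = ref_chain,
    reference_protein = ref_orf$protein,
    reference_protein_length = ref_orf$length_aa)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gn <- Biostrings::DNAStringSet(genome)
    Biostrings::writeXStringSet(gn, file.path(dir, "genome.fa"))
    write_gene_model_gff3(model, file.path(dir, "model.gff3"))
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(truth, file.path(dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  list(genome = genome, model = model, truth = truth)
}

#' The three principal isoform templates of the fixture locus
#'
#' @param model Fixture [gene_model()] from [build_fixture_genome()].
#' @return Named list of [isoform_template()]s: `SSR-SINE-ref`
#'   (SSR-SINE-E2..), `SSR-ref` (SSR-E2..), `E1-ref` (the reference chain).
#' @export
fixture_templates <- function(model) {
  ids <- exon_ids(model)
  ref_body <- ids[!(ids %in% c("SSR", "SINE", "E1"))]
  chains <- list("SSR-SINE-ref" = c("SSR", "SINE", ref_body),
                 "SSR-ref" = c("SSR", ref_body),
                 "E1-ref" = c("E1", ref_body))
  out <- lapply(names(chains), function(nm) {
    t <- isoform_template(nm, chains[[nm]], model)
    t
  })
  stats::setNames(out, names(chains))
}

phred_string <- function(q, n) {
  paste(rep(rawToChar(as.raw(33L + as.integer(q))), n), collapse = "")
}

add_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    subst <- vapply(chars[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    chars[hit] <- subst
  }
  paste(chars, collapse = "")
}

#' Simulate long reads from a known isoform mixture
#'
#' Reads are substrings of the three fixture isoform transcripts, drawn from
#' the stated mixture with lengths uniform on `[min_len, max_len]` truncated
#' at the transcript length (draws beyond it become full transcripts). Each
#' read carries a random 5' adapter of `adapter_len` nt (removed by
#' [qc_filter()]'s head trim), constant per-read Phred qualities (a
#' `low_quality_frac` of reads gets `low_quality_phred`, the rest
#' `mean_quality`), and substitution errors at `error_rate`.
#'
#' @param spec A [fixture_spec()].
#' @param model Fixture gene model (built from `spec` if omitted).
#' @param fastq Optional FASTQ output path.
#' @return List: `reads` (data frame `id`, `seq`, `qual`), `truth` (per-read
#'   isoform of origin, transcript span, quality class), `templates`.
#' @export
simulate_long_reads <- function(spec = fixture_spec(), model = NULL,
                                fastq = NULL) {
  lr <- spec$long_reads
  if (abs(sum(lr$mixture) - 1) > 1e-9) stop("mixture proportions must sum to 1")
  if (!length(lr$mixture)) stop("empty isoform mixture")
  if (is.null(model)) model <- build_fixture_genome(spec)$model
  templates <- fixture_templates(model)
  if (!all(names(lr$mixture) %in% names(templates)))
    stop("mixture names must match fixture templates")
  set.seed(spec$seed + 1L)
  iso <- sample(names(lr$mixture), lr$n_reads, replace = TRUE,
                prob = lr$mixture)
  rows <- lapply(seq_len(lr$n_reads), function(i) {
    tseq <- templates[[iso[i]]]$seq
    L <- nchar(tseq)
    len <- min(L, round(stats::runif(1, lr$min_len, lr$max_len)))
    s <- sample.int(L - len + 1L, 1L)
    frag <- substr(tseq, s, s + len - 1)
    lowq <- stats::runif(1) < lr$low_quality_frac
    q <- if (lowq) lr$low_quality_phred else lr$mean_quality
    seq <- paste0(random_dna(lr$adapter_len), add_substitutions(frag, lr$error_rate))
    data.frame(id = sprintf("read%04d", i), seq = seq,
               qual = phred_string(q, nchar(seq)),
               isoform = iso[i], tx_start = s, tx_end = s + len - 1,
               low_quality = lowq, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  reads <- df[, c("id", "seq", "qual")]
  truth <- df[, c("id", "isoform", "tx_start", "tx_end", "low_quality")]
  if (!is.null(fastq)) write_fastq(reads, fastq)
  list(reads = reads, truth = truth, templates = templates)
}

#' Write reads to FASTQ
#'
#' @param reads Data frame with `id`, `seq`, `qual`.
#' @param path Output FASTQ.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' Simulate junction-spanning short-read alignments with planted depths
#'
#' Emits a spliced-alignment block table: for each junction, `depths[j]`
#' reads spanning it with overhangs drawn uniformly from `overhang_range`,
#' plus `n_nonspanning` single-block reads inside the donor exon of the
#' first junction.
#'
#' @param model Fixture gene model.
#' @param junctions Data frame from [junction_defs()].
#' @param depths Named integer vector (by junction name) of planted
#'   spanning-read counts.
#' @param sample Sample label.
#' @param overhang_range Length-2 vector of overhang bounds (default
#'   `c(10, 60)`).
#' @param n_nonspanning Exonic non-spanning reads to add (default 5).
#' @param seed Seed.
#' @return Data frame (`sample`, `read_id`, `mapq`, `start`, `end`) for
#'   [count_junction_reads()], with truth in the `junction` attribute.
#' @export
simulate_junction_reads <- function(model, junctions, depths, sample = "s1",
                                    overhang_range = c(10, 60),
                                    n_nonspanning = 5, seed = 1) {
  set.seed(seed)
  stopifnot(all(names(depths) %in% junctions$name))
  rows <- list(); k <- 0
  for (jn in names(depths)) {
    j <- junctions[junctions$name == jn, ]
    for (r in seq_len(depths[[jn]])) {
      k <- k + 1
      o1 <- sample(seq(overhang_range[1], overhang_range[2]), 1)
      o2 <- sample(seq(overhang_range[1], overhang_range[2]), 1)
      rows[[k]] <- data.frame(
        sample = sample, read_id = sprintf("sr%05d", k), mapq = 60,
        start = c(j$donor_edge - o1 + 1, j$acceptor_edge),
        end = c(j$donor_edge, j$acceptor_edge + o2 - 1),
        junction = jn, stringsAsFactors = FALSE)
    }
  }
  donor1 <- get_exon(model, junctions$donor[1])$interval
  for (r in seq_len(n_nonspanning)) {
    k <- k + 1
    s <- sample(seq(donor1$start, donor1$end - 30), 1)
    rows[[k]] <- data.frame(sample = sample, read_id = sprintf("sr%05d", k),
                            mapq = 60, start = s, end = s + 29,
                            junction = NA_character_, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_profiles <- function() {
  groups <- c("M.WT.Cb", "F.WT.Cb", "M.KO.Cb", "F.KO.Cb",
              "M.WT.Br", "F.WT.Br", "M.KO.Br", "F.KO.Br")
  pr <- matrix(0, nrow = 4, ncol = 8,
               dimnames = list(paste0("cluster", 1:4), groups))
  pr["cluster1", "F.KO.Cb"] <- 1.2   # female cerebellum up in the mutant
  pr["cluster2", "M.KO.Cb"] <- 1.2
  pr["cluster3", "F.KO.Br"] <- -1.2
  pr["cluster4", "M.KO.Br"] <- -1.2
  pr
}

#' Simulate the 2^3 full-factorial expression matrix with planted clusters
#'
#' Sixteen samples by default: sex (M/F) x genotype (WT/KO) x organ (Cb/Br)
#' with `replicates` specimens per cell, hence 8 specimens per genotype.
#' Probe values are a per-probe baseline plus the cluster's group profile
#' plus Gaussian noise of sd `sigma` on the log2 scale; `n_null` probes get
#' a flat profile.
#'
#' @param spec A [fixture_spec()].
#' @return List: `mat` (probes x samples), `design`, `truth` (probe,
#'   cluster label, 0 for null, and planted per-group log2FC versus the
#'   grand mean), `profiles`.
#' @export
simulate_expression <- function(spec = fixture_spec()) {
  ex <- spec$expression
  if (ex$replicates < 2) stop("need replicates >= 2")
  profiles <- ex$profiles %||% default_profiles()
  groups <- colnames(profiles)
  design <- expand.grid(replicate = seq_len(ex$replicates), group = groups,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  parts <- do.call(rbind, strsplit(design$group, ".", fixed = TRUE))
  design <- data.frame(sample = paste0(design$group, ".", design$replicate),
                       sex = parts[, 1], genotype = parts[, 2],
                       organ = parts[, 3], replicate = design$replicate,
                       stringsAsFactors = FALSE)
  set.seed(spec$seed + 2L)
  n_clustered <- nrow(profiles) * ex$probes_per_cluster
  n_probes <- n_clustered + ex$n_null
  cluster <- c(rep(seq_len(nrow(profiles)), each = ex$probes_per_cluster),
               rep(0L, ex$n_null))
  baseline <- stats::runif(n_probes, ex$baseline[1], ex$baseline[2])
  mu <- matrix(0, n_probes, length(groups), dimnames = list(NULL, groups))
  mu[cluster > 0, ] <- profiles[cluster[cluster > 0], , drop = FALSE]
  mat <- matrix(NA_real_, n_probes, nrow(design),
                dimnames = list(sprintf("p%05d", seq_len(n_probes)),
                                design$sample))
  grp_of_sample <- paste(design$sex, design$genotype, design$organ, sep = ".")
  for (s in seq_len(nrow(design)))
    mat[, s] <- baseline + mu[, grp_of_sample[s]] +
      stats::rnorm(n_probes, 0, ex$sigma)
  lfc_truth <- mu - rowMeans(mu)
  truth <- data.frame(probe = rownames(mat), cluster = cluster,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(lfc_truth))
  list(mat = mat, design = design, truth = truth, profiles = profiles)
}

#' Simulate promoter sets with planted motif prevalence
#'
#' Each gene gets its own random promoter window of `2 * flank + 1` nt; with
#' per-set probability `prevalence` the motif consensus (the PWM's
#' maximum-scoring word) is planted at a random offset on a random strand.
#'
#' @param spec A [fixture_spec()].
#' @return List: `promoters` (data frame `gene`, `seq`, `clipped` — the
#'   format of [extract_promoters()]), `tss` (synthetic TSS table),
#'   `gene_sets`, `motif` (the planting [pwm()]), `truth` (per gene:
#'   set, planted flag, offset, strand).
#' @export
simulate_promoters <- function(spec = fixture_spec()) {
  pm <- spec$promoters
  if (any(pm$prevalence < 0 | pm$prevalence > 1))
    stop("prevalence must lie in [0, 1]")
  stopifnot(identical(names(pm$set_sizes), names(pm$prevalence)))
  set.seed(spec$seed + 3L)
  w <- nchar(pm$consensus)
  counts <- vapply(strsplit(pm$consensus, "")[[1]], function(b) {
    v <- stats::setNames(rep(2, 4), c("A", "C", "G", "T")); v[b] <- 94; v
  }, numeric(4))
  motif <- pwm(counts, id = pm$motif_id)
  win_len <- 2 * pm$flank + 1
  gc <- pm$gc
  bg_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rows <- list(); k <- 0
  for (set in names(pm$set_sizes)) {
    for (i in seq_len(pm$set_sizes[[set]])) {
      k <- k + 1
      seq <- random_dna(win_len, prob = bg_prob)
      planted <- stats::runif(1) < pm$prevalence[[set]]
      offset <- NA_integer_; strand <- NA_character_
      if (planted) {
        offset <- sample.int(win_len - w + 1L, 1L)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") pm$consensus else revcomp(pm$consensus)
        substr(seq, offset, offset + w - 1) <- ins
      }
      rows[[k]] <- data.frame(gene = sprintf("%s_g%04d", set, i), set = set,
                              seq = seq, planted = planted, offset = offset,
                              strand = strand, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  promoters <- data.frame(gene = df$gene, seq = df$seq, clipped = FALSE,
                          stringsAsFactors = FALSE)
  tss <- data.frame(gene = df$gene, chrom = df$gene,
                    position = pm$flank + 1, strand = "+",
                    stringsAsFactors = FALSE)
  gene_sets <- split(df$gene, df$set)[names(pm$set_sizes)]
  list(promoters = promoters, tss = tss, gene_sets = gene_sets,
       motif = motif, truth = df[, c("gene", "set", "planted", "offset", "strand")])
}
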