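#' Isoform template
#'
#' An artificial reference sequence representing one candidate exon chain.
#' Long reads are aligned against a set of these and classified by which
#' junction breakpoints their alignments span.
#'
#' @param id Template label.
#' @param exon_chain Character vector of exon ids in transcription order.
#' @param model A [gene_model()] with sequence access.
#' @return Object of class `isoform_template` with fields `id`, `exon_chain`,
#'   `seq`, `boundaries` and `junctions` (data frame: `donor`, `acceptor`,
#'   `breakpoint` = cumulative upstream length in nt, i.e. the 0-based
#'   transcript offset of the acceptor's first base).
#' @export
isoform_template <- function(id, exon_chain, model) {
  sp <- splice(exon_chain, model)
  n <- length(exon_chain)
  junctions <- if (n > 1) {
    data.frame(donor = exon_chain[-n], acceptor = exon_chain[-1],
               breakpoint = sp$boundaries$end0[-n],
               stringsAsFactors = FALSE)
  } else {
    data.frame(donor = character(0), acceptor = character(0),
               breakpoint = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(id = id, exon_chain = exon_chain, seq = sp$seq,
                 boundaries = sp$boundaries, junctions = junctions),
            class = "isoform_template")
}

#' @export
print.isoform_template <- function(x, ...) {
  cat(sprintf("isoform_template %s: %s (%d nt, %d junctions)\n", x$id,
              paste(x$exon_chain, collapse = "-"), nchar(x$seq),
              nrow(x$junctions)))
  invisible(x)
}

#' Enumerate candidate isoform templates
#'
#' In `chains` mode, every order-preserving exon subsequence that starts at an
#' allowed start exon, ends at the required terminal exon and satisfies the
#' constraints is emitted exactly once. In `junction_pairs` mode one template
#' is emitted per ordered exon pair (donor before acceptor in transcription
#' order), optionally restricted to an allowed pair list. Output is
#' deterministic: templates are sorted lexicographically by id, and ids encode
#' the exon chain.
#'
#' @param model A [gene_model()].
#' @param mode `"chains"` or `"junction_pairs"`.
#' @param start_exons Allowed start exon ids (chains mode). Default: exons
#'   with role `novel_start` or `reference_first`, or the first exon if none.
#' @param terminal_exon Required terminal exon id (chains mode). Default: the
#'   last exon in transcription order.
#' @param required_exons,excluded_exons Optional exon id constraints.
#' @param max_chain_length Optional cap on exons per chain.
#' @param allowed_pairs Optional 2-column matrix/data.frame of donor/acceptor
#'   ids (junction_pairs mode).
#' @return Named list of [isoform_template()] objects, lexicographically
#'   sorted by id.
#' @export
enumerate_templates <- function(model,
                                mode = c("chains", "junction_pairs"),
                                start_exons = NULL,
                                terminal_exon = NULL,
                                required_exons = character(0),
                                excluded_exons = character(0),
                                max_chain_length = Inf,
                                allowed_pairs = NULL) {
  mode <- match.arg(mode)
  ids <- exon_ids(model)
  chk <- function(x, what) {
    bad <- setdiff(x, ids)
    if (length(bad)) stop("unknown ", what, ": ", paste(bad, collapse = ", "))
    x
  }
  chk(required_exons, "required exon"); chk(excluded_exons, "excluded exon")

  if (mode == "junction_pairs") {
    pairs <- expand.grid(donor = seq_along(ids), acceptor = seq_along(ids))
    pairs <- pairs[pairs$donor < pairs$acceptor, , drop = FALSE]
    if (!is.null(allowed_pairs)) {
      allowed_pairs <- as.data.frame(allowed_pairs, stringsAsFactors = FALSE)
      chk(unlist(allowed_pairs), "exon in allowed_pairs")
      key <- paste(ids[pairs$donor], ids[pairs$acceptor])
      pairs <- pairs[key %in% paste(allowed_pairs[[1]], allowed_pairs[[2]]), ,
                     drop = FALSE]
    }
    chains <- lapply(seq_len(nrow(pairs)),
                     function(i) ids[c(pairs$donor[i], pairs$acceptor[i])])
  } else {
    if (is.null(start_exons)) {
      roles <- vapply(model$exons, function(e) e$role, character(1))
      start_exons <- ids[roles %in% c("novel_start", "reference_first")]
      if (!length(start_exons)) start_exons <- ids[1]
    }
    chk(start_exons, "start exon")
    if (!length(start_exons)) stop("no allowed start exon")
    if (is.null(terminal_exon)) terminal_exon <- ids[length(ids)]
    chk(terminal_exon, "terminal exon")
    chains <- list()
    for (s in match(start_exons, ids)) {
      t <- match(terminal_exon, ids)
      if (s > t) next
      middle <- setdiff(seq(s, t), c(s, t, match(excluded_exons, ids)))
      middle <- if (s == t) integer(0) else middle
      # all subsets of the optional internal exons
      for (mask in 0:(2^length(middle) - 1)) {
        sel <- middle[bitwAnd(mask, 2^(seq_along(middle) - 1)) > 0]
        chain_idx <- sort(unique(c(s, sel, t)))
        chain <- ids[chain_idx]
        if (length(chain) > max_chain_length) next
        if (!all(required_exons %in% chain)) next
        if (any(excluded_exons %in% chain)) next
        chains[[length(chains) + 1L]] <- chain
      }
    }
    chains <- unique(chains)
  }
  if (!length(chains))
    return(structure(list(), names = character(0)))
  tids <- vapply(chains, paste, character(1), collapse = "-")
  ord <- order(tids)
  templates <- lapply(ord, function(i) isoform_template(tids[i], chains[[i]], model))
  names(templates) <- tids[ord]
  templates
}

#' Write a template reference set (FASTA + junction TSV)
#'
#' The FASTA id line carries `chain=` and `breakpoints=` tags; the companion
#' TSV lists one row per junction.
#'
#' @param templates Non-empty list of [isoform_template()] objects.
#' @param fasta_path,tsv_path Output paths (TSV defaults to the FASTA path
#'   with a `.junctions.tsv` extension).
#' @return `fasta_path`, invisibly.
#' @export
write_templates <- function(templates, fasta_path,
                            tsv_path = sub("\\.fa(sta)?$", "", fasta_path)) {
  if (!length(templates)) stop("refusing to write an empty template set")
  ids <- vapply(templates, function(t) t$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate template ids; write refused")
  if (identical(tsv_path, sub("\\.fa(sta)?$", "", fasta_path)))
    tsv_path <- paste0(tsv_path, ".junctions.tsv")
  seqs <- Biostrings::DNAStringSet(vapply(templates, function(t) t$seq, character(1)))
  names(seqs) <- vapply(templates, function(t) {
    sprintf("%s chain=%s breakpoints=%s", t$id,
            paste(t$exon_chain, collapse = ","),
            paste(t$junctions$breakpoint, collapse = ","))
  }, character(1))
  Biostrings::writeXStringSet(seqs, fasta_path)
  jt <- do.call(rbind, lapply(templates, function(t) {
    if (!nrow(t$junctions)) return(NULL)
    data.frame(template = t$id, junction_index = seq_len(nrow(t$junctions)),
               donor = t$junctions$donor, acceptor = t$junctions$acceptor,
               breakpoint = t$junctions$breakpoint,
               transcript_pos = t$junctions$breakpoint + 1,  # 1-based acceptor base
               stringsAsFactors = FALSE)
  }))
  if (is.null(jt))
    jt <- data.frame(template = character(0), junction_index = integer(0),
                     donor = character(0), acceptor = character(0),
                     breakpoint = numeric(0), transcript_pos = numeric(0))
  utils::write.table(jt, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Read back a template set written by [write_templates()]
#'
#' @param fasta_path Template FASTA (with `chain=`/`breakpoints=` tags).
#' @return Named list of `isoform_template`-like objects (id, exon_chain,
#'   seq, junctions); boundary tables are reconstructed from the chain tags
#'   and breakpoints.
#' @export
read_templates <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- lapply(seq_along(seqs), function(i) {
    hdr <- names(seqs)[i]
    id <- sub("\\s.*$", "", hdr)
    chain <- strsplit(sub(".*chain=(\\S+).*", "\\1", hdr), ",")[[1]]
    bp_str <- sub(".*breakpoints=(\\S*).*", "\\1", hdr)
    bps <- if (nzchar(bp_str)) as.numeric(strsplit(bp_str, ",")[[1]]) else numeric(0)
    junctions <- data.frame(
      donor = if (length(bps)) chain[-length(chain)] else character(0),
      acceptor = if (length(bps)) chain[-1] else character(0),
      breakpoint = bps, stringsAsFactors = FALSE)
    structure(list(id = id, exon_chain = chain,
                   seq = as.character(seqs[[i]]), junctions = junctions),
              class = "isoform_template")
  })
  names(out) <- vapply(out, function(t) t$id, character(1))
  out
}
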