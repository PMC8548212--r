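#' Transcript annotation for ORF prediction
#'
#' Bundles a spliced transcript sequence with its exon boundary table and the
#' candidate translation starts.
#'
#' @param seq Spliced nucleotide sequence (A/C/G/T/N).
#' @param boundaries Exon boundary table from [splice()] (or any data frame
#'   with `exon`, `start`, `end` transcript columns).
#' @param starts Optional data frame of candidate starts: `pos` (1-based
#'   transcript position of the A of an ATG) and `provenance`
#'   (`"annotated"`/`"scanned"`).
#' @return Object of class `transcript_annotation`.
#' @export
transcript_annotation <- function(seq, boundaries,
                                  starts = data.frame(pos = numeric(0),
                                                      provenance = character(0))) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over {A,C,G,T,N}")
  for (p in starts$pos)
    if (substr(seq, p, p + 2) != "ATG")
      stop("candidate start at ", p, " is not the A of an ATG")
  structure(list(seq = seq, boundaries = boundaries, starts = starts),
            class = "transcript_annotation")
}

#' Annotate an isoform of a gene model for ORF prediction
#'
#' Splices the exon chain and maps each exon's annotated ATG (if any) to
#' transcript coordinates as an `annotated` candidate start.
#'
#' @param exon_chain Character vector of exon ids in transcription order.
#' @param model A [gene_model()].
#' @return A [transcript_annotation()].
#' @export
annotate_isoform <- function(exon_chain, model) {
  sp <- splice(exon_chain, model)
  starts <- do.call(rbind, lapply(exon_chain, function(id) {
    e <- get_exon(model, id)
    if (is.na(e$annotated_start)) return(NULL)
    tx0 <- sp$boundaries$start0[sp$boundaries$exon == id]
    data.frame(pos = tx0 + e$annotated_start, provenance = "annotated",
               stringsAsFactors = FALSE)
  }))
  if (is.null(starts))
    starts <- data.frame(pos = numeric(0), provenance = character(0))
  transcript_annotation(sp$seq, sp$boundaries, starts)
}

translate_codons <- function(codons) {
  if (!length(codons)) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(paste(codons, collapse = "")),
    if.fuzzy.codon = "X"))
}

#' Predict open reading frames on a transcript
#'
#' For each admitted start, translation runs codon by codon until the first
#' in-frame stop (standard nuclear code; codons containing N translate to X
#' and never terminate) or, flagged `open`, the end of the sequence. Each
#' residue is attributed to the exon containing the first nucleotide of its
#' codon.
#'
#' @param transcript A [transcript_annotation()].
#' @param policy Start-selection policy: `"annotated_starts"` (use the
#'   transcript's annotated candidates), `"first_atg"`, or `"all_atgs"`.
#' @return List of `orf_result` objects: `start` (1-based), `stop` (position
#'   of the stop codon's last base, or `NA` with `open = TRUE`), `protein`,
#'   `length_aa`, `residue_exons` (exon-of-origin per residue), `open`.
#' @export
find_orfs <- function(transcript,
                      policy = c("annotated_starts", "first_atg", "all_atgs")) {
  policy <- match.arg(policy)
  seq <- transcript$seq
  starts <- switch(policy,
    annotated_starts = transcript$starts$pos,
    first_atg = {
      m <- regexpr("ATG", seq, fixed = TRUE)
      if (m[1] > 0) m[1] else numeric(0)
    },
    all_atgs = {
      m <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
      if (m[1] > 0) as.numeric(m) else numeric(0)
    })
  lapply(starts, function(s) orf_from_start(seq, s, transcript$boundaries))
}

orf_from_start <- function(seq, start, boundaries) {
  cods <- codons_from(seq, start)
  stop_idx <- which(cods %in% STOP_CODONS)
  if (length(stop_idx)) {
    n_aa <- stop_idx[1] - 1L
    stop_pos <- start + stop_idx[1] * 3 - 1
    open <- FALSE
  } else {
    n_aa <- length(cods)
    stop_pos <- NA_real_
    open <- TRUE
  }
  coding <- cods[seq_len(n_aa)]
  protein <- translate_codons(coding)
  first_nt <- start + 3 * (seq_len(n_aa) - 1)
  residue_exons <- vapply(first_nt, function(p) {
    row <- which(boundaries$start <= p & boundaries$end >= p)
    if (length(row) != 1L) NA_character_ else boundaries$exon[row]
  }, character(1))
  structure(list(start = start, stop = stop_pos, protein = protein,
                 length_aa = n_aa, residue_exons = residue_exons, open = open),
            known_exons = boundaries$exon,
            class = "orf_result")
}

#' @export
print.orf_result <- function(x, ...) {
  cat(sprintf("orf_result: start %d, %s, %d aa\n", x$start,
              if (x$open) "open (no stop)" else sprintf("stop ends at %d", x$stop),
              x$length_aa))
  invisible(x)
}

#' Residues an ORF draws from one exon
#'
#' A codon belongs to the exon containing its first nucleotide.
#'
#' @param orf An `orf_result` from [find_orfs()].
#' @param exon_id Exon label present in the transcript's boundary table.
#' @return Integer residue count.
#' @export
residues_from_exon <- function(orf, exon_id) {
  known <- attr(orf, "known_exons", exact = TRUE)
  if (!exon_id %in% c(known, orf$residue_exons))
    stop("exon not in the transcript boundary table: ", exon_id)
  sum(orf$residue_exons == exon_id)
}

#' Compare the N-terminus of a novel protein against a reference
#'
#' The shared block is the longest common suffix; everything upstream of it
#' in the new protein is "novel" and everything upstream of it in the
#' reference is "replaced".
#'
#' @param new_protein,reference_protein Non-empty amino-acid strings.
#' @return List of class `nterm_comparison`: `novel`, `replaced`,
#'   `shared_cterm`.
#' @export
compare_nterm <- function(new_protein, reference_protein) {
  if (!nzchar(new_protein) || !nzchar(reference_protein))
    stop("proteins must be non-empty")
  a <- rev(strsplit(new_protein, "")[[1]])
  b <- rev(strsplit(reference_protein, "")[[1]])
  n <- min(length(a), length(b))
  diff <- which(a[seq_len(n)] != b[seq_len(n)])
  shared <- if (length(diff)) diff[1] - 1L else n
  structure(list(novel = nchar(new_protein) - shared,
                 replaced = nchar(reference_protein) - shared,
                 shared_cterm = shared),
            class = "nterm_comparison")
}

#' @export
print.nterm_comparison <- function(x, ...) {
  cat(sprintf("nterm_comparison: %d novel, %d replaced, %d shared C-terminal\n",
              x$novel, x$replaced, x$shared_cterm))
  invisible(x)
}

#' Excise a deletion from a transcript
#'
#' @param transcript A [transcript_annotation()].
#' @param del_start,del_end 1-based inclusive transcript coordinates of the
#'   deleted interval.
#' @return Edited [transcript_annotation()]; exon boundary spans shrink by
#'   their overlap with the deletion, downstream candidate starts shift left,
#'   and starts inside the deletion are dropped.
#' @export
apply_deletion <- function(transcript, del_start, del_end) {
  n <- nchar(transcript$seq)
  if (del_start < 1 || del_end > n || del_start > del_end)
    stop("deletion interval outside transcript bounds")
  len <- del_end - del_start + 1
  seq2 <- paste0(substr(transcript$seq, 1, del_start - 1),
                 substring(transcript$seq, del_end + 1))
  b <- transcript$boundaries
  overlap <- pmax(0, pmin(b$end, del_end) - pmax(b$start, del_start) + 1)
  # recompute spans cumulatively from the shrunken exon lengths
  newlen <- (b$end - b$start + 1) - overlap
  end0 <- cumsum(newlen); start0 <- end0 - newlen
  b$start <- start0 + 1; b$end <- end0
  b$start0 <- start0; b$end0 <- end0
  st <- transcript$starts
  keep <- st$pos < del_start | st$pos > del_end
  st <- st[keep, , drop = FALSE]
  st$pos <- ifelse(st$pos > del_end, st$pos - len, st$pos)
  # drop starts whose ATG was destroyed by the edit
  st <- st[substring(seq2, st$pos, st$pos + 2) == "ATG", , drop = FALSE]
  out <- transcript_annotation(seq2, b, st)
  attr(out, "deletion") <- c(start = del_start, end = del_end)
  out
}

#' Variant consequence of a deletion on an ORF
#'
#' Re-runs translation from the original start on the edited transcript. The
#' frameshift flag is set iff the deletion length is not a multiple of 3 and
#' the deletion lies at or downstream of the start codon. The knockout call
#' is a declared mechanistic heuristic: frameshift plus truncation below
#' `ko_fraction` of the intact ORF length.
#'
#' @param orf_before `orf_result` on the intact transcript.
#' @param transcript_after Edited transcript from [apply_deletion()].
#' @param ko_fraction Truncation fraction below which a frameshifted ORF is
#'   called knocked out (default 0.2).
#' @return List of class `variant_consequence`: `frameshift`,
#'   `premature_stop` (transcript position of the new stop codon's last base
#'   or `NA`), `truncated_length_aa`, `ko_call`, and the re-predicted
#'   `orf_after`.
#' @export
consequence <- function(orf_before, transcript_after, ko_fraction = 0.2) {
  del <- attr(transcript_after, "deletion", exact = TRUE)
  if (is.null(del)) stop("transcript_after must come from apply_deletion()")
  len <- del["end"] - del["start"] + 1
  start <- orf_before$start
  if (del["end"] < start) start <- start - len
  if (substr(transcript_after$seq, start, start + 2) != "ATG")
    stop("start codon destroyed by the deletion; no ORF to re-predict")
  orf_after <- orf_from_start(transcript_after$seq, start,
                              transcript_after$boundaries)
  frameshift <- (len %% 3 != 0) && del["start"] >= orf_before$start
  truncated <- orf_after$length_aa
  structure(list(
    frameshift = unname(frameshift),
    premature_stop = if (!orf_after$open &&
                         orf_after$length_aa < orf_before$length_aa)
      orf_after$stop else NA_real_,
    truncated_length_aa = truncated,
    ko_call = unname(frameshift && truncated < ko_fraction * orf_before$length_aa),
    orf_after = orf_after),
    class = "variant_consequence")
}

#' @export
print.variant_consequence <- function(x, ...) {
  cat(sprintf("variant_consequence: frameshift=%s, premature stop %s, %d aa, ko_call=%s\n",
              x$frameshift,
              if (is.na(x$premature_stop)) "none" else sprintf("at %d", x$premature_stop),
              x$truncated_length_aa, x$ko_call))
  invisible(x)
}
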