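#' Define isoform-discriminating splice junctions on a gene model
#'
#' @param model A [gene_model()].
#' @param pairs Data frame (or 2-column matrix) of `donor`, `acceptor` exon
#'   ids; the donor must precede the acceptor in transcription order.
#' @return Data frame with `name` (`donor-acceptor`), `donor`, `acceptor`,
#'   and the genomic edge coordinates `donor_edge` (last transcribed base of
#'   the donor exon) and `acceptor_edge` (first transcribed base of the
#'   acceptor exon).
#' @export
junction_defs <- function(model, pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("donor", "acceptor")
  ids <- exon_ids(model)
  di <- match(pairs$donor, ids); ai <- match(pairs$acceptor, ids)
  if (anyNA(di) || anyNA(ai))
    stop("junction references exon(s) absent from the model")
  if (any(di >= ai)) stop("donor must precede acceptor in transcription order")
  donor_edge <- vapply(di, function(i) {
    iv <- model$exons[[i]]$interval
    if (model$strand == "+") iv$end else iv$start
  }, numeric(1))
  acceptor_edge <- vapply(ai, function(i) {
    iv <- model$exons[[i]]$interval
    if (model$strand == "+") iv$start else iv$end
  }, numeric(1))
  data.frame(name = paste(pairs$donor, pairs$acceptor, sep = "-"),
             donor = pairs$donor, acceptor = pairs$acceptor,
             donor_edge = donor_edge, acceptor_edge = acceptor_edge,
             stringsAsFactors = FALSE)
}

# does one spliced read (genomic blocks, 1-based inclusive, transcription
# order) span the junction with >= min_overhang matched bases on both sides?
read_spans_junction <- function(blocks, junction, strand, min_overhang) {
  if (nrow(blocks) < 2) return(FALSE)
  for (k in seq_len(nrow(blocks) - 1)) {
    b1 <- blocks[k, ]; b2 <- blocks[k + 1, ]
    if (strand == "+") {
      hit <- b1[2] == junction$donor_edge && b2[1] == junction$acceptor_edge
    } else {
      hit <- b1[1] == junction$donor_edge && b2[2] == junction$acceptor_edge
    }
    if (hit && (b1[2] - b1[1] + 1) >= min_overhang &&
        (b2[2] - b2[1] + 1) >= min_overhang) return(TRUE)
  }
  FALSE
}

#' Count junction-spanning short reads
#'
#' A read increments a junction iff two consecutive aligned blocks abut the
#' junction's donor and acceptor edges exactly and each flanking block
#' carries at least `min_overhang` matched bases. A read counts at most once
#' per junction, but a read spanning two different junctions increments both.
#'
#' @param alignments Data frame of spliced-read blocks with columns `sample`,
#'   `read_id`, `start`, `end` (1-based inclusive genomic block coordinates,
#'   one row per block), e.g. from [read_spliced_sam()].
#' @param junctions Data frame from [junction_defs()].
#' @param strand Strand of the locus (`"+"` or `"-"`).
#' @param min_overhang Minimum matched bases each side (default 8).
#' @param min_mapq Optional mapping-quality floor applied when `alignments`
#'   carries a `mapq` column (default 0, i.e. no filter).
#' @return Data frame `sample` x `junction` with raw `count`s (all declared
#'   samples x junctions present, zero-filled).
#' @export
count_junction_reads <- function(alignments, junctions, strand = "+",
                                 min_overhang = 8, min_mapq = 0) {
  samples <- unique(alignments$sample)
  if (!is.null(alignments$mapq))
    alignments <- alignments[alignments$mapq >= min_mapq, , drop = FALSE]
  grid <- expand.grid(sample = samples, junction = junctions$name,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$count <- rep(0L, nrow(grid))
  if (nrow(alignments)) {
    key <- paste(alignments$sample, alignments$read_id, sep = "\r")
    for (grp in split(alignments, key)) {
      ord <- order(grp$start, decreasing = (strand == "-"))
      blocks <- as.matrix(grp[ord, c("start", "end"), drop = FALSE])
      for (j in seq_len(nrow(junctions))) {
        if (read_spans_junction(blocks, junctions[j, ], strand, min_overhang)) {
          row <- grid$sample == grp$sample[1] & grid$junction == junctions$name[j]
          grid$count[row] <- grid$count[row] + 1L
        }
      }
    }
  }
  grid
}

#' Read spliced short-read alignments from SAM/BAM into a block table
#'
#' N operations in the CIGAR split a read into its genomic blocks.
#'
#' @param path SAM or BAM file.
#' @param sample Sample label attached to every read.
#' @return Data frame with `sample`, `read_id`, `mapq`, `start`, `end` (one
#'   row per aligned block), suitable for [count_junction_reads()].
#' @export
read_spliced_sam <- function(path, sample) {
  if (grepl("\\.sam$", tolower(path)))
    path <- Rsamtools::asBam(path, destination = tempfile(fileext = ""),
                             overwrite = TRUE, indexDestination = FALSE)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    path, param = Rsamtools::ScanBamParam(flag = flag, what = c("qname", "mapq")))
  gl <- GenomicAlignments::grglist(ga)  # per-read exonic blocks (N-separated)
  ul <- unlist(gl, use.names = FALSE)
  n_per <- S4Vectors::elementNROWS(gl)
  data.frame(
    sample = sample,
    read_id = rep(S4Vectors::mcols(ga)$qname, n_per),
    mapq = rep(S4Vectors::mcols(ga)$mapq, n_per),
    start = GenomicAlignments::start(ul),
    end = GenomicAlignments::end(ul),
    stringsAsFactors = FALSE)
}

#' Normalize junction counts to counts-per-FPKM
#'
#' The default reading of "counts per FPKM" divides the junction-spanning
#' read count by the locus-level FPKM of the gene in that sample, yielding a
#' within-sample expression-adjusted junction abundance. The alternative
#' `"cpm"` mode scales raw counts to counts per million mapped fragments
#' using the library size instead.
#'
#' @param counts Data frame from [count_junction_reads()] (`sample`,
#'   `junction`, `count`).
#' @param gene_fpkm Named numeric vector: locus FPKM per sample (`per_fpkm`
#'   mode).
#' @param library_size Named numeric vector: mapped fragments per sample
#'   (`cpm` mode).
#' @param mode `"per_fpkm"` (default) or `"cpm"`.
#' @return `counts` with added `normalized` and `flagged` columns; a sample
#'   with zero/missing denominator and a positive count is flagged and its
#'   normalized value is `NA`.
#' @export
normalize_counts <- function(counts, gene_fpkm = NULL, library_size = NULL,
                             mode = c("per_fpkm", "cpm")) {
  mode <- match.arg(mode)
  denom <- if (mode == "per_fpkm") gene_fpkm[counts$sample]
           else library_size[counts$sample] / 1e6
  denom <- as.numeric(denom)
  ok <- !is.na(denom) & denom > 0
  counts$normalized <- ifelse(ok, counts$count / denom,
                              ifelse(counts$count == 0, 0, NA_real_))
  counts$flagged <- !ok & counts$count > 0
  counts$denominator <- denom
  counts
}

#' Per-sample junction share of each isoform
#'
#' @param counts Data frame (`sample`, `junction`, and `count` or
#'   `normalized`).
#' @param use Column to form shares from (default `"count"`).
#' @return Data frame `sample`, `junction`, `share`; shares sum to 1 within
#'   every reportable sample. All-zero samples are dropped with a warning.
#' @export
isoform_share <- function(counts, use = "count") {
  totals <- tapply(counts[[use]], counts$sample, sum)
  zero <- names(totals)[is.na(totals) | totals == 0]
  if (length(zero))
    warning("sample(s) with no junction evidence dropped: ",
            paste(zero, collapse = ", "))
  keep <- !(counts$sample %in% zero)
  out <- counts[keep, c("sample", "junction"), drop = FALSE]
  out$share <- counts[[use]][keep] / as.numeric(totals[counts$sample[keep]])
  rownames(out) <- NULL
  out
}
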