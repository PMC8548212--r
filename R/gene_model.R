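#' Exon of a locus gene model
#'
#' @param id Exon label, e.g. `"SSR"`, `"SINE"`, `"E1"`.
#' @param interval A [genomic_interval()].
#' @param role One of `"novel_start"`, `"reference_first"`, `"internal"`,
#'   `"terminal"`.
#' @param annotated_start Optional 1-based position (within the exon, in
#'   transcript orientation) of the A of a putative ATG.
#' @param annotated_stop Optional 1-based position of the first base of a stop
#'   codon within the exon.
#' @return An object of class `exon`.
#' @export
exon <- function(id, interval, role = c("internal", "novel_start",
                                        "reference_first", "terminal"),
                 annotated_start = NA_real_, annotated_stop = NA_real_) {
  role <- match.arg(role)
  if (!inherits(interval, "genomic_interval")) stop("interval must be a genomic_interval")
  len <- interval_length(interval)
  for (p in c(annotated_start, annotated_stop)) {
    if (!is.na(p) && (p < 1 || p > len - 2))
      stop("annotated codon position ", p, " outside [1, ", len - 2,
           "] for exon ", id)
  }
  structure(list(id = as.character(id), interval = interval, role = role,
                 annotated_start = annotated_start,
                 annotated_stop = annotated_stop),
            class = "exon")
}

#' Locus gene model
#'
#' An ordered set of exons on one chromosome and strand, together with a
#' sequence accessor. Exons are kept in transcription order (increasing
#' coordinates on `+`, decreasing on `-`) and must not overlap.
#'
#' @param exons List of [exon()] objects in transcription order.
#' @param seq_accessor Function taking a [genomic_interval()] and returning
#'   the genome-forward nucleotide string for it, or `NULL` for a
#'   sequence-less model.
#' @return An object of class `gene_model`.
#' @seealso [splice()], [read_gene_model()], [gene_model_from_sequence()]
#' @export
gene_model <- function(exons, seq_accessor = NULL) {
  if (length(exons) < 1L) stop("need at least one exon")
  ids <- vapply(exons, function(e) e$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate exon ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  chrom <- unique(vapply(exons, function(e) e$interval$chrom, character(1)))
  strand <- unique(vapply(exons, function(e) e$interval$strand, character(1)))
  if (length(chrom) != 1L || length(strand) != 1L)
    stop("all exons must share one chromosome and strand")
  starts <- vapply(exons, function(e) e$interval$start, numeric(1))
  ends <- vapply(exons, function(e) e$interval$end, numeric(1))
  ord <- if (strand == "+") starts else -starts
  if (is.unsorted(ord, strictly = TRUE))
    stop("exons must be given in transcription order")
  # pairwise non-overlap: in genomic order, each start must exceed previous end
  g <- order(starts)
  if (any(starts[g][-1] <= ends[g][-length(g)]))
    stop("exon intervals overlap")
  structure(list(chrom = chrom, strand = strand, exons = exons,
                 seq_accessor = seq_accessor),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d exons on %s(%s)\n", length(x$exons), x$chrom, x$strand))
  for (e in x$exons)
    cat(sprintf("  %-6s %-15s %s-%s (%d nt)\n", e$id, e$role,
                format(e$interval$start, big.mark = ","),
                format(e$interval$end, big.mark = ","),
                interval_length(e$interval)))
  invisible(x)
}

exon_ids <- function(model) vapply(model$exons, function(e) e$id, character(1))

get_exon <- function(model, id) {
  i <- match(id, exon_ids(model))
  if (is.na(i)) stop("unknown exon id: ", id)
  model$exons[[i]]
}

#' Build a gene model whose sequences come from an in-memory genome
#'
#' @param exons List of [exon()] objects in transcription order.
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @return A `gene_model` with a sequence accessor over `genome`.
#' @export
gene_model_from_sequence <- function(exons, genome) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  acc <- function(iv) {
    if (!iv$chrom %in% names(genome)) stop("chromosome not in genome: ", iv$chrom)
    if (iv$end > nchar(genome[[iv$chrom]])) stop("interval beyond chromosome end")
    substr(genome[[iv$chrom]], iv$start, iv$end)
  }
  gene_model(exons, seq_accessor = acc)
}

#' Splice exons into a transcript sequence
#'
#' Concatenates the genome-forward sequences of the named exons in
#' transcription order and, on the minus strand, reverse-complements the
#' assembly once, so the returned sequence reads in transcript orientation.
#'
#' @param exon_ids_chr Character vector of exon ids, in transcription order.
#' @param model A [gene_model()] with a sequence accessor.
#' @return List with `seq` (nucleotide string) and `boundaries`, a data frame
#'   with one row per exon: `exon`, 1-based inclusive `start`/`end` and
#'   0-based half-open `start0`/`end0` in transcript coordinates, plus the
#'   genomic bounds.
#' @export
splice <- function(exon_ids_chr, model) {
  ids <- exon_ids(model)
  idx <- match(exon_ids_chr, ids)
  if (anyNA(idx)) stop("unknown exon id(s): ",
                       paste(exon_ids_chr[is.na(idx)], collapse = ", "))
  if (is.unsorted(idx, strictly = TRUE))
    stop("exon ids must be unique and in transcription order")
  exs <- model$exons[idx]
  if (is.null(model$seq_accessor)) stop("gene model has no sequence accessor")
  fwd <- vapply(exs, function(e) model$seq_accessor(e$interval), character(1))
  if (model$strand == "+") {
    seq <- paste0(fwd, collapse = "")
  } else {
    # transcription order on '-' is decreasing coordinates; assemble in genomic
    # order then reverse-complement the whole chain once
    seq <- revcomp(paste0(rev(fwd), collapse = ""))
  }
  lens <- vapply(exs, function(e) interval_length(e$interval), numeric(1))
  end0 <- cumsum(lens)
  start0 <- end0 - lens
  boundaries <- data.frame(
    exon = exon_ids_chr,
    start = start0 + 1, end = end0,
    start0 = start0, end0 = end0,
    genomic_start = vapply(exs, function(e) e$interval$start, numeric(1)),
    genomic_end = vapply(exs, function(e) e$interval$end, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(seq = seq, boundaries = boundaries)
}

#' Map a transcript coordinate back to its genomic position
#'
#' @param pos 1-based transcript position(s).
#' @param boundaries Boundary table from [splice()].
#' @param strand `"+"` or `"-"`.
#' @return Numeric vector of 1-based genomic positions.
#' @export
transcript_to_genomic <- function(pos, boundaries, strand = "+") {
  vapply(pos, function(p) {
    row <- which(boundaries$start <= p & boundaries$end >= p)
    if (length(row) != 1L) stop("transcript position ", p, " outside transcript")
    off <- p - boundaries$start[row]
    if (strand == "+") boundaries$genomic_start[row] + off
    else boundaries$genomic_end[row] - off
  }, numeric(1))
}

#' Transcription elongation time of a pre-mRNA
#'
#' A locus spanning hundreds of kilobases takes hours to transcribe at typical
#' RNA polymerase II elongation rates of 1-3 kb/min; for a ~600 kb pre-mRNA
#' that is between 3.3 and 10 h.
#'
#' @param length_kb Pre-mRNA (genomic) length in kilobases.
#' @param rate_kb_per_min Elongation rate in kb/min.
#' @param digits Decimal places for the rounded display value (half-up).
#' @return List with `hours` (full precision) and `hours_rounded`.
#' @examples
#' transcription_time(600, 1)$hours          # 10
#' transcription_time(600, 3)$hours_rounded  # 3.3
#' @export
transcription_time <- function(length_kb, rate_kb_per_min, digits = 1) {
  if (length_kb < 0) stop("length must be >= 0")
  if (rate_kb_per_min <= 0) stop("rate must be > 0")
  h <- length_kb / rate_kb_per_min / 60
  list(hours = h, hours_rounded = round_half_up(h, digits))
}
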