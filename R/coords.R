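#' Genomic interval in 1-based inclusive coordinates
#'
#' External files and reports use 1-based inclusive coordinates (the convention
#' of genome browsers and GFF3); internal arithmetic uses 0-based half-open
#' spans via [to_halfopen()] / [from_halfopen()] so that lengths and junction
#' offsets are plain differences.
#'
#' @param chrom Chromosome (sequence) name.
#' @param start,end 1-based inclusive positions, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `genomic_interval`.
#' @examples
#' iv <- genomic_interval("chr5", 51912715, 51912718)
#' interval_length(iv)  # 4
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) != 1L || length(start) != 1L || length(end) != 1L)
    stop("genomic_interval() takes scalar arguments")
  if (is.na(start) || is.na(end) || start < 1 || start > end)
    stop("invalid interval: need 1 <= start <= end, got [", start, ", ", end, "]")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

#' Length of a 1-based inclusive interval
#'
#' @param iv A [genomic_interval()].
#' @return Number of nucleotides, `end - start + 1`.
#' @export
interval_length <- function(iv) {
  if (!inherits(iv, "genomic_interval")) stop("iv must be a genomic_interval")
  iv$end - iv$start + 1
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s(%s) [%d nt]\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$strand, interval_length(x)))
  invisible(x)
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' @param start,end 1-based inclusive bounds.
#' @return `to_halfopen()`: list with `start0` (0-based) and `end0`
#'   (exclusive); `from_halfopen()` the inverse.
#' @keywords internal
#' @export
to_halfopen <- function(start, end) list(start0 = start - 1, end0 = end)

#' @rdname to_halfopen
#' @param start0,end0 0-based half-open bounds.
#' @export
from_halfopen <- function(start0, end0) list(start = start0 + 1, end = end0)
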