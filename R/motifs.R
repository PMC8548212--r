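#' Position weight matrix over A,C,G,T
#'
#' Builds a log-odds scoring matrix from a position frequency matrix (counts
#' or frequencies) against a background distribution:
#' `log2((f + pseudo) / (bg + pseudo))` per cell. The default scoring
#' threshold policy is a fraction (80%) of the motif's maximum achievable
#' log-odds score.
#'
#' @param pfm 4 x L numeric matrix with rownames A, C, G, T (counts or
#'   column-normalized frequencies), L >= 4.
#' @param id Motif identifier (e.g. `"ERE"`, `"PPARG-RE"`).
#' @param background Background nucleotide frequencies (length 4, sums to 1).
#' @param pseudo Pseudo-frequency added before the log (default 0.01).
#' @return Object of class `pwm` with `freq`, `logodds`, `max_score`,
#'   `min_score` and `width`.
#' @export
pwm <- function(pfm, id = "motif", background = rep(0.25, 4), pseudo = 0.01) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) stop("pfm must have 4 rows (A, C, G, T)")
  if (is.null(rownames(pfm))) rownames(pfm) <- c("A", "C", "G", "T")
  pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(pfm) < 4) stop("motif width must be >= 4")
  if (any(pfm < 0)) stop("pfm entries must be non-negative")
  freq <- sweep(pfm, 2, colSums(pfm), `/`)
  if (any(abs(colSums(freq) - 1) > 1e-9)) stop("frequency columns must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  logodds <- log2(sweep(freq + pseudo, 1, background + pseudo, `/`))
  structure(list(id = id, freq = freq, logodds = logodds,
                 background = background,
                 max_score = sum(apply(logodds, 2, max)),
                 min_score = sum(apply(logodds, 2, min)),
                 width = ncol(freq)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: width %d, score range [%.2f, %.2f]\n",
              x$id, x$width, x$min_score, x$max_score))
  invisible(x)
}

#' Reverse complement of a PWM
#' @param x A [pwm()].
#' @return The reverse-complement `pwm` (scans the minus strand).
#' @export
revcomp_pwm <- function(x) {
  rc <- x$freq[c("T", "G", "C", "A"), rev(seq_len(x$width)), drop = FALSE]
  rownames(rc) <- c("A", "C", "G", "T")
  pwm(rc, id = paste0(x$id, "_rc"), background = x$background)
}

#' Read JASPAR-style PFM text
#'
#' Accepts the common JASPAR layouts: a `>ID name` header followed by four
#' rows, either bracketed (`A [ 3 5 ... ]`) or bare counts.
#'
#' @param path PFM text file (may contain several motifs).
#' @param background,pseudo Passed to [pwm()].
#' @return Named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudo = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers in ", path)
  out <- lapply(seq_along(heads), function(i) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    block <- lines[from:to]
    if (length(block) < 4) stop("motif block with fewer than 4 rows")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    pwm(m, id = id, background = background, pseudo = pseudo)
  })
  names(out) <- vapply(out, function(p) p$id, character(1))
  out
}

#' Extract strand-oriented promoter windows around TSSs
#'
#' Windows cover TSS +/- `flank`; minus-strand windows are
#' reverse-complemented so position 1 is the most upstream base. Windows
#' running off a chromosome end are clipped and flagged.
#'
#' @param tss Data frame with `gene`, `chrom`, `position` (1-based TSS),
#'   `strand`.
#' @param genome Named character vector or `DNAStringSet` of chromosomes.
#' @param flank Flank length in nt (default 1000).
#' @return Data frame: `gene`, `seq`, `start`, `end` (genomic bounds of the
#'   extracted window), `strand`, `clipped`.
#' @export
extract_promoters <- function(tss, genome, flank = 1000) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  rows <- lapply(seq_len(nrow(tss)), function(i) {
    chrom <- tss$chrom[i]
    if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
    L <- nchar(genome[[chrom]])
    p <- tss$position[i]
    if (p < 1 || p > L) stop("TSS off chromosome for gene ", tss$gene[i])
    s <- max(1, p - flank); e <- min(L, p + flank)
    seq <- substr(genome[[chrom]], s, e)
    if (tss$strand[i] == "-") seq <- revcomp(seq)
    data.frame(gene = tss$gene[i], seq = seq, start = s, end = e,
               strand = tss$strand[i],
               clipped = (p - flank < 1) || (p + flank > L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

encode_dna <- function(seq) {
  # A=1 C=2 G=3 T=4, N (and anything else) = 5
  code <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

score_offsets <- function(code, logodds) {
  w <- ncol(logodds)
  n_off <- length(code) - w + 1
  if (n_off < 1) return(numeric(0))
  lut <- rbind(logodds, 0)  # row 5: N contributes 0 log-odds
  scores <- numeric(n_off)
  for (j in seq_len(w))
    scores <- scores + lut[cbind(code[j:(j + n_off - 1)], j)]
  scores
}

#' Scan a sequence with a PWM on both strands
#'
#' The log-odds score is computed at every offset on the forward sequence
#' and, via the reverse-complement matrix, on the reverse strand; positions
#' with N contribute zero log-odds (background). Offsets are 1-based
#' positions of the motif's leftmost base in the forward window; minus-strand
#' hits are reported at their mirrored forward offset.
#'
#' @param window Nucleotide string over A,C,G,T,N.
#' @param motif A [pwm()].
#' @param threshold Absolute log-odds threshold; default 80% of the motif's
#'   maximum achievable score.
#' @param both_strands Scan the reverse strand as well (default `TRUE`).
#' @return Data frame of hits: `offset`, `strand`, `score` (all `>=
#'   threshold`); zero rows when the window is shorter than the motif.
#' @export
scan_pwm <- function(window, motif, threshold = 0.8 * motif$max_score,
                     both_strands = TRUE) {
  window <- toupper(window)
  code <- encode_dna(window)
  fwd <- score_offsets(code, motif$logodds)
  keep_f <- which(fwd >= threshold)
  hits <- data.frame(offset = keep_f, strand = rep("+", length(keep_f)),
                     score = fwd[keep_f], stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- revcomp_pwm(motif)
    rev_scores <- score_offsets(code, rc$logodds)
    keep_r <- which(rev_scores >= threshold)
    hits <- rbind(hits, data.frame(offset = keep_r,
                                   strand = rep("-", length(keep_r)),
                                   score = rev_scores[keep_r],
                                   stringsAsFactors = FALSE))
  }
  rownames(hits) <- NULL
  hits[order(hits$offset), , drop = FALSE]
}

#' Scan a promoter table for one motif
#'
#' @param promoters Data frame from [extract_promoters()].
#' @param motif A [pwm()].
#' @param threshold Passed to [scan_pwm()].
#' @return Data frame of hits with `gene`, `motif`, `offset`, `strand`,
#'   `score`.
#' @export
scan_promoters <- function(promoters, motif,
                           threshold = 0.8 * motif$max_score) {
  rows <- lapply(seq_len(nrow(promoters)), function(i) {
    h <- scan_pwm(promoters$seq[i], motif, threshold)
    if (!nrow(h)) return(NULL)
    cbind(gene = promoters$gene[i], motif = motif$id, h,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(0), motif = character(0),
                      offset = numeric(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Motif presence per gene set
#'
#' A gene is motif-bearing when it has at least one hit, regardless of hit
#' multiplicity.
#'
#' @param hits Hits data frame with a `gene` column (e.g. from
#'   [scan_promoters()]).
#' @param gene_sets Named list of character vectors of gene ids.
#' @return List: `fractions` (data frame `set`, `n`, `with_motif`,
#'   `fraction`; empty sets flagged) and `tables` (named list of 2 x 2
#'   contingency matrices, one per unordered set pair, rows = sets, columns
#'   = with/without motif).
#' @export
presence_table <- function(hits, gene_sets) {
  bearing <- unique(hits$gene)
  fractions <- do.call(rbind, lapply(names(gene_sets), function(s) {
    g <- unique(gene_sets[[s]])
    data.frame(set = s, n = length(g), with_motif = sum(g %in% bearing),
               fraction = if (length(g)) mean(g %in% bearing) else NA_real_,
               empty = length(g) == 0, stringsAsFactors = FALSE)
  }))
  rownames(fractions) <- NULL
  tables <- list()
  ns <- names(gene_sets)
  if (length(ns) >= 2) {
    for (i in seq_len(length(ns) - 1)) for (j in seq((i + 1), length(ns))) {
      a <- fractions[fractions$set == ns[i], ]
      b <- fractions[fractions$set == ns[j], ]
      m <- matrix(c(a$with_motif, a$n - a$with_motif,
                    b$with_motif, b$n - b$with_motif),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c(ns[i], ns[j]), c("with", "without")))
      tables[[paste(ns[i], ns[j], sep = " vs ")]] <- m
    }
  }
  list(fractions = fractions, tables = tables)
}

#' Pearson chi-square enrichment test on a 2 x 2 table
#'
#' Pearson's chi-square without continuity correction, df = 1. All marginals
#' must be positive.
#'
#' @param table 2 x 2 matrix of counts (rows = gene sets, columns =
#'   with/without motif).
#' @return List of class `enrichment_result`: `statistic`, `p_value`, `df`,
#'   `counts`, `proportions` (per-row motif-bearing fraction).
#' @export
chi_square_enrichment <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2 x 2 table")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal: chi-square undefined")
  ht <- stats::chisq.test(table, correct = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value, df = unname(ht$parameter),
                 counts = table,
                 proportions = table[, 1] / rowSums(table)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: chi-square %.4g (df %d), p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  proportions with motif: %s\n",
              paste(sprintf("%s %.3f", names(x$proportions), x$proportions),
                    collapse = ", ")))
  invisible(x)
}
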