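#' Differential-expression gate configuration
#'
#' Thresholds of the signal-to-noise-ratio gated factorial analysis: omnibus
#' ANOVA FDR below `fdr_alpha`, a grand-mean effect-size gate at
#' `snr_lfc` (|log2FC| > 0.286, the SNR > 1 threshold), a practical-difference
#' gate on pairwise contrasts at `practical_lfc` (|log2FC| > 0.094, a 5%
#' difference), and a post hoc pairwise alpha.
#'
#' @param fdr_alpha ANOVA FDR threshold (default 0.05).
#' @param snr_lfc Grand-mean |log2FC| gate (default 0.286).
#' @param practical_lfc Pairwise |log2FC| gate (default 0.094).
#' @param posthoc_alpha Post hoc pairwise p threshold (default 0.05).
#' @return List of class `de_config`.
#' @export
de_config <- function(fdr_alpha = 0.05, snr_lfc = 0.286,
                      practical_lfc = 0.094, posthoc_alpha = 0.05) {
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, posthoc_alpha > 0, posthoc_alpha < 1,
            snr_lfc > 0, practical_lfc > 0)
  structure(list(fdr_alpha = fdr_alpha, snr_lfc = snr_lfc,
                 practical_lfc = practical_lfc, posthoc_alpha = posthoc_alpha),
            class = "de_config")
}

check_design <- function(design) {
  needed <- c("sample", "sex", "genotype", "organ")
  if (!all(needed %in% names(design)))
    stop("design needs columns: ", paste(needed, collapse = ", "))
  stopifnot(all(design$sex %in% c("M", "F")),
            all(design$genotype %in% c("WT", "KO")),
            all(design$organ %in% c("Cb", "Br")))
  grp <- interaction(design$sex, design$genotype, design$organ,
                     sep = ".", drop = FALSE)
  tab <- table(grp)
  if (length(tab) != 8 || any(tab == 0))
    stop("design must be full factorial: every sex x genotype x organ cell present")
  if (any(tab < 2)) stop("need >= 2 replicates per cell")
  factor(grp)
}

#' Fit the per-probe 2^3 full-factorial ANOVA
#'
#' For every probe, a fixed-effects omnibus ANOVA across the 8
#' sex x genotype x organ groups (the saturated three-factor model, so the
#' omnibus F equals the one-way F over the 8 cells), group-versus-grand-mean
#' log2 fold changes, Benjamini-Hochberg FDR across probes, and Welch
#' two-sample post hoc t-tests for the requested contrasts (default: WT
#' versus KO within each sex x organ cell).
#'
#' @param mat Numeric matrix of log2-scale intensities, probes x samples;
#'   column names must match `design$sample`.
#' @param design Data frame with `sample`, `sex` (`M`/`F`), `genotype`
#'   (`WT`/`KO`), `organ` (`Cb`/`Br`); full factorial, >= 2 replicates/cell.
#' @param contrasts Named list of length-2 character vectors
#'   `c(group1, group2)` in `sex.genotype.organ` notation; the contrast
#'   log2FC is group2 minus group1.
#' @return Object of class `factorial_anova_fit`: per-probe `results`
#'   (omnibus `p`, BH `q`, `flagged` for undefined variance),
#'   `group_means`, `lfc_grand` (probes x groups), and per-contrast post hoc
#'   tables (`lfc`, `p`).
#' @export
fit_factorial_anova <- function(mat, design, contrasts = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("probe", seq_len(nrow(mat)))
  if (!all(design$sample %in% colnames(mat)))
    stop("design samples missing from matrix columns")
  mat <- mat[, design$sample, drop = FALSE]
  if (any(!is.finite(mat))) stop("expression matrix must be finite")
  grp <- check_design(design)
  levels_g <- levels(grp)
  S <- ncol(mat); G <- length(levels_g)
  n_g <- as.numeric(table(grp)[levels_g])

  # per-group means and within-group sums of squares, vectorised over probes
  gm <- sapply(levels_g, function(g) rowMeans(mat[, grp == g, drop = FALSE]))
  gv <- sapply(levels_g, function(g) {
    x <- mat[, grp == g, drop = FALSE]
    rowSums((x - rowMeans(x))^2) / (ncol(x) - 1)
  })
  if (!is.matrix(gm)) {  # single-probe input
    gm <- matrix(gm, nrow = 1, dimnames = list(rownames(mat), levels_g))
    gv <- matrix(gv, nrow = 1, dimnames = list(rownames(mat), levels_g))
  }
  grand <- rowMeans(mat)
  ss_between <- rowSums(sweep((gm - grand)^2, 2, n_g, `*`))
  ss_within <- rowSums(sweep(gv, 2, n_g - 1, `*`))
  df1 <- G - 1; df2 <- S - G
  msw <- ss_within / df2
  flagged <- msw <= 0 | !is.finite(msw)
  fstat <- ifelse(flagged, NA_real_, (ss_between / df1) / msw)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")

  if (is.null(contrasts)) {
    cells <- expand.grid(sex = c("M", "F"), organ = c("Cb", "Br"),
                         stringsAsFactors = FALSE)
    contrasts <- stats::setNames(
      lapply(seq_len(nrow(cells)), function(i)
        c(paste(cells$sex[i], "WT", cells$organ[i], sep = "."),
          paste(cells$sex[i], "KO", cells$organ[i], sep = "."))),
      paste0(cells$sex, ".", cells$organ, ":KO-WT"))
  }
  posthoc <- lapply(contrasts, function(ct) {
    i1 <- match(ct[1], levels_g); i2 <- match(ct[2], levels_g)
    if (is.na(i1) || is.na(i2)) stop("contrast names unknown group: ",
                                     paste(ct, collapse = " vs "))
    se2 <- gv[, i1] / n_g[i1] + gv[, i2] / n_g[i2]
    tt <- (gm[, i2] - gm[, i1]) / sqrt(se2)
    df_w <- se2^2 / ((gv[, i1] / n_g[i1])^2 / (n_g[i1] - 1) +
                       (gv[, i2] / n_g[i2])^2 / (n_g[i2] - 1))
    data.frame(probe = rownames(mat),
               lfc = gm[, i2] - gm[, i1],
               p = 2 * stats::pt(abs(tt), df_w, lower.tail = FALSE),
               stringsAsFactors = FALSE, row.names = NULL)
  })

  structure(list(
    results = data.frame(probe = rownames(mat), p = p, q = q,
                         flagged = flagged, stringsAsFactors = FALSE,
                         row.names = NULL),
    group_means = gm, group_vars = gv, grand_mean = grand,
    lfc_grand = gm - grand, n_per_group = stats::setNames(n_g, levels_g),
    posthoc = posthoc, design = design, groups = levels_g,
    df = c(df1 = df1, df2 = df2)),
    class = "factorial_anova_fit")
}

#' @export
print.factorial_anova_fit <- function(x, ...) {
  cat(sprintf("factorial_anova_fit: %d probes, %d samples, %d groups (df %d/%d)\n",
              nrow(x$results), nrow(x$design), length(x$groups),
              x$df["df1"], x$df["df2"]))
  cat(sprintf("  omnibus FDR < 0.05: %d probes; %d flagged (undefined variance)\n",
              sum(x$results$q < 0.05, na.rm = TRUE), sum(x$results$flagged)))
  cat("  contrasts:", paste(names(x$posthoc), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.factorial_anova_fit <- function(object, config = de_config(), ...) {
  calls <- call_differential(object, config)
  by_ct <- split(calls, calls$contrast)
  out <- data.frame(
    contrast = names(by_ct),
    multivariate_significant = vapply(by_ct, function(d)
      sum(d$multivariate_significant), integer(1)),
    pairwise_differential = vapply(by_ct, function(d)
      sum(d$pairwise_differential), integer(1)),
    robust = vapply(by_ct, function(d) sum(d$robust), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  print(object)
  print(out)
  invisible(out)
}

#' Apply the differential-expression gates
#'
#' Flags per probe and contrast: `multivariate_significant` iff the omnibus
#' FDR q is below `fdr_alpha` and the largest |group-vs-grand-mean log2FC|
#' exceeds `snr_lfc`; `pairwise_differential` iff additionally the post hoc p
#' is below `posthoc_alpha` and the |pairwise log2FC| exceeds
#' `practical_lfc`; `robust` iff pairwise-differential with |pairwise log2FC|
#' above `snr_lfc`. All flags are recomputable from the stored numbers.
#'
#' @param fit A [fit_factorial_anova()] result.
#' @param config A [de_config()].
#' @return Data frame, one row per probe x contrast: `probe`, `contrast`,
#'   `log2FC` (pairwise), `max_abs_lfc_grand`, `anova_q`, `posthoc_p`, and
#'   the three logical flags.
#' @export
call_differential <- function(fit, config = de_config()) {
  stopifnot(inherits(fit, "factorial_anova_fit"), inherits(config, "de_config"))
  max_abs <- apply(abs(fit$lfc_grand), 1, max)
  mv <- !is.na(fit$results$q) & fit$results$q < config$fdr_alpha &
    max_abs > config$snr_lfc
  out <- do.call(rbind, lapply(names(fit$posthoc), function(ct) {
    ph <- fit$posthoc[[ct]]
    pw <- mv & !is.na(ph$p) & ph$p < config$posthoc_alpha &
      abs(ph$lfc) > config$practical_lfc
    data.frame(probe = ph$probe, contrast = ct, log2FC = ph$lfc,
               max_abs_lfc_grand = max_abs, anova_q = fit$results$q,
               posthoc_p = ph$p,
               multivariate_significant = mv,
               pairwise_differential = pw,
               robust = pw & abs(ph$lfc) > config$snr_lfc,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' Curate probes against annotation quality
#'
#' Keeps probes mapping to exactly one non-RIKEN gene symbol; probes mapping
#' to RIKEN cDNA clones, to multiple genes, or to no gene (including probes
#' absent from the annotation) are removed and tallied per category.
#'
#' @param probes Character vector of probe ids.
#' @param annotation Data frame with `probe` and `symbols` (comma-separated
#'   gene symbols, empty/`NA` for none) and optionally `riken` (logical;
#'   otherwise symbols ending in `"Rik"` are treated as RIKEN clones).
#' @return List: `kept` (probe ids), `removed` (named counts: `riken`,
#'   `multi_gene`, `no_gene`), `table` (per-probe category).
#' @export
curate_probes <- function(probes, annotation) {
  idx <- match(probes, annotation$probe)
  syms <- ifelse(is.na(idx), "", annotation$symbols[idx])
  syms[is.na(syms)] <- ""
  sym_list <- strsplit(syms, "\\s*,\\s*")
  sym_list <- lapply(sym_list, function(s) s[nzchar(s)])
  n_sym <- lengths(sym_list)
  riken <- if ("riken" %in% names(annotation)) {
    ifelse(is.na(idx), FALSE, annotation$riken[idx]) & n_sym == 1
  } else {
    vapply(sym_list, function(s) length(s) == 1 && grepl("Rik$", s), logical(1))
  }
  category <- ifelse(n_sym == 0, "no_gene",
                     ifelse(n_sym > 1, "multi_gene",
                            ifelse(riken, "riken", "keep")))
  list(kept = probes[category == "keep"],
       removed = c(riken = sum(category == "riken"),
                   multi_gene = sum(category == "multi_gene"),
                   no_gene = sum(category == "no_gene")),
       table = data.frame(probe = probes, category = category,
                          stringsAsFactors = FALSE))
}

#' PCA of the significant-probe expression matrix
#'
#' Centered principal component analysis over samples (samples are the
#' observations, probes the variables). Deterministic up to component sign.
#'
#' @param mat Probes x samples matrix restricted to significant probes
#'   (>= 2 probes, >= 3 samples).
#' @return List of class `pca_summary`: `var_explained` (percent, per
#'   retained component, non-increasing, summing to <= 100), `scores`
#'   (samples x components), `rank_deficient` flag (zero-variance components
#'   were dropped).
#' @export
pca_on_significant <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 3)
    stop("need >= 2 probes and >= 3 samples for PCA")
  pc <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  keep <- pc$sdev^2 > 1e-12 * tot
  structure(list(
    var_explained = 100 * pc$sdev[keep]^2 / tot,
    scores = pc$x[, keep, drop = FALSE],
    rank_deficient = any(!keep)),
    class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("pca_summary:", length(x$var_explained), "components;",
      "variance explained (%):",
      paste(sprintf("%.1f", x$var_explained[seq_len(min(5, length(x$var_explained)))]),
            collapse = ", "),
      if (x$rank_deficient) "(rank deficient)" else "", "\n")
  invisible(x)
}

#' Cluster differential probes into expression patterns
#'
#' Agglomerative hierarchical clustering of per-probe group-mean log2FC
#' profiles under correlation distance (1 - Pearson r) with average linkage,
#' cut into `k` clusters. Emits per-cluster log2FC min, max and
#' interquartile range.
#'
#' @param profiles Probes x groups matrix of log2FC profiles (e.g.
#'   `fit$lfc_grand` restricted to curated differential probes).
#' @param k Number of patterns (default 4).
#' @param cut_height Optional dendrogram cut height used instead of `k`.
#' @return List of class `pattern_clusters`: `assignments` (data frame
#'   `probe`, `cluster`), `summary` (per-cluster `n`, `lfc_min`, `lfc_max`,
#'   `lfc_q1`, `lfc_q3`), and the `hclust` tree.
#' @export
cluster_patterns <- function(profiles, k = 4, cut_height = NULL) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("probe", seq_len(nrow(profiles)))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(profiles)) stop("k exceeds probe count")
  if (nrow(profiles) == 1L || k == 1L) {
    cl <- stats::setNames(rep(1L, nrow(profiles)), rownames(profiles))
    tree <- NULL
    if (nrow(profiles) > 1) {
      d <- stats::as.dist(1 - stats::cor(t(profiles)))
      tree <- stats::hclust(d, method = "average")
    }
  } else {
    d <- stats::as.dist(1 - stats::cor(t(profiles)))
    if (any(is.na(d))) stop("constant profile rows give undefined correlation")
    tree <- stats::hclust(d, method = "average")
    cl <- if (is.null(cut_height)) stats::cutree(tree, k = k)
          else stats::cutree(tree, h = cut_height)
  }
  assignments <- data.frame(probe = rownames(profiles), cluster = unname(cl),
                            stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(g) {
    v <- profiles[cl == g, , drop = FALSE]
    qs <- stats::quantile(v, c(0.25, 0.75))
    data.frame(cluster = g, n = sum(cl == g), lfc_min = min(v),
               lfc_max = max(v), lfc_q1 = unname(qs[1]), lfc_q3 = unname(qs[2]),
               row.names = NULL)
  }))
  structure(list(assignments = assignments, summary = summ, tree = tree),
            class = "pattern_clusters")
}

#' @export
print.pattern_clusters <- function(x, ...) {
  cat("pattern_clusters:", nrow(x$assignments), "probes in",
      nrow(x$summary), "clusters\n")
  print(x$summary)
  invisible(x)
}

#' Quantile-normalize an expression matrix (utility)
#'
#' The factorial stage accepts already-normalized intensities; this helper is
#' provided for inputs that still need cross-sample quantile normalization.
#'
#' @param mat Probes x samples numeric matrix.
#' @return Matrix of the same shape with identical column distributions
#'   (ties receive the mean reference quantile).
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  ranks <- apply(mat, 2, rank, ties.method = "average")
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(ranks, 2, function(r) stats::approx(seq_along(ref), ref, r)$y)
  dimnames(out) <- dimnames(mat)
  out
}
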