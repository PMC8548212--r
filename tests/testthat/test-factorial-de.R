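null_dataset <- function(n_probes, seed, sigma = 0.3) {
  spec <- fixture_spec(seed = seed,
                       expression = list(probes_per_cluster = 0, n_null = n_probes,
                                         sigma = sigma))
  simulate_expression(spec)
}

test_that("constant probes are flagged with zero fold changes", {
  ex <- null_dataset(5, seed = 2)
  ex$mat[1, ] <- 8
  fit <- fit_factorial_anova(ex$mat, ex$design)
  expect_true(fit$results$flagged[1])
  expect_true(is.na(fit$results$p[1]))
  expect_equal(unname(fit$lfc_grand[1, ]), rep(0, 8))
  expect_false(any(fit$results$flagged[-1]))
})

test_that("omnibus p-values agree with per-probe aov on a small dataset", {
  ex <- null_dataset(20, seed = 3)
  fit <- fit_factorial_anova(ex$mat, ex$design)
  grp <- factor(paste(ex$design$sex, ex$design$genotype, ex$design$organ,
                      sep = "."))
  for (i in c(1, 7, 20)) {
    a <- stats::anova(stats::lm(ex$mat[i, ] ~ grp))
    expect_equal(fit$results$p[i], a$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the hand-rolled step-up oracle", {
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(5:200, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-12)
  }
  ex <- null_dataset(50, seed = 5)
  fit <- fit_factorial_anova(ex$mat, ex$design)
  expect_equal(fit$results$q, oracle_bh(fit$results$p), tolerance = 1e-12)
})

test_that("type-I error of the omnibus test is near nominal under the null", {
  ex <- null_dataset(1000, seed = 6)
  fit <- fit_factorial_anova(ex$mat, ex$design)
  frac <- mean(fit$results$p < 0.05)
  half <- 2.576 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), half)
  expect_equal(sum(call_differential(fit)$pairwise_differential), 0)
})

test_that("a planted 1-log2 shift is detected with high power", {
  profiles <- matrix(0, 1, 8,
                     dimnames = list("up", colnames(default_profiles_test())))
  profiles["up", "F.KO.Cb"] <- 1
  # n = 4 per group: the omnibus F at n = 2 has analytic power ~0.75 for this
  # effect before FDR, so the high-power regime requires the larger replication
  spec <- fixture_spec(seed = 8,
                       expression = list(probes_per_cluster = 100, n_null = 100,
                                         sigma = 0.25, replicates = 4,
                                         profiles = profiles))
  ex <- simulate_expression(spec)
  fit <- fit_factorial_anova(ex$mat, ex$design)
  calls <- call_differential(fit)
  mv <- unique(calls[, c("probe", "multivariate_significant")])
  shifted <- ex$truth$probe[ex$truth$cluster == 1]
  expect_gt(mean(mv$multivariate_significant[match(shifted, mv$probe)]), 0.9)
  # fold-change estimates essentially unbiased
  bias <- fit$lfc_grand[shifted, "F.KO.Cb"] - (1 - 1 / 8)
  expect_lt(mean(abs(mean(bias))), 0.05)
})

test_that("gate logic follows the three-threshold cascade", {
  mk_fit <- function(q, lfc_grand, posthoc_p, pair_lfc) {
    structure(list(
      results = data.frame(probe = "p1", p = q, q = q, flagged = FALSE),
      lfc_grand = matrix(lfc_grand, 1, 1, dimnames = list("p1", "g")),
      posthoc = list(ct = data.frame(probe = "p1", lfc = pair_lfc,
                                     p = posthoc_p))),
      class = "factorial_anova_fit")
  }
  # |lfc| 0.20 fails the 0.286 SNR gate despite q = 0.01
  r <- call_differential(mk_fit(0.01, 0.20, 0.001, 0.20))
  expect_false(r$multivariate_significant)
  # |lfc| 0.30 with q 0.01 and post hoc 0.001 passes all gates
  r <- call_differential(mk_fit(0.01, 0.30, 0.001, 0.30))
  expect_true(r$multivariate_significant && r$pairwise_differential && r$robust)
  # q = 0.2 blocks everything
  r <- call_differential(mk_fit(0.2, 3, 1e-6, 3))
  expect_false(any(r$multivariate_significant, r$pairwise_differential, r$robust))
  # pairwise lfc between 0.094 and 0.286: differential but not robust
  r <- call_differential(mk_fit(0.01, 0.30, 0.001, 0.15))
  expect_true(r$pairwise_differential)
  expect_false(r$robust)
})

test_that("flags are recomputable from the stored numbers", {
  ex <- null_dataset(100, seed = 9)
  ex$mat[1:10, ex$design$genotype == "KO" & ex$design$organ == "Cb"] <-
    ex$mat[1:10, ex$design$genotype == "KO" & ex$design$organ == "Cb"] + 1
  fit <- fit_factorial_anova(ex$mat, ex$design)
  cfg <- de_config()
  calls <- call_differential(fit, cfg)
  manual_mv <- calls$anova_q < cfg$fdr_alpha &
    calls$max_abs_lfc_grand > cfg$snr_lfc
  expect_equal(calls$multivariate_significant, manual_mv)
  manual_pw <- manual_mv & calls$posthoc_p < cfg$posthoc_alpha &
    abs(calls$log2FC) > cfg$practical_lfc
  expect_equal(calls$pairwise_differential, manual_pw)
  expect_equal(calls$robust, manual_pw & abs(calls$log2FC) > cfg$snr_lfc)
})

test_that("probe curation removes RIKEN, multi-gene and no-gene probes", {
  ann <- data.frame(
    probe = c("p1", "p2", "p3", "p4", "p5"),
    symbols = c("Gria1", "Gria1,Gria2", "", "2310067B10Rik", "Cplx2"),
    stringsAsFactors = FALSE)
  cur <- curate_probes(c("p1", "p2", "p3", "p4", "p5", "p6"), ann)
  expect_equal(cur$kept, c("p1", "p5"))
  expect_equal(cur$removed, c(riken = 1L, multi_gene = 1L, no_gene = 2L))
  all_ok <- curate_probes(c("p1", "p5"), ann)
  expect_equal(all_ok$kept, c("p1", "p5"))
})

test_that("PCA separates a strong organ axis from a weaker sex axis", {
  groups <- colnames(default_profiles_test())
  profiles <- rbind(
    organ = ifelse(grepl("Cb$", groups), 2, -2),
    sex = ifelse(grepl("^F", groups), 0.6, -0.6))
  colnames(profiles) <- groups
  spec <- fixture_spec(seed = 10,
                       expression = list(probes_per_cluster = 60, n_null = 0,
                                         sigma = 0.2, profiles = profiles))
  ex <- simulate_expression(spec)
  pca <- pca_on_significant(ex$mat)
  expect_true(all(diff(pca$var_explained) <= 1e-9))
  expect_lte(sum(pca$var_explained), 100 + 1e-9)
  organ <- ex$design$organ[match(rownames(pca$scores), ex$design$sample)]
  sex <- ex$design$sex[match(rownames(pca$scores), ex$design$sample)]
  # PC1 separates organs, PC2 sexes, each with a clean margin
  expect_true(max(pca$scores[organ == "Cb", 1]) <
                min(pca$scores[organ == "Br", 1]) ||
              min(pca$scores[organ == "Cb", 1]) >
                max(pca$scores[organ == "Br", 1]))
  expect_true(max(pca$scores[sex == "F", 2]) < min(pca$scores[sex == "M", 2]) ||
              min(pca$scores[sex == "F", 2]) > max(pca$scores[sex == "M", 2]))
})

test_that("duplicated samples drop a zero-variance component", {
  ex <- null_dataset(30, seed = 11)
  mat <- cbind(ex$mat, dup = ex$mat[, 1])
  pca <- pca_on_significant(mat)
  expect_true(pca$rank_deficient)
  expect_error(pca_on_significant(ex$mat[1, , drop = FALSE]), ">= 2 probes")
})

test_that("planted patterns are recovered by correlation clustering", {
  spec <- fixture_spec(seed = 12,
                       expression = list(probes_per_cluster = 50, n_null = 0,
                                         sigma = 0.25))
  ex <- simulate_expression(spec)
  fit <- fit_factorial_anova(ex$mat, ex$design)
  cl <- cluster_patterns(fit$lfc_grand, k = 4)
  ari <- mclust::adjustedRandIndex(cl$assignments$cluster, ex$truth$cluster)
  expect_gt(ari, 0.9)
  expect_equal(sort(unique(cl$assignments$cluster)), 1:4)
  expect_true(all(c("lfc_min", "lfc_max", "lfc_q1", "lfc_q3") %in%
                    names(cl$summary)))
  # invariance under probe permutation
  perm <- sample(nrow(fit$lfc_grand))
  cl2 <- cluster_patterns(fit$lfc_grand[perm, ], k = 4)
  ari_perm <- mclust::adjustedRandIndex(
    cl2$assignments$cluster[match(cl$assignments$probe, cl2$assignments$probe)],
    cl$assignments$cluster)
  expect_equal(ari_perm, 1)
  one <- cluster_patterns(fit$lfc_grand[1:5, ], k = 1)
  expect_equal(unique(one$assignments$cluster), 1L)
  expect_error(cluster_patterns(fit$lfc_grand[1:3, ], k = 5), "exceeds")
})

test_that("quantile normalization equalizes column distributions", {
  set.seed(13)
  mat <- matrix(rnorm(200, sd = c(1, 3)), 50, 4)
  qn <- quantile_normalize(mat)
  for (j in 2:4) expect_equal(sort(qn[, 1]), sort(qn[, j]), tolerance = 1e-9)
})
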