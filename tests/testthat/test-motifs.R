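consensus_pwm_test <- function(consensus, id = "m") {
  counts <- vapply(strsplit(consensus, "")[[1]], function(b) {
    v <- setNames(rep(2, 4), c("A", "C", "G", "T")); v[b] <- 94; v
  }, numeric(4))
  rownames(counts) <- c("A", "C", "G", "T")
  pwm(counts, id = id)
}

test_that("pwm construction validates and normalizes frequencies", {
  m <- consensus_pwm_test("ACGTACGT")
  expect_equal(unname(colSums(m$freq)), rep(1, 8), tolerance = 1e-12)
  expect_gt(m$max_score, m$min_score)
  expect_error(pwm(matrix(1, 3, 6)), "4 rows")
  expect_error(pwm(matrix(1, 4, 3)), "width")
})

test_that("JASPAR-style PFM text parses in bracketed and bare layouts", {
  txt <- c(">M1 first",
           "A [ 10  0  2 90 ]",
           "C [  5  0  3  2 ]",
           "G [ 80  5 90  4 ]",
           "T [  5 95  5  4 ]",
           ">M2",
           "1 2 3 4 5",
           "4 3 2 1 5",
           "1 1 1 1 1",
           "4 4 4 4 1")
  f <- tempfile(fileext = ".jaspar")
  writeLines(txt, f)
  pw <- read_jaspar(f)
  expect_equal(names(pw), c("M1", "M2"))
  expect_equal(pw$M1$width, 4)
  expect_equal(pw$M2$width, 5)
  expect_equal(unname(pw$M1$freq["G", 1]), 0.8)
  shipped <- read_jaspar(system.file("extdata", "synthetic_motifs.jaspar",
                                     package = "fusionsplice"))
  expect_equal(names(shipped), c("ERE_synthetic", "PPARGRE_synthetic"))
  expect_equal(shipped$ERE_synthetic$width, 15)
})

test_that("promoter windows are strand-oriented and clip at chromosome ends", {
  set.seed(21)
  chrom <- paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE),
                 collapse = "")
  genome <- c(chr1 = chrom)
  tss <- data.frame(gene = c("gp", "gm", "gc"), chrom = "chr1",
                    position = c(5000, 5000, 500),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  pr <- extract_promoters(tss, genome, flank = 1000)
  expect_equal(pr$start[1], 4000)
  expect_equal(pr$end[1], 6000)
  expect_equal(nchar(pr$seq[1]), 2001)
  expect_false(pr$clipped[1])
  # minus strand equals the reverse complement of the plus-strand oracle
  expect_equal(pr$seq[2], oracle_revcomp(pr$seq[1]))
  expect_true(pr$clipped[3])
  expect_equal(nchar(pr$seq[3]), 1500)
  expect_error(extract_promoters(
    data.frame(gene = "x", chrom = "chr1", position = 9001, strand = "+"),
    genome), "off chromosome")
})

test_that("planted consensus sites are found on the correct strand and offset", {
  m <- consensus_pwm_test("AGGTCACAGTGACCT")
  set.seed(22)
  bg <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  w <- nchar("AGGTCACAGTGACCT")
  win <- bg
  substr(win, 100, 100 + w - 1) <- "AGGTCACAGTGACCT"
  hits <- scan_pwm(win, m)
  expect_true(any(hits$offset == 100 & hits$strand == "+"))
  win2 <- bg
  substr(win2, 100, 100 + w - 1) <- oracle_revcomp("AGGTCACAGTGACCT")
  hits2 <- scan_pwm(win2, m)
  expect_true(any(hits2$offset == 100 & hits2$strand == "-"))
  none <- scan_pwm(strrep("N", 300), m, threshold = 0.1)
  expect_equal(nrow(none), 0)
  short <- scan_pwm("ACGT", m)
  expect_equal(nrow(short), 0)
})

test_that("vectorized scores match the brute-force per-offset oracle", {
  set.seed(23)
  for (rep in 1:10) {
    m <- consensus_pwm_test(paste(sample(c("A", "C", "G", "T"),
                                         sample(6:12, 1), replace = TRUE),
                                  collapse = ""))
    win <- paste(sample(c("A", "C", "G", "T", "N"), 250, replace = TRUE,
                        prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
    hits <- scan_pwm(win, m, threshold = m$min_score - 1, both_strands = FALSE)
    want <- oracle_scan(win, m$logodds)
    expect_equal(hits$score[order(hits$offset)], want, tolerance = 1e-9)
  }
})

test_that("presence counts a gene once regardless of hit multiplicity", {
  hits <- data.frame(gene = c("g1", "g1", "g1", "g2"), motif = "m",
                     offset = c(1, 5, 9, 2), strand = "+", score = 1)
  sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5"))
  pt <- presence_table(hits, sets)
  expect_equal(pt$fractions$with_motif, c(2L, 0L))
  expect_equal(pt$fractions$fraction, c(2 / 3, 0))
  expect_equal(unname(pt$tables[["A vs B"]][1, ]), c(2, 1))
  empty <- presence_table(hits, list(A = character(0)))
  expect_true(empty$fractions$empty)
})

test_that("planted prevalence is recovered within the binomial 99% CI", {
  spec <- fixture_spec(seed = 24,
                       promoters = list(set_sizes = c(s = 200),
                                        prevalence = c(s = 0.5),
                                        flank = 300))
  pr <- simulate_promoters(spec)
  hits <- scan_promoters(pr$promoters, pr$motif)
  pt <- presence_table(hits, pr$gene_sets)
  half <- 2.576 * sqrt(0.5 * 0.5 / 200)
  expect_lt(abs(pt$fractions$fraction - 0.5), half + 0.02)
})

test_that("Pearson chi-square matches the closed form without correction", {
  eq <- chi_square_enrichment(matrix(c(50, 50, 50, 50), 2, byrow = TRUE))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  m <- matrix(c(20, 80, 5, 95), 2, byrow = TRUE)
  r <- chi_square_enrichment(m)
  expect_equal(r$statistic, oracle_chisq(m), tolerance = 1e-9)
  # closed form: expected cells (12.5, 87.5) in both rows -> 2*(4.5 + 0.642857)
  expect_equal(r$statistic, 10.2857, tolerance = 1e-4)
  # symmetry under simultaneous row and column swaps
  swapped <- m[2:1, 2:1]
  expect_equal(chi_square_enrichment(swapped)$statistic, r$statistic)
  set.seed(25)
  for (rep in 1:200) {
    t2 <- matrix(rpois(4, 30) + 1, 2)
    expect_equal(chi_square_enrichment(t2)$statistic, oracle_chisq(t2),
                 tolerance = 1e-9)
  }
  expect_error(chi_square_enrichment(matrix(c(0, 0, 5, 5), 2)), "marginal")
})
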