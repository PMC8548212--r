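make_read <- function(id, seq, q) {
  data.frame(id = id, seq = seq,
             qual = if (is.na(q)) NA_character_ else
               paste(rep(rawToChar(as.raw(33L + q)), nchar(seq)), collapse = ""),
             stringsAsFactors = FALSE)
}

test_that("qc_filter trims heads and applies the mean-quality gate", {
  reads <- rbind(make_read("ok", strrep("ACGT", 300), 30),
                 make_read("low", strrep("ACGT", 300), 9),
                 make_read("noq", strrep("ACGT", 300), NA))
  out <- qc_filter(reads, read_filter_config())
  expect_equal(out$id, c("ok", "noq"))
  expect_equal(nchar(out$seq), c(1150, 1150))  # 1200 - 50 head trim
  expect_equal(out$no_quality, c(FALSE, TRUE))
  strict <- qc_filter(reads, read_filter_config(keep_unqualified = FALSE))
  expect_equal(strict$id, "ok")
  empty <- qc_filter(reads[0, ], read_filter_config())
  expect_equal(nrow(empty), 0)
})

test_that("classify_alignment applies MAPQ and junction-window rules", {
  fx <- get_fixture()
  tpl <- fixture_templates(fx$model)
  t1 <- tpl[["SSR-ref"]]
  bp <- t1$junctions$breakpoint[1]  # SSR|E2 at 448
  spanning <- alignment_record("r1", t1$id, 60, cbind(bp - 20, bp + 20))
  res <- classify_alignment(spanning, t1)
  expect_equal(res$assigned, t1$id)
  expect_equal(res$reason, "pass")
  expect_true(grepl("SSR-E2", res$spanned_junctions))

  lowq <- alignment_record("r2", t1$id, 10, cbind(bp - 20, bp + 20))
  expect_equal(classify_alignment(lowq, t1)$reason, "low_mapq")

  inside <- alignment_record("r3", t1$id, 60, cbind(10, 400))
  expect_equal(classify_alignment(inside, t1)$reason, "no_junction")

  short_overhang <- alignment_record("r4", t1$id, 60, cbind(bp - 3, bp + 300))
  got <- classify_alignment(short_overhang, t1)
  expect_false(grepl("SSR-E2", got$spanned_junctions))
})

test_that("every read gets exactly one assignment row with a reason", {
  spec <- fixture_spec(seed = 42)
  fx <- get_fixture()
  sim <- simulate_long_reads(spec, fx$model)
  reads <- qc_filter(sim$reads)
  aln <- align_exact(reads, sim$templates)
  asn <- classify_reads(reads, aln, sim$templates)
  expect_equal(sort(asn$read_id), sort(reads$id))
  expect_true(all(asn$reason %in%
                    c("pass", "low_mapq", "no_junction", "ambiguous", "unaligned")))
  expect_true(all(!is.na(asn$assigned) == (asn$reason == "pass")))
  # assigned implies at least one spanned junction
  expect_true(all(nzchar(asn$spanned_junctions[asn$reason == "pass"])))
})

test_that("error-free junction-spanning reads are classified perfectly", {
  spec <- fixture_spec(seed = 42)
  fx <- get_fixture()
  sim <- simulate_long_reads(spec, fx$model)
  reads <- qc_filter(sim$reads)
  asn <- classify_reads(reads, align_exact(reads, sim$templates), sim$templates)
  truth <- sim$truth[match(asn$read_id, sim$truth$id), ]
  assigned <- !is.na(asn$assigned)
  expect_gt(sum(assigned), 100)
  expect_equal(mean(asn$assigned[assigned] == truth$isoform[assigned]), 1)
})

test_that("a read spanning only shared junctions is ambiguous, not misassigned", {
  fx <- get_fixture()
  tpl <- fixture_templates(fx$model)
  t1 <- tpl[["SSR-SINE-ref"]]
  shared_bp <- t1$junctions$breakpoint[t1$junctions$donor == "E5"]
  aln <- list(alignment_record("r1", t1$id, 60,
                               cbind(shared_bp - 50, shared_bp + 50)))
  reads <- data.frame(id = "r1", seq = strrep("A", 100), qual = NA,
                      stringsAsFactors = FALSE)
  asn <- classify_reads(reads, aln, tpl)
  expect_equal(asn$reason, "ambiguous")
  expect_true(is.na(asn$assigned))
})

test_that("support summary recovers a planted mixture and sums to one", {
  spec <- fixture_spec(seed = 7)
  fx <- get_fixture(7)
  sim <- simulate_long_reads(spec, fx$model)
  reads <- qc_filter(sim$reads)
  asn <- classify_reads(reads, align_exact(reads, sim$templates), sim$templates)
  supp <- summarize_support(asn, sim$templates)
  expect_equal(sum(supp$full_length_proportion), 1, tolerance = 1e-12)
  # planted 0.7 / 0.2 / 0.1; binomial 99% CI half-width at n full-length reads
  n <- sum(supp$full_length_reads)
  for (i in seq_len(3)) {
    p0 <- c(0.7, 0.2, 0.1)[match(supp$isoform[i],
                                 c("SSR-SINE-ref", "SSR-ref", "E1-ref"))]
    half <- 2.576 * sqrt(p0 * (1 - p0) / n)
    expect_lt(abs(supp$full_length_proportion[i] - p0), half + 0.02)
  }
  # order invariance
  perm <- asn[sample.int(nrow(asn)), ]
  expect_equal(summarize_support(perm, sim$templates), supp)
})

test_that("summary of zero assigned reads is empty-and-flagged", {
  fx <- get_fixture()
  tpl <- fixture_templates(fx$model)
  asn <- data.frame(read_id = "r1", assigned = NA_character_,
                    spanned_junctions = "", covers_all_junctions = FALSE,
                    read_length = 100, reason = "no_junction",
                    stringsAsFactors = FALSE)
  supp <- summarize_support(asn, tpl)
  expect_equal(supp$junction_reads, rep(0L, 3))
  expect_true(all(is.nan(supp$full_length_proportion)))
})

test_that("all full-length reads on one template give proportion one", {
  fx <- get_fixture()
  tpl <- fixture_templates(fx$model)
  asn <- data.frame(read_id = c("a", "b"), assigned = "SSR-ref",
                    spanned_junctions = "SSR-E2", covers_all_junctions = TRUE,
                    read_length = 3000, reason = "pass",
                    stringsAsFactors = FALSE)
  supp <- summarize_support(asn, tpl)
  expect_equal(supp$full_length_proportion[supp$isoform == "SSR-ref"], 1)
})

test_that("SAM ingestion reproduces exact-matcher assignments", {
  spec <- fixture_spec(seed = 42, long_reads = list(n_reads = 60))
  fx <- get_fixture()
  sim <- simulate_long_reads(spec, fx$model)
  reads <- qc_filter(sim$reads)
  # hand-written SAM: one perfect full-match record per aligned read
  ex <- align_exact(reads, sim$templates)
  sam <- tempfile(fileext = ".sam")
  hdr <- vapply(sim$templates, function(t)
    sprintf("@SQ\tSN:%s\tLN:%d", t$id, nchar(t$seq)), character(1))
  body <- vapply(ex, function(a) {
    len <- a$blocks[1, 2] - a$blocks[1, 1]
    rseq <- substr(sim$templates[[a$template_id]]$seq,
                   a$blocks[1, 1] + 1, a$blocks[1, 2])
    sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
            a$read_id, a$template_id, a$blocks[1, 1] + 1, a$mapq, len, rseq)
  }, character(1))
  writeLines(c(hdr, body), sam)
  got <- read_alignments_sam(sam)
  expect_equal(length(got), length(ex))
  o <- match(vapply(ex, `[[`, "", "read_id"),
             vapply(got, `[[`, "", "read_id"))
  for (i in seq_along(ex)) {
    g <- got[[o[i]]]
    expect_equal(g$template_id, ex[[i]]$template_id)
    expect_equal(g$blocks, ex[[i]]$blocks, ignore_attr = TRUE)
  }
})
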