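test_that("find_peaks applies the 10-read floor inclusively", {
  cov <- cov_from_counts(rep("chr1", 3), rep("+", 3),
                         c(1000L, 1001L, 1002L), c(12L, 9L, 10L))
  peaks <- find_peaks(cov)
  expect_equal(peaks$pos, c(1000L, 1002L))
  expect_equal(peaks$count, c(12L, 10L))
  # empty coverage
  expect_equal(nrow(find_peaks(accumulate_coverage(data.table()))), 0L)
  expect_error(find_peaks(cov, min_reads = 0), "min_reads")
})

test_that("peaks are assigned to strand-matched containing exons", {
  exons <- rbind(exon_table("chr1", 100, 200, "+", "g1"),
                 exon_table("chr1", 100, 200, "-", "g2"))
  peaks <- data.table(chrom = "chr1", pos = c(150L, 250L), strand = "+",
                      count = c(15L, 15L))
  out <- assign_peaks_to_exons(peaks, exons)
  expect_equal(nrow(out), 1L)          # 250 in no exon -> dropped
  expect_equal(out$gene_id, "g1")      # strand match required
  out2 <- assign_peaks_to_exons(data.table(chrom = "chr1", pos = 150L,
                                           strand = "-", count = 15L), exons)
  expect_equal(out2$gene_id, "g2")
})

test_that("overlap ties break to the longest exon, then smallest gene_id", {
  exons <- rbind(exon_table("chr1", 100, 200, "+", "gB"),
                 exon_table("chr1", 0, 300, "+", "gA"),
                 exon_table("chr1", 0, 300, "+", "gC"))
  out <- assign_peaks_to_exons(
    data.table(chrom = "chr1", pos = 150L, strand = "+", count = 20L), exons)
  expect_equal(out$gene_id, "gA")
  expect_equal(out$exon_end - out$exon_start, 300L)
})

test_that("assignment matches a brute-force rule over random configurations", {
  set.seed(41)
  for (rep in 1:20) {
    ne <- sample(3:8, 1)
    exons <- data.table(
      chrom = "chr1",
      start = sample(0:500, ne),
      strand = sample(c("+", "-"), ne, replace = TRUE),
      gene_id = sample(sprintf("g%02d", 1:5), ne, replace = TRUE),
      region = "exon")
    exons[, end := start + sample(50:400, ne, replace = TRUE)]
    setcolorder(exons, c("chrom", "start", "end", "strand", "gene_id", "region"))
    peak <- data.table(chrom = "chr1", pos = sample(0:800, 1),
                       strand = sample(c("+", "-"), 1), count = 20L)
    got <- assign_peaks_to_exons(peak, exons)
    containing <- exons[strand == peak$strand & start <= peak$pos &
                          peak$pos < end]
    if (nrow(containing) == 0L) {
      expect_equal(nrow(got), 0L)
    } else {
      containing[, len := end - start]
      setorder(containing, -len, gene_id, start)
      expect_equal(got$gene_id, containing$gene_id[1])
      expect_equal(got$exon_start, containing$start[1])
    }
  }
})

test_that("windows are centred, exon-clipped, and zero-filled", {
  cov <- cov_from_counts("chr1", "+", 500L, 20L)
  # interior peak in a long exon: full 100-nt window [450, 550)
  w <- build_window(cov, "chr1", 500L, "+", 0L, 1000L)
  expect_equal(c(w$start, w$end), c(450L, 550L))
  expect_equal(length(w$depths), 100L)
  expect_equal(w$peak_offset, 50L)
  expect_equal(w$depths[51], 20L)
  expect_equal(sum(w$depths), 20L)  # zeros elsewhere
  # peak near the exon start: clipped left
  w2 <- build_window(cov, "chr1", 10L, "+", 0L, 1000L)
  expect_equal(c(w2$start, w2$end), c(0L, 60L))
  expect_equal(w2$peak_offset, 10L)
  # short exon: the whole exon
  w3 <- build_window(cov, "chr1", 15L, "+", 0L, 30L)
  expect_equal(c(w3$start, w3$end), c(0L, 30L))
  expect_error(build_window(cov, "chr1", 5L, "+", 10L, 30L), "within")
})

test_that("window containment and length bounds hold for random configurations", {
  set.seed(42)
  cov <- random_coverage()
  for (rep in 1:50) {
    es <- sample(0:2000, 1)
    ee <- es + sample(5:400, 1)
    pos <- sample(es:(ee - 1L), 1)
    ws <- sample(c(10L, 41L, 100L), 1)
    w <- build_window(cov, "chr1", pos, "+", es, ee, window_size = ws)
    expect_gte(w$start, es)
    expect_lte(w$end, ee)
    expect_lte(w$end - w$start, ws)
    expect_true(w$start <= pos && pos < w$end)
    expect_equal(length(w$depths), w$end - w$start)
  }
})

test_that("Poisson MLE is the background mean, with optional peak exclusion", {
  expect_equal(fit_poisson_mu(c(0, 1, 2, 3), exclude_peak = FALSE), 1.5)
  expect_equal(fit_poisson_mu(c(0, 0, 0), exclude_peak = FALSE), 0)
  expect_equal(fit_poisson_mu(c(10, 1, 1), peak_offset = 0L), 1)
  expect_error(fit_poisson_mu(c(10), peak_offset = 0L), "background")
  expect_error(fit_poisson_mu(c(-1, 2), exclude_peak = FALSE), "non-negative")
})

test_that("poisson_upper_tail matches brute-force pmf summation", {
  for (mu in c(0.1, 0.5, 1, 2, 5, 10)) {
    ks <- 0:50
    got <- poisson_upper_tail(ks, mu)
    want <- vapply(ks, pois_tail_oracle, numeric(1), mu = mu)
    expect_true(all(abs(got - want) <= 1e-9),
                label = sprintf("all |ppois - oracle| <= 1e-9 at mu=%g", mu))
  }
})

test_that("poisson_upper_tail handles boundaries and degenerate nulls", {
  expect_equal(poisson_upper_tail(0, 5), 1)
  expect_equal(poisson_upper_tail(0, 0), 1)
  expect_equal(poisson_upper_tail(5, 0), 0)
  # frozen spec-scale value, independently recomputed by the oracle
  expect_equal(poisson_upper_tail(10, 1), pois_tail_oracle(10, 1),
               tolerance = 1e-9)
  expect_lt(abs(poisson_upper_tail(10, 1) - 1.1142e-7), 1e-11)
  expect_error(poisson_upper_tail(-1, 1), "non-negative")
  expect_error(poisson_upper_tail(1, -1), "non-negative")
  expect_error(poisson_upper_tail(1.5, 1), "integer")
})

test_that("bh_adjust implements the step-up formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(43)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("bh_adjust agrees with an independent step-up implementation", {
  set.seed(44)
  for (i in 1:1000) {
    n <- sample(1:50, 1)
    p <- runif(n)
    if (i %% 5 == 0) p <- round(p, 1)  # exercise ties
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("raising a peak count with fixed background never raises its p-value", {
  mu <- fit_poisson_mu(rep(c(0, 1, 2), 10), exclude_peak = FALSE)
  p <- poisson_upper_tail(10:40, mu)
  expect_true(all(diff(p) <= 0))
})

test_that("test_peaks runs the whole per-sample pipeline", {
  exons <- exon_table("chr1", 0, 1000, "+", "g1")
  # flat coverage of 1 everywhere: no position reaches the floor
  flat <- stranded_coverage(data.table(chrom = "chr1", strand = "+",
                                       pos = 0:999, count = 1L))
  expect_equal(nrow(test_peaks(flat, exons)), 0L)
  # one planted strong stop over a mu ~ 1 background
  set.seed(45)
  dt <- data.table(chrom = "chr1", strand = "+", pos = 0:999,
                   count = rpois(1000, 1))
  dt[pos == 500, count := count + 50L]
  tt <- test_peaks(stranded_coverage(dt), exons)
  expect_equal(tt[pos == 500, significant], TRUE)
  expect_lt(tt[pos == 500, p_value], 1e-30)
  expect_equal(tt$q_value, bh_oracle(tt$p_value))
  expect_true(all(tt$window_end - tt$window_start <= 100))
})

test_that("a window with no background positions is skipped with a message", {
  # single-base exon: exclusion leaves nothing to fit
  exons <- exon_table("chr1", 500, 501, "+", "g1")
  cov <- cov_from_counts("chr1", "+", 500L, 30L)
  expect_message(out <- test_peaks(cov, exons), "skipped 1")
  expect_equal(nrow(out), 0L)
})
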