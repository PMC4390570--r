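test_that("snp_fst reproduces the two-population formula", {
  expect_equal(snp_fst(c(0.3, 0.3)), 0)
  expect_equal(snp_fst(c(0, 1)), 1)              # s2 = 0.5, pbar*qbar = 0.25
  expect_equal(snp_fst(c(0.2, 0.4)), 0.02 / 0.22)
  expect_true(is.na(snp_fst(c(1, 1))))           # fixed everywhere: 0/0
  expect_error(snp_fst(0.5), "two populations")
  expect_error(snp_fst(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("snp_fst matches brute-force evaluation on random inputs", {
  set.seed(20)
  p1 <- runif(10000); p2 <- runif(10000)
  got <- vapply(seq_along(p1), function(i) snp_fst(c(p1[i], p2[i])),
                numeric(1))
  brute <- vapply(seq_along(p1), function(i) {
    s2 <- var(c(p1[i], p2[i]))
    pb <- mean(c(p1[i], p2[i]))
    s2 / (pb * (1 - pb) + s2 / 2)
  }, numeric(1))
  expect_lt(max(abs(got - brute)), 1e-12)
  # symmetry in population order
  rev <- vapply(seq_along(p1), function(i) snp_fst(c(p2[i], p1[i])),
                numeric(1))
  expect_identical(got, rev)
})

test_that("fst_scan contrasts cycles and flags unusable loci", {
  freqs <- data.frame(
    locus = rep(c("a", "b", "c", "d"), 2),
    cycle = rep(c("C2", "C5"), each = 4),
    p_hat = c(0.3, 0, 1, 0.2, 0.3, 1, 1, 0.4),
    n_obs = 20L)
  class(freqs) <- c("allele_freq_table", "data.frame")
  sc <- fst_scan(freqs, "C2", "C5")
  expect_equal(sc$fst[sc$locus == "a"], 0)
  expect_equal(sc$fst[sc$locus == "b"], 1)
  expect_false(sc$usable[sc$locus == "c"])
  expect_equal(sc$fst[sc$locus == "d"], snp_fst(c(0.2, 0.4)))
  expect_error(fst_scan(freqs, "C2", "C9"), "absent")
})

test_that("null thresholds are ordered and reduce to the locus quantile", {
  set.seed(22)
  null <- drift_null_thresholds(runif(200, 0.1, 0.9), wqs_protocol(),
                                n_reps = 300)
  expect_gte(null$fwer_threshold, null$perlocus_q95)
  expect_gte(null$perlocus_q99, null$perlocus_q95)
  expect_length(null$max_fst_sample, 300)
  # single locus: the familywise threshold is that locus's own quantile
  set.seed(23)
  n1 <- drift_null_thresholds(0.5, wqs_protocol(), n_reps = 400)
  expect_equal(n1$fwer_threshold,
               unname(quantile(n1$max_fst_sample, 0.95, type = 1)))
  # more loci, higher maxima: paired seeded runs
  cmp <- vapply(1:10, function(s) {
    set.seed(100 + s)
    p0 <- runif(1000, 0.1, 0.9)
    big <- drift_null_thresholds(p0, wqs_protocol(), n_reps = 60)
    set.seed(100 + s)
    small <- drift_null_thresholds(p0[1:100], wqs_protocol(), n_reps = 60)
    big$fwer_threshold >= small$fwer_threshold
  }, logical(1))
  expect_gte(mean(cmp), 0.9)
})

test_that("the effective-marker option subsamples the null genome", {
  set.seed(24)
  null <- drift_null_thresholds(runif(500, 0.1, 0.9), wqs_protocol(),
                                n_reps = 50, meff = 120)
  expect_identical(null$meff_used, 120)
})

test_that("empirical outlier threshold follows the floor convention", {
  set.seed(25)
  mk_scan <- function(fst) {
    s <- data.frame(locus = paste0("L", seq_along(fst)), fst = fst,
                    s2 = 0, p_bar = 0.5, usable = TRUE)
    class(s) <- c("fst_scan", "data.frame")
    s
  }
  # the program-size case: 17,590 distinct values, 99% threshold
  sc <- mk_scan(sample(runif(17590)))
  out <- empirical_outlier_threshold(sc, 0.99)
  expect_identical(out$n_flagged, 175L)
  expect_identical(empirical_outlier_threshold(mk_scan(runif(200)),
                                               0.99)$n_flagged, 2L)
  # ties: all-equal values flag nothing under strict exceedance
  expect_identical(empirical_outlier_threshold(mk_scan(rep(0.2, 50)),
                                               0.99)$n_flagged, 0L)
})

test_that("enrichment analysis reports observed exceedance proportions", {
  null <- structure(list(perlocus_q95 = 0.3, perlocus_q99 = 0.5),
                    class = "null_distribution")
  mk_scan <- function(fst) {
    s <- data.frame(locus = paste0("L", seq_along(fst)), fst = fst,
                    s2 = 0, p_bar = 0.5, usable = TRUE)
    class(s) <- c("fst_scan", "data.frame")
    s
  }
  e0 <- enrichment_analysis(mk_scan(rep(0, 100)), null)
  expect_equal(c(e0$observed_prop95, e0$observed_prop99), c(0, 0))
  forced <- c(rep(0.9, 10), rep(0, 90))
  ef <- enrichment_analysis(mk_scan(forced), null)
  expect_gte(ef$observed_prop99, 0.10)
  expect_equal(ef$expected_prop95, 0.05)
})

test_that("effective marker number tracks matrix rank structure", {
  set.seed(26)
  base <- rbinom(100, 2, 0.5)
  # 50 copies of one locus: a single independent test
  dup <- matrix(rep(base, 50), ncol = 50)
  expect_identical(effective_marker_number(dup, 0.99), 1L)
  # two mutually independent blocks of perfectly correlated loci
  b2 <- rbinom(100, 2, 0.5)
  two <- cbind(matrix(rep(base, 10), ncol = 10),
               matrix(rep(b2, 10), ncol = 10))
  expect_identical(effective_marker_number(two, 0.99), 2L)
  # independent loci: near-full rank
  ind <- vapply(1:200, function(i) rbinom(500, 2L, 0.5), integer(500))
  meff <- effective_marker_number(ind, 0.995)
  expect_gte(meff, 180L)
  expect_lte(meff, 200L)
  # windowed mode agrees on scale and respects the rank bound
  meff_w <- effective_marker_number(ind, 0.995, window_size = 50)
  expect_lte(abs(meff_w - meff), 20L)
  small <- ind[1:10, ]
  expect_lte(effective_marker_number(small, 0.999, window_size = 20), 9L)
  expect_error(effective_marker_number(cbind(ind, 1L), 0.99),
               "zero-variance")
})
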