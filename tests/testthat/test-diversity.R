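test_that("gene diversity evaluates and is orientation-invariant", {
  expect_equal(gene_diversity(0.5), 0.5)
  expect_equal(gene_diversity(1), 0)
  expect_equal(gene_diversity(0.9), 0.18)
  expect_error(gene_diversity(1.2), "\\[0, 1\\]")
  p <- seq(0, 1, by = 0.01)
  expect_equal(gene_diversity(p), gene_diversity(1 - p))
  expect_true(all(gene_diversity(p) <= 0.5))
})

make_freq_table <- function(p_by_cycle, loci = NULL) {
  cycles <- names(p_by_cycle)
  n <- length(p_by_cycle[[1]])
  ids <- if (is.null(loci)) paste0("L", seq_len(n)) else loci$id
  out <- do.call(rbind, lapply(cycles, function(cy)
    data.frame(locus = ids, cycle = cy, p_hat = p_by_cycle[[cy]],
               n_obs = 40L, stringsAsFactors = FALSE)))
  class(out) <- c("allele_freq_table", "data.frame")
  out
}

test_that("diversity_scan summarizes per cycle", {
  ft <- make_freq_table(list(C2 = rep(0.5, 10), C5 = rep(0.5, 10)))
  sc <- diversity_scan(ft, c("C2", "C5"))
  expect_equal(sc$summary$mean_d, c(0.5, 0.5))
  expect_equal(sc$summary$sd_d, c(0, 0))
  expect_equal(sc$d[, "C2"], sc$d[, "C5"])  # unchanged frequencies
  # genome-wide mean equals the mean of per-locus D exactly
  set.seed(30)
  ft2 <- make_freq_table(list(C2 = runif(200), C5 = runif(200)))
  sc2 <- diversity_scan(ft2, c("C2", "C5"))
  expect_equal(sc2$summary$mean_d[1], mean(sc2$d[, "C2"]), tolerance = 1e-12)
  expect_error(diversity_scan(ft, c("C2", "C9")), "absent")
})

test_that("diversity declines across cycles in simulated selection programs", {
  set.seed(31)
  declined <- replicate(20, {
    p0 <- runif(150, 0.025, 0.975)
    pf <- simulate_drift_trajectories(p0, wqs_protocol(), n_reps = 1)
    mean(gene_diversity(pf)) < mean(gene_diversity(p0))
  })
  expect_gte(mean(declined), 0.95)
})

test_that("region reductions reproduce the worked percent arithmetic", {
  # one region on chr2 holding diversity 0.355 -> 0.135, genome-wide
  # background 0.352 -> 0.285
  n_in <- 40; n_out <- 160
  loci <- data.frame(
    id = paste0("L", seq_len(n_in + n_out)),
    chrom = c(rep("chr2", n_in), rep("chr1", n_out)),
    bp = c(seq(120e6, 144e6, length.out = n_in),
           seq(1e6, 200e6, length.out = n_out)),
    stringsAsFactors = FALSE)
  p_in <- function(d) (1 - sqrt(1 - 2 * d)) / 2  # invert D = 2p(1-p)
  ft <- make_freq_table(list(
    C2 = c(rep(p_in(0.355), n_in), rep(p_in(0.3512500), n_out)),
    C5 = c(rep(p_in(0.135), n_in), rep(p_in(0.3225), n_out))), loci = loci)
  sc <- diversity_scan(ft, c("C2", "C5"), loci = loci)
  reg <- region_reduction_summary(sc, genomic_region("chr2", 117e6, 147e6,
                                                     "chr2_loss"),
                                  "C2", "C5")
  expect_equal(reg$mean_d_from, 0.355, tolerance = 1e-10)
  expect_equal(reg$mean_d_to, 0.135, tolerance = 1e-10)
  expect_identical(reg$percent_reduction_rounded, 62)
  # unchanged diversity reduces by 0%
  ft0 <- make_freq_table(list(C2 = rep(0.3, n_in + n_out),
                              C5 = rep(0.3, n_in + n_out)), loci = loci)
  sc0 <- diversity_scan(ft0, c("C2", "C5"), loci = loci)
  reg0 <- region_reduction_summary(sc0, genomic_region("chr2", 117e6, 147e6),
                                   "C2", "C5")
  expect_identical(reg0$percent_reduction_rounded, 0)
  expect_error(region_reduction_summary(sc, genomic_region("chr9", 1, 2),
                                        "C2", "C5"), "no loci")
})

test_that("drift expectation closed form and its inverse agree", {
  expect_equal(expected_drift_diversity(0.42, 30, 0), 0.42)
  expect_equal(expected_drift_diversity(0.5, 20, 1), 0.4875)
  expect_equal(expected_drift_diversity(0.5, 1e12, 5), 0.5, tolerance = 1e-9)
  expect_equal(implied_effective_size(0.5, 0.4875, 1), 20)
  expect_identical(implied_effective_size(0.3, 0.3, 2), Inf)
})

test_that("the implied effective size of a WQS run shows the bottleneck", {
  set.seed(32)
  p0 <- runif(400, 0.025, 0.975)
  pf <- simulate_drift_trajectories(p0, wqs_protocol(), n_reps = 2)
  ne <- implied_effective_size(mean(gene_diversity(p0)),
                               mean(gene_diversity(pf)), t = 3)
  expect_true(is.finite(ne))
  expect_lt(ne, 450)
})
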