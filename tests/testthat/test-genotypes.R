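test_that("genotype_matrix validates its parts", {
  expect_error(genotype_matrix(matrix(3L, 2, 2)), "0, 1, 2 or NA")
  expect_error(genotype_matrix(matrix(0L, 2, 2),
                               loci = data.frame(id = c("a", "a"),
                                                 chrom = NA, bp = NA)),
               "duplicate")
  g <- tiny_genotypes()
  expect_identical(dim(g), c(3L, 4L))
})

test_that("delimited round trip is exact, including missing and empty", {
  g <- tiny_genotypes()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path)
  expect_identical(g2$dosages, g$dosages)
  expect_identical(g2$loci, g$loci, ignore_attr = TRUE)
  expect_identical(g2$samples$cycle, g$samples$cycle)
  # empty (0-locus) matrix still round-trips a valid header-only file
  g0 <- genotype_matrix(matrix(integer(0), nrow = 2, ncol = 0),
                        samples = data.frame(id = c("a", "b"),
                                             cycle = c("C2", "C2")))
  p0 <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g0, p0)
  g0b <- read_genotypes(p0)
  expect_identical(dim(g0b), c(2L, 0L))
})

test_that("VCF genotypes map to dosages and multi-allelic records fail", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path)
  g <- read_genotypes(path, format = "vcf", cycles = c("C2", "C2", "C5"))
  expect_identical(unname(g$dosages[, "rs1"]), c(0L, 1L, 2L))
  expect_identical(unname(g$dosages[, "rs2"]), c(NA_integer_, 1L, 2L))
  expect_identical(g$loci$bp, c(100L, 200L))
  bad <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(bad, extra_alt = TRUE)
  expect_error(read_genotypes(bad, format = "vcf"), "[Mm]ulti-allelic")
})

test_that("allele frequencies follow the maximum-likelihood rule", {
  g <- tiny_genotypes()
  f <- estimate_allele_frequencies(g)
  # column s1 = (0,1,2) -> 3/6; s2 = (2,NA,0) -> 2/4; s4 = (0,0,NA) -> 0
  expect_equal(f$p_hat[f$locus == "s1"], 0.5)
  expect_equal(f$p_hat[f$locus == "s2"], 0.5)
  expect_equal(f$p_hat[f$locus == "s4"], 0)
  expect_identical(f$n_obs[f$locus == "s2"], 2L)
  d <- matrix(c(0L, 1L, NA), 3, 1)
  expect_equal(estimate_allele_frequencies(genotype_matrix(d))$p_hat, 0.25)
  expect_equal(
    estimate_allele_frequencies(genotype_matrix(matrix(2L, 4, 1)))$p_hat, 1)
  fc <- estimate_allele_frequencies(g, by_cycle = TRUE)
  expect_equal(fc$p_hat[fc$locus == "s1" & fc$cycle == "C2"], 0.25)
  expect_equal(fc$p_hat[fc$locus == "s1" & fc$cycle == "C5"], 1)
})

test_that("frequency estimation ignores sample order and missing placement", {
  set.seed(10)
  g <- geno_at_freqs(60, c(0.2, 0.5, 0.8))
  g$dosages[sample(60, 10), 2] <- NA
  f1 <- estimate_allele_frequencies(g)
  perm <- sample(60)
  g2 <- genotype_matrix(g$dosages[perm, ],
                        samples = g$samples[perm, ])
  f2 <- estimate_allele_frequencies(g2)
  expect_equal(f1$p_hat, f2$p_hat)
})

test_that("estimated frequencies concentrate around the truth", {
  set.seed(11)
  p <- runif(300, 0.05, 0.95)
  g <- geno_at_freqs(500, p)
  f <- estimate_allele_frequencies(g)
  bound <- 3 * sqrt(p * (1 - p) / (2 * 500))
  expect_gte(mean(abs(f$p_hat - p) < bound), 0.99)
})

test_that("the MAF filter applies a strict inequality and logs removals", {
  n <- 200
  make_col <- function(p) {
    k <- round(2 * n * p)  # exact alternate-allele count among 2n alleles
    d <- integer(n)
    d[seq_len(k %/% 2)] <- 2L
    if (k %% 2 == 1L) d[k %/% 2 + 1L] <- 1L
    d
  }
  mafs <- c(0, 0.01, 0.025, 0.03, 0.5)
  d <- vapply(mafs, make_col, integer(n))
  colnames(d) <- paste0("L", seq_along(mafs))
  g <- genotype_matrix(d)
  kept <- filter_loci(g, maf_min = 0.025, max_missing = 1)
  expect_identical(kept$loci$id, c("L4", "L5"))
  expect_identical(attr(kept, "filter_log")$removed_maf, 3L)
  # fully missing locus removed on the missingness rule
  d2 <- cbind(d, miss = rep(NA_integer_, n))
  g2 <- genotype_matrix(d2)
  expect_false("miss" %in% filter_loci(g2, 0, 0.20)$loci$id)
  # identity settings return the input unchanged
  expect_identical(filter_loci(g, 0, 1)$dosages, g$dosages)
})

test_that("filtering is idempotent", {
  set.seed(12)
  g <- geno_at_freqs(80, runif(50, 0, 0.6))
  g$dosages[sample(length(g$dosages), 300)] <- NA
  once <- filter_loci(g, 0.025, 0.2)
  twice <- filter_loci(once, 0.025, 0.2)
  expect_identical(once$dosages, twice$dosages)
})

test_that("imputation fills by the requested rule", {
  d <- matrix(c(2L, 2L, NA), 3, 1)
  gi <- impute_missing(genotype_matrix(d), "locus_mean")
  expect_identical(unname(gi$dosages[3, 1]), 2L)
  g <- tiny_genotypes()
  gfull <- impute_missing(genotype_matrix(g$dosages[, 1, drop = FALSE]))
  expect_identical(gfull$dosages[, 1], g$dosages[, 1])  # no-missing identity
  expect_error(impute_missing(genotype_matrix(matrix(NA_integer_, 3, 1))),
               "no observed genotypes")
  # frequency_draw respects Hardy-Weinberg proportions at p = 0.5
  set.seed(13)
  d <- matrix(c(rep(0L, 10), rep(2L, 10), rep(NA, 10000)), ncol = 1)
  gi <- impute_missing(genotype_matrix(d), "frequency_draw")
  filled <- gi$dosages[-(1:20), 1]
  expect_lt(abs(mean(filled == 1L) - 0.5), 0.02)
})
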