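test_that("broad-sense heritability formula and monotonicity", {
  H <- function(G, GE, E, e = 2, r = 2)
    broad_sense_H(list(sigma2_G = G, sigma2_GE = GE, sigma2_e = E,
                       e = e, r = r))
  expect_equal(H(1, 0, 0), 1)
  expect_equal(H(1, 1, 1), 1 / (1 + 0.5 + 0.25))
  expect_equal(H(0, 1, 1), 0)
  expect_error(H(0, 0, 0), "all variance components")
  # monotone in each component
  expect_gt(H(2, 1, 1), H(1, 1, 1))
  expect_lt(H(1, 2, 1), H(1, 1, 1))
  expect_lt(H(1, 1, 2), H(1, 1, 1))
})

test_that("noise-free family data recovers variance components exactly", {
  set.seed(40)
  g <- matrix(0L, 25, 1, dimnames = list(paste0("f", 1:25), "L1"))
  ph <- simulate_phenotypes(g, n_env = 2, n_rep = 2,
                            varcomps = c(G = 4, GE = 0, E = 0), env_sd = 1)
  vc <- fit_family_varcomps(ph)
  expect_equal(vc$sigma2_e, 0, tolerance = 1e-8)
  expect_equal(vc$sigma2_G, var(attr(ph, "truth")$family_values),
               tolerance = 1e-6)
})

test_that("REML matches the balanced-design ANOVA oracle", {
  for (seed in c(1, 2)) {
    ph <- balanced_trial(nf = 100L, seed = seed)
    vc <- fit_family_varcomps(ph)
    oracle <- ems_oracle(ph)
    expect_equal(c(vc$sigma2_G, vc$sigma2_GE, vc$sigma2_e),
                 unname(oracle), tolerance = 1e-6)
  }
})

test_that("REML agrees with an independent mixed-model fitter", {
  skip_if_not_installed("lme4")
  ph <- balanced_trial(nf = 80L, seed = 3)
  vc <- fit_family_varcomps(ph)
  fit <- lme4::lmer(
    value ~ environment + environment:factor(replicate) +
      (1 | family) + (1 | family:environment),
    data = ph, REML = TRUE)
  vcd <- as.data.frame(lme4::VarCorr(fit))
  expect_equal(vc$sigma2_G, vcd$vcov[vcd$grp == "family"], tolerance = 1e-4)
  expect_equal(vc$sigma2_GE, vcd$vcov[vcd$grp == "family:environment"],
               tolerance = 1e-4)
  expect_equal(vc$sigma2_e, vcd$vcov[vcd$grp == "Residual"], tolerance = 1e-4)
  # BLUPs correlate essentially perfectly with the reference ranking
  expect_gt(cor(vc$blups,
                lme4::ranef(fit)$family[names(vc$blups), 1]), 0.999)
})

test_that("a single environment yields a structural-zero interaction", {
  set.seed(41)
  g <- matrix(0L, 30, 1, dimnames = list(paste0("f", 1:30), "L1"))
  ph <- simulate_phenotypes(g, n_env = 1, n_rep = 3,
                            varcomps = c(G = 2, GE = 0, E = 1))
  vc <- fit_family_varcomps(ph)
  expect_false(vc$gxe_estimable)
  expect_identical(vc$sigma2_GE, 0)
  expect_gt(vc$sigma2_G, 0)
})

test_that("the genomic relationship matrix has VanRaden structure", {
  set.seed(42)
  d <- matrix(rbinom(200 * 2000, 2L, rep(runif(2000, 0.1, 0.9), each = 200)),
              200, 2000)
  G <- genomic_relationship_matrix(d)
  expect_equal(dim(G), c(200L, 200L))
  expect_lt(abs(mean(diag(G)) - 1), 0.1)
  expect_lt(max(abs(rowSums(G))), 1e-8)   # centering identity
  # identical samples: off-diagonal equals both diagonals
  d2 <- rbind(d[1, ], d[1, ], d[2:10, ])
  G2 <- genomic_relationship_matrix(d2)
  expect_equal(G2[1, 2], G2[1, 1])
  expect_equal(G2[1, 2], G2[2, 2])
  expect_error(genomic_relationship_matrix(matrix(1L, 5, 3)), "monomorphic")
  expect_error(genomic_relationship_matrix(matrix(c(0L, NA, 1L, 2L), 2, 2)),
               "impute")
})

test_that("G-BLUP REML recovers signal, null and noiseless extremes", {
  # h2 is identified by the spread of the kinship eigenvalues, so use a
  # family-structured relationship matrix (half-sib blocks), the setting
  # recurrent-selection programs actually present
  set.seed(43)
  n <- 300
  fam <- rep(seq_len(n / 10), each = 10)
  G <- outer(fam, fam, function(a, b) ifelse(a == b, 0.5, 0)) + diag(0.5, n)
  L <- chol(G)
  h2 <- replicate(20, {
    u <- drop(crossprod(L, rnorm(n))) * sqrt(2)
    y <- 3 + u + rnorm(n, 0, sqrt(2))
    gblup_reml(y, G)$h2_g
  })
  expect_lt(abs(mean(h2) - 0.5), 0.1)
  h0 <- replicate(50, gblup_reml(rnorm(n), G)$h2_g)
  expect_lt(mean(h0), 0.05)
  u <- drop(crossprod(L, rnorm(n)))
  expect_gt(gblup_reml(1 + u, G)$h2_g, 0.95)
  expect_error(gblup_reml(rnorm(n), G, fixed = matrix(0, n, 2)), "singular")
})

test_that("with an identity kinship the variance split is complete", {
  set.seed(44)
  n <- 500
  y <- rnorm(n, 10, sqrt(3))
  fit <- gblup_reml(y, diag(n))
  expect_lt(abs((fit$sigma2_u + fit$sigma2_res) / var(y) - 1), 0.05)
})

test_that("association scan has power and honors its contracts", {
  set.seed(45)
  n <- 300
  d <- matrix(rbinom(n * 400, 2L, 0.4), n, 400,
              dimnames = list(NULL, paste0("m", 1:400)))
  G <- genomic_relationship_matrix(d)
  mk <- d[, 1]
  beta <- sqrt(0.2 * 4 / var(mk))   # 20% of a phenotypic variance of 4
  y <- 2 + mk * beta + rnorm(n, 0, sqrt(4 - 0.2 * 4))
  res <- association_scan(y, d, G)
  expect_true(res$significant[1])
  expect_lt(res$p_value[1], 1e-4)
  # contracts: monomorphic skipped, fixed-effect duplicate collinear
  cyc <- factor(rep(c("C2", "C5"), each = n / 2))
  d2 <- cbind(d[, 1:3], mono = 1L, dup = as.integer(cyc == "C5") * 2L)
  res2 <- association_scan(y, d2, G, fixed = cyc)
  expect_identical(res2$flag[4], "monomorphic")
  expect_identical(res2$flag[5], "collinear")
  expect_true(all(is.na(res2$p_value[4:5])))
})

test_that("null association p-values are approximately uniform", {
  set.seed(46)
  n <- 300
  d <- matrix(rbinom(n * 2000, 2L, 0.5), n, 2000)
  G <- genomic_relationship_matrix(d)
  res <- association_scan(rnorm(n), d, G)
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("exact per-marker refitting agrees with the P3D approximation", {
  set.seed(47)
  n <- 150
  d <- matrix(rbinom(n * 20, 2L, 0.4), n, 20)
  G <- genomic_relationship_matrix(matrix(rbinom(n * 300, 2L, 0.5), n, 300))
  y <- rnorm(n) + d[, 1] * 0.8
  p3d <- association_scan(y, d, G)
  exact <- association_scan(y, d, G, refit = TRUE)
  expect_gt(cor(-log10(p3d$p_value), -log10(exact$p_value)), 0.99)
})
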