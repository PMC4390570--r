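# SNP-wise Fst between selection cycles and its drift-simulation null.
#
# Fst for a locus with per-population frequencies p_1..p_r is
#   s^2 / (pbar (1 - pbar) + s^2 / r),
# with s^2 the sample variance (denominator r - 1) of frequency between
# populations and pbar the mean. A locus monomorphic for the same allele in
# both populations has 0/0 and is flagged unusable.

#' SNP-wise Fst from per-population allele frequencies
#'
#' @param p_by_pop Numeric vector of per-population frequencies (length
#'   `r >= 2`).
#' @return Fst in `[0, 1]`; exactly 0 when the populations do not differ;
#'   `NA` when the locus is fixed for the same allele everywhere (undefined
#'   0/0).
#' @export
snp_fst <- function(p_by_pop) {
  r <- length(p_by_pop)
  if (r < 2L) stop("need at least two populations")
  if (any(p_by_pop < 0 | p_by_pop > 1)) stop("frequencies must be in [0, 1]")
  s2 <- stats::var(p_by_pop)
  pbar <- mean(p_by_pop)
  den <- pbar * (1 - pbar) + s2 / r
  if (den == 0) return(NA_real_)
  s2 / den
}

# vectorized two-population form used by scans and null simulation
.fst2 <- function(pa, pb) {
  s2 <- (pa - pb)^2 / 2
  pbar <- (pa + pb) / 2
  den <- pbar * (1 - pbar) + s2 / 2
  out <- ifelse(den > 0, s2 / den, NA_real_)
  out
}

#' Fst scan between two selection cycles
#'
#' @param freqs An `allele_freq_table` from
#'   [estimate_allele_frequencies()] with `by_cycle = TRUE`.
#' @param cycle_a,cycle_b Cycle labels to contrast.
#' @return A `data.frame` of class `fst_scan` with per-locus columns
#'   `locus`, `fst`, `s2`, `p_bar` and `usable` (`FALSE` for loci fixed for
#'   the same allele in both cycles, where Fst is undefined).
#' @export
fst_scan <- function(freqs, cycle_a, cycle_b) {
  fm <- .freq_matrix(freqs)
  if (!all(c(cycle_a, cycle_b) %in% colnames(fm)))
    stop("requested cycles absent from frequency table")
  pa <- fm[, cycle_a]
  pb <- fm[, cycle_b]
  s2 <- (pa - pb)^2 / 2
  pbar <- (pa + pb) / 2
  fst <- .fst2(pa, pb)
  out <- data.frame(locus = rownames(fm), fst = unname(fst),
                    s2 = unname(s2), p_bar = unname(pbar),
                    usable = !is.na(fst), stringsAsFactors = FALSE)
  attr(out, "cycles") <- c(cycle_a, cycle_b)
  class(out) <- c("fst_scan", "data.frame")
  out
}

#' Drift-simulation significance thresholds for an Fst scan
#'
#' Simulates `n_reps` drift-only outcomes of the breeding protocol for every
#' locus (starting from the observed `p0`), computes per-locus Fst of each
#' simulated final frequency against its start, and derives (i) the
#' family-wise threshold as the `1 - fwer` quantile of the per-replicate
#' maximum Fst across loci, and (ii) pooled per-locus 95% and 99% quantiles
#' of all simulated Fst values (the uncorrected enrichment thresholds, of
#' which 5% and 1% of drift-only loci are expected to exceed).
#'
#' @param p0 Starting (earlier-cycle) allele frequencies. Loci fixed at 0 or
#'   1 are excluded from the null (their Fst is undefined under pure drift).
#' @param protocol A [breeding_protocol()] spanning the contrasted cycles.
#' @param n_reps Number of null replicates.
#' @param fwer Family-wise error rate for the max-Fst threshold.
#' @param meff Optional effective number of markers; when supplied, each
#'   replicate genome uses `meff` loci sampled with replacement from the
#'   `p0` spectrum (the effective-marker variant of the multiple-testing
#'   correction; see [effective_marker_number()]).
#' @return An object of class `null_distribution`: `max_fst_sample`,
#'   `fwer_threshold`, `perlocus_q95`, `perlocus_q99`, `n_reps`,
#'   `meff_used`. Quantiles use the empirical inverse-CDF (type 1)
#'   convention; exceedance is strict.
#' @export
drift_null_thresholds <- function(p0, protocol, n_reps = 1000L, fwer = 0.05,
                                  meff = NULL) {
  p0 <- p0[!is.na(p0)]
  if (length(p0) < 1L) stop("p0 must be non-empty")
  p0 <- p0[p0 > 0 & p0 < 1]
  if (length(p0) < 1L) stop("no polymorphic starting frequencies")
  if (!is.null(meff)) p0 <- sample(p0, meff, replace = TRUE)
  pf <- simulate_drift_trajectories(p0, protocol, n_reps = n_reps)
  fst <- .fst2(p0, pf)  # p0 recycles down columns (locus-major)
  maxima <- apply(fst, 2L, max, na.rm = TRUE)
  structure(list(
    max_fst_sample = maxima,
    fwer_threshold = unname(stats::quantile(maxima, 1 - fwer, type = 1)),
    perlocus_q95 = unname(stats::quantile(fst, 0.95, na.rm = TRUE, type = 1)),
    perlocus_q99 = unname(stats::quantile(fst, 0.99, na.rm = TRUE, type = 1)),
    n_reps = as.integer(n_reps),
    fwer = fwer,
    meff_used = meff),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "drift null (%d reps%s):\n  max-Fst FWER %.0f%% threshold: %.4f\n  per-locus q95: %.4f, q99: %.4f\n",
    x$n_reps, if (is.null(x$meff_used)) "" else
      sprintf(", Meff = %d", x$meff_used),
    100 * (1 - x$fwer), x$fwer_threshold, x$perlocus_q95, x$perlocus_q99))
  invisible(x)
}

#' Empirical outlier threshold for an Fst scan
#'
#' The data-derived alternative to simulation thresholds: the empirical
#' `quantile` of usable Fst values (inverse-CDF convention). With `M` usable
#' loci and distinct values, exactly `floor((1 - quantile) * M)` loci fall
#' strictly above it.
#'
#' @param scan An [fst_scan()].
#' @param quantile Outlier quantile level (e.g. 0.99).
#' @return List with `threshold` and `n_flagged`.
#' @export
empirical_outlier_threshold <- function(scan, quantile = 0.99) {
  stopifnot(inherits(scan, "fst_scan"))
  x <- scan$fst[scan$usable]
  if (length(x) < 1L) stop("no usable loci in scan")
  thr <- unname(stats::quantile(x, quantile, type = 1))
  list(threshold = thr, n_flagged = sum(x > thr))
}

#' Enrichment of high-Fst loci relative to the drift null
#'
#' Compares the observed proportions of usable scan loci exceeding the
#' pooled per-locus 95% and 99% drift quantiles with their theoretical
#' drift-only expectations of 5% and 1%.
#'
#' @param scan An [fst_scan()].
#' @param null A [drift_null_thresholds()] result.
#' @return List of class `enrichment_result` with `expected_prop95 = 0.05`,
#'   `expected_prop99 = 0.01`, `observed_prop95`, `observed_prop99` and the
#'   underlying locus counts.
#' @export
enrichment_analysis <- function(scan, null) {
  stopifnot(inherits(scan, "fst_scan"), inherits(null, "null_distribution"))
  x <- scan$fst[scan$usable]
  structure(list(
    expected_prop95 = 0.05, expected_prop99 = 0.01,
    observed_prop95 = mean(x > null$perlocus_q95),
    observed_prop99 = mean(x > null$perlocus_q99),
    n_usable = length(x),
    n_exceed95 = sum(x > null$perlocus_q95),
    n_exceed99 = sum(x > null$perlocus_q99)),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: %.3f%% of %d loci exceed q95 (expect 5%%), %.3f%% exceed q99 (expect 1%%)\n",
    100 * x$observed_prop95, x$n_usable, 100 * x$observed_prop99))
  invisible(x)
}

#' Effective number of independent markers
#'
#' Counts the smallest number of leading eigenvalues of the marker
#' correlation matrix (composite LD) whose sum reaches `pca_cutoff` of the
#' total — the effective number of independent tests. For large panels the
#' computation runs on consecutive windows of loci and sums the per-window
#' counts.
#'
#' @param g A [genotype_matrix()] without missing values (impute first) or a
#'   numeric samples x loci matrix.
#' @param pca_cutoff Fraction of eigenvalue mass to capture (e.g. 0.99 or
#'   0.95).
#' @param window_size Number of loci per window; `NULL` processes all loci
#'   in one block.
#' @return Integer count `M_eff <= min(n_loci, n_samples - 1)`.
#' @export
effective_marker_number <- function(g, pca_cutoff = 0.99,
                                    window_size = NULL) {
  d <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  if (anyNA(d)) stop("missing values present; impute first")
  if (nrow(d) < 2L) stop("need at least two samples")
  v <- apply(d, 2L, stats::var)
  if (any(v == 0))
    stop("constant (zero-variance) locus present; filter first")
  L <- ncol(d)
  windows <- if (is.null(window_size)) list(seq_len(L))
             else split(seq_len(L), ceiling(seq_len(L) / window_size))
  meff <- 0L
  for (w in windows) {
    ev <- eigen(stats::cor(d[, w, drop = FALSE]), symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
    k <- which(cumsum(ev) >= pca_cutoff * sum(ev))[1L]
    meff <- meff + k
  }
  # window sums cannot claim more independent tests than the data's rank
  as.integer(min(meff, L, nrow(d) - 1L))
}
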