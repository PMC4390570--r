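# Unlinked single-locus drift engine.
#
# Loci are assumed to be in linkage equilibrium, so every locus (and every
# replicate) evolves independently and the whole ensemble can be advanced as
# flat vectors of genotype-class counts (n_aa, n_Aa, n_AA). Counts, not just
# allele frequencies, are tracked: single-seed-descent selfing converts
# heterozygotes to homozygotes and thereby inflates the drift variance of the
# subsequent family-sampling bottleneck, which a frequency-only scheme would
# understate.

# Multinomial draw over three classes, vectorized over loci x replicates,
# decomposed into two binomials. p0+p1+p2 need not be normalized.
.rmulti3 <- function(n, p0, p1, p2) {
  tot <- p0 + p1 + p2
  k2 <- stats::rbinom(length(n), n, ifelse(tot > 0, p2 / tot, 0))
  rest <- p0 + p1
  k1 <- stats::rbinom(length(n), n - k2, ifelse(rest > 0, p1 / rest, 0))
  list(k0 = n - k2 - k1, k1 = k1, k2 = k2)
}

# Multivariate hypergeometric: draw k individuals without replacement from
# classes of sizes (m0, m1, m2); vectorized.
.rhyper3 <- function(m0, m1, m2, k) {
  k2 <- stats::rhyper(length(k), m2, m0 + m1, k)
  k1 <- stats::rhyper(length(k), m1, m0, k - k2)
  list(k0 = k - k2 - k1, k1 = k1, k2 = k2)
}

# Single-seed-descent selfing collapsed over g generations: a heterozygous
# lineage representative remains heterozygous with probability (1/2)^g and
# fixes to either homozygote with probability (1 - (1/2)^g)/2 each.
.ssd_self <- function(k0, k1, k2, g) {
  if (g == 0L) return(list(k0 = k0, k1 = k1, k2 = k2))
  s <- 0.5^g
  a <- (1 - s) / 2
  up <- stats::rbinom(length(k1), k1, a)
  stay <- stats::rbinom(length(k1), k1 - up, s / (s + a))
  list(k0 = k0 + (k1 - up - stay), k1 = stay, k2 = k2 + up)
}

# Offspring genotype-class probabilities under bulk-entry recombination:
# each offspring draws an ordered pair of distinct families uniformly from
# the n selected, then one gamete from each representative. Conditional on
# the selected-family class counts the offspring are iid, with
#   P(AA) = E[g_u g_v],  P(aa) = E[(1-g_u)(1-g_v)]
# over distinct ordered pairs (u, v), where g is the gamete A-probability
# (0, 1/2, 1) of the family's representative genotype.
.bulk_entry_probs <- function(k0, k1, k2, n) {
  s1 <- 0.5 * k1 + k2        # sum of g_u
  s2 <- 0.25 * k1 + k2       # sum of g_u^2
  t1 <- k0 + 0.5 * k1        # sum of (1 - g_u)
  t2 <- k0 + 0.25 * k1       # sum of (1 - g_u)^2
  den <- n * (n - 1)
  p_AA <- (s1^2 - s2) / den
  p_aa <- (t1^2 - t2) / den
  list(p0 = p_aa, p1 = pmax(1 - p_AA - p_aa, 0), p2 = p_AA)
}

# Advance one cycle for flat vectors of genotype-class counts.
# `truncation_selection`: select families by descending allele-A dosage
# (fully heritable single-locus criterion) instead of at random.
.advance_counts <- function(k0, k1, k2, spec, scheme, next_pop,
                            truncation_selection = FALSE) {
  # S0 founders drawn with replacement from the current population (only
  # class ratios matter, so k may also hold Hardy-Weinberg probabilities
  # describing an infinite base pool)
  f <- .rmulti3(rep.int(spec$n_s0_plants, length(k0)), k0, k1, k2)
  # selfing by single-seed descent to the family representative
  f <- .ssd_self(f$k0, f$k1, f$k2, spec$selfing_generations)
  # agronomic screen: uniform subsample in drift mode
  f <- .rhyper3(f$k0, f$k1, f$k2,
                rep.int(spec$n_after_screen, length(k0)))
  # selection of families for recombination
  if (truncation_selection) {
    k2s <- pmin(f$k2, spec$n_selected)
    k1s <- pmin(f$k1, spec$n_selected - k2s)
    f <- list(k0 = spec$n_selected - k2s - k1s, k1 = k1s, k2 = k2s)
  } else {
    f <- .rhyper3(f$k0, f$k1, f$k2,
                  rep.int(spec$n_selected, length(k0)))
  }
  # recombination into the next cycle's population
  if (scheme == "bulk_entry_diallel") {
    if (spec$n_selected < 2L)
      stop("bulk-entry recombination needs at least 2 selected families")
    pr <- .bulk_entry_probs(f$k0, f$k1, f$k2, spec$n_selected)
  } else {
    p <- (f$k1 + 2 * f$k2) / (2 * spec$n_selected)
    pr <- list(p0 = (1 - p)^2, p1 = 2 * p * (1 - p), p2 = p^2)
  }
  .rmulti3(rep.int(next_pop, length(k0)), pr$p0, pr$p1, pr$p2)
}

#' Simulate drift-only allele-frequency trajectories through a breeding protocol
#'
#' Fast unlinked engine: every locus evolves independently through all cycles
#' of `protocol` (Hardy--Weinberg base population at the supplied starting
#' frequencies), tracking exact genotype-class counts through founder
#' sampling, single-seed-descent selfing, screening, (random or truncation)
#' selection, and recombination. This is the drift-null generator used to
#' calibrate Fst significance thresholds.
#'
#' @param p0 Numeric vector of starting allele frequencies in `[0, 1]`.
#' @param protocol A [breeding_protocol()].
#' @param n_reps Number of independent replicates per locus.
#' @param truncation_selection If `TRUE`, each cycle's selection step keeps
#'   the families with the highest allele-A dosage (a fully heritable
#'   single-locus selection criterion) instead of a uniform draw. Used for
#'   signal injection; the default `FALSE` is the drift null.
#' @return A `length(p0)` x `n_reps` matrix of final allele frequencies,
#'   measured in the last recombined population.
#' @details Randomness is taken from R's global stream; call [set.seed()]
#'   for reproducibility. Fixed loci (`p0` 0 or 1) stay fixed.
#' @export
simulate_drift_trajectories <- function(p0, protocol, n_reps = 1000L,
                                        truncation_selection = FALSE) {
  stopifnot(inherits(protocol, "breeding_protocol"))
  if (length(p0) < 1L) stop("p0 must be non-empty")
  if (any(!is.finite(p0)) || any(p0 < 0) || any(p0 > 1))
    stop("starting frequencies must lie in [0, 1]")
  if (protocol$plants_per_family != 1L)
    stop("the unlinked engine supports plants_per_family = 1 only")
  n_reps <- as.integer(n_reps)
  nl <- length(p0)
  p <- rep(p0, times = n_reps)  # locus-major within replicate blocks
  m <- length(p)

  # Base population: an effectively infinite Hardy-Weinberg pool at p0.
  # The first cycle's founder draw from it is binomial in the HWE genotype
  # probabilities, which .advance_counts handles as class ratios.
  st <- list(k0 = (1 - p)^2, k1 = 2 * p * (1 - p), k2 = p^2)

  for (spec in protocol$cycles) {
    st <- .advance_counts(st$k0, st$k1, st$k2, spec,
                          protocol$recombination_scheme,
                          protocol$next_cycle_pop_size,
                          truncation_selection = truncation_selection)
  }
  pf <- (st$k1 + 2 * st$k2) / (2 * protocol$next_cycle_pop_size)
  matrix(pf, nrow = nl, ncol = n_reps,
         dimnames = list(names(p0), NULL))
}
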