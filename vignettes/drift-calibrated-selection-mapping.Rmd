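---
title: "Drift-calibrated selection mapping in recurrent-selection populations"
author: "wqscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-calibrated selection mapping in recurrent-selection populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wqscan)
```

## The problem

A closed breeding population advanced by recurrent selection — cycles of
family evaluation, selection of the best 10–50 families, and intermating —
experiences two forces that move allele frequencies: the selection it was
designed to apply, and genetic drift from its small effective size. A
selection-mapping scan asks, SNP by SNP, whether the frequency change
between an early and a late cycle is larger than drift alone can explain.
The catch is that "drift alone" is not a textbook Wright–Fisher quantity
here: the program's demography (a few hundred S0 plants, selfing to S2
families, screening, a 20-family recombination bottleneck each cycle)
produces far more drift than the nominal census size suggests. `wqscan`
therefore calibrates the null by simulating the breeding protocol itself.

The package is organized around the Wisconsin Quality Synthetic (WQS) maize
program as its motivating preset — cycles C2 through C5 of selection for
silage yield and composition, genotyped at about 17.6k usable SNPs — but
every demographic quantity is a parameter, so any protocol of the same
shape can be expressed.

## The breeding-protocol model

A `cycle_spec` describes one cycle: `n_s0_plants` S0 founders drawn from
the current population, each selfed `selfing_generations` times by
single-seed descent to a family representative, a random agronomic screen
down to `n_after_screen` families, selection of `n_selected` families
(uniformly at random under the drift null; by a ranking function when
signal is injected), and recombination into `next_cycle_pop_size`
offspring. The WQS preset (`wqs_protocol()`) uses 450, 450 and 200 S0
plants for its three advances, 20 selected families, and two selfing
generations, following the program's published protocol.

Two recombination schemes are provided. `bulk_entry_diallel` mirrors the
bulk entry method: each offspring draws an unordered pair of *distinct*
selected families and one gamete from each, so every family contributes
equally in expectation without materializing all pairwise crosses.
`random_union` draws both gametes with replacement (selfing allowed) and
exists mainly because it makes the idealized Wright–Fisher closed form
`D_t = D_0 (1 - 1/(2N))^t` exactly testable.

### Two engines, one model

The **unlinked engine** (`simulate_drift_trajectories`) treats loci as
independent ("linkage equilibrium"), which is the standard — and
conservative — assumption for the drift null. It is exact, not
approximate: per locus it tracks the three genotype-class counts
(aa/Aa/AA) through every sampling event. Tracking classes rather than
allele frequencies matters because single-seed-descent selfing converts
heterozygotes to homozygotes; the resulting inbreeding inflates the drift
variance of the 20-family bottleneck, which a frequency-only simulation
would understate. All steps are exact multinomial or multivariate
hypergeometric draws, vectorized across loci and replicates, so a full
1,000-replicate null for 2,000 SNPs takes seconds. For bulk-entry
recombination the offspring genotype-class probabilities are computed in
closed form: conditional on the selected families' class counts, offspring
are iid over random distinct ordered pairs `(u, v)` with
`P(AA) = (S1^2 - S2)/(n(n-1))`, where `S1` and `S2` are the sums of the
family gamete probabilities and their squares. A property test confirms
the two engines agree on final-frequency mean and spread.

Under the drift null the screen size `n_after_screen` is provably
irrelevant — two successive uniform subsamples compose to one — so its
preset value (keep 50%, the middle of the program's reported 50–67%
discard range) only matters when a selection function is active. How many
plants per selected family contributed gametes at recombination is not
recorded in the program's description; the default is the most
conservative (maximal-drift) reading of one S2 plant per family, with a
`plants_per_family` parameter in the individual-based engine for
sensitivity analysis. The unlinked engine requires the one-plant setting,
since its class bookkeeping assumes a single representative genotype.

The **linked engine** (`simulate_wqs_genomes`, `advance_cycle`,
`meiosis_gamete`) is the synthetic-data generator. It is individual-based
over a genetic map, with Haldane-model meiosis (Poisson crossovers at
chromosome-cM/100 per meiosis, no interference — chosen because it is the
standard closed-form-testable model), and emits the selected family
representatives of each cycle as the "genotyped" samples, mimicking how
remnant seed of selected families is genotyped in practice. The final
cycle contributes S1 plants drawn from the last population. The default
founder spectrum is uniform on (0.025, 0.975), which gives mean founder
gene diversity of 0.35 — the level typical of a maize synthetic at this
marker density — and the generator can mask genotypes at per-locus rates
uniform on (0, 0.14), reproducing a mean missingness of 7% with a 0–20%
range.

What the generator does *not* emulate: mutation, migration, crossover
interference, tester genomes (selection acts only through a ranking
function on family genotypes or phenotypes), ascertainment bias of array
SNPs, and genotype-calling error. Passing tests on synthetic data
therefore demonstrate the statistical machinery is correct under the
stated model, not that real-data complications are absorbed.

## The F_ST scan and its null

Allele frequencies are maximum-likelihood estimates: observed
alternate-allele copies over twice the observed individuals, per cycle,
with allele orientation fixed from the pooled data so trajectories are
comparable. The SNP-wise statistic between two cycles is

\[ F_{ST} = \frac{s^2}{\bar p (1-\bar p) + s^2/r}, \]

with `s^2` the sample variance of frequency between the `r = 2`
populations (denominator `r - 1`, the usual sample-variance convention)
and `\bar p` their mean. Loci fixed for the same allele in both cycles are
0/0 and flagged unusable; they are excluded from scans and nulls.

`drift_null_thresholds` replays the protocol `n_reps` times (default
1,000) for every SNP from its observed early-cycle frequency and derives
two kinds of thresholds from the same ensemble:

* the **family-wise threshold** — the 95% quantile of the per-replicate
  maximum F_ST across all SNPs, controlling the probability of any false
  positive under drift;
* the **pooled per-locus 95% and 99% quantiles**, of which exactly 5% and
  1% of drift-only loci are expected to fall above; comparing the observed
  exceedance proportions against these expectations is the enrichment
  analysis.

Quantiles use the empirical inverse-CDF (type 1) convention and exceedance
is strict; with `M` distinct usable values, a `q` outlier threshold flags
exactly `floor((1-q) M)` loci, which is what makes the 17,590-locus /
175-flagged worked example exact. An optional `meff` argument rebuilds the
null genome from `M_eff` SNPs resampled from the starting spectrum, the
effective-number-of-markers variant of the correction;
`effective_marker_number` computes `M_eff` as the number of leading
eigenvalues of the marker correlation matrix needed to reach a cutoff
(0.99 or 0.95) of the total eigenvalue mass, optionally in consecutive
windows for large panels, and is always capped by the matrix rank.

## Gene diversity

`gene_diversity` is `D = 2pq`, expected heterozygosity. `diversity_scan`
evaluates it per SNP and cycle with genome-wide means and SDs;
`region_reduction_summary` averages D over physical regions and reports
`100 (D_from - D_to)/D_from`, rounded to integer percent for reporting
with full precision retained. `wqs_regions()` provides ±15 Mbp windows
around the three regions of pronounced loss reported for the WQS program
(chr2 ~132 Mbp, chr3 ~55 Mbp, chr4 ~78 Mbp); the windows are configurable
because those regions were originally delineated visually and only their
centers are anchored. `expected_drift_diversity` and
`implied_effective_size` connect the realized decay to the idealized
closed form; on WQS-preset simulations the implied Ne lands far below the
450 S0 plants, quantifying how strongly the 20-family bottleneck
dominates.

## Variance components, G-BLUP and association

`fit_family_varcomps` fits the standard multi-environment family model —
environment and replicate-within-environment fixed, family and
family-by-environment random, iid residuals — by REML. The optimizer is an
EM-REML warm start followed by Fisher scoring with step-halving (EM
fallback when scoring proposes an inadmissible step), iterated to a
relative-change tolerance of 1e-10; components are truncated at zero, and
a component that converges onto the boundary is pinned and the reduced
model refit. On balanced designs this reproduces the closed-form ANOVA
expected-mean-squares solution to near machine precision, which the tests
assert against an independently coded oracle (and against `lme4` as a
second, independent fitter). Noise-free data — every family constant
across plots — is detected up front and handled exactly rather than by
chasing a singular likelihood. With a single environment the interaction
variance is structurally zero and flagged as such. Broad-sense
heritability on a family-mean basis is
`H = sigma2_G / (sigma2_G + sigma2_GE/e + sigma2_e/(r e))`.

`genomic_relationship_matrix` is the VanRaden form
`G = W_C W_C' / (2 sum p q)` with dosages centered by `2p` and
constant loci dropped. `gblup_reml` fits `y = Xb + u + e`,
`u ~ N(0, G sigma2_u)`, by a single eigendecomposition of `G` followed by
one-dimensional REML profiling of `lambda = sigma2_u/sigma2_e`
(`h2_G = lambda/(1+lambda)`), with the boundary `lambda -> 0` checked
explicitly. One point deserves emphasis: `h2_G` is identified by the
*spread* of the kinship eigenvalues. With essentially unrelated
individuals `G` approaches the identity and the likelihood in `lambda` is
nearly flat; the multi-family structure of a breeding program is exactly
what makes the parameter estimable, and the recovery tests therefore use
family-structured kinships. Cycle (equivalently, trial year — the two are
confounded by design) enters as a fixed effect, and family BLUPs enter the
across-cycle G-BLUP unstandardized; an analysis preferring per-cycle
standardization can simply rescale `y`.

`association_scan` adds each marker as a fixed covariate to the G-BLUP
model, re-using the null-model variance components for every marker (the
population-parameters-previously-determined approximation, with exact
per-marker REML behind `refit = TRUE`; the two agree to a correlation
above 0.99 on test data) and reports two-sided t tests of the GLS marker
effect. The significance threshold defaults to `P = 1e-4` with no further
multiple-testing correction, matching the practice the package
accompanies. Monomorphic markers are skipped; markers collinear with the
fixed effects are flagged rather than tested.

## Numerical conventions and degenerate inputs

* Quantiles: empirical type 1 throughout; exceedance strict; ties
  therefore flag nothing.
* Frequencies of 0 or 1 are absorbing in the simulator; such loci are
  excluded from nulls (their F_ST is undefined under drift).
* `filter_loci` uses a strict `maf > maf_min` rule (the conventional
  "greater than 0.025" phrasing); `maf_min = 0` disables the frequency
  filter entirely so the identity contract holds.
* `impute_missing`'s `locus_mean` fills `round(2 p)`; `frequency_draw`
  samples Hardy–Weinberg genotypes at the observed frequency. Both are
  deliberately simple: haplotype-model imputation is out of scope, and
  the diversity scan uses raw frequencies with missing exclusion by
  default.
* Randomness comes from R's global stream (`set.seed` before any
  stochastic call reproduces results bit for bit); `run_pipeline` derives
  a deterministic sub-seed per stage from the master seed.

## The selection-injected fixture

`generate_fixture_dataset("selection_injected")` plants five loci under
truncation selection on a single-locus criterion with heritability 0.3,
starting from intermediate frequencies (0.15–0.5). A fully heritable
criterion would fix the favored allele within the first advance — leaving
the locus monomorphic in *both* genotyped cohorts and hence invisible to
the scan — so partial heritability is what spreads the response across
cycles and produces the elevated-but-finite F_ST a scan should flag. The
power property (selected loci exceeding the per-locus 99% drift quantile
in over 80% of runs) is asserted on the unlinked engine with a fully
heritable criterion, where the comparison is base-population frequency
against final population.

## Problem sizes

The test suite and acceptance checks run at the sizes the analyses use:
2,000 unlinked loci with 1,000 null replicates for threshold calibration
(about ten seconds), 200 fresh null genomes for family-wise coverage, 50
replicate datasets of 150 families (e = 2, r = 3) for H recovery, 50
replicates at n = 300 for genomic-heritability recovery and association
power, and 10,000-draw Monte Carlo checks for meiosis and selfing ratios.
The linked generator is exercised at 100–2,000 SNPs; the
`wqs_like_full` preset (17,590 SNPs) runs in a few minutes when the full
scan size is wanted.

## Known limitations

* The drift null conditions on observed starting frequencies; uncertainty
  in those estimates (finite genotyped cohorts) is not propagated into the
  thresholds.
* The null assumes linkage equilibrium between markers, which
  over-counts independent tests; the `M_eff` variant bounds the effect
  but linked null simulation is not implemented.
* Selection injection models a single-locus criterion; polygenic
  selection signatures (many small shifts) are precisely what such scans
  miss, and the package makes no attempt to detect them.
* The family model assumes balanced or near-balanced designs; heavily
  unbalanced historical trials will fit but the EMS-oracle equivalence no
  longer holds exactly.
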