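# Phenotype generator with the variance structure of multi-environment
# family trials: fixed environment and replicate-within-environment effects,
# random family and family-by-environment effects, iid residuals.

#' Describe a trait's genetic architecture
#'
#' @param qtl_loci Integer indices (into the genotype loci) of causal loci;
#'   empty for a purely polygenic (infinitesimal) trait.
#' @param qtl_effects Additive effect per alternate-allele copy, one per QTL.
#' @param h2_target Narrow-sense heritability of the selection criterion in
#'   `[0, 1]` (used when the architecture drives in-simulation selection).
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(qtl_loci = integer(0),
                               qtl_effects = numeric(0),
                               h2_target = 1) {
  stopifnot(length(qtl_loci) == length(qtl_effects),
            all(is.finite(qtl_effects)),
            h2_target >= 0, h2_target <= 1)
  structure(list(qtl_loci = as.integer(qtl_loci),
                 qtl_effects = as.numeric(qtl_effects),
                 h2_target = h2_target),
            class = "trait_architecture")
}

#' Simulate multi-environment family-trial phenotypes
#'
#' `value = mu + g_i + l_j + gl_ij + b_k(j) + e_ijk`: the family genetic
#' value `g_i` comes from QTL dosages rescaled to the family variance (plus
#' a polygenic remainder), or is purely polygenic when no architecture is
#' given; environment and replicate-within-environment effects are fixed
#' draws; family-by-environment deviations and residuals are iid normal
#' with the requested variances.
#'
#' @param geno A [genotype_matrix()] whose samples are the phenotyped
#'   families.
#' @param arch Optional [trait_architecture()]; its QTL then determine the
#'   heritable signal, scaled so the QTL part explains `prop_qtl` of the
#'   family variance.
#' @param n_env,n_rep Environments and replicates per environment.
#' @param varcomps Named vector `c(G = , GE = , E = )` of family,
#'   family-by-environment and residual variances (>= 0).
#' @param mu Intercept.
#' @param env_sd,rep_sd Spread of the fixed environment and
#'   replicate-within-environment effects.
#' @param prop_qtl Fraction of the family variance explained by the QTL
#'   score when `arch` has QTL.
#' @param trait Trait name recorded in the output.
#' @return A `data.frame` with columns `family`, `environment`, `replicate`,
#'   `trait`, `value`; attribute `"truth"` carries the simulated family
#'   genetic values and the variance components used.
#' @export
simulate_phenotypes <- function(geno, arch = NULL, n_env = 2L, n_rep = 3L,
                                varcomps = c(G = 4, GE = 2, E = 6),
                                mu = 100, env_sd = 1, rep_sd = 0,
                                prop_qtl = 1, trait = "trait") {
  stopifnot(all(varcomps >= 0), all(c("G", "GE", "E") %in% names(varcomps)))
  fams <- if (inherits(geno, "genotype_matrix")) geno$samples$id
          else rownames(geno)
  nf <- length(fams)
  d <- if (inherits(geno, "genotype_matrix")) geno$dosages else as.matrix(geno)

  gvar <- varcomps[["G"]]
  if (!is.null(arch) && length(arch$qtl_loci) > 0L) {
    if (max(arch$qtl_loci) > ncol(d))
      stop("QTL index outside the genotype loci")
    score <- drop(d[, arch$qtl_loci, drop = FALSE] %*% arch$qtl_effects)
    sv <- stats::var(score)
    qtl_part <- if (sv > 0)
      (score - mean(score)) * sqrt(prop_qtl * gvar / sv) else rep(0, nf)
    g <- qtl_part + stats::rnorm(nf, 0, sqrt((1 - prop_qtl) * gvar))
  } else {
    g <- stats::rnorm(nf, 0, sqrt(gvar))
  }
  l <- stats::rnorm(n_env, 0, env_sd)
  b <- matrix(stats::rnorm(n_env * n_rep, 0, rep_sd), n_env, n_rep)
  ge <- matrix(stats::rnorm(nf * n_env, 0, sqrt(varcomps[["GE"]])), nf, n_env)

  idx <- expand.grid(rep = seq_len(n_rep), env = seq_len(n_env),
                     fam = seq_len(nf))
  value <- mu + g[idx$fam] + l[idx$env] + ge[cbind(idx$fam, idx$env)] +
    b[cbind(idx$env, idx$rep)] +
    stats::rnorm(nrow(idx), 0, sqrt(varcomps[["E"]]))
  out <- data.frame(family = fams[idx$fam],
                    environment = paste0("env", idx$env),
                    replicate = idx$rep,
                    trait = trait, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- list(family_values = stats::setNames(g, fams),
                             varcomps = varcomps,
                             H = gvar / (gvar + varcomps[["GE"]] / n_env +
                                           varcomps[["E"]] / (n_env * n_rep)))
  out
}
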