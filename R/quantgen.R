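# Quantitative-genetic layer: family variance components and broad-sense
# heritability from multi-environment trials, the VanRaden genomic
# relationship matrix, G-BLUP genomic heritability by eigen-rotation REML,
# and a mixed-model association scan with population-parameters-previously-
# determined (P3D) variance components.

# ---- family variance components -------------------------------------------

# REML log-likelihood pieces for y = Xb + sum_i Z_i u_i + e, computed from
# dense V. Returns loglik, P y, and P (n x n).
.reml_eval <- function(y, X, Zs, sig) {
  n <- length(y)
  V <- diag(sig[length(sig)], n)
  for (i in seq_along(Zs))
    V <- V + sig[i] * tcrossprod(Zs[[i]])
  R <- chol(V)
  Vi <- chol2inv(R)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  Rx <- chol(XtViX)
  P <- Vi - crossprod(XtVi, chol2inv(Rx) %*% XtVi)
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(R))) + 2 * sum(log(diag(Rx))) +
                  sum(y * Py))
  list(ll = ll, P = P, Py = Py)
}

# Fisher-scoring REML with EM warm start for variance components
# sig = (sigma^2_1, ..., sigma^2_k, sigma^2_e). Components listed in `fixed0`
# are pinned to zero.
.reml_fit <- function(y, X, Zs, tol = 1e-10, max_iter = 200L) {
  n <- length(y)
  k <- length(Zs)
  free <- rep(TRUE, k + 1L)
  repeat {
    sig <- rep(stats::var(y) / (sum(free)), k + 1L)
    sig[!free] <- 0
    ev <- .reml_eval(y, X, Zs, sig)
    As <- c(lapply(Zs, tcrossprod), list(diag(1, n)))
    for (it in seq_len(max_iter)) {
      idx <- which(free)
      # scores and expected information on the free components
      PA <- lapply(idx, function(i) ev$P %*% As[[i]])
      sc <- vapply(seq_along(idx), function(j) {
        i <- idx[j]
        -0.5 * (sum(diag(PA[[j]])) - sum(ev$Py * (As[[i]] %*% ev$Py)))
      }, numeric(1))
      info <- matrix(0, length(idx), length(idx))
      for (a in seq_along(idx)) for (b in seq_len(a)) {
        info[a, b] <- info[b, a] <- 0.5 * sum(PA[[a]] * t(PA[[b]]))
      }
      step <- tryCatch(solve(info, sc), error = function(e) sc / diag(info))
      qs <- c(vapply(Zs, ncol, integer(1)), n)
      em <- sig
      em[idx] <- sig[idx] + sig[idx]^2 / qs[idx] * 2 * sc  # EM-REML update
      new <- sig
      new[idx] <- sig[idx] + step
      # step-halve into the admissible region / uphill; fall back to the
      # (always admissible, always uphill) EM update if scoring fails
      h <- 0
      ev_new <- NULL
      while (h < 32) {
        if (all(new[idx] > -1e-12)) {
          new[idx] <- pmax(new[idx], 0)
          if (sum(new) > 0) {
            ev_new <- tryCatch(.reml_eval(y, X, Zs, pmax(new, 1e-12)),
                               error = function(e) NULL)
            if (!is.null(ev_new) && ev_new$ll >= ev$ll - 1e-8) break
          }
        }
        h <- h + 1
        new[idx] <- if (h < 31) sig[idx] + step / 2^h else em[idx]
      }
      if (h >= 32 || is.null(ev_new)) break  # nothing improves: converged
      delta <- max(abs(new[idx] - sig[idx]) / (abs(sig[idx]) + 1e-8))
      sig <- new
      ev <- ev_new
      if (delta < tol) break
    }
    # pin components that converged onto the zero boundary and refit
    hit <- free & c(rep(TRUE, k), FALSE) & sig < 1e-7 * max(sig, 1e-12)
    if (!any(hit)) break
    free[hit] <- FALSE
  }
  list(sig = pmax(sig, 0), ll = ev$ll, P = ev$P, Py = ev$Py,
       iterations = it, fixed_zero = !free)
}

#' Fit the family / family-by-environment variance-component model
#'
#' Fits `y = env + rep-within-env (fixed) + family + family:env (random) + e`
#' by REML (EM warm start, Fisher scoring to convergence; negative component
#' estimates truncated at zero) and returns the variance components, design
#' constants and per-family BLUPs.
#'
#' @param pheno A phenotype `data.frame` with columns `family`,
#'   `environment`, `replicate`, `trait`, `value` (replicate nested within
#'   environment).
#' @param trait Trait name to analyse (defaults to the only trait present).
#' @return An object of class `variance_components` with `sigma2_G`,
#'   `sigma2_GE`, `sigma2_e`, `e` (environments), `r` (replicates per
#'   environment), `blups`, `loglik`. With a single environment the
#'   family-by-environment variance is inestimable and is returned as a
#'   structural zero with `gxe_estimable = FALSE`.
#' @export
fit_family_varcomps <- function(pheno, trait = NULL) {
  stopifnot(all(c("family", "environment", "replicate", "value") %in%
                  names(pheno)))
  if (!is.null(trait) && "trait" %in% names(pheno))
    pheno <- pheno[pheno$trait == trait, , drop = FALSE]
  pheno <- pheno[is.finite(pheno$value), , drop = FALSE]
  fam <- factor(pheno$family)
  env <- factor(pheno$environment)
  rep_ <- factor(pheno$replicate)
  if (nlevels(fam) < 2L) stop("need at least two families")
  y <- pheno$value
  e <- nlevels(env)
  r <- nlevels(rep_)  # nominal replicates per environment
  X <- if (e > 1L) stats::model.matrix(~ env + env:rep_) else
    stats::model.matrix(~ rep_)
  X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  Z1 <- stats::model.matrix(~ fam - 1)
  gxe_estimable <- e > 1L
  # Degenerate noise-free data (each family constant across plots): the REML
  # boundary sigma2_e = sigma2_GE = 0 is exact; estimate sigma2_G from the
  # X-adjusted family means directly rather than chasing a singular surface.
  rss_full <- sum(qr.resid(qr(cbind(X, Z1)), y)^2)
  if (rss_full < 1e-12 * max(sum((y - mean(y))^2), 1e-300)) {
    ghat <- tapply(qr.resid(qr(X), y), fam, mean)
    blups <- ghat - mean(ghat)
    return(structure(list(sigma2_G = stats::var(as.vector(ghat)),
                          sigma2_GE = 0, sigma2_e = 0, e = e, r = r,
                          blups = stats::setNames(as.vector(blups), levels(fam)),
                          loglik = NA_real_, gxe_estimable = gxe_estimable,
                          iterations = 0L),
                     class = "variance_components"))
  }
  Zs <- if (gxe_estimable)
    list(Z1, stats::model.matrix(~ fam:env - 1)) else list(Z1)
  fit <- .reml_fit(y, X, Zs)
  sig <- fit$sig
  sigma2_G <- sig[1L]
  sigma2_GE <- if (gxe_estimable) sig[2L] else 0
  sigma2_e <- sig[length(sig)]
  blups <- drop(sigma2_G * crossprod(Z1, fit$Py))
  names(blups) <- levels(fam)
  structure(list(sigma2_G = sigma2_G, sigma2_GE = sigma2_GE,
                 sigma2_e = sigma2_e, e = e, r = r,
                 blups = blups, loglik = fit$ll,
                 gxe_estimable = gxe_estimable,
                 iterations = fit$iterations),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "variance components: sigma2_G = %.4g, sigma2_GE = %.4g, sigma2_e = %.4g\n",
    x$sigma2_G, x$sigma2_GE, x$sigma2_e))
  cat(sprintf("design: e = %d environments, r = %d replicates; H = %.3f\n",
              x$e, x$r, broad_sense_H(x)))
  invisible(x)
}

#' Broad-sense heritability on a family-mean basis
#'
#' `H = sigma2_G / (sigma2_G + sigma2_GE / e + sigma2_e / (r e))`.
#'
#' @param vc A [fit_family_varcomps()] result, or a list with the same
#'   fields.
#' @return Heritability in `[0, 1]`.
#' @export
broad_sense_H <- function(vc) {
  stopifnot(vc$e >= 1, vc$r >= 1)
  den <- vc$sigma2_G + vc$sigma2_GE / vc$e + vc$sigma2_e / (vc$r * vc$e)
  if (den == 0) stop("all variance components are zero")
  vc$sigma2_G / den
}

# ---- genomic relationship and G-BLUP --------------------------------------

#' VanRaden genomic relationship matrix
#'
#' `G = W_C W_C' / (2 sum_l p_l q_l)` with `W_C` the dosage matrix centered
#' by `2 p_l`, frequencies computed from the supplied samples. Monomorphic
#' loci contribute nothing and are dropped.
#'
#' @param g A [genotype_matrix()] with no missing values (impute first).
#' @return A symmetric samples x samples matrix.
#' @export
genomic_relationship_matrix <- function(g) {
  d <- if (inherits(g, "genotype_matrix")) g$dosages else as.matrix(g)
  if (anyNA(d)) stop("missing values present; impute first")
  p <- colMeans(d) / 2
  poly <- p > 0 & p < 1 & apply(d, 2L, stats::var) > 0
  if (!any(poly)) stop("all loci monomorphic")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(d, 2L, 2 * p)
  tcrossprod(W) / (2 * sum(p * (1 - p)))
}

#' G-BLUP REML fit by eigen-rotation
#'
#' Fits `y = X b + u + e`, `u ~ N(0, G sigma2_u)`, by REML: one
#' eigendecomposition of `G` rotates the model to independent observations,
#' then the variance ratio `lambda = sigma2_u / sigma2_e` is profiled and
#' optimized in one dimension.
#'
#' @param y Response (e.g. per-family BLUPs), length n.
#' @param G n x n symmetric positive semi-definite relationship matrix.
#' @param fixed Fixed-effects design: a factor (e.g. selection cycle /
#'   trial year), a model matrix, or `NULL` for intercept only.
#' @param interval Search interval for `log(lambda)`.
#' @return Object of class `gblup_fit`: `sigma2_u`, `sigma2_res`, `h2_g`
#'   (`= sigma2_u / (sigma2_u + sigma2_res)`), `fixed_effects`, `u` (BLUPs),
#'   `loglik`, plus the cached rotation for downstream association scans.
#' @export
gblup_reml <- function(y, G, fixed = NULL, interval = c(-12, 12)) {
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n)
  X <- .fixed_design(fixed, n)
  p <- ncol(X)
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)

  prof <- function(loglam) {
    lam <- exp(loglam)
    w <- 1 / (lam * d + 1)
    XtW <- Xt * w
    XtWX <- crossprod(Xt, XtW)
    beta <- solve(XtWX, crossprod(XtW, yt))
    res <- yt - drop(Xt %*% beta)
    rss <- sum(w * res^2)
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2e) + sum(log(lam * d + 1)) +
                    determinant(XtWX, logarithm = TRUE)$modulus + (n - p))
    list(ll = as.numeric(ll), s2e = s2e, beta = beta, res = res, w = w,
         lam = lam)
  }
  opt <- stats::optimize(function(l) prof(l)$ll, interval = interval,
                         maximum = TRUE, tol = 1e-10)
  best <- prof(opt$maximum)
  # compare against the boundary lambda -> 0 (pure noise)
  null0 <- prof(log(1e-12))
  if (null0$ll > best$ll) best <- null0
  lam <- best$lam
  s2e <- best$s2e
  u <- drop(U %*% (lam * d * best$w * best$res))
  structure(list(sigma2_u = lam * s2e, sigma2_res = s2e,
                 h2_g = lam / (1 + lam),
                 fixed_effects = drop(best$beta), u = u,
                 loglik = best$ll, lambda = lam,
                 rotation = list(U = U, d = d, Xt = Xt, yt = yt, p = p)),
            class = "gblup_fit")
}

.fixed_design <- function(fixed, n) {
  X <- if (is.null(fixed)) matrix(1, n, 1L)
  else if (is.factor(fixed) || is.character(fixed))
    stats::model.matrix(~ factor(fixed))
  else as.matrix(fixed)
  if (nrow(X) != n) stop("fixed-effects design does not match y")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular fixed-effects design")
  X
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "G-BLUP REML: sigma2_u = %.4g, sigma2_res = %.4g, h2_G = %.3f\n",
    x$sigma2_u, x$sigma2_res, x$h2_g))
  invisible(x)
}

# ---- association scan ------------------------------------------------------

#' Mixed-model association scan
#'
#' Tests each marker as an added fixed covariate in the G-BLUP model.
#' Variance components come from the null (no-marker) fit and are re-used
#' for every marker (the P3D approximation); `refit = TRUE` re-estimates
#' them per marker instead. The per-marker test is a two-sided t test of
#' the GLS marker effect.
#'
#' @param y Response (per-family values), length n.
#' @param markers A [genotype_matrix()] (imputed) or numeric n x m dosage
#'   matrix.
#' @param G Relationship matrix for the polygenic term.
#' @param fixed Fixed-effects design as in [gblup_reml()].
#' @param alpha Significance threshold on the p-value (default `1e-4`).
#' @param refit Re-estimate variance components for every marker (slow,
#'   exact) instead of the P3D approximation.
#' @return A `data.frame` of class `association_result` with per-marker
#'   `effect`, `se`, `stat`, `p_value`, `significant`, and a `flag` column
#'   (`"ok"`, `"monomorphic"`, `"collinear"`).
#' @export
association_scan <- function(y, markers, G, fixed = NULL, alpha = 1e-4,
                             refit = FALSE) {
  M <- if (inherits(markers, "genotype_matrix")) markers$dosages
       else as.matrix(markers)
  if (anyNA(M)) stop("markers contain missing values; impute first")
  n <- length(y)
  stopifnot(nrow(M) == n)
  ids <- colnames(M) %||% paste0("m", seq_len(ncol(M)))
  null_fit <- gblup_reml(y, G, fixed)
  rot <- null_fit$rotation
  w <- 1 / (null_fit$lambda * rot$d + 1)
  sw <- sqrt(w)
  A <- rot$Xt * sw
  b <- rot$yt * sw
  Mt <- crossprod(rot$U, M) * sw
  # residualize response and markers on the fixed effects (GLS metric)
  qa <- qr(A)
  bstar <- b - A %*% qr.coef(qa, b)
  Mstar <- Mt - A %*% qr.coef(qa, Mt)
  p <- rot$p
  df <- n - p - 1L

  mono <- apply(M, 2L, function(x) stats::var(x) == 0)
  smm <- colSums(Mstar^2)
  tot <- colSums(Mt^2)
  collinear <- !mono & smm < 1e-10 * pmax(tot, 1e-300)

  effect <- se <- stat <- pval <- rep(NA_real_, ncol(M))
  ok <- !mono & !collinear
  if (refit) {
    for (j in which(ok)) {
      Xj <- cbind(.fixed_design(fixed, n), M[, j])
      fj <- gblup_reml(y, G, Xj)
      effect[j] <- fj$fixed_effects[length(fj$fixed_effects)]
      # Wald from the refitted GLS
      wj <- 1 / (fj$lambda * fj$rotation$d + 1)
      Aj <- fj$rotation$Xt * sqrt(wj)
      cv <- fj$sigma2_res * solve(crossprod(Aj))
      se[j] <- sqrt(cv[nrow(cv), ncol(cv)])
      stat[j] <- effect[j] / se[j]
      pval[j] <- 2 * stats::pt(-abs(stat[j]), df)
    }
  } else {
    effect[ok] <- (colSums(Mstar * drop(bstar)))[ok] / smm[ok]
    rss <- sum(bstar^2) - effect^2 * smm
    s2 <- rss / df
    se[ok] <- sqrt(s2[ok] / smm[ok])
    stat[ok] <- effect[ok] / se[ok]
    pval[ok] <- 2 * stats::pt(-abs(stat[ok]), df)
  }
  out <- data.frame(locus = ids, effect = effect, se = se, stat = stat,
                    p_value = pval,
                    significant = !is.na(pval) & pval < alpha,
                    flag = ifelse(mono, "monomorphic",
                                  ifelse(collinear, "collinear", "ok")),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "null_fit") <- null_fit
  class(out) <- c("association_result", "data.frame")
  out
}
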