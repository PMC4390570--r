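# Genotype container and I/O. Dosages count copies of the alternate allele
# (0/1/2, NA = missing); allele orientation is fixed across cycles so that
# frequency trajectories, Fst and gene diversity are comparable between
# cycles. Delimited dialect: tab-separated, samples as rows, first column
# the sample id, second the cycle label, then one column per locus; missing
# coded "NA". Locus coordinates travel in a sidecar "<path>.map" file.

#' Construct a genotype matrix
#'
#' @param dosages Integer matrix, samples x loci, values in `{0, 1, 2, NA}`
#'   counting copies of the alternate allele.
#' @param loci `data.frame` with columns `id`, `chrom`, `bp` (one row per
#'   locus; `chrom`/`bp` may be `NA` when no map is available).
#' @param samples `data.frame` with columns `id` and `cycle`.
#' @param cycle_levels Ordered set of cycle labels; defaults to order of
#'   first appearance.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, loci = NULL, samples = NULL,
                            cycle_levels = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(loci))
    loci <- data.frame(id = colnames(dosages) %||% sprintf("L%d", seq_len(ncol(dosages))),
                       chrom = rep(NA_character_, ncol(dosages)),
                       bp = rep(NA_integer_, ncol(dosages)),
                       stringsAsFactors = FALSE)
  if (is.null(samples))
    samples <- data.frame(id = rownames(dosages) %||% paste0("S", seq_len(nrow(dosages))),
                          cycle = "all", stringsAsFactors = FALSE)
  if (nrow(loci) != ncol(dosages))
    stop("loci table does not match dosage columns")
  if (nrow(samples) != nrow(dosages))
    stop("sample table does not match dosage rows")
  if (anyDuplicated(loci$id)) stop("duplicate locus id")
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(cycle_levels)) cycle_levels <- unique(samples$cycle)
  if (!all(samples$cycle %in% cycle_levels))
    stop("sample cycle labels outside declared cycle set")
  dimnames(dosages) <- list(samples$id, loci$id)
  structure(list(dosages = dosages, loci = loci, samples = samples,
                 cycle_levels = cycle_levels),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci, cycles: %s\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(x$cycle_levels, collapse = ", ")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("missing: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read genotypes from a delimited matrix or a VCF
#'
#' Delimited files use the package dialect (see [write_genotypes()]); a
#' sidecar `<path>.map` file, when present, supplies locus coordinates.
#' VCF input (v4.x) uses the GT field only: `0/0`, `0/1`, `1/1`, `./.`
#' (phased equivalents included) map to dosages 0, 1, 2, NA; records with
#' more than one ALT allele are rejected.
#'
#' @param path Input file.
#' @param format `"delimited"` or `"vcf"`.
#' @param cycles Optional per-sample cycle labels for VCF input (VCF carries
#'   no cycle metadata); recycled `NA` otherwise.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("delimited", "vcf"),
                           cycles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "delimited") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
    if (ncol(d) < 2L) stop("malformed genotype file (need sample and cycle columns)")
    ids <- d[[1L]]
    cyc <- d[[2L]]
    if (ncol(d) > 2L) {
      dos <- as.matrix(d[, -(1:2), drop = FALSE])
      dos <- matrix(as.integer(dos), nrow = nrow(d),
                    dimnames = list(ids, colnames(d)[-(1:2)]))
    } else {
      dos <- matrix(integer(0), nrow = nrow(d), ncol = 0L,
                    dimnames = list(ids, NULL))
    }
    loci <- NULL
    mapfile <- paste0(path, ".map")
    if (file.exists(mapfile) && ncol(dos) > 0L) {
      m <- utils::read.table(mapfile, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
      if (!identical(as.character(m$id), colnames(dos)))
        stop("sidecar map does not match genotype columns")
      loci <- data.frame(id = as.character(m$id), chrom = as.character(m$chrom),
                         bp = as.integer(m$bp), stringsAsFactors = FALSE)
    }
    genotype_matrix(dos, loci = loci,
                    samples = data.frame(id = ids, cycle = cyc,
                                         stringsAsFactors = FALSE))
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    alt <- fix[, "ALT"]
    if (any(grepl(",", alt, fixed = TRUE)))
      stop("multi-allelic VCF record(s) present; only biallelic sites supported")
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- function(x) {
      x <- gsub("|", "/", x, fixed = TRUE)
      out <- rep(NA_integer_, length(x))
      out[x == "0/0"] <- 0L
      out[x %in% c("0/1", "1/0")] <- 1L
      out[x == "1/1"] <- 2L
      out
    }
    dos <- t(apply(gt, 2L, code))  # samples x loci
    dos <- matrix(as.integer(dos), nrow = ncol(gt),
                  dimnames = list(colnames(gt), rownames(gt)))
    ids <- rownames(gt)
    if (anyDuplicated(ids)) stop("duplicate locus id in VCF")
    loci <- data.frame(id = ids, chrom = as.character(fix[, "CHROM"]),
                       bp = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
    cyc <- cycles %||% rep(NA_character_, ncol(gt))
    genotype_matrix(dos, loci = loci,
                    samples = data.frame(id = colnames(gt), cycle = cyc,
                                         stringsAsFactors = FALSE))
  }
}

#' Write genotypes in the delimited dialect
#'
#' Writes the tab-separated sample x locus matrix plus a `<path>.map`
#' sidecar with locus coordinates, such that
#' `read_genotypes(write_genotypes(g, path))` reproduces `g` exactly.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- data.frame(sample = g$samples$id, cycle = g$samples$cycle,
                  stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(g$dosages) > 0L)
    d <- cbind(d, as.data.frame(g$dosages, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(g$loci[, c("id", "chrom", "bp")], paste0(path, ".map"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Maximum-likelihood allele frequencies, optionally per cycle
#'
#' The estimator is the observed count of alternate-allele copies divided by
#' twice the number of individuals with an observed genotype at the locus.
#'
#' @param g A [genotype_matrix()].
#' @param by_cycle If `TRUE`, estimate separately within each cycle.
#' @return A `data.frame` of class `allele_freq_table` with columns `locus`,
#'   `cycle` (`"all"` when pooled), `p_hat` and `n_obs`. Loci with zero
#'   observed genotypes in a cycle get `p_hat = NA`.
#' @export
estimate_allele_frequencies <- function(g, by_cycle = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"))
  groups <- if (by_cycle) g$cycle_levels else "all"
  out <- lapply(groups, function(cy) {
    rows <- if (identical(cy, "all")) rep(TRUE, nrow(g$dosages))
            else g$samples$cycle == cy
    d <- g$dosages[rows, , drop = FALSE]
    n_obs <- colSums(!is.na(d))
    p <- colSums(d, na.rm = TRUE) / (2 * n_obs)
    p[n_obs == 0L] <- NA_real_
    data.frame(locus = g$loci$id, cycle = cy, p_hat = unname(p),
               n_obs = as.integer(unname(n_obs)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("allele_freq_table", "data.frame")
  out
}

# loci x cycles matrix view of an allele_freq_table
.freq_matrix <- function(freqs) {
  loci <- unique(freqs$locus)
  cycles <- unique(freqs$cycle)
  m <- matrix(NA_real_, length(loci), length(cycles),
              dimnames = list(loci, cycles))
  m[cbind(match(freqs$locus, loci), match(freqs$cycle, cycles))] <- freqs$p_hat
  m
}

#' Filter loci on minor-allele frequency and missingness
#'
#' Retains loci whose pooled minor-allele frequency is strictly greater than
#' `maf_min` and whose missing proportion is at most `max_missing`. The
#' minor allele is determined from the pooled dataset so allele orientation
#' stays stable across cycles.
#'
#' @param g A [genotype_matrix()].
#' @param maf_min Minor-allele frequency threshold in `[0, 0.5]` (strict
#'   inequality).
#' @param max_missing Maximum tolerated missing proportion in `[0, 1]`.
#' @return The filtered [genotype_matrix()]; attribute `"filter_log"` lists
#'   counts removed per criterion.
#' @export
filter_loci <- function(g, maf_min = 0.025, max_missing = 0.20) {
  stopifnot(inherits(g, "genotype_matrix"),
            maf_min >= 0, maf_min <= 0.5, max_missing >= 0, max_missing <= 1)
  d <- g$dosages
  n_obs <- colSums(!is.na(d))
  p <- ifelse(n_obs > 0, colSums(d, na.rm = TRUE) / (2 * n_obs), NA_real_)
  maf <- pmin(p, 1 - p)
  missp <- colMeans(is.na(d))
  # maf_min = 0 disables the frequency filter entirely (identity contract);
  # positive thresholds use the strict ">" rule
  keep_maf <- if (maf_min == 0) rep(TRUE, ncol(d))
              else !is.na(maf) & maf > maf_min
  keep_miss <- missp <= max_missing
  keep <- keep_maf & keep_miss
  out <- genotype_matrix(d[, keep, drop = FALSE],
                         loci = g$loci[keep, , drop = FALSE],
                         samples = g$samples, cycle_levels = g$cycle_levels)
  attr(out, "filter_log") <- list(
    n_input = ncol(d),
    removed_maf = sum(!keep_maf),
    removed_missing = sum(!keep_miss),
    n_retained = sum(keep))
  out
}

#' Impute missing genotypes
#'
#' `locus_mean` fills each missing genotype with the rounded expected dosage
#' `round(2 * p_hat)`; `frequency_draw` samples a genotype from
#' Hardy--Weinberg proportions at the locus's observed frequency.
#'
#' @param g A [genotype_matrix()].
#' @param method `"locus_mean"` or `"frequency_draw"`.
#' @return A [genotype_matrix()] with no missing values.
#' @export
impute_missing <- function(g, method = c("locus_mean", "frequency_draw")) {
  method <- match.arg(method)
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0L))
    stop("locus with no observed genotypes cannot be imputed: ",
         paste(g$loci$id[n_obs == 0L], collapse = ", "))
  if (!anyNA(d)) return(g)
  p <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  for (j in which(colSums(is.na(d)) > 0L)) {
    nas <- which(is.na(d[, j]))
    if (method == "locus_mean") {
      d[nas, j] <- as.integer(round(2 * p[j]))
    } else {
      d[nas, j] <- sample(0:2, length(nas), replace = TRUE,
                          prob = c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2))
    }
  }
  genotype_matrix(d, loci = g$loci, samples = g$samples,
                  cycle_levels = g$cycle_levels)
}
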