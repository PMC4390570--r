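# Gene diversity (expected heterozygosity) scans across selection cycles.

#' Gene diversity at a biallelic locus
#'
#' `D = 1 - (p^2 + q^2) = 2 p q`, the expected heterozygosity; at most 0.5
#' for a biallelic locus and 0 iff fixed. Invariant to allele orientation.
#'
#' @param p Allele frequency (vectorized), in `[0, 1]`.
#' @return Gene diversity value(s).
#' @export
gene_diversity <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p must be in [0, 1]")
  1 - (p^2 + (1 - p)^2)
}

#' Per-SNP, per-cycle gene diversity scan
#'
#' @param freqs An `allele_freq_table` from
#'   [estimate_allele_frequencies()] with `by_cycle = TRUE`.
#' @param cycles Ordered cycle labels to include.
#' @param loci Optional `data.frame` with `id`, `chrom`, `bp` giving locus
#'   coordinates (required for region summaries).
#' @return An object of class `diversity_scan`: `d` (loci x cycles matrix),
#'   `summary` (per-cycle genome-wide mean and SD of D), `loci`.
#' @export
diversity_scan <- function(freqs, cycles, loci = NULL) {
  fm <- .freq_matrix(freqs)
  if (!all(cycles %in% colnames(fm)))
    stop("cycle(s) absent from frequency table: ",
         paste(setdiff(cycles, colnames(fm)), collapse = ", "))
  d <- gene_diversity(fm[, cycles, drop = FALSE])
  summ <- data.frame(cycle = cycles,
                     mean_d = apply(d, 2L, mean, na.rm = TRUE),
                     sd_d = apply(d, 2L, stats::sd, na.rm = TRUE),
                     n_loci = apply(d, 2L, function(x) sum(!is.na(x))),
                     row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(loci)) {
    loci <- loci[match(rownames(d), loci$id), , drop = FALSE]
  }
  structure(list(d = d, summary = summ, loci = loci),
            class = "diversity_scan")
}

#' @export
print.diversity_scan <- function(x, ...) {
  cat("diversity_scan over", nrow(x$d), "loci\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Region definition helper
#'
#' @param chrom Chromosome identifier.
#' @param start_bp,end_bp 1-based inclusive physical bounds.
#' @param label Region name.
#' @return A one-row `data.frame`; `rbind` several to build a region set.
#' @export
genomic_region <- function(chrom, start_bp, end_bp, label = NULL) {
  stopifnot(start_bp <= end_bp)
  data.frame(chrom = as.character(chrom), start_bp = as.numeric(start_bp),
             end_bp = as.numeric(end_bp),
             label = label %||% sprintf("%s:%.0f-%.0f", chrom, start_bp, end_bp),
             stringsAsFactors = FALSE)
}

#' Default diversity-loss regions of the WQS program
#'
#' Windows of `half_width` bp on either side of the centers of the three
#' regions of pronounced diversity loss reported for the WQS population
#' (chromosome 2 near 132 Mbp, chromosome 3 near 55 Mbp, chromosome 4 near
#' 78 Mbp).
#'
#' @param half_width Window half-width in bp.
#' @return A region `data.frame` (one row per region).
#' @export
wqs_regions <- function(half_width = 15e6) {
  centers <- data.frame(chrom = c("chr2", "chr3", "chr4"),
                        center = c(132e6, 55e6, 78e6))
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    genomic_region(centers$chrom[i],
                   max(1, centers$center[i] - half_width),
                   centers$center[i] + half_width,
                   label = paste0(centers$chrom[i], "_loss"))))
}

#' Region-level diversity reduction between two cycles
#'
#' For each region, averages D over the loci inside it in both cycles and
#' reports the percent reduction `100 (D_from - D_to) / D_from`, rounded to
#' the nearest integer percent for reporting (raw values retained).
#'
#' @param scan A [diversity_scan()] carrying locus coordinates.
#' @param regions Region `data.frame` (see [genomic_region()]).
#' @param cycle_from,cycle_to Cycle labels present in the scan.
#' @return `data.frame` with per-region mean D at both cycles, raw and
#'   rounded percent reduction, and locus counts.
#' @export
region_reduction_summary <- function(scan, regions, cycle_from, cycle_to) {
  stopifnot(inherits(scan, "diversity_scan"))
  if (is.null(scan$loci) || all(is.na(scan$loci$chrom)))
    stop("scan carries no locus coordinates; supply 'loci' to diversity_scan")
  if (!all(c(cycle_from, cycle_to) %in% colnames(scan$d)))
    stop("cycles absent from scan")
  out <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    inr <- !is.na(scan$loci$chrom) & scan$loci$chrom == r$chrom &
      scan$loci$bp >= r$start_bp & scan$loci$bp <= r$end_bp
    if (!any(inr)) stop("region contains no loci: ", r$label)
    d_from <- mean(scan$d[inr, cycle_from], na.rm = TRUE)
    d_to <- mean(scan$d[inr, cycle_to], na.rm = TRUE)
    if (d_from == 0) stop("zero initial diversity in region: ", r$label)
    pct <- 100 * (d_from - d_to) / d_from
    data.frame(label = r$label, n_loci = sum(inr),
               mean_d_from = d_from, mean_d_to = d_to,
               percent_reduction = pct,
               percent_reduction_rounded = round(pct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Expected gene diversity under pure drift
#'
#' Closed form `d0 * (1 - 1/(2 ne))^t` for an idealized population of
#' effective size `ne` after `t` cycles; the comparison benchmark for
#' realized diversity decay.
#'
#' @param d0 Starting gene diversity.
#' @param ne Effective population size (> 0).
#' @param t Number of cycles (>= 0).
#' @return Expected diversity.
#' @export
expected_drift_diversity <- function(d0, ne, t) {
  stopifnot(ne > 0, t >= 0)
  d0 * (1 - 1 / (2 * ne))^t
}

#' Effective size implied by an observed diversity decay
#'
#' Inverts [expected_drift_diversity()]: given genome-wide mean D at the
#' first and last cycle and the elapsed number of cycles, returns the
#' idealized-population size that would produce the same decay.
#'
#' @param d0,dt Mean gene diversity at start and end.
#' @param t Cycles elapsed.
#' @return Implied effective size (Inf if no decay).
#' @export
implied_effective_size <- function(d0, dt, t) {
  stopifnot(d0 > 0, t > 0)
  if (dt >= d0) return(Inf)
  1 / (2 * (1 - (dt / d0)^(1 / t)))
}
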