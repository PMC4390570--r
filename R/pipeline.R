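# End-to-end orchestration: one flat key=value config drives
# simulate -> filter -> impute -> Fst scan + drift null -> diversity ->
# variance components / G-BLUP / association -> machine-readable report.
# Identical config + seed => identical report.

#' Default pipeline configuration
#'
#' Flat key/value settings; every key can be overridden by [run_config()]
#' input or the `overrides` argument of [run_pipeline()].
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    # input mode: either genotype_file (+ optional phenotype_file) or simulate
    genotype_file = "",
    phenotype_file = "",
    simulate = TRUE,
    n_loci = 2000L,
    n_chrom = 10L,
    protocol = "wqs",            # or "custom" with fields below unused
    maf_min = 0.025,
    max_missing = 0.20,
    impute_method = "locus_mean",
    null_reps = 1000L,
    fwer = 0.05,
    region_half_width = 15e6,
    stages = "simulate,filter,scan,diversity,quantgen",
    seed = 1L,
    out_dir = "results/pipeline"
  )
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are
#' coerced to the type of the matching [default_config()] entry. Unknown
#' keys are an error.
#'
#' @param path Config file, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file.
#' @return Validated config list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  set_kv <- function(cfg, key, val) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    proto <- cfg[[key]]
    cfg[[key]] <- if (is.integer(proto)) as.integer(val)
      else if (is.numeric(proto)) as.numeric(val)
      else if (is.logical(proto)) as.logical(val)
      else as.character(val)
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
      if (length(kv) != 2L) stop("malformed config line: ", ln)
      cfg <- set_kv(cfg, trimws(kv[1L]), trimws(kv[2L]))
    }
  }
  for (k in names(overrides)) cfg <- set_kv(cfg, k, overrides[[k]])
  if (nzchar(cfg$genotype_file) && cfg$simulate)
    stop("exactly one of genotype_file / simulate must be set")
  if (!nzchar(cfg$genotype_file) && !cfg$simulate)
    stop("exactly one of genotype_file / simulate must be set")
  if (nzchar(cfg$genotype_file) && !file.exists(cfg$genotype_file))
    stop("genotype file not found: ", cfg$genotype_file)
  class(cfg) <- "run_config"
  cfg
}

.stage_seed <- function(seed, stage) {
  # deterministic per-stage substream, kept within 32-bit range
  offsets <- c(simulate = 101, filter = 211, scan = 307,
               diversity = 401, quantgen = 503)
  as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %% 2147483647)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the enabled stages in dependency order, writes every stage's
#' table under `out_dir`, and returns (and writes) a machine-readable
#' report. Identical config and seed produce identical results.
#'
#' @param config A [run_config()] (or `NULL` for defaults).
#' @param overrides Named list of config overrides.
#' @return The run report (list), invisibly also written as
#'   `report.json` under `out_dir`.
#' @export
run_pipeline <- function(config = NULL, overrides = list()) {
  cfg <- if (is.null(config)) run_config(NULL, overrides)
         else if (inherits(config, "run_config")) config
         else run_config(config, overrides)
  stages <- strsplit(cfg$stages, ",", fixed = TRUE)[[1L]]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed,
                 software_version = as.character(utils::packageVersion("wqscan")),
                 stages = stages)
  protocol <- wqs_protocol()

  # ---- data stage ----
  if (cfg$simulate) {
    if (!"simulate" %in% stages) stop("simulate stage required in simulate mode")
    set.seed(.stage_seed(cfg$seed, "simulate"))
    map <- uniform_map(cfg$n_loci, cfg$n_chrom)
    sim <- simulate_wqs_genomes(protocol, map,
                                missing_rate_range = c(0, 0.14))
    g <- sim$genotypes
    write_genotypes(g, file.path(cfg$out_dir, "genotypes.tsv"))
    report$simulate <- list(n_samples = nrow(g$dosages),
                            n_loci = ncol(g$dosages),
                            cycles = g$cycle_levels)
  } else {
    g <- read_genotypes(cfg$genotype_file)
    report$input <- list(genotype_file = cfg$genotype_file,
                         n_samples = nrow(g$dosages),
                         n_loci = ncol(g$dosages))
  }

  # ---- filter ----
  if ("filter" %in% stages) {
    g <- filter_loci(g, cfg$maf_min, cfg$max_missing)
    flog <- attr(g, "filter_log")
    report$filter <- flog
    utils::write.table(
      data.frame(criterion = c("input", "failed_maf", "failed_missing", "retained"),
                 count = c(flog$n_input, flog$removed_maf,
                           flog$removed_missing, flog$n_retained)),
      file.path(cfg$out_dir, "filter_log.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cyc <- g$cycle_levels
  first <- cyc[1L]; last <- cyc[length(cyc)]
  freqs <- estimate_allele_frequencies(g, by_cycle = TRUE)

  # ---- selection scan ----
  if ("scan" %in% stages) {
    set.seed(.stage_seed(cfg$seed, "scan"))
    scan <- fst_scan(freqs, first, last)
    fm <- .freq_matrix(freqs)
    null <- drift_null_thresholds(fm[, first], protocol,
                                  n_reps = cfg$null_reps, fwer = cfg$fwer)
    out99 <- empirical_outlier_threshold(scan, 0.99)
    enr <- enrichment_analysis(scan, null)
    utils::write.table(
      cbind(scan, g$loci[match(scan$locus, g$loci$id), c("chrom", "bp")]),
      file.path(cfg$out_dir, "fst_scan.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(fwer_threshold = null$fwer_threshold,
           perlocus_q95 = null$perlocus_q95,
           perlocus_q99 = null$perlocus_q99,
           n_reps = null$n_reps,
           seed = .stage_seed(cfg$seed, "scan")),
      file.path(cfg$out_dir, "null_thresholds.json"), auto_unbox = TRUE,
      digits = NA)
    report$scan <- list(
      cycles = c(first, last), n_usable = sum(scan$usable),
      fwer_threshold = null$fwer_threshold,
      perlocus_q95 = null$perlocus_q95, perlocus_q99 = null$perlocus_q99,
      n_above_fwer = sum(scan$fst[scan$usable] > null$fwer_threshold),
      outlier99_threshold = out99$threshold,
      outlier99_flagged = out99$n_flagged,
      observed_prop95 = enr$observed_prop95,
      observed_prop99 = enr$observed_prop99)
  }

  # ---- diversity ----
  if ("diversity" %in% stages) {
    dsc <- diversity_scan(freqs, cyc, loci = g$loci)
    utils::write.table(
      cbind(g$loci, as.data.frame(dsc$d)),
      file.path(cfg$out_dir, "diversity_scan.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    md <- dsc$summary$mean_d
    genomewide <- 100 * (md[1L] - md[length(md)]) / md[1L]
    report$diversity <- list(
      per_cycle = dsc$summary,
      genomewide_percent_reduction = genomewide,
      implied_ne = implied_effective_size(md[1L], md[length(md)],
                                          length(cyc) - 1L))
  }

  # ---- quantgen ----
  if ("quantgen" %in% stages) {
    set.seed(.stage_seed(cfg$seed, "quantgen"))
    pheno <- if (cfg$simulate) simulate_phenotypes(g)
             else if (nzchar(cfg$phenotype_file))
               utils::read.csv(cfg$phenotype_file, stringsAsFactors = FALSE)
             else NULL
    if (!is.null(pheno)) {
      vc <- fit_family_varcomps(pheno)
      gi <- impute_missing(g, cfg$impute_method)
      G <- genomic_relationship_matrix(gi)
      fams <- names(vc$blups)
      keep <- match(fams, gi$samples$id)
      fit <- gblup_reml(vc$blups, G[keep, keep],
                        fixed = factor(gi$samples$cycle[keep]))
      assoc <- association_scan(vc$blups, gi$dosages[keep, , drop = FALSE],
                                G[keep, keep],
                                fixed = factor(gi$samples$cycle[keep]))
      utils::write.table(assoc, file.path(cfg$out_dir, "association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$quantgen <- list(
        sigma2_G = vc$sigma2_G, sigma2_GE = vc$sigma2_GE,
        sigma2_e = vc$sigma2_e, H = broad_sense_H(vc),
        h2_g = fit$h2_g,
        n_significant = sum(assoc$significant, na.rm = TRUE))
    }
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Generate a self-contained synthetic fixture dataset
#'
#' Emits genotype, map, phenotype and truth files for a named preset:
#' `wqs_like_small` (2,000 SNPs, 4 cycles, 20 families per cycle),
#' `wqs_like_full` (17,590 SNPs, the scan size of the motivating program),
#' `selection_injected` (small preset plus 5 truncation-selected loci,
#' listed in the truth file).
#'
#' @param preset Fixture name.
#' @param seed Integer seed (fully determines the files).
#' @param out_dir Output directory (created if needed).
#' @return Named list of the files written, invisibly.
#' @export
generate_fixture_dataset <- function(preset = c("wqs_like_small",
                                                "wqs_like_full",
                                                "selection_injected"),
                                     seed = 1L, out_dir = ".") {
  preset <- match.arg(preset)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  n_loci <- if (preset == "wqs_like_full") 17590L else 2000L
  protocol <- wqs_protocol()
  map <- uniform_map(n_loci)
  sim <- simulate_wqs_genomes(protocol, map,
                              missing_rate_range = c(0, 0.14))
  g <- sim$genotypes
  truth <- list(seed = as.integer(seed), preset = preset,
                founder_freq = sim$founder_freq,
                cycle_freq = as.data.frame(sim$cycle_freq),
                sample_freq = as.data.frame(sim$sample_freq),
                varcomps = c(G = 4, GE = 2, E = 6))

  qtl <- integer(0)
  if (preset == "selection_injected") {
    # 5 loci driven by per-cycle truncation selection, rendered unlinked:
    # replace 5 genotype columns by independently simulated selected loci
    # inject at loci where the favored allele starts at intermediate
    # frequency, the scenario selection mapping is meant to detect
    candidates <- which(sim$founder_freq >= 0.15 & sim$founder_freq <= 0.5)
    qtl <- sort(sample(candidates, 5L))
    cycf <- factor(g$samples$cycle, levels = g$cycle_levels)
    for (j in qtl) {
      p0 <- sim$founder_freq[j]
      sel <- .selected_locus_samples(p0, protocol, g)
      g$dosages[, j] <- sel
      truth$sample_freq[j, ] <- tapply(sel, cycf, mean) / 2
    }
    truth$selected_loci <- g$loci$id[qtl]
  }

  geno_path <- file.path(out_dir, "genotypes.tsv")
  write_genotypes(g, geno_path)
  map_path <- file.path(out_dir, "map.tsv")
  write_map(map, map_path)

  arch <- if (length(qtl) > 0L)
    trait_architecture(qtl, rep(1, length(qtl))) else NULL
  pheno <- simulate_phenotypes(g, arch = arch,
                               varcomps = truth$varcomps)
  pheno_path <- file.path(out_dir, "phenotypes.csv")
  utils::write.csv(pheno, pheno_path, row.names = FALSE)
  truth$family_values <- attr(pheno, "truth")$family_values

  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(genotypes = geno_path, map = map_path,
                 phenotypes = pheno_path, truth = truth_path))
}

# Simulate the genotyped-sample dosages of one selected unlinked locus,
# matching the per-cycle sample layout of `g`: the n_selected family
# representatives of each advance plus the final-cycle families. Selection
# is truncation on a noisy single-locus criterion with heritability
# `sel_h2`; full heritability fixes the locus within the first advance,
# which would leave nothing to scan, so the fixture spreads the response
# over the cycles.
.selected_locus_samples <- function(p0, protocol, g, sel_h2 = 0.3) {
  cyc <- g$cycle_levels
  tab <- table(factor(g$samples$cycle, levels = cyc))
  # explicit family genotype vectors (single locus, so cheap)
  pop <- sample(0:2, protocol$next_cycle_pop_size, replace = TRUE,
                prob = c((1 - p0)^2, 2 * p0 * (1 - p0), p0^2))
  out <- integer(0)
  ssd1 <- function(v) {  # one SSD selfing generation, vectorized
    het <- v == 1L
    v[het] <- stats::rbinom(sum(het), 2L, 0.5)
    v
  }
  for (k in seq_along(protocol$cycles)) {
    spec <- protocol$cycles[[k]]
    fams <- sample(pop, spec$n_s0_plants, replace = TRUE)
    for (gg in seq_len(spec$selfing_generations)) fams <- ssd1(fams)
    fams <- sample(fams, spec$n_after_screen)
    vg <- stats::var(fams)
    noise_sd <- if (vg > 0 && sel_h2 > 0 && sel_h2 < 1)
      sqrt(vg * (1 - sel_h2) / sel_h2) else 0
    score <- fams + stats::rnorm(length(fams), 0, noise_sd)
    sel <- fams[order(score, decreasing = TRUE)[seq_len(spec$n_selected)]]
    out <- c(out, sample(sel)[seq_len(tab[k])])
    # bulk-entry recombination
    M <- protocol$next_cycle_pop_size
    i1 <- sample.int(spec$n_selected, M, replace = TRUE)
    off <- (i1 + sample.int(spec$n_selected - 1L, M, replace = TRUE) - 1L) %%
      spec$n_selected + 1L  # second family distinct from the first
    gam <- function(i) stats::rbinom(M, 1L, sel[i] / 2)
    pop <- gam(i1) + gam(off)
  }
  # final cycle: S1 plants selfed once from the last population
  s1 <- ssd1(sample(pop, tab[length(tab)]))
  c(out, s1)
}
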