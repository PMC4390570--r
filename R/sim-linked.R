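# Linked whole-genome engine: individual-based simulation with recombination
# over a genetic map. Used as the synthetic-data generator; the unlinked
# engine in sim-unlinked.R is the fast path for drift-null thresholds.

#' Construct a genetic map
#'
#' @param chrom Chromosome identifier per locus.
#' @param id Locus identifier (unique).
#' @param cM Genetic position in centimorgans, non-decreasing within a
#'   chromosome.
#' @param bp Physical position (1-based), unique within a chromosome.
#' @return A `data.frame` of class `genetic_map`.
#' @export
genetic_map <- function(chrom, id, cM, bp) {
  m <- data.frame(chrom = as.character(chrom), id = as.character(id),
                  cM = as.numeric(cM), bp = as.integer(bp),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(m$id)) stop("locus ids must be unique")
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    if (is.unsorted(m$cM[i])) stop("cM must be non-decreasing within chromosome ", ch)
    if (anyDuplicated(m$bp[i])) stop("bp must be unique within chromosome ", ch)
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' An evenly spaced synthetic genetic map
#'
#' Convenience map builder: `n_loci` markers spread uniformly over
#' `n_chrom` chromosomes of equal genetic and physical length, mimicking the
#' low crossover density of a maize-like genome (about 1.5--2 crossovers per
#' chromosome per meiosis at the default 160 cM).
#'
#' @param n_loci Total marker count.
#' @param n_chrom Number of chromosomes.
#' @param chrom_cM Genetic length per chromosome (cM).
#' @param chrom_bp Physical length per chromosome (bp).
#' @return A [genetic_map()].
#' @export
uniform_map <- function(n_loci, n_chrom = 10L, chrom_cM = 160,
                        chrom_bp = 2.3e8) {
  per <- diff(round(seq(0, n_loci, length.out = n_chrom + 1L)))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), per)
  pos <- unlist(lapply(per, function(k) seq_len(k) / (k + 1)))
  genetic_map(chrom = chrom,
              id = sprintf("snp%05d", seq_len(n_loci)),
              cM = pos * chrom_cM,
              bp = as.integer(round(pos * chrom_bp)))
}

# read/write the 4-column delimited map dialect (chrom, id, cM, bp)
#' Read a genetic map from a 4-column tab-delimited file
#' @param path File with columns chrom, id, cM, bp (header required).
#' @return A [genetic_map()].
#' @export
read_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  genetic_map(m$chrom, m$id, m$cM, m$bp)
}

#' @rdname read_map
#' @param map A [genetic_map()] to write.
#' @export
write_map <- function(map, path) {
  utils::write.table(as.data.frame(map)[, c("chrom", "id", "cM", "bp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Precompute per-chromosome locus indices and cM ranges once per map.
.map_index <- function(map) {
  idx <- split(seq_len(nrow(map)), map$chrom)
  lapply(idx, function(i)
    list(i = i, cM = map$cM[i], len = max(map$cM[i]) - min(map$cM[i]),
         lo = min(map$cM[i])))
}

#' Produce one gamete by meiosis under the Haldane model
#'
#' Crossovers per chromosome are Poisson with mean chromosome-cM/100 (no
#' interference), positions uniform on the genetic length; chromosomes
#' assort independently.
#'
#' @param h1,h2 Parental haplotypes: integer vectors of 0/1 over the map loci.
#' @param map A [genetic_map()].
#' @return An integer haplotype vector (mosaic of `h1` and `h2`).
#' @export
meiosis_gamete <- function(h1, h2, map) {
  if (length(h1) != nrow(map) || length(h2) != nrow(map))
    stop("haplotype length does not match the map")
  .meiosis(h1, h2, .map_index(map))
}

.meiosis <- function(h1, h2, mi) {
  out <- h1
  for (ch in mi) {
    nxo <- stats::rpois(1L, ch$len / 100)
    phase0 <- sample.int(2L, 1L) == 2L
    if (nxo == 0L) {
      if (phase0) out[ch$i] <- h2[ch$i]
    } else {
      cuts <- sort(stats::runif(nxo, ch$lo, ch$lo + ch$len))
      seg <- findInterval(ch$cM, cuts)  # parity of crossover count to the left
      from2 <- xor(phase0, seg %% 2L == 1L)
      ii <- ch$i[from2]
      out[ii] <- h2[ii]
    }
  }
  out
}

#' Self a genotype by single-seed descent
#'
#' Each generation draws one selfed offspring (two independent meioses of the
#' same plant); expected per-locus heterozygosity halves per generation.
#'
#' @param genotype A list with haplotypes `h1` and `h2` (0/1 integer vectors).
#' @param generations Number of selfing generations (>= 0).
#' @param map A [genetic_map()].
#' @return A genotype list with elements `h1`, `h2`.
#' @export
self_single_seed_descent <- function(genotype, generations, map) {
  stopifnot(generations >= 0)
  mi <- .map_index(map)
  g <- genotype
  for (k in seq_len(generations))
    g <- list(h1 = .meiosis(g$h1, g$h2, mi), h2 = .meiosis(g$h1, g$h2, mi))
  g
}

#' Create a population state
#'
#' @param h1,h2 Integer matrices (individuals x loci) of 0/1 alleles; rows are
#'   the two haplotypes of each individual.
#' @param cycle_label Population label.
#' @return An object of class `population_state`.
#' @export
population_state <- function(h1, h2, cycle_label = "G0") {
  stopifnot(is.matrix(h1), is.matrix(h2), all(dim(h1) == dim(h2)),
            nrow(h1) > 0)
  structure(list(h1 = h1, h2 = h2, cycle_label = cycle_label),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("population_state '%s': %d individuals x %d loci\n",
              x$cycle_label, nrow(x$h1), ncol(x$h1)))
  invisible(x)
}

#' Founder population at linkage equilibrium
#'
#' @param n Number of diploid individuals.
#' @param p Per-locus allele frequencies.
#' @param cycle_label Label for the base population.
#' @return A [population_state()].
#' @export
founder_population <- function(n, p, cycle_label = "G0") {
  L <- length(p)
  draw <- function() matrix(stats::rbinom(n * L, 1L, rep(p, each = n)),
                            nrow = n, ncol = L)
  population_state(draw(), draw(), cycle_label)
}

.dosage_of <- function(g) g$h1 + g$h2

#' Advance a population one cycle of the breeding protocol
#'
#' Individual-based (linked) counterpart of the unlinked fast path: draws S0
#' founders, selfs each lineage by single-seed descent, screens at random,
#' selects families (at random under the drift null, by `selection_fn`
#' ranking otherwise) and recombines the selected family representatives by
#' the protocol's scheme into the next cycle's population.
#'
#' @param pop A [population_state()].
#' @param spec A [cycle_spec()].
#' @param protocol A [breeding_protocol()] (recombination scheme, offspring
#'   count, plants per family).
#' @param selection_fn Optional function; receives the families-by-loci
#'   dosage matrix of the screened family representatives and returns a
#'   numeric score per family. The `n_selected` highest-scoring families are
#'   selected. `NULL` (default) selects uniformly at random (drift null).
#' @param map A [genetic_map()].
#' @param next_label Label for the resulting population.
#' @return A [population_state()] for the next cycle. Attribute
#'   `"selected_families"` holds the selected family representatives as a
#'   list with haplotype matrices `h1`, `h2` (one row per family, first plant
#'   of each family).
#' @export
advance_cycle <- function(pop, spec, protocol, selection_fn = NULL, map,
                          next_label = "next") {
  stopifnot(inherits(pop, "population_state"), inherits(spec, "cycle_spec"),
            inherits(protocol, "breeding_protocol"))
  n <- nrow(pop$h1)
  L <- ncol(pop$h1)
  if (nrow(map) != L) stop("map does not match population loci")
  mi <- .map_index(map)
  ppf <- protocol$plants_per_family

  founders <- sample.int(n, spec$n_s0_plants, replace = TRUE)

  # Self each lineage: SSD through (g-1) generations to a single plant, then
  # plants_per_family sib plants from one final selfing generation.
  g <- spec$selfing_generations
  fam <- vector("list", spec$n_s0_plants)
  for (k in seq_len(spec$n_s0_plants)) {
    plant <- list(h1 = pop$h1[founders[k], ], h2 = pop$h2[founders[k], ])
    if (g == 0L) {
      fam[[k]] <- list(plant)
    } else {
      if (g > 1L) plant <- self_single_seed_descent(plant, g - 1L, map)
      fam[[k]] <- lapply(seq_len(ppf), function(j)
        list(h1 = .meiosis(plant$h1, plant$h2, mi),
             h2 = .meiosis(plant$h1, plant$h2, mi)))
    }
  }

  screened <- sample.int(spec$n_s0_plants, spec$n_after_screen)
  fam <- fam[screened]

  if (is.null(selection_fn)) {
    sel <- sample.int(spec$n_after_screen, spec$n_selected)
  } else {
    dos <- t(matrix(vapply(fam, function(f) .dosage_of(f[[1L]]), integer(L)),
                    nrow = L))
    score <- selection_fn(dos)
    if (length(score) != spec$n_after_screen)
      stop("selection_fn must return one score per screened family")
    sel <- order(score, decreasing = TRUE)[seq_len(spec$n_selected)]
  }
  fam <- fam[sel]
  ns <- spec$n_selected

  # Recombination
  M <- protocol$next_cycle_pop_size
  h1 <- matrix(0L, M, L)
  h2 <- matrix(0L, M, L)
  bulk <- protocol$recombination_scheme == "bulk_entry_diallel"
  if (bulk && ns < 2L) stop("bulk entry needs >= 2 selected families")
  for (o in seq_len(M)) {
    if (bulk) {
      pair <- sample.int(ns, 2L)
    } else {
      pair <- sample.int(ns, 2L, replace = TRUE)
    }
    f1 <- fam[[pair[1L]]]; f2 <- fam[[pair[2L]]]
    pl1 <- f1[[sample.int(length(f1), 1L)]]
    pl2 <- f2[[sample.int(length(f2), 1L)]]
    h1[o, ] <- .meiosis(pl1$h1, pl1$h2, mi)
    h2[o, ] <- .meiosis(pl2$h1, pl2$h2, mi)
  }

  out <- population_state(h1, h2, next_label)
  reps1 <- t(matrix(vapply(fam, function(f) f[[1L]]$h1, integer(L)), nrow = L))
  reps2 <- t(matrix(vapply(fam, function(f) f[[1L]]$h2, integer(L)), nrow = L))
  attr(out, "selected_families") <- list(h1 = reps1, h2 = reps2)
  out
}

#' Simulate multi-cycle whole-genome data for a breeding program
#'
#' Linked synthetic-data generator: founder haplotypes are drawn at linkage
#' equilibrium from `founder_spectrum`, the population is advanced through
#' every cycle of `protocol`, and the selected family representatives of each
#' cycle are emitted as the "genotyped" samples (mimicking the remnant-seed
#' sampling of real recurrent-selection programs). For the final cycle,
#' `n_final` individuals drawn from the last population and selfed once
#' stand in for its S1 families.
#'
#' @param protocol A [breeding_protocol()].
#' @param map A [genetic_map()].
#' @param founder_spectrum Either a numeric vector of founder allele
#'   frequencies (length `nrow(map)`) or a function `f(n)` returning one.
#'   The default `runif(n, 0.025, 0.975)` yields mean founder gene diversity
#'   of about 0.35.
#' @param n_founders Size of the base population.
#' @param n_final Families emitted for the final cycle label.
#' @param missing_rate_range Range of per-locus missing-genotype rates
#'   applied to the emitted matrix (uniform per locus); `c(0, 0)` disables
#'   missingness.
#' @return A list of class `wqs_sim`: `genotypes` (a [genotype_matrix()]
#'   spanning all cycles), `founder_freq`, `cycle_freq` (loci x cycles true
#'   allele frequencies in the full populations) and `sample_freq` (loci x
#'   cycles frequencies of the emitted family cohorts before missingness;
#'   the 20-family cohorts drift well away from the full populations, so
#'   only these are recoverable from the emitted genotypes).
#' @export
simulate_wqs_genomes <- function(protocol, map,
                                 founder_spectrum = function(n)
                                   stats::runif(n, 0.025, 0.975),
                                 n_founders = protocol$next_cycle_pop_size,
                                 n_final = protocol$cycles[[
                                   length(protocol$cycles)]]$n_selected,
                                 missing_rate_range = c(0, 0)) {
  stopifnot(inherits(protocol, "breeding_protocol"), nrow(map) > 0)
  L <- nrow(map)
  p <- if (is.function(founder_spectrum)) founder_spectrum(L)
       else founder_spectrum
  if (length(p) != L) stop("founder_spectrum must provide one frequency per locus")
  labels <- protocol$cycle_labels
  pop <- founder_population(n_founders, p, labels[1L])

  nc <- length(protocol$cycles)
  cycle_freq <- matrix(NA_real_, L, nc + 1L,
                       dimnames = list(map$id, labels))
  cycle_freq[, 1L] <- colMeans(pop$h1 + pop$h2) / 2

  dosage_blocks <- list()
  sample_cycles <- character(0)
  for (k in seq_len(nc)) {
    pop <- advance_cycle(pop, protocol$cycles[[k]], protocol,
                         selection_fn = NULL, map = map,
                         next_label = labels[k + 1L])
    selfam <- attr(pop, "selected_families")
    # selected family representatives carry the label of the cycle they were
    # selected in (their remnant seed represents that cycle)
    dosage_blocks[[k]] <- selfam$h1 + selfam$h2
    sample_cycles <- c(sample_cycles,
                       rep(labels[k], nrow(selfam$h1)))
    cycle_freq[, k + 1L] <- colMeans(pop$h1 + pop$h2) / 2
  }
  # final cycle: S1 families from the last population
  mi <- .map_index(map)
  idx <- sample.int(nrow(pop$h1), n_final)
  fin <- matrix(0L, n_final, L)
  for (j in seq_len(n_final)) {
    g <- list(h1 = pop$h1[idx[j], ], h2 = pop$h2[idx[j], ])
    s1 <- list(h1 = .meiosis(g$h1, g$h2, mi), h2 = .meiosis(g$h1, g$h2, mi))
    fin[j, ] <- s1$h1 + s1$h2
  }
  dosage_blocks[[nc + 1L]] <- fin
  sample_cycles <- c(sample_cycles, rep(labels[nc + 1L], n_final))

  dos <- do.call(rbind, dosage_blocks)
  if (any(missing_rate_range > 0)) {
    rate <- stats::runif(L, missing_rate_range[1L], missing_rate_range[2L])
    mask <- matrix(stats::runif(length(dos)) < rep(rate, each = nrow(dos)),
                   nrow(dos), L)
    dos[mask] <- NA_integer_
  }
  # frequencies of the emitted cohorts before any missingness masking
  sample_freq <- do.call(cbind, lapply(split(seq_len(nrow(dos)),
                                             factor(sample_cycles, levels = labels)),
                                       function(i) colMeans(dos[i, , drop = FALSE]) / 2))
  rownames(sample_freq) <- map$id
  g <- genotype_matrix(
    dos,
    loci = data.frame(id = map$id, chrom = map$chrom, bp = map$bp,
                      stringsAsFactors = FALSE),
    samples = data.frame(
      id = sprintf("%s_f%03d", sample_cycles,
                   stats::ave(seq_along(sample_cycles), sample_cycles,
                              FUN = seq_along)),
      cycle = sample_cycles, stringsAsFactors = FALSE),
    cycle_levels = labels)
  structure(list(genotypes = g, founder_freq = p, cycle_freq = cycle_freq,
                 sample_freq = sample_freq),
            class = "wqs_sim")
}
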