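#' Specify one cycle of a recurrent-selection protocol
#'
#' A cycle starts from S0 plants drawn out of the current population, selfs
#' each lineage by single-seed descent, screens families for agronomic
#' suitability, selects the top families on the selection criterion (or at
#' random under the drift null), and recombines them into the next cycle.
#'
#' @param n_s0_plants Number of S0 plants initiating S1 families.
#' @param n_after_screen Number of families kept after the agronomic screen.
#'   Defaults to half of `n_s0_plants` (screens in real programs discarded
#'   roughly 50--67% of families). Under the drift null the screen is a
#'   uniform subsample, so this value does not affect drift outcomes.
#' @param n_selected Number of families selected for recombination.
#' @param selfing_generations Number of self-pollination steps from the S0
#'   plant to the recombined family representative (integer >= 0).
#' @return An object of class `cycle_spec`.
#' @seealso [breeding_protocol()], [wqs_protocol()]
#' @export
cycle_spec <- function(n_s0_plants, n_after_screen = ceiling(n_s0_plants / 2),
                       n_selected, selfing_generations = 2L) {
  n_s0_plants <- as.integer(n_s0_plants)
  n_after_screen <- as.integer(n_after_screen)
  n_selected <- as.integer(n_selected)
  selfing_generations <- as.integer(selfing_generations)
  stopifnot(length(n_s0_plants) == 1L, length(n_after_screen) == 1L,
            length(n_selected) == 1L, length(selfing_generations) == 1L)
  if (n_s0_plants < 1L || n_after_screen < 1L || n_selected < 1L)
    stop("all family counts must be >= 1")
  if (selfing_generations < 0L)
    stop("selfing_generations must be >= 0")
  if (!(n_selected <= n_after_screen && n_after_screen <= n_s0_plants))
    stop("need n_selected <= n_after_screen <= n_s0_plants")
  structure(list(n_s0_plants = n_s0_plants,
                 n_after_screen = n_after_screen,
                 n_selected = n_selected,
                 selfing_generations = selfing_generations),
            class = "cycle_spec")
}

#' Assemble a breeding protocol from cycle specifications
#'
#' @param cycles A list of [cycle_spec()] objects, one per selection cycle,
#'   in chronological order.
#' @param recombination_scheme `"bulk_entry_diallel"`: every selected family
#'   is crossed to every other selected family with equal expected
#'   contribution -- realized by drawing, for each offspring, an unordered
#'   pair of distinct selected families and one gamete from each.
#'   `"random_union"`: each offspring's two gametes come from families drawn
#'   independently with replacement (idealized Wright--Fisher mating; used
#'   for closed-form drift checks).
#' @param next_cycle_pop_size Number of individuals formed per cycle by
#'   recombination.
#' @param plants_per_family Number of sib plants representing a selected
#'   family when it contributes gametes (individual-based engine only; the
#'   unlinked fast path requires 1, the most conservative — maximal drift —
#'   setting).
#' @param cycle_labels Optional character vector of population labels, length
#'   `length(cycles) + 1` (base population first).
#' @return An object of class `breeding_protocol`.
#' @export
breeding_protocol <- function(cycles,
                              recombination_scheme = c("bulk_entry_diallel",
                                                       "random_union"),
                              next_cycle_pop_size = 450L,
                              plants_per_family = 1L,
                              cycle_labels = NULL) {
  recombination_scheme <- match.arg(recombination_scheme)
  if (inherits(cycles, "cycle_spec")) cycles <- list(cycles)
  if (length(cycles) < 1L) stop("at least one cycle is required")
  ok <- vapply(cycles, inherits, logical(1), what = "cycle_spec")
  if (!all(ok)) stop("'cycles' must be a list of cycle_spec objects")
  next_cycle_pop_size <- as.integer(next_cycle_pop_size)
  plants_per_family <- as.integer(plants_per_family)
  if (next_cycle_pop_size < 1L) stop("next_cycle_pop_size must be >= 1")
  if (plants_per_family < 1L) stop("plants_per_family must be >= 1")
  if (is.null(cycle_labels))
    cycle_labels <- paste0("G", seq(0L, length(cycles)))
  if (length(cycle_labels) != length(cycles) + 1L)
    stop("cycle_labels must have length(cycles) + 1 entries")
  structure(list(cycles = cycles,
                 recombination_scheme = recombination_scheme,
                 next_cycle_pop_size = next_cycle_pop_size,
                 plants_per_family = plants_per_family,
                 cycle_labels = as.character(cycle_labels)),
            class = "breeding_protocol")
}

#' The WQS recurrent-selection preset (cycles C2 through C5)
#'
#' Default demographic history of the Wisconsin Quality Synthetic maize
#' program over the genotyped span: 450 S1 families screened for the C2->C3
#' and C3->C4 advances, 200 for C4->C5, the top 20 S2 families selected and
#' recombined by the bulk entry method each cycle, with two selfing
#' generations (S0 plant -> S1 -> S2 representative).
#'
#' @param n_s0 Integer vector of S0 plant counts, one per cycle.
#' @param n_selected Families selected for recombination each cycle.
#' @param selfing_generations Selfing depth per cycle.
#' @param screen_keep Fraction of screened families retained.
#' @param next_cycle_pop_size Individuals formed by recombination per cycle.
#' @return A [breeding_protocol()].
#' @export
wqs_protocol <- function(n_s0 = c(450L, 450L, 200L), n_selected = 20L,
                         selfing_generations = 2L, screen_keep = 0.5,
                         next_cycle_pop_size = 450L) {
  cycles <- lapply(n_s0, function(n)
    cycle_spec(n_s0_plants = n,
               n_after_screen = max(n_selected, ceiling(n * screen_keep)),
               n_selected = n_selected,
               selfing_generations = selfing_generations))
  breeding_protocol(cycles,
                    recombination_scheme = "bulk_entry_diallel",
                    next_cycle_pop_size = next_cycle_pop_size,
                    cycle_labels = paste0("C", seq(2L, 2L + length(n_s0))))
}

#' @export
print.cycle_spec <- function(x, ...) {
  cat(sprintf(
    "cycle_spec: %d S0 plants -> %d screened -> %d selected (%d selfing gen)\n",
    x$n_s0_plants, x$n_after_screen, x$n_selected, x$selfing_generations))
  invisible(x)
}

#' @export
print.breeding_protocol <- function(x, ...) {
  cat(sprintf("breeding_protocol: %d cycle(s), %s recombination, pop size %d\n",
              length(x$cycles), x$recombination_scheme, x$next_cycle_pop_size))
  cat("labels:", paste(x$cycle_labels, collapse = " -> "), "\n")
  for (cs in x$cycles) print(cs)
  invisible(x)
}
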