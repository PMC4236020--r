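#' Adjust an adult neuron count to the termination of neurogenesis
#'
#' Postnatal apoptosis removes roughly a third of the neurons present at
#' the end of neurogenesis, so counts at termination are taken to be
#' 1.5-fold higher than in the adult brain.
#'
#' @param adult_count adult cortical neuron count(s), `>= 0`.
#' @param factor apoptosis adjustment factor (default 1.5).
#' @return `factor * adult_count`.
#' @examples
#' apoptosis_adjust(1.37e7)  # 2.055e7
#' @export
apoptosis_adjust <- function(adult_count, factor = 1.5) {
  if (any(!is.finite(adult_count)) || any(adult_count < 0)) {
    stop("'adult_count' must be non-negative", call. = FALSE)
  }
  factor * adult_count
}

#' Absolute percent deviation between predicted and observed counts
#'
#' @param predicted predicted neuron count(s).
#' @param observed observed neuron count(s), `> 0`.
#' @return `|100 * (predicted - observed) / observed|`.
#' @examples
#' deviation(1.5e7, 1e7)  # 50
#' @export
deviation <- function(predicted, observed) {
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop("'observed' must be positive", call. = FALSE)
  }
  abs(100 * (predicted - observed) / observed)
}

#' Per-cycle founder counts under a Sherley-style proliferative decay
#'
#' During early neurogenesis a diminishing fraction of neuroepithelial
#' cells keeps proliferating at the ventricle. This is modelled as a
#' per-cycle growth factor `(1 + n_t)` on the founder pool, with the
#' proliferative-fraction parameter `n_t` interpolated linearly from
#' `n_start` (1 at onset) to `n_end` (0 at the end of the schedule).
#' With `n == 1` throughout the pool doubles every cycle; with `n == 0`
#' it is constant. The default prediction pathway of [predict_neurons()]
#' treats tabulated founder pools as final estimates (constant schedule);
#' the decaying schedule is the documented option used when deriving
#' founder estimates from early-embryonic measurements.
#'
#' @param founder_pool founder count at the first cycle.
#' @param k number of cycles (`>= 1`).
#' @param n_start,n_end proliferative fraction in `[0, 1]` at the first and
#'   last cycle.
#' @return Numeric vector of length `k`: the pool size at each cycle.
#' @examples
#' founder_schedule(100, 3, n_start = 1, n_end = 1)  # 100 200 400
#' founder_schedule(3.99e5, 11, n_start = 0, n_end = 0)  # constant
#' @export
founder_schedule <- function(founder_pool, k, n_start = 1, n_end = 0) {
  if (length(k) != 1L || !is.finite(k) || k < 1) {
    stop("'k' must be a single value >= 1", call. = FALSE)
  }
  k <- as.integer(floor(k))
  for (nm in c(n_start = n_start, n_end = n_end)) {
    if (!is.finite(nm) || nm < 0 || nm > 1) {
      stop("'n_start' and 'n_end' must lie in [0, 1]", call. = FALSE)
    }
  }
  n_t <- if (k == 1L) n_start else seq(n_start, n_end, length.out = k)
  growth <- 1 + n_t
  pool <- founder_pool * cumprod(c(1, growth[-k]))
  pool
}

#' Averaged cell-cycle length from per-progenitor-type values
#'
#' The forward model uses a single averaged cell-cycle length per species.
#' When stage-resolved cell-cycle lengths are available (apical vs basal
#' progenitors, proliferative vs neurogenic), this helper collapses them to
#' the weighted average used in place of the fixed value. Predictions based
#' on fixed and averaged dynamic values agree closely when the stage values
#' scatter around the species average.
#'
#' @param stage_hours named numeric vector of per-stage cell-cycle lengths
#'   (hours).
#' @param weights optional non-negative weights (default equal).
#' @return A single averaged cell-cycle length in hours.
#' @export
effective_cell_cycle <- function(stage_hours, weights = NULL) {
  if (any(!is.finite(stage_hours)) || any(stage_hours <= 0)) {
    stop("'stage_hours' must be positive", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(stage_hours))
  if (length(weights) != length(stage_hours) || any(weights < 0) ||
      sum(weights) == 0) {
    stop("'weights' must be non-negative and match 'stage_hours'",
         call. = FALSE)
  }
  sum(stage_hours * weights) / sum(weights)
}

#' Predict the cortical neuron count at the termination of neurogenesis
#'
#' The deterministic forward model: the neuroepithelial founder pool is
#' partitioned across the seven progenitor lineages according to the
#' neurogenic program, every lineage runs from the first to the final day
#' of neurogenesis, and each partition is multiplied by its lineage's
#' cumulative neuron output at `floor(n_cycles)` whole cycles.
#'
#' The returned count is an end-of-neurogenesis quantity; compare it
#' against [apoptosis_adjust()]-ed observed adult counts.
#'
#' @param params a single-row species `data.frame` (see
#'   [read_species_csv()]) or a list with at least `founder_pool` and
#'   either `neurogenic_days` + `cell_cycle_hours`.
#' @param program a [neurogenic_program()] (or anything coercible).
#' @param lineages list of [lineage()] objects (default all seven).
#' @param stage_cell_cycle_hours optional named vector of per-stage
#'   cell-cycle lengths; when given, their [effective_cell_cycle()] average
#'   replaces `params$cell_cycle_hours`.
#' @return Predicted neuron count at the termination of neurogenesis.
#' @examples
#' mouse <- species_table()[species_table()$species == "Mouse", ]
#' predict_neurons(mouse, "mouse")
#' @export
predict_neurons <- function(params, program, lineages = lineages_all(),
                            stage_cell_cycle_hours = NULL) {
  program <- validate_program(program)
  founder_pool <- params$founder_pool
  neurogenic_days <- params$neurogenic_days
  cc <- if (is.null(stage_cell_cycle_hours)) {
    params$cell_cycle_hours
  } else {
    effective_cell_cycle(stage_cell_cycle_hours)
  }
  if (is.null(founder_pool) || is.na(founder_pool)) {
    stop("'params' must provide a founder_pool", call. = FALSE)
  }
  if (is.null(neurogenic_days) || is.null(cc) ||
      is.na(neurogenic_days) || is.na(cc)) {
    stop("'params' must provide neurogenic_days and cell_cycle_hours",
         call. = FALSE)
  }
  if (founder_pool == 0 || neurogenic_days == 0) return(0)
  k <- whole_cycles(neurogenic_days, cc)
  per_founder <- vapply(seq_along(lineages), function(i) {
    lineage_output(lineages[[i]], k)
  }, numeric(1))
  sum(founder_pool * unclass(program) * per_founder)
}

#' Forward-model predictions and deviations for a species table
#'
#' Runs [predict_neurons()] for every row of a species table under one
#' program (or each species' own built-in program) and reports percent
#' deviations from the apoptosis-adjusted observed counts.
#'
#' @param tab species `data.frame` (see [read_species_csv()]).
#' @param program a program understood by [neurogenic_program()], or
#'   `"own"` to use each species' built-in proportions.
#' @param adjust logical; compare against 1.5x-adjusted observed counts
#'   (default) or raw adult counts.
#' @return `tab` with columns `predicted`, `target` and `deviation_pct`
#'   appended.
#' @export
predict_table <- function(tab, program, adjust = TRUE) {
  own <- identical(program, "own")
  if (!own) program <- validate_program(program)
  predicted <- vapply(seq_len(nrow(tab)), function(i) {
    prog_i <- if (own) species_program(tab$species[i]) else program
    predict_neurons(tab[i, ], prog_i)
  }, numeric(1))
  target <- if (adjust) apoptosis_adjust(tab$observed_neurons) else
    tab$observed_neurons
  tab$predicted <- predicted
  tab$target <- target
  tab$deviation_pct <- deviation(predicted, target)
  tab
}
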