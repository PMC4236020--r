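#' Neurogenic period required to reach a target neuron count
#'
#' Inverts the forward model over the neurogenic period: the smallest
#' period (in days) at which the predicted end-of-neurogenesis count
#' reaches the target, holding the founder pool and program fixed. Because
#' lineage series are evaluated at whole cycles, the answer is resolved by
#' bisection to within half a cell cycle and then snapped to the smallest
#' whole-cycle boundary that attains the target.
#'
#' @param params single-row species `data.frame`.
#' @param program program coercible via [neurogenic_program()].
#' @param target_neurons target count at the termination of neurogenesis
#'   (apply [apoptosis_adjust()] beforehand when the goal is an adult
#'   count).
#' @param max_days search upper bound; an error is raised if the target is
#'   unreachable within it.
#' @return Required neurogenic period in days.
#' @examples
#' mouse <- species_table()[species_table()$species == "Mouse", ]
#' required_period(mouse, "human", apoptosis_adjust(1e9))
#' @export
required_period <- function(params, program, target_neurons,
                            max_days = 1e4) {
  if (!is.finite(target_neurons) || target_neurons <= 0) {
    stop("'target_neurons' must be positive", call. = FALSE)
  }
  program <- validate_program(program)
  pred_at <- function(days) {
    p <- params
    p$neurogenic_days <- days
    predict_neurons(p, program)
  }
  if (pred_at(max_days) < target_neurons) {
    stop("target unreachable within ", max_days, " days", call. = FALSE)
  }
  cc_days <- params$cell_cycle_hours / 24
  lo <- cc_days  # at least one cycle
  hi <- max_days
  if (pred_at(lo) >= target_neurons) {
    hi <- lo
  } else {
    while (hi - lo > cc_days / 2) {
      mid <- (lo + hi) / 2
      if (pred_at(mid) >= target_neurons) hi <- mid else lo <- mid
    }
  }
  # snap to the whole-cycle boundary (series change only at whole cycles)
  k <- whole_cycles(hi, params$cell_cycle_hours)
  while (k > 1 && pred_at((k - 1) * cc_days) >= target_neurons) k <- k - 1
  k * cc_days
}

#' Founder pool required to reach a target neuron count
#'
#' The forward model is linear in the founder pool, so the required pool is
#' the observed pool scaled by `target / prediction`.
#'
#' @inheritParams required_period
#' @return Required founder-cell count.
#' @export
required_founders <- function(params, program, target_neurons) {
  if (!is.finite(target_neurons) || target_neurons <= 0) {
    stop("'target_neurons' must be positive", call. = FALSE)
  }
  program <- validate_program(program)
  pred <- predict_neurons(params, program)
  if (pred <= 0) {
    stop("forward model predicts zero neurons; cannot scale founders",
         call. = FALSE)
  }
  params$founder_pool * target_neurons / pred
}

#' Relative cost of reaching a target under two neurogenic programs
#'
#' Fold difference in the neurogenic period (and founder pool) required to
#' reach a target count under program A versus program B. A period ratio
#' of 2 means program A needs twice the time program B does.
#'
#' @inheritParams required_period
#' @param program_a,program_b the two programs to compare.
#' @return A list with `period_ratio`, `founder_ratio` and the underlying
#'   per-program requirements.
#' @export
efficiency_ratio <- function(params, program_a, program_b, target_neurons,
                             max_days = 1e4) {
  pa <- required_period(params, program_a, target_neurons, max_days)
  pb <- required_period(params, program_b, target_neurons, max_days)
  fa <- required_founders(params, program_a, target_neurons)
  fb <- required_founders(params, program_b, target_neurons)
  list(period_ratio = pa / pb,
       founder_ratio = fa / fb,
       period = c(a = pa, b = pb),
       founders = c(a = fa, b = fb))
}
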