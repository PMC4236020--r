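#' Progenitor lineage definitions
#'
#' The forward model summarises cortical neurogenesis as seven progenitor
#' lineages, each a fixed division-rule tree seeded by one apical radial
#' glia (aRG) founder cell:
#'
#' * **Lineage 1** (direct neurogenesis): the aRG self-renews every cell
#'   cycle and produces one post-mitotic neuron per division.
#' * **Lineage 2** (indirect via neurogenic basal intermediate progenitors):
#'   the aRG produces one n-bIP per cycle; each n-bIP divides once, one
#'   cycle later, into two neurons.
#' * **Lineage 3** (basal radial glia): the aRG produces one bRG per cycle;
#'   each bRG thereafter self-renews asymmetrically, producing one neuron
#'   per cycle.
#' * **Lineages 4-7** (proliferative basal progenitors): the aRG produces
#'   one bRG per cycle; each bRG produces, per cycle, one proliferative
#'   basal progenitor (p-bIP) seed of amplification depth d = 1..4
#'   (lineage id minus 3). A depth-d seed undergoes d rounds of symmetric
#'   proliferative division and the resulting 2^d cells each divide
#'   terminally into two neurons, so one seed yields 2^(d+1) neurons after
#'   d+1 cycles. Lineage 5 carries the convergence constant c = 0.989
#'   multiplying its series.
#'
#' Closed forms per founder after `k` whole cycles (with `C(n,2) = n(n-1)/2`
#' and negative arguments truncated to zero):
#' \deqn{L_1(k) = k,\quad L_2(k) = 2(k-1),\quad L_3(k) = C(k,2),}
#' \deqn{L_{3+d}(k) = 2^{d+1} C(k-d-1,\,2),\ d = 1..4,}
#' lineage 5 additionally multiplied by c = 0.989.
#'
#' @param id integer lineage identifier in 1..7.
#' @return A list of class `"cortigen_lineage"` with elements `id`, `roles`
#'   (ordered progenitor stages), `depth` (number of symmetric proliferative
#'   rounds; 0 for lineages 1-3) and `convergence_constant` (0.989 for
#'   lineage 5, otherwise `NULL`).
#' @examples
#' lineage(3)
#' lineage_output(lineage(2), 10)  # 18 neurons per founder
#' @seealso [lineage_output()], [predict_neurons()]
#' @export
lineage <- function(id) {
  if (length(id) != 1L || !is.finite(id) || id != as.integer(id) ||
      id < 1L || id > 7L) {
    stop("'id' must be a single integer in 1..7", call. = FALSE)
  }
  id <- as.integer(id)
  roles <- switch(id,
    c("aRG", "neuron"),
    c("aRG", "n-bIP", "neuron"),
    c("aRG", "bRG", "neuron"),
    c("aRG", "bRG", "p-bIP", "n-bIP", "neuron"),
    c("aRG", "bRG", "p-bIP", "p-bIP", "n-bIP", "neuron"),
    c("aRG", "bRG", "p-bIP", "p-bIP", "p-bIP", "n-bIP", "neuron"),
    c("aRG", "bRG", "p-bIP", "p-bIP", "p-bIP", "p-bIP", "n-bIP", "neuron"))
  structure(
    list(id = id,
         roles = roles,
         depth = max(0L, id - 3L),
         convergence_constant = if (id == 5L) 0.989 else NULL),
    class = "cortigen_lineage")
}

#' @export
print.cortigen_lineage <- function(x, ...) {
  cat("<lineage ", x$id, "> ", paste(x$roles, collapse = " -> "), "\n",
      sep = "")
  if (!is.null(x$convergence_constant))
    cat("convergence constant c =", x$convergence_constant, "\n")
  invisible(x)
}

#' All seven progenitor lineages
#'
#' @return A list of the seven [lineage()] objects, in id order.
#' @export
lineages_all <- function() lapply(1:7, lineage)

# n(n-1)/2, truncated at zero for n < 2
choose2 <- function(n) ifelse(n >= 2, n * (n - 1) / 2, 0)

# whole cycles completed in a period; tiny epsilon guards float roundoff
# when the period is an exact multiple of the cell-cycle length
whole_cycles <- function(neurogenic_days, cell_cycle_hours) {
  floor(n_cycles(neurogenic_days, cell_cycle_hours) + 1e-9)
}

#' Cumulative neuron output of a lineage
#'
#' Evaluates the closed-form neuron series of a progenitor lineage: the
#' number of neurons produced per founder cell after `k` whole cell cycles.
#' The series are derived from the division rules documented in
#' [lineage()]; an exhaustive agent-level simulation of the same rules
#' yields identical counts.
#'
#' @param lin a [lineage()] object, or an integer id in 1..7.
#' @param k number of whole cell cycles (vectorised, `k >= 0`).
#' @return Numeric vector of cumulative neurons per founder.
#' @examples
#' lineage_output(1, 10)  # 10
#' lineage_output(2, 10)  # 18
#' lineage_output(3, 0:5) # 0 0 1 3 6 10
#' @export
lineage_output <- function(lin, k) {
  if (!inherits(lin, "cortigen_lineage")) lin <- lineage(lin)
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("'k' must be non-negative and finite", call. = FALSE)
  }
  out <- switch(lin$id,
    k,
    2 * pmax(k - 1, 0),
    choose2(k),
    4  * choose2(k - 2),
    8  * choose2(k - 3) * lin$convergence_constant,
    16 * choose2(k - 4),
    32 * choose2(k - 5))
  out
}

#' Number of cell cycles in a neurogenic period
#'
#' @param neurogenic_days length of the neurogenic period in days.
#' @param cell_cycle_hours average progenitor cell-cycle length in hours.
#' @return Real-valued cycle count `neurogenic_days * 24 / cell_cycle_hours`.
#'   Series evaluation uses `floor()` of this value (divisions are discrete
#'   events; the fractional remainder is ignored).
#' @examples
#' n_cycles(9, 18.5)   # mouse, ~11.68
#' n_cycles(112, 45)   # human, ~59.7
#' @export
n_cycles <- function(neurogenic_days, cell_cycle_hours) {
  if (any(!is.finite(neurogenic_days)) || any(neurogenic_days <= 0)) {
    stop("'neurogenic_days' must be positive", call. = FALSE)
  }
  if (any(!is.finite(cell_cycle_hours)) || any(cell_cycle_hours <= 0)) {
    stop("'cell_cycle_hours' must be positive", call. = FALSE)
  }
  neurogenic_days * 24 / cell_cycle_hours
}
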