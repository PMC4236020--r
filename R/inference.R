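#' Enumerate neurogenic programs on a proportion grid
#'
#' All vectors of lineage proportions over the seven lineages that sum to 1
#' on a fixed grid (stars-and-bars enumeration), optionally with some
#' lineages constrained to zero.
#'
#' @param step grid step; `1/step` must be (near-)integer. Best-fit tables
#'   use 0.05 by default, matching the granularity of published program
#'   estimates.
#' @param zero integer ids of lineages constrained to zero weight (e.g.
#'   `4:7` for mouse-type programs).
#' @return A matrix with one program per row (columns `lineage1`..`7`).
#' @examples
#' nrow(enumerate_programs(0.5))        # 28 = C(8, 6)
#' nrow(enumerate_programs(1))          # 7
#' nrow(enumerate_programs(0.1, zero = 4:7))  # 66 = C(12, 2)
#' @export
enumerate_programs <- function(step = 0.05, zero = integer(0)) {
  if (length(step) != 1L || !is.finite(step) || step <= 0 || step > 1) {
    stop("'step' must lie in (0, 1]", call. = FALSE)
  }
  m <- round(1 / step)
  if (abs(m - 1 / step) > 1e-8) {
    stop("'step' must divide 1 evenly", call. = FALSE)
  }
  free <- setdiff(1:7, zero)
  if (!length(free)) stop("all lineages constrained to zero", call. = FALSE)
  # compositions of m into length(free) non-negative parts
  comp <- compositions(m, length(free))
  out <- matrix(0, nrow = nrow(comp), ncol = 7,
                dimnames = list(NULL, paste0("lineage", 1:7)))
  out[, free] <- comp * step
  out
}

# all vectors of non-negative integers of length k summing to m
compositions <- function(m, k) {
  if (k == 1L) return(matrix(m, ncol = 1L))
  do.call(rbind, lapply(0:m, function(first) {
    rest <- compositions(m - first, k - 1L)
    cbind(first, rest, deparse.level = 0)
  }))
}

#' Best-fit neurogenic program for one species
#'
#' Exhaustive search over a proportion grid for the program minimising the
#' percent deviation between the forward-model prediction and the
#' apoptosis-adjusted observed neuron count. Ties are broken by preferring
#' the least total weight on the proliferative lineages 4-7, then by
#' lexicographic order (parsimony of proliferative potential, deterministic
#' output).
#'
#' @param params single-row species `data.frame`.
#' @param grid matrix of candidate programs (rows), e.g. from
#'   [enumerate_programs()].
#' @param target target neuron count; defaults to the 1.5x-adjusted
#'   observed count.
#' @return A list with `program` (a [neurogenic_program()]), `deviation`
#'   (percent) and `predicted`.
#' @export
best_fit_program <- function(params, grid = enumerate_programs(0.05),
                             target = NULL) {
  if (is.null(dim(grid)) || nrow(grid) == 0L) {
    stop("'grid' must be a non-empty matrix of programs", call. = FALSE)
  }
  if (is.null(target)) target <- apoptosis_adjust(params$observed_neurons)
  k <- whole_cycles(params$neurogenic_days, params$cell_cycle_hours)
  per_founder <- vapply(lineages_all(), lineage_output, numeric(1), k = k)
  predicted <- as.numeric(grid %*% per_founder) * params$founder_pool
  dev <- deviation(predicted, target)
  best <- which(dev == min(dev))
  if (length(best) > 1L) {
    prolif <- rowSums(grid[best, 4:7, drop = FALSE])
    best <- best[prolif == min(prolif)]
    if (length(best) > 1L) {
      # prefer weight on the lower-numbered (less proliferative) lineages
      ord <- do.call(order, c(as.data.frame(-grid[best, , drop = FALSE])))
      best <- best[ord[1L]]
    }
  }
  best <- best[1L]
  list(program = neurogenic_program(grid[best, ]),
       deviation = dev[best],
       predicted = predicted[best])
}

#' Deviation table across reference programs
#'
#' Applies several named programs (by default mouse, marmoset and human) to
#' every species in a table, reporting the raw percent deviation from the
#' apoptosis-adjusted observed count under each program together with the
#' deviations normalised to shares summing to 1 per species. Rows missing
#' required fields are skipped with a warning.
#'
#' @param tab species `data.frame`.
#' @param programs named list of programs (coercible via
#'   [neurogenic_program()]).
#' @param adjust compare against 1.5x-adjusted counts (default) or raw.
#' @return A `data.frame` with per-program deviation and share columns.
#' @export
cross_program_table <- function(tab,
                                programs = list(mouse = "mouse",
                                                marmoset = "marmoset",
                                                human = "human"),
                                adjust = TRUE) {
  programs <- lapply(programs, neurogenic_program)
  keep <- stats::complete.cases(
    tab[, c("species", "neurogenic_days", "observed_neurons",
            "founder_pool", "cell_cycle_hours")])
  if (any(!keep)) {
    warning("skipping ", sum(!keep), " row(s) with missing required fields: ",
            paste(tab$species[!keep], collapse = ", "), call. = FALSE)
    tab <- tab[keep, , drop = FALSE]
  }
  target <- if (adjust) apoptosis_adjust(tab$observed_neurons) else
    tab$observed_neurons
  devs <- sapply(programs, function(p) {
    vapply(seq_len(nrow(tab)), function(i) {
      deviation(predict_neurons(tab[i, ], p), target[i])
    }, numeric(1))
  })
  devs <- matrix(devs, nrow = nrow(tab),
                 dimnames = list(NULL, names(programs)))
  shares <- devs / rowSums(devs)
  out <- data.frame(species = tab$species, devs, check.names = FALSE)
  colnames(shares) <- paste0(names(programs), "_share")
  cbind(out, shares)
}
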