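#' Stage-structured (Lefkovitch) projection matrix for a neurogenic program
#'
#' Builds a stage-classified projection matrix over the lineages with
#' non-zero weight in a program. Per-cycle fecundity of lineage `j` is the
#' lineage series evaluated after `cycles` cycles divided by `cycles`
#' (average neuron output per founder per cycle); program weights act as
#' per-cycle survival (mortality complements), and newborn recruitment is
#' distributed across stages by the program weights:
#' `A[i, j] = p_i * f_j + (i == j) * p_j`.
#'
#' The dominant eigenpair of `A` gives the asymptotic growth rate, the
#' stable-stage distribution (right eigenvector normalised to sum 1) and
#' the reproductive values (left eigenvector, normalised against the
#' stable-stage distribution).
#'
#' @param program program coercible via [neurogenic_program()].
#' @param lineages list of [lineage()] objects.
#' @param cycles horizon over which the lineage series are summed
#'   (default 100).
#' @return An object of class `"stage_matrix"`: a list with the matrix
#'   `A`, `stages` (lineage ids), `growth_rate`, `stable_stage` and
#'   `reproductive_value`.
#' @export
build_stage_matrix <- function(program, lineages = lineages_all(),
                               cycles = 100) {
  program <- validate_program(program)
  active <- unname(which(unclass(program) > 0))
  if (!length(active)) stop("program has no active lineage", call. = FALSE)
  p <- unclass(program)[active]
  f <- vapply(lineages[active], lineage_output, numeric(1),
              k = cycles) / cycles
  if (all(f == 0) && all(p == 0)) stop("all-zero matrix", call. = FALSE)
  A <- outer(p, f) + diag(p, nrow = length(p))
  dimnames(A) <- list(paste0("lineage", active), paste0("lineage", active))
  eigenpair <- dominant_eigen(A)
  structure(
    list(A = A, stages = active,
         growth_rate = eigenpair$value,
         stable_stage = eigenpair$right,
         reproductive_value = eigenpair$left),
    class = "stage_matrix")
}

#' @export
print.stage_matrix <- function(x, ...) {
  cat("<stage matrix> lineages:", paste(x$stages, collapse = ", "), "\n")
  cat("dominant growth rate:", format(x$growth_rate), "\n")
  cat("stable-stage distribution:\n")
  print(round(x$stable_stage, 4))
  invisible(x)
}

# dominant eigenvalue with normalised right/left eigenvectors
dominant_eigen <- function(A) {
  er <- eigen(A)
  i <- which.max(Mod(er$values))
  lambda <- Re(er$values[i])
  v <- Re(er$vectors[, i])
  if (sum(v) < 0) v <- -v
  v <- v / sum(v)
  el <- eigen(t(A))
  j <- which.max(Mod(el$values))
  u <- Re(el$vectors[, j])
  if (sum(u) < 0) u <- -u
  u <- u / sum(u * v)
  list(value = lambda, right = v, left = u)
}

#' Growth-rate change from excluding lineages one at a time
#'
#' For each active lineage, rebuilds the stage matrix without it, assuming
#' 100% survival in the remaining lineages (recruitment weights
#' renormalised), and reports the dominant growth rate with and without the
#' exclusion. Removing a proliferative lineage (4-7) from a human-type
#' program depresses growth more than removing a lineage 1-3 of equal
#' weight.
#'
#' @inheritParams build_stage_matrix
#' @return A `data.frame` with columns `excluded`, `growth_rate` (of the
#'   reduced matrix) and `delta` (reduced minus full).
#' @export
lineage_exclusion <- function(program, lineages = lineages_all(),
                              cycles = 100) {
  program <- validate_program(program)
  active <- which(unclass(program) > 0)
  if (length(active) < 2L) {
    stop("need at least two active lineages to exclude one", call. = FALSE)
  }
  full <- build_stage_matrix(program, lineages, cycles)
  rows <- lapply(active, function(ex) {
    keep <- setdiff(active, ex)
    # 100% survival in the remaining lineages; recruitment spread equally
    p_surv <- rep(1, length(keep))
    w <- rep(1 / length(keep), length(keep))
    f <- vapply(lineages[keep], lineage_output, numeric(1),
                k = cycles) / cycles
    A <- outer(w, f) + diag(p_surv, nrow = length(keep))
    lam <- dominant_eigen(A)$value
    data.frame(excluded = ex, growth_rate = lam,
               delta = lam - full$growth_rate)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_growth_rate") <- full$growth_rate
  out
}

#' Closed-form dynamics of asymmetric versus proliferative progenitors
#'
#' Three coupled ODEs describe a constant pool of asymmetrically dividing
#' mother cells `a`, post-mitotic neurons `b` and proliferative daughters
#' `c`. At each division a mother produces a neuron with likelihood `r`
#' (direct neurogenesis) or a proliferative daughter with likelihood
#' `1 - r` (indirect); each proliferative daughter performs one round of
#' symmetric proliferation followed by a final self-consuming division,
#' yielding 4 neurons, at maturation rate `k_m`:
#' \deqn{a' = 0,\quad c' = (1-r)a - k_m c,\quad b' = r a + 4 k_m c.}
#'
#' The closed-form solution is
#' \deqn{c(t) = c_0 e^{-k_m t} + \frac{(1-r)a_0}{k_m}(1 - e^{-k_m t}),}
#' \deqn{b(t) = b_0 + r a_0 t + 4(1-r)a_0 t +
#'   4\left(c_0 - \frac{(1-r)a_0}{k_m}\right)(1 - e^{-k_m t}).}
#'
#' @param a0,b0,c0 initial numbers of mothers, neurons and proliferative
#'   daughters.
#' @param r likelihood in `[0, 1]` of direct (r = 1) versus indirect
#'   (r = 0) neurogenesis.
#' @param t_end end time in cell-cycle units (`> 0`).
#' @param k_m maturation rate of proliferative daughters (default 1 per
#'   cycle).
#' @param n_steps number of time points returned (including 0 and
#'   `t_end`).
#' @return A `data.frame` with columns `t`, `a`, `b`, `c`.
#' @examples
#' ode_solve(a0 = 100, b0 = 2, c0 = 2, r = 0.1, t_end = 10)
#' @export
ode_solve <- function(a0, b0 = 0, c0 = 0, r, t_end, k_m = 1,
                      n_steps = 101L) {
  if (!is.finite(r) || r < 0 || r > 1) {
    stop("'r' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(t_end) || t_end <= 0) {
    stop("'t_end' must be positive", call. = FALSE)
  }
  if (min(a0, b0, c0) < 0) stop("counts must be >= 0", call. = FALSE)
  t <- seq(0, t_end, length.out = n_steps)
  decay <- exp(-k_m * t)
  c_inf <- (1 - r) * a0 / k_m
  c_t <- c0 * decay + c_inf * (1 - decay)
  b_t <- b0 + r * a0 * t + 4 * (1 - r) * a0 * t +
    4 * (c0 - c_inf) * (1 - decay)
  data.frame(t = t, a = rep(a0, n_steps), b = b_t, c = c_t)
}

#' Neuron-output surface over initial pool size and division likelihood
#'
#' Evaluates `b(t)` at one fixed time on a grid of initial mother-pool
#' sizes `a0` and direct-division likelihoods `r`. Output increases
#' maximally when the initial pool grows and the likelihood of indirect
#' neurogenesis increases (`r` towards 0).
#'
#' @param a0_range numeric vector of initial pool sizes.
#' @param r_range numeric vector of `r` values in `[0, 1]`.
#' @param t evaluation time (default 10).
#' @param b0,c0 initial neuron and daughter counts (defaults 2 and 2).
#' @param k_m maturation rate.
#' @return Matrix of `b(t)` with rows indexed by `a0_range` and columns by
#'   `r_range`.
#' @export
ode_grid <- function(a0_range, r_range, t = 10, b0 = 2, c0 = 2, k_m = 1) {
  if (!length(a0_range) || !length(r_range)) {
    stop("ranges must be non-empty", call. = FALSE)
  }
  out <- outer(a0_range, r_range, function(a0, r) {
    c_inf <- (1 - r) * a0 / k_m
    decay <- exp(-k_m * t)
    b0 + r * a0 * t + 4 * (1 - r) * a0 * t +
      4 * (c0 - c_inf) * (1 - decay)
  })
  dimnames(out) <- list(a0 = format(a0_range), r = format(r_range))
  out
}
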