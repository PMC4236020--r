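#' Generate a synthetic species parameter table
#'
#' Builds a table shaped like the reference species parameters: neurogenic
#' and gestation periods, founder pools, cell-cycle lengths, and observed
#' neuron counts produced by running the forward model itself under a
#' known neurogenic program with multiplicative log-normal noise (counts
#' are positive and allometries ln-linear, so noise is applied on the log
#' scale). With `noise_sd = 0` the generated "observed" counts equal the
#' forward-model predictions exactly (divided by the apoptosis factor), so
#' program inference can be tested by recovery.
#'
#' @param n_species number of species (>= 1).
#' @param program generating program (coercible via
#'   [neurogenic_program()]).
#' @param noise_sd standard deviation of the ln-scale observation noise
#'   (>= 0).
#' @param seed integer seed; the same seed reproduces the table
#'   bit-for-bit.
#' @return A species `data.frame` compatible with [read_species_csv()]
#'   schemas, with an attribute `"program"` holding the generating
#'   program.
#' @examples
#' tab <- gen_species_table(17, seed = 1)
#' all(tab$founder_pool > 0)
#' @export
gen_species_table <- function(n_species, program = "mouse",
                              noise_sd = 0.05, seed = 1L) {
  if (length(n_species) != 1L || !is.finite(n_species) || n_species < 1) {
    stop("'n_species' must be >= 1", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be >= 0", call. = FALSE)
  }
  n_species <- as.integer(n_species)
  program <- neurogenic_program(program)
  set.seed(seed)
  neurogenic_days <- exp(stats::runif(n_species, log(9), log(115)))
  gestation_days <- neurogenic_days * stats::runif(n_species, 1.8, 2.6)
  cell_cycle_hours <- sample(c(18.5, 30, 45), n_species, replace = TRUE)
  founder_pool <- round(exp(stats::runif(n_species, log(2.5e4), log(3.2e7))))
  tab <- data.frame(
    species = sprintf("synth_%03d", seq_len(n_species)),
    gestation_days = gestation_days,
    neurogenic_days = neurogenic_days,
    observed_neurons = NA_real_,
    founder_pool = founder_pool,
    cell_cycle_hours = cell_cycle_hours)
  pred <- vapply(seq_len(n_species), function(i) {
    predict_neurons(tab[i, ], program)
  }, numeric(1))
  noise <- exp(stats::rnorm(n_species, 0, noise_sd))
  # store the adult-scale count: end-of-neurogenesis prediction divided by
  # the apoptosis adjustment
  tab$observed_neurons <- pred * noise / 1.5
  attr(tab, "program") <- program
  tab
}

#' Generate a bimodal gyrencephaly dataset
#'
#' Simulates a trait table with the structure of the comparative analyses:
#' a bimodal GI distribution with a gap at `gi_break`, ln-linear
#' GI-on-neuron-number allometries with group-specific slopes, brain
#' weights on a shared allometry, and gestation periods tuned so that
#' ln(brain weight per gestation day) has distinct group means.
#'
#' @param n_species total species count (split between groups by
#'   `prop_high`).
#' @param gi_break GI value separating the groups (default 1.5).
#' @param break_ln_neurons ln neuron number at the regime boundary
#'   (default `log(1e9)`).
#' @param slopes per-group slopes of ln GI on ln neurons
#'   (default `c(0.072, 0.140)`).
#' @param intercepts per-group intercepts (defaults chosen to meet at GI
#'   ~1.5 near the boundary: `c(-1.188, -2.370)`).
#' @param group_means,group_sds per-group mean and sd of ln neuron number.
#' @param bwgd_means per-group mean of ln(brain weight / gestation day)
#'   (default `c(-2.04, 0.583)`).
#' @param noise_sd sd of ln-scale noise on GI (and brain weight).
#' @param prop_high fraction of species in the high-GI group.
#' @param seed integer seed.
#' @return A `data.frame` with columns `species`, `gi`, `gi_group`,
#'   `neurons`, `brain_weight_g`, `gestation_days`.
#' @export
gen_bimodal_gi <- function(n_species = 100L, gi_break = 1.5,
                           break_ln_neurons = log(1e9),
                           slopes = c(0.072, 0.140),
                           intercepts = c(-1.188, -2.370),
                           group_means = c(log(2e8), log(6e9)),
                           group_sds = c(0.6, 0.7),
                           bwgd_means = c(-2.04, 0.583),
                           noise_sd = 0.02,
                           prop_high = 0.4, seed = 1L) {
  if (n_species < 1) stop("'n_species' must be >= 1", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("'noise_sd' must be >= 0", call. = FALSE)
  }
  if (group_means[1L] >= break_ln_neurons ||
      group_means[2L] <= break_ln_neurons) {
    warning("group means do not straddle the neuron-number boundary",
            call. = FALSE)
  }
  set.seed(seed)
  n_hi <- round(n_species * prop_high)
  n_lo <- n_species - n_hi
  # truncated normals keep each group on its own side of the boundary
  rtrunc <- function(n, mean, sd, lower, upper) {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(n, mean, sd)
      out <- c(out, draw[draw > lower & draw < upper])
    }
    out[seq_len(n)]
  }
  ln_lo <- rtrunc(n_lo, group_means[1L], group_sds[1L],
                  -Inf, break_ln_neurons - 0.05)
  ln_hi <- if (n_hi > 0) rtrunc(n_hi, group_means[2L], group_sds[2L],
                                break_ln_neurons + 0.05, Inf) else numeric(0)
  ln_n <- c(ln_lo, ln_hi)
  grp <- rep(c("low", "high"), c(n_lo, n_hi))
  slope <- ifelse(grp == "low", slopes[1L], slopes[2L])
  inter <- ifelse(grp == "low", intercepts[1L], intercepts[2L])
  ln_gi <- slope * ln_n + inter + stats::rnorm(n_species, 0, noise_sd)
  gi <- pmax(exp(ln_gi), 1.0)
  # brain weight: shared ln-linear allometry on neuron number
  ln_bw <- 1.05 * ln_n - 18.0 + stats::rnorm(n_species, 0, 0.1)
  bwgd <- ifelse(grp == "low", bwgd_means[1L], bwgd_means[2L]) +
    stats::rnorm(n_species, 0, 0.3)
  gestation <- exp(ln_bw - bwgd)
  data.frame(species = sprintf("synth_%03d", seq_len(n_species)),
             gi = gi, gi_group = grp,
             neurons = exp(ln_n),
             brain_weight_g = exp(ln_bw),
             gestation_days = gestation)
}

#' Simulate a tree with a continuous trait
#'
#' Simulates a pure-birth (Yule) ultrametric phylogeny and evolves a
#' continuous trait along it under Brownian motion, optionally on a
#' delta-transformed version of the tree (change concentrated late for
#' `delta > 1`). Tip values are simulated on the (transformed) tree by
#' drawing independent normal increments along each branch.
#'
#' @param n_tips number of tips (>= 2).
#' @param model `"brownian"` or `"delta"`.
#' @param sigma2 Brownian rate.
#' @param root_value trait value at the root.
#' @param delta depth exponent (used when `model = "delta"`; `delta = 1`
#'   reproduces Brownian exactly, same seed giving identical tip values).
#' @param birth speciation rate of the Yule tree.
#' @param seed integer seed.
#' @return A list of class `"trait_tree"`: `tree` (`phylo`; the original,
#'   untransformed time tree), `sim_tree` (the tree on which increments
#'   were drawn), `traits` (named tip values) and `root_value`.
#' @export
gen_tree_with_trait <- function(n_tips, model = c("brownian", "delta"),
                                sigma2 = 1, root_value = 0, delta = 1,
                                birth = 1, seed = 1L) {
  model <- match.arg(model)
  if (n_tips < 2L) stop("'n_tips' must be >= 2", call. = FALSE)
  if (model == "delta" && (!is.finite(delta) || delta <= 0)) {
    stop("'delta' must be > 0", call. = FALSE)
  }
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  sim_tree <- if (model == "delta") delta_transform(tree, delta) else tree
  # independent increments edge by edge, accumulated root-to-tip
  n <- length(tree$tip.label)
  vals <- rep(NA_real_, n + tree$Nnode)
  vals[n + 1L] <- root_value
  incr <- stats::rnorm(nrow(sim_tree$edge), 0,
                       sqrt(sigma2 * sim_tree$edge.length))
  for (e in seq_len(nrow(sim_tree$edge))) {
    # edges in phylo preorder: parents appear before children
    parent <- sim_tree$edge[e, 1L]
    child <- sim_tree$edge[e, 2L]
    vals[child] <- vals[parent] + incr[e]
  }
  traits <- vals[seq_len(n)]
  names(traits) <- tree$tip.label
  structure(list(tree = tree, sim_tree = sim_tree, traits = traits,
                 root_value = root_value, model = model, delta = delta,
                 sigma2 = sigma2),
            class = "trait_tree")
}

#' @export
print.trait_tree <- function(x, ...) {
  cat("<trait tree>", length(x$tree$tip.label), "tips,", x$model,
      "model\n")
  invisible(x)
}
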