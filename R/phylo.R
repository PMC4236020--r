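#' @importFrom ape read.tree write.tree
NULL

# validate a tree + trait pairing; returns trait vector ordered by tip label
check_traits <- function(tree, traits) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object",
                                     call. = FALSE)
  if (is.null(names(traits))) {
    if (length(traits) != length(tree$tip.label)) {
      stop("unnamed traits must match the number of tips", call. = FALSE)
    }
    names(traits) <- tree$tip.label
  }
  missing <- setdiff(tree$tip.label, names(traits))
  if (length(missing)) {
    stop("tips missing trait values: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  traits[tree$tip.label]
}

# Felsenstein pruning pass: profile-ML quantities for x ~ N(mu 1, sigma2 C)
# returns root estimate (= GLS mean), accumulated contrast quadratic form,
# log|C0| and the root variance multiplier
bm_prune <- function(tree, x) {
  n <- length(tree$tip.label)
  n_node <- tree$Nnode
  val <- c(as.numeric(x), rep(NA_real_, n_node))
  var <- c(rep(0, n), rep(NA_real_, n_node))
  logdet <- 0
  quad <- 0
  edge <- tree$edge
  elen <- tree$edge.length
  children <- split(seq_len(nrow(edge)), edge[, 1L])
  # process internal nodes once all their children are resolved
  repeat {
    done <- TRUE
    for (nd in as.integer(names(children))) {
      if (!is.na(val[nd])) next
      kid_edges <- children[[as.character(nd)]]
      kids <- edge[kid_edges, 2L]
      if (any(is.na(val[kids]))) { done <- FALSE; next }
      v <- var[kids] + elen[kid_edges]
      xv <- val[kids]
      # fold children pairwise
      cur_x <- xv[1L]; cur_v <- v[1L]
      for (j in seq_along(kids)[-1L]) {
        V <- cur_v + v[j]
        logdet <- logdet + log(V)
        quad <- quad + (cur_x - xv[j])^2 / V
        cur_x <- (cur_x * v[j] + xv[j] * cur_v) / V
        cur_v <- cur_v * v[j] / V
      }
      val[nd] <- cur_x
      var[nd] <- cur_v
    }
    if (done) break
  }
  root <- n + 1L
  list(root_value = val[root], root_var = var[root],
       logdet = logdet + log(ifelse(var[root] > 0, var[root], 1)),
       root_var_term = var[root], quad = quad)
}

# ML log-likelihood of Brownian motion on a tree (profile over mu, sigma2)
bm_ml <- function(tree, x) {
  if (any(tree$edge.length <= 0)) {
    stop("non-positive branch lengths", call. = FALSE)
  }
  n <- length(x)
  pr <- bm_prune(tree, x)
  sigma2 <- pr$quad / n
  # log|C0| counts the root variance only when the root estimate has one
  logdet_c0 <- pr$logdet
  log_lik <- -0.5 * (n * log(2 * pi * sigma2) + logdet_c0 + n)
  list(sigma2 = sigma2, root = pr$root_value,
       root_var_mult = pr$root_var_term, log_lik = log_lik)
}

#' Delta transform of node depths
#'
#' Pagel's delta: node depths (root-to-node distances), normalised by the
#' maximum depth, are raised to the power `delta` and rescaled to the
#' original total depth; branch lengths are recomputed as differences of
#' transformed depths. `delta > 1` concentrates evolutionary change late
#' (towards the tips), `delta < 1` early; `delta = 1` is the identity.
#'
#' @param tree a `phylo` object.
#' @param delta positive exponent.
#' @return The transformed `phylo` object (topology and tip set
#'   unchanged; total depth preserved).
#' @examples
#' tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
#' delta_transform(tr, 2)  # internal node depth 0.5 -> 0.25
#' @export
delta_transform <- function(tree, delta) {
  if (!is.finite(delta) || delta <= 0) {
    stop("'delta' must be > 0", call. = FALSE)
  }
  if (delta == 1) return(tree)
  depth <- ape::node.depth.edgelength(tree)
  total <- max(depth)
  new_depth <- total * (depth / total)^delta
  tree$edge.length <- new_depth[tree$edge[, 2L]] -
    new_depth[tree$edge[, 1L]]
  tree
}

#' Fit a Brownian or delta model of continuous trait evolution
#'
#' Maximum-likelihood fit of a Brownian-motion model (rate `sigma2`,
#' ancestral root state) or a delta-transformed Brownian model (additional
#' depth exponent `delta`, optimised by bounded search) to tip traits on a
#' phylogeny, using the pruning algorithm for the phylogenetic
#' multivariate-normal likelihood. The delta fit is compared with the
#' Brownian fit by a likelihood-ratio test against the chi-squared
#' distribution with 1 degree of freedom.
#'
#' @param tree a `phylo` object with positive branch lengths.
#' @param traits named numeric vector of tip trait values.
#' @param model `"brownian"` or `"delta"`.
#' @param delta_range search interval for the delta exponent.
#' @return A list with `model`, `sigma2`, `root`, `delta` (1 for
#'   brownian), `log_lik`, `aic`, and for the delta model `lrt`
#'   (`statistic`, `p`) against the Brownian fit.
#' @export
fit_trait_model <- function(tree, traits, model = c("brownian", "delta"),
                            delta_range = c(0.05, 10)) {
  model <- match.arg(model)
  x <- check_traits(tree, traits)
  if (length(x) < 4L) stop("need >= 4 tips", call. = FALSE)
  bm <- bm_ml(tree, x)
  k_bm <- 2
  if (model == "brownian") {
    return(list(model = "brownian", sigma2 = bm$sigma2, root = bm$root,
                delta = 1, log_lik = bm$log_lik,
                aic = 2 * k_bm - 2 * bm$log_lik))
  }
  nll <- function(d) -bm_ml(delta_transform(tree, d), x)$log_lik
  opt <- stats::optimize(nll, interval = delta_range)
  # the identity delta = 1 is always admissible; keep it if the numeric
  # optimum is not better
  if (-opt$objective < bm$log_lik) {
    opt <- list(minimum = 1, objective = -bm$log_lik)
  }
  fit <- bm_ml(delta_transform(tree, opt$minimum), x)
  k_delta <- 3
  lrt_stat <- max(0, 2 * (fit$log_lik - bm$log_lik))
  list(model = "delta", sigma2 = fit$sigma2, root = fit$root,
       delta = opt$minimum, log_lik = fit$log_lik,
       aic = 2 * k_delta - 2 * fit$log_lik,
       lrt = list(statistic = lrt_stat,
                  p = stats::pchisq(lrt_stat, df = 1, lower.tail = FALSE)))
}

#' Ancestral state reconstruction by generalised least squares
#'
#' Reconstructs continuous ancestral states at every internal node under
#' Brownian motion (optionally on a delta-transformed tree), by GLS
#' prediction: the estimate at a node is the GLS root mean plus the
#' covariance-weighted deviation of the tips, and its standard error
#' includes the uncertainty of the root mean. The root row's standard
#' error is the classical root SEM.
#'
#' @param tree a `phylo` object.
#' @param traits named numeric vector of tip values.
#' @param sigma2,delta model parameters, e.g. from [fit_trait_model()]
#'   (defaults: ML `sigma2` on the given tree, `delta = 1`).
#' @return A `data.frame` with one row per internal node (node ids as in
#'   `tree$edge`): `node`, `state`, `se`. The first row is the root.
#' @export
ancestral_states <- function(tree, traits, sigma2 = NULL, delta = 1) {
  x <- check_traits(tree, traits)
  if (delta != 1) tree <- delta_transform(tree, delta)
  n <- length(tree$tip.label)
  if (is.null(sigma2)) sigma2 <- bm_ml(tree, x)$sigma2
  depth <- ape::node.depth.edgelength(tree)
  all_ids <- seq_len(n + tree$Nnode)
  mrca_all <- ape::mrca(tree, full = TRUE)
  covm <- matrix(depth[mrca_all], nrow = length(all_ids))
  C <- covm[seq_len(n), seq_len(n), drop = FALSE]
  Ci <- solve(C)
  one <- rep(1, n)
  denom <- as.numeric(t(one) %*% Ci %*% one)
  mu <- as.numeric(t(one) %*% Ci %*% x) / denom
  resid <- x - mu
  nodes <- (n + 1L):(n + tree$Nnode)
  states <- numeric(length(nodes))
  ses <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    cvec <- covm[nd, seq_len(n)]
    w <- Ci %*% cvec
    states[i] <- mu + sum(w * resid)
    base_var <- depth[nd] - as.numeric(t(cvec) %*% w)
    mu_var <- (1 - sum(w))^2 / denom
    ses[i] <- sqrt(pmax(sigma2 * (base_var + mu_var), 0))
  }
  data.frame(node = nodes, state = states, se = ses)
}

#' Directional counts of trait-bin transitions on a phylogeny
#'
#' Discretises a continuous trait into bins (e.g. from [jenks_breaks()]),
#' reconstructs ancestral states, and counts, along every branch, whether
#' the bin decreases (high-to-low) or increases (low-to-high). Uncertainty
#' is propagated by sampling each internal node's state from its GLS
#' reconstruction distribution `n_sim` times (adjacent-bin moves dominate
#' because node states vary smoothly along branches).
#'
#' @param tree a `phylo` object.
#' @param traits named numeric tip values.
#' @param bin_edges increasing vector of internal bin boundaries.
#' @param n_sim number of posterior draws (>= 1).
#' @param seed optional integer seed.
#' @param sample_se logical; `FALSE` uses the point reconstruction in
#'   every draw.
#' @return A list with `high_to_low`, `low_to_high` (means over draws),
#'   `sem` (standard errors of those means) and `n_sim`.
#' @export
transition_directions <- function(tree, traits, bin_edges, n_sim = 1000L,
                                  seed = NULL, sample_se = TRUE) {
  if (n_sim < 1L) stop("'n_sim' must be >= 1", call. = FALSE)
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("'bin_edges' must be strictly increasing", call. = FALSE)
  }
  x <- check_traits(tree, traits)
  if (!is.null(seed)) set.seed(seed)
  anc <- ancestral_states(tree, x)
  n <- length(tree$tip.label)
  bin_of <- function(v) findInterval(v, c(-Inf, bin_edges, Inf))
  tip_bins <- bin_of(x)
  n_bins <- length(bin_edges) + 1L
  if (!all(seq_len(n_bins) %in% tip_bins)) {
    stop("empty bin: every bin must contain at least one tip",
         call. = FALSE)
  }
  edge <- tree$edge
  counts <- matrix(0, n_sim, 2L,
                   dimnames = list(NULL, c("high_to_low", "low_to_high")))
  for (s in seq_len(n_sim)) {
    node_states <- if (sample_se) {
      stats::rnorm(nrow(anc), anc$state, anc$se)
    } else anc$state
    bins <- c(tip_bins, bin_of(node_states))
    d <- bins[edge[, 2L]] - bins[edge[, 1L]]
    counts[s, 1L] <- sum(pmax(-d, 0))
    counts[s, 2L] <- sum(pmax(d, 0))
  }
  list(high_to_low = mean(counts[, 1L]),
       low_to_high = mean(counts[, 2L]),
       sem = c(high_to_low = stats::sd(counts[, 1L]) / sqrt(n_sim),
               low_to_high = stats::sd(counts[, 2L]) / sqrt(n_sim)),
       n_sim = n_sim)
}
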