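# Independent oracles used across the test suite.

# Exhaustive agent-level simulation of the lineage division rules.
# Synchronous bookkeeping of cell counts per progenitor type; one founder
# aRG; returns cumulative neurons after k whole cycles. Division rules:
#   aRG: self-renews every cycle; daughter is a neuron (lineage 1), an
#        n-bIP (lineage 2) or a bRG (lineages 3-7)
#   bRG: self-renews; produces one neuron per cycle (lineage 3) or one
#        p-bIP seed of depth id-3 per cycle (lineages 4-7)
#   n-bIP: one terminal division into 2 neurons, one cycle after birth
#   p-bIP depth d>0: one symmetric proliferative division into 2 cells of
#        depth d-1; depth 0 behaves as an n-bIP
# Lineage 5's convergence constant multiplies the final count.
simulate_lineage_agents <- function(id, k) {
  depth_max <- max(0L, id - 3L)
  arg <- 1
  brg <- 0
  nbip <- 0
  pbip <- rep(0, depth_max + 1L)  # index d+1 holds depth-d count
  neurons <- 0
  for (t in seq_len(k)) {
    brg_new <- 0; nbip_new <- 0
    pbip_new <- rep(0, depth_max + 1L)
    # aRG divisions
    if (id == 1L) neurons <- neurons + arg
    if (id == 2L) nbip_new <- nbip_new + arg
    if (id >= 3L) brg_new <- brg_new + arg
    # bRG divisions
    if (id == 3L) neurons <- neurons + brg
    if (id >= 4L) pbip_new[depth_max + 1L] <- pbip_new[depth_max + 1L] + brg
    # n-bIP terminal divisions
    neurons <- neurons + 2 * nbip
    # p-bIP proliferative cascade
    if (depth_max > 0L) {
      for (d in seq_len(depth_max)) {
        pbip_new[d] <- pbip_new[d] + 2 * pbip[d + 1L]
      }
    }
    neurons <- neurons + 2 * pbip[1L]  # depth-0 act as n-bIPs
    pbip <- pbip_new
    nbip <- nbip_new
    brg <- brg + brg_new
  }
  if (id == 5L) neurons <- neurons * 0.989
  neurons
}

# Power iteration for the dominant eigenpair of a non-negative matrix
power_iteration <- function(A, tol = 1e-12, max_iter = 100000L) {
  v <- rep(1, nrow(A))
  lambda <- 0
  for (i in seq_len(max_iter)) {
    w <- A %*% v
    lambda_new <- sqrt(sum(w^2))
    w <- as.numeric(w) / lambda_new
    if (max(abs(w - v)) < tol) { v <- w; lambda <- lambda_new; break }
    v <- w
    lambda <- lambda_new
  }
  v <- v / sum(v)
  list(value = as.numeric((t(v) %*% A %*% v) / sum(v^2)), vector = v)
}

# Dense multivariate-normal log-likelihood of Brownian motion on a tree
# (profile ML over the root mean and rate), O(n^3) route
dense_bm_ml <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric(t(one) %*% Ci %*% x) / as.numeric(t(one) %*% Ci %*% one)
  quad <- as.numeric(t(x - mu) %*% Ci %*% (x - mu))
  sigma2 <- quad / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) +
                  as.numeric(determinant(C)$modulus) + n)
  list(sigma2 = sigma2, root = mu, log_lik = ll)
}

# Shoelace polygon area for the trapezoid-strip surface reconstruction:
# contour lengths laid out as widths centred on the axis
shoelace_surface <- function(contours, horizontal_length) {
  nx <- length(contours)
  xs <- seq(0, horizontal_length, length.out = nx)
  px <- c(xs, rev(xs))
  py <- c(contours / 2, rev(-contours / 2))
  m <- length(px)
  j <- c(m, seq_len(m - 1L))
  abs(sum(px[j] * py - px * py[j])) / 2
}

# Direct double-sum energy distance between two samples
double_sum_energy <- function(a, b) {
  n <- length(a); m <- length(b)
  cross <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    cross <- cross + abs(a[i] - b[j])
  }
  wa <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) wa <- wa + abs(a[i] - a[j])
  wb <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) wb <- wb + abs(b[i] - b[j])
  n * m / (n + m) * (2 * cross / (n * m) - wa / n^2 - wb / m^2)
}

# Exhaustive best contiguous partition into s segments (per-segment OLS)
exhaustive_segmented_rss <- function(x, y, s, min_size = 3L) {
  n <- length(x)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  seg_rss <- function(i, j) {
    xx <- x[i:j]; yy <- y[i:j]
    if (length(unique(xx)) < 2L) return(sum((yy - mean(yy))^2))
    sum(stats::resid(stats::lm(yy ~ xx))^2)
  }
  best <- Inf
  cut_sets <- utils::combn(seq_len(n - 1L), s - 1L)
  for (c_i in seq_len(ncol(cut_sets))) {
    cuts <- cut_sets[, c_i]
    bounds <- c(0L, cuts, n)
    sizes <- diff(bounds)
    if (any(sizes < min_size)) next
    tot <- 0
    for (seg in seq_len(s)) {
      tot <- tot + seg_rss(bounds[seg] + 1L, bounds[seg + 1L])
    }
    if (tot < best) best <- tot
  }
  best
}

# Exhaustive optimal partition for Jenks natural breaks
exhaustive_jenks_wss <- function(values, n_classes) {
  v <- sort(values)
  n <- length(v)
  wss_of <- function(i, j) sum((v[i:j] - mean(v[i:j]))^2)
  best <- Inf
  cut_sets <- utils::combn(seq_len(n - 1L), n_classes - 1L)
  for (c_i in seq_len(ncol(cut_sets))) {
    bounds <- c(0L, cut_sets[, c_i], n)
    tot <- 0
    for (cl in seq_len(n_classes)) {
      tot <- tot + wss_of(bounds[cl] + 1L, bounds[cl + 1L])
    }
    if (tot < best) best <- tot
  }
  best
}
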