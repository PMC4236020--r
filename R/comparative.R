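#' Segmented linear regression with AIC model selection
#'
#' Fits piecewise ordinary least-squares models with 1 to `max_segments`
#' segments and selects the segment count by AIC, with parameter count
#' `k = 3 * segments` (a slope and intercept per segment, `segments - 1`
#' breakpoints, one residual variance).
#'
#' Two breakpoint policies are available. The default, `breaks = "jenks"`,
#' places the candidate boundaries at the Jenks natural breaks of the `x`
#' values ([jenks_breaks()]); breakpoints then reflect the structure of
#' the predictor distribution (grade-shifted allometries have clustered
#' x) and the AIC comparison across segment counts is a fair nested-model
#' comparison. `breaks = "optimal"` instead finds the contiguous
#' partition minimising total residual sum of squares by exact dynamic
#' programming over the observed x-order; it yields the tightest fit for
#' a given segment count, but because the breakpoints are optimised
#' against the residuals it biases AIC towards extra segments and is
#' intended for fixed-`max_segments` fitting rather than segment-count
#' selection.
#'
#' Segment counts whose minimum-size constraint cannot be met are skipped
#' with a warning.
#'
#' @param x,y numeric vectors; `x` need not be pre-sorted.
#' @param max_segments maximum number of segments to consider (1-5).
#' @param min_size minimum points per segment (default 3).
#' @param breaks `"jenks"` or `"optimal"` (see above).
#' @return An object of class `"segmented_fit"`: a list with `n_segments`,
#'   `breakpoints`, `segments` (a `data.frame` of per-segment slope,
#'   intercept, range and n), `rss`, `log_lik`, `aic`, and `aic_table`
#'   (AIC per candidate segment count).
#' @examples
#' x <- c(runif(30, 15, 20), runif(30, 21, 25))
#' y <- ifelse(x < 20.5, 0.072 * x - 1.188, 0.140 * x - 2.370)
#' segmented_regression(x, y)$n_segments  # 2
#' @export
segmented_regression <- function(x, y, max_segments = 5L, min_size = 3L,
                                 breaks = c("jenks", "optimal")) {
  break_mode <- match.arg(breaks)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_size) stop("too few points", call. = FALSE)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]

  rss_seg <- segment_rss_matrix(x, y)
  fits <- list()
  aic_table <- data.frame(n_segments = integer(0), aic = numeric(0))
  for (s in seq_len(max_segments)) {
    if (n < s * min_size) {
      warning("skipping ", s, "-segment model: needs >= ", s * min_size,
              " points", call. = FALSE)
      next
    }
    part <- if (break_mode == "optimal" || s == 1L) {
      best_partition(rss_seg, s, min_size)
    } else {
      jenks_partition(x, s, rss_seg)
    }
    if (is.null(part) || any(part$ends - part$starts + 1L < min_size)) {
      warning("skipping ", s, "-segment model: a class has fewer than ",
              min_size, " points", call. = FALSE)
      next
    }
    rss <- max(part$rss, 0)
    # floor the variance at numerical-noise scale so exact fits do not
    # hand arbitrarily large likelihood gains to extra segments
    noise_floor <- 1e-9 * max(stats::var(y), .Machine$double.eps)
    sigma2 <- max(rss / n, noise_floor)
    log_lik <- -n / 2 * (log(2 * pi * sigma2) + 1)
    k_par <- 3 * s
    aic <- 2 * k_par - 2 * log_lik
    seg_tab <- do.call(rbind, lapply(seq_len(s), function(j) {
      i0 <- part$starts[j]; i1 <- part$ends[j]
      cf <- ols_coef(x[i0:i1], y[i0:i1])
      data.frame(segment = j, slope = cf[2L], intercept = cf[1L],
                 x_min = x[i0], x_max = x[i1], n = i1 - i0 + 1L)
    }))
    breaks <- if (s > 1L) {
      vapply(seq_len(s - 1L), function(j) {
        (x[part$ends[j]] + x[part$starts[j + 1L]]) / 2
      }, numeric(1))
    } else numeric(0)
    fits[[length(fits) + 1L]] <- list(
      n_segments = s, breakpoints = breaks, segments = seg_tab,
      rss = rss, log_lik = log_lik, aic = aic)
    aic_table <- rbind(aic_table,
                       data.frame(n_segments = s, aic = aic))
  }
  if (!length(fits)) stop("no segment count feasible", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  best$aic_table <- aic_table
  class(best) <- "segmented_fit"
  best
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("<segmented fit>", x$n_segments, "segment(s), AIC",
      format(x$aic), "\n")
  if (length(x$breakpoints))
    cat("breakpoints:", paste(format(x$breakpoints), collapse = ", "), "\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}

# intercept/slope of a least-squares line (n >= 2; vertical-tie safe)
ols_coef <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(c(mean(y), 0))
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(mean(y) - b * mean(x), b)
}

# rss_seg[i, j]: residual sum of squares of the OLS line over points i..j
segment_rss_matrix <- function(x, y) {
  n <- length(x)
  out <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    sx <- 0; sy <- 0; sxx <- 0; sxy <- 0; syy <- 0
    for (j in i:n) {
      sx <- sx + x[j]; sy <- sy + y[j]
      sxx <- sxx + x[j]^2; sxy <- sxy + x[j] * y[j]; syy <- syy + y[j]^2
      m <- j - i + 1
      vx <- sxx - sx^2 / m
      cxy <- sxy - sx * sy / m
      vy <- syy - sy^2 / m
      out[i, j] <- if (vx <= 1e-12) vy else vy - cxy^2 / vx
    }
  }
  out
}

# contiguous partition of sorted x into s classes at Jenks natural breaks
jenks_partition <- function(x, s, rss_seg) {
  cl <- jenks_breaks(x, s)$classes  # x sorted, classes non-decreasing
  starts <- match(seq_len(s), cl)
  if (any(is.na(starts))) return(NULL)
  ends <- c(starts[-1L] - 1L, length(x))
  rss <- sum(vapply(seq_len(s), function(j) {
    rss_seg[starts[j], ends[j]]
  }, numeric(1)))
  list(starts = starts, ends = ends, rss = rss)
}

# optimal partition of 1..n into s contiguous segments of >= min_size
best_partition <- function(rss_seg, s, min_size) {
  n <- nrow(rss_seg)
  # dp[seg, j]: min rss of first j points in 'seg' segments
  dp <- matrix(Inf, s, n)
  back <- matrix(NA_integer_, s, n)
  for (j in min_size:n) dp[1L, j] <- rss_seg[1L, j]
  if (s > 1L) {
    for (seg in 2:s) {
      for (j in (seg * min_size):n) {
        cuts <- ((seg - 1L) * min_size):(j - min_size)
        vals <- dp[seg - 1L, cuts] + rss_seg[cuts + 1L, j]
        b <- which.min(vals)
        dp[seg, j] <- vals[b]
        back[seg, j] <- cuts[b]
      }
    }
  }
  ends <- integer(s); starts <- integer(s)
  j <- n
  for (seg in s:1) {
    ends[seg] <- j
    starts[seg] <- if (seg == 1L) 1L else back[seg, j] + 1L
    j <- starts[seg] - 1L
  }
  list(starts = starts, ends = ends, rss = dp[s, n])
}

#' Two-sample comparison of regression slopes
#'
#' Tests whether two independently fitted OLS slopes differ, using pooled
#' residual variance: `t = (b1 - b2) / se`, with
#' `df = n1 + n2 - 4`.
#'
#' @param x1,y1,x2,y2 the two groups' data (>= 3 points each).
#' @return A list with `t`, `df`, `p`, and the two `slopes` with standard
#'   errors.
#' @export
slope_contrast <- function(x1, y1, x2, y2) {
  if (length(x1) < 3L || length(x2) < 3L) {
    stop("need >= 3 points per group", call. = FALSE)
  }
  f1 <- stats::lm(y1 ~ x1)
  f2 <- stats::lm(y2 ~ x2)
  b1 <- stats::coef(f1)[2L]; b2 <- stats::coef(f2)[2L]
  n1 <- length(x1); n2 <- length(x2)
  df <- n1 + n2 - 4L
  s2 <- (sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)) / df
  se <- sqrt(s2 * (1 / sum((x1 - mean(x1))^2) +
                   1 / sum((x2 - mean(x2))^2)))
  tval <- unname((b1 - b2) / se)
  p <- 2 * stats::pt(-abs(tval), df)
  list(t = tval, df = df, p = p,
       slopes = c(unname(b1), unname(b2)), se = se)
}

#' Boundary estimate between two scaling regimes
#'
#' Locates the boundary between a low and a high group as the midpoint
#' between the largest low-group x and the smallest high-group x (and
#' likewise on the y axis), with uncertainty by bootstrap resampling of
#' species within groups.
#'
#' @param x,y trait coordinates (e.g. ln neuron number and GI).
#' @param group logical or factor with two levels; `TRUE`/second level =
#'   high group.
#' @param n_boot bootstrap resamples (0 = point estimate only).
#' @param seed optional integer seed for the bootstrap.
#' @return A list with `x_star`, `y_star`, and bootstrap standard errors
#'   `x_se`, `y_se` (`NA` when `n_boot = 0`).
#' @export
threshold_estimate <- function(x, y, group, n_boot = 1000L, seed = NULL) {
  g <- as.logical(if (is.factor(group)) group == levels(group)[2L] else group)
  lo <- which(!g); hi <- which(g)
  if (!length(lo) || !length(hi)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (max(x[lo]) >= min(x[hi])) {
    stop("groups overlap on x (max low = ", format(max(x[lo])),
         ", min high = ", format(min(x[hi])), ")", call. = FALSE)
  }
  point <- function(ilo, ihi) {
    c(x = (max(x[ilo]) + min(x[ihi])) / 2,
      y = (max(y[ilo]) + min(y[ihi])) / 2)
  }
  est <- point(lo, hi)
  x_se <- y_se <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- replicate(n_boot, {
      point(sample(lo, length(lo), replace = TRUE),
            sample(hi, length(hi), replace = TRUE))
    })
    x_se <- stats::sd(boots[1L, ])
    y_se <- stats::sd(boots[2L, ])
  }
  list(x_star = unname(est["x"]), y_star = unname(est["y"]),
       x_se = x_se, y_se = y_se)
}

#' Energy distance between two samples
#'
#' The e-distance of two clusters A and B:
#' `(n m / (n + m)) * (2 E|a - b| - E|a - a'| - E|b - b'|)`,
#' with expectations over all pairs (including self-pairs in the within
#' terms' denominator `n^2`).
#'
#' @param a,b numeric vectors.
#' @return Non-negative scalar; 0 for identical singletons.
#' @export
energy_distance <- function(a, b) {
  n <- length(a); m <- length(b)
  if (!n || !m) stop("empty cluster", call. = FALSE)
  cross <- mean(abs(outer(a, b, "-")))
  within_a <- mean(abs(outer(a, a, "-")))
  within_b <- mean(abs(outer(b, b, "-")))
  n * m / (n + m) * (2 * cross - within_a - within_b)
}

#' Hierarchical clustering by minimum energy distance
#'
#' Agglomerative clustering of scalar values: at each step the two
#' clusters with the smallest e-distance ([energy_distance()]) are merged,
#' and the merge height is that e-distance. The top split is the pair of
#' clusters joined by the final (greatest-height) merge; on a bimodal
#' trait such as the gyrencephaly index it separates the two modes.
#'
#' @param values named or unnamed numeric vector (n >= 2).
#' @return A list with `merge_heights` (in merge order), `top_split`
#'   (integer vector of 1/2 cluster labels per input value) and `order`
#'   (merge history as a list of index vectors).
#' @export
energy_dendrogram <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to cluster", call. = FALSE)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 2L) {
    nc <- length(clusters)
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        d <- energy_distance(values[clusters[[i]]], values[clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  final_d <- energy_distance(values[clusters[[1L]]], values[clusters[[2L]]])
  heights <- c(heights, final_d)
  labels <- integer(n)
  labels[clusters[[1L]]] <- 1L
  labels[clusters[[2L]]] <- 2L
  # report cluster 1 = lower-mean cluster for stable orientation
  if (mean(values[labels == 1L]) > mean(values[labels == 2L])) {
    labels <- 3L - labels
  }
  list(merge_heights = heights, top_split = labels,
       order = clusters)
}

#' Jenks natural breaks (exact dynamic programming)
#'
#' Partitions sorted values into `n_classes` contiguous classes minimising
#' the within-class sum of squared deviations (the Jenks-Caspall / Fisher
#' optimal-partition criterion), solved exactly by dynamic programming.
#'
#' @param values numeric vector.
#' @param n_classes number of classes (2 <= n_classes <= length(values)).
#' @return A list with `breaks` (boundaries at midpoints between adjacent
#'   class-edge values, length `n_classes - 1`), `classes` (class index
#'   per input value) and `wss` (total within-class sum of squares).
#' @examples
#' jenks_breaks(c(1, 1, 1, 9, 9, 9), 2)$breaks  # 5
#' @export
jenks_breaks <- function(values, n_classes) {
  n <- length(values)
  if (n_classes < 2L) stop("'n_classes' must be >= 2", call. = FALSE)
  if (n_classes > n) stop("'n_classes' exceeds number of values",
                          call. = FALSE)
  ord <- order(values)
  v <- values[ord]
  # within-class ss for v[i..j]
  css <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- 0; ss <- 0
    for (j in i:n) {
      s <- s + v[j]; ss <- ss + v[j]^2
      css[i, j] <- ss - s^2 / (j - i + 1)
    }
  }
  dp <- matrix(Inf, n_classes, n)
  back <- matrix(NA_integer_, n_classes, n)
  dp[1L, ] <- css[1L, ]
  if (n_classes > 1L) {
    for (k in 2:n_classes) {
      for (j in k:n) {
        cuts <- (k - 1L):(j - 1L)
        vals <- dp[k - 1L, cuts] + css[cuts + 1L, j]
        b <- which.min(vals)
        dp[k, j] <- vals[b]
        back[k, j] <- cuts[b]
      }
    }
  }
  edges <- integer(n_classes - 1L)
  j <- n
  if (n_classes > 1L) {
    for (k in n_classes:2) {
      edges[k - 1L] <- back[k, j]
      j <- back[k, j]
    }
  }
  breaks <- vapply(edges, function(e) (v[e] + v[e + 1L]) / 2, numeric(1))
  classes_sorted <- findInterval(v, vec = c(-Inf, breaks, Inf),
                                 left.open = FALSE)
  classes <- integer(n)
  classes[ord] <- classes_sorted
  list(breaks = breaks, classes = classes, wss = dp[n_classes, n])
}

#' Brain weight produced per gestation day, contrasted across GI groups
#'
#' Computes `ln(brain_weight / gestation_days)` per species, splits the
#' species into low- and high-GI groups at a threshold (default GI 1.5),
#' and contrasts the group means with a Welch t-test. The fold difference
#' between groups is `exp(mean_high - mean_low)` (a ratio of geometric
#' means, invariant to the units of brain weight).
#'
#' @param tab `data.frame` with columns `brain_weight_g`, `gestation_days`
#'   and either `gi` (numeric) or `gi_group` (`"low"`/`"high"`).
#' @param gi_threshold split point on GI (default 1.5).
#' @return A list with per-group `means` and `sds` of the ln trait, `t`,
#'   `df`, `p` (Welch), and `fold` = exp(difference of means). Rows with
#'   missing gestation or brain weight are dropped with a warning.
#' @export
brainweight_per_gestation <- function(tab, gi_threshold = 1.5) {
  need <- c("brain_weight_g", "gestation_days")
  if (!all(need %in% names(tab))) {
    stop("columns brain_weight_g and gestation_days required",
         call. = FALSE)
  }
  keep <- !is.na(tab$brain_weight_g) & !is.na(tab$gestation_days)
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " row(s) with missing values",
            call. = FALSE)
    tab <- tab[keep, , drop = FALSE]
  }
  grp <- if ("gi" %in% names(tab) && !all(is.na(tab$gi))) {
    ifelse(tab$gi > gi_threshold, "high", "low")
  } else if ("gi_group" %in% names(tab)) {
    tab$gi_group
  } else {
    stop("need a 'gi' or 'gi_group' column", call. = FALSE)
  }
  lnval <- log(tab$brain_weight_g / tab$gestation_days)
  lo <- lnval[grp == "low"]; hi <- lnval[grp == "high"]
  if (length(lo) < 2L || length(hi) < 2L) {
    stop("need >= 2 species per GI group", call. = FALSE)
  }
  tt <- stats::t.test(hi, lo)
  list(means = c(low = mean(lo), high = mean(hi)),
       sds = c(low = stats::sd(lo), high = stats::sd(hi)),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       fold = exp(mean(hi) - mean(lo)))
}
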