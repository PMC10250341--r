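# Evaluation statistics: binned distributions and KL divergence, agreement
# with the identity line, quadrant gating, and KDE density profiles.

#' Bin property values into a smoothed probability distribution
#'
#' Histograms the points on fixed bin edges (1-D, or 2-D over two property
#' columns), adds `epsilon` to every bin and renormalises to sum to one.
#' Points outside the outer edges are clipped to them and counted.
#'
#' @param points Numeric vector (1-D) or two-column matrix/data.frame (2-D).
#' @param edges Strictly increasing bin edges: a numeric vector (1-D) or a
#'   list of two such vectors (2-D).
#' @param epsilon Smoothing mass added to every bin before renormalising;
#'   keeps [kl_divergence()] finite (default 1e-12).
#' @return An object of class `"ifc_binned"`: `edges`, probability vector or
#'   matrix `p`, `epsilon`, `n`, `n_clipped`.
#' @export
bin_distribution <- function(points, edges, epsilon = 1e-12) {
  one_d <- !is.list(edges)
  if (one_d) edges <- list(edges)
  for (e in edges)
    if (any(diff(e) <= 0)) stop("bin edges must be strictly increasing")
  pts <- if (is.null(dim(points))) matrix(points, ncol = 1) else as.matrix(points)
  if (nrow(pts) == 0) stop("empty point set")
  if (ncol(pts) != length(edges))
    stop("points dimensionality does not match edges")
  n_clipped <- 0L
  idx <- matrix(0L, nrow(pts), ncol(pts))
  for (d in seq_along(edges)) {
    e <- edges[[d]]
    out <- pts[, d] < e[1] | pts[, d] > e[length(e)]
    n_clipped <- n_clipped + sum(out)
    x <- pmin(pmax(pts[, d], e[1]), e[length(e)])
    idx[, d] <- findInterval(x, e, rightmost.closed = TRUE, all.inside = TRUE)
  }
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  counts <- array(0, dims)
  flat <- idx[, 1]
  if (length(dims) == 2) flat <- flat + dims[1] * (idx[, 2] - 1L)
  tab <- tabulate(flat, nbins = prod(dims))
  counts[] <- tab
  p <- counts + epsilon
  p <- p / sum(p)
  structure(list(edges = if (one_d) edges[[1]] else edges,
                 p = if (length(dims) == 1) as.vector(p) else p,
                 epsilon = epsilon, n = nrow(pts), n_clipped = n_clipped),
            class = "ifc_binned")
}

#' Kullback-Leibler divergence between two binned distributions
#'
#' \deqn{D_{KL}(P \| Q) = \sum_i P(x_i) \log\left(P(x_i)/Q(x_i)\right)}
#' with natural logarithm; bins where `P` is zero contribute nothing. The
#' smaller the divergence, the more similar the distributions; it is zero
#' only for identical distributions and asymmetric in general. Both
#' distributions must share identical bin edges.
#'
#' @param P,Q `"ifc_binned"` objects from [bin_distribution()].
#' @return Non-negative scalar (nats).
#' @export
#' @examples
#' P <- bin_distribution(c(rep(0.5, 5), rep(1.5, 5)), 0:2, epsilon = 0)
#' kl_divergence(P, P)
kl_divergence <- function(P, Q) {
  stopifnot(inherits(P, "ifc_binned"), inherits(Q, "ifc_binned"))
  if (!isTRUE(all.equal(P$edges, Q$edges, tolerance = 0)))
    stop("distributions must share identical bin edges")
  p <- as.vector(P$p); q <- as.vector(Q$p)
  nz <- p > 0
  if (any(q[nz] == 0)) stop("Q has zero mass where P does not; use epsilon smoothing")
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Agreement with the identity line (R-squared against y = x)
#'
#' \deqn{R^2 = 1 - \sum_i (y_i - x_i)^2 / \sum_i (y_i - \bar y)^2}
#' This scores how well `y` agrees with `x` itself, not with a refitted
#' slope: it is 1 exactly when `y = x`.
#'
#' @param x Reference values.
#' @param y Values compared against `x`.
#' @return Scalar R-squared (can be negative for poor agreement).
#' @export
r_square_identity <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("zero variance in y: identity-line R^2 undefined")
  1 - sum((y - x)^2) / ss_tot
}

#' Quadrant gate thresholds
#'
#' Gating of the C_sm vs sigma_cyto plane into four quadrants by one
#' threshold per axis; defaults 1.4 uF/cm^2 and 0.4 S/m.
#'
#' @param csm_threshold C_sm threshold, uF/cm^2.
#' @param sigma_threshold sigma_cyto threshold, S/m.
#' @return An object of class `"quadrant_gate"`.
#' @export
quadrant_gate <- function(csm_threshold = 1.4, sigma_threshold = 0.4) {
  stopifnot(csm_threshold > 0, sigma_threshold > 0)
  structure(list(csm_threshold = csm_threshold,
                 sigma_threshold = sigma_threshold), class = "quadrant_gate")
}

#' Cell proportions in the four gate quadrants
#'
#' Quadrants follow the standard counter-clockwise order on the sigma_cyto
#' (x) vs C_sm (y) plane: Q1 high-sigma/high-C_sm, Q2 low-sigma/high-C_sm,
#' Q3 low/low, Q4 high-sigma/low-C_sm. A point lying exactly on a threshold
#' is assigned to the adjacent quadrant with the higher index (thresholds are
#' "low" side), stated once here for determinism.
#'
#' @param csm,sigma_cyto Numeric vectors of fitted properties.
#' @param gate A [quadrant_gate()].
#' @return Named numeric vector `Q1`..`Q4`, summing to exactly 1.
#' @export
quadrant_proportions <- function(csm, sigma_cyto, gate = quadrant_gate()) {
  stopifnot(length(csm) == length(sigma_cyto), length(csm) > 0)
  hi_s <- sigma_cyto > gate$sigma_threshold
  hi_c <- csm > gate$csm_threshold
  q <- c(Q1 = sum(hi_s & hi_c), Q2 = sum(!hi_s & hi_c),
         Q3 = sum(!hi_s & !hi_c), Q4 = sum(hi_s & !hi_c))
  q / length(csm)
}

#' Kernel density profile of a property distribution
#'
#' Gaussian KDE on a fixed evaluation grid, used for the population-peak
#' summaries of ridgeline-style density plots (e.g. "the C_sm peak sits near
#' 2.6 uF/cm^2").
#'
#' @param x Property values (>= 10 points).
#' @param from,to Evaluation range (defaults: data range).
#' @param n Number of evaluation grid points.
#' @return List: `grid`, `density` (integrates to ~1 over the grid), `peak`
#'   (grid value with maximal density) and `local_maxima` (all interior modes
#'   plus retained boundary maxima, decreasing density order).
#' @export
density_profile <- function(x, from = min(x), to = max(x), n = 512) {
  stopifnot(length(x) >= 10)
  d <- stats::density(x, from = from, to = to, n = n)
  y <- d$y
  interior <- which(diff(sign(diff(y))) == -2) + 1L
  ends <- c(if (y[1] > y[2]) 1L, if (y[n] > y[n - 1]) n)
  maxima <- unique(c(interior, ends))
  maxima <- maxima[order(-y[maxima])]
  list(grid = d$x, density = y, peak = d$x[which.max(y)],
       local_maxima = d$x[maxima])
}
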