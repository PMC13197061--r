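# Quantitative comparison of surface maps and sample sets: MSE, a spherical
# SSIM whose sliding window is the 1-ring patch of each vertex, and the
# Gaussian Frechet distance between embedded sample sets.

#' Mean squared error between two maps
#' @param a,b Same-shape numeric vectors or matrices.
#' @return Scalar mean of squared differences.
#' @export
map_mse <- function(a, b) {
  if (!all(dim2(a) == dim2(b))) stop("'a' and 'b' shapes differ")
  mean((a - b)^2)
}

#' Structural similarity on the sphere
#'
#' SSIM with local statistics computed over each vertex's 1-ring patch (the
#' vertex plus its 5 or 6 ring neighbors — the canonical local neighborhood
#' of the mesh, playing the role of the sliding window), averaged over
#' vertices. Both maps are first shifted by their joint minimum so that
#' signed (standardized) feature maps behave like image data on `[0, R]`,
#' which the luminance term assumes. Identical maps score exactly 1;
#' anticorrelated zero-mean maps score below 0.
#'
#' @param a,b Per-vertex numeric vectors on `ico`.
#' @param ico The `ico_sphere` the maps live on.
#' @param k1,k2 Stabilization constants (defaults 0.01, 0.03).
#' @param data_range Dynamic range `R` of the data; constants are
#'   `c1 = (k1 R)^2`, `c2 = (k2 R)^2`. Defaults to the joint range of the
#'   two maps.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim_sphere <- function(a, b, ico, k1 = 0.01, k2 = 0.03, data_range = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  nv <- nrow(ico$vertices)
  if (length(a) != nv || length(b) != nv)
    stop("map length must match the sphere's vertex count")
  if (is.null(data_range)) data_range <- max(c(a, b)) - min(c(a, b))
  if (data_range <= 0) stop("'data_range' must be positive")
  # SSIM's luminance term assumes non-negative image data; shift both maps by
  # their joint minimum so feature maps in standardized (signed) units behave
  # like images on [0, R]
  off <- min(c(a, b))
  a <- a - off
  b <- b - off
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  tab <- ico$neighbor_table
  val <- ico$valence
  pent <- val == 5L
  patch_sum <- function(x) {
    s <- x + rowSums(matrix(x[tab], nv))
    s[pent] <- s[pent] - x[pent]   # pad slot repeats the center
    s
  }
  np <- val + 1
  mu_a <- patch_sum(a) / np
  mu_b <- patch_sum(b) / np
  va <- patch_sum(a^2) / np - mu_a^2
  vb <- patch_sum(b^2) / np - mu_b^2
  cab <- patch_sum(a * b) / np - mu_a * mu_b
  s <- ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
  mean(s)
}

#' Gaussian Frechet distance between two embedded sample sets
#'
#' \eqn{\|\mu_X-\mu_Y\|^2 + \mathrm{tr}(\Sigma_X+\Sigma_Y -
#' 2(\Sigma_X\Sigma_Y)^{1/2})}, the distance between the Gaussian fits of the
#' two point clouds (the mathematical core of FID scores). The matrix square
#' root is taken through a symmetric eigendecomposition; near-singular
#' covariances are diagonally loaded and a message emitted.
#'
#' @param X,Y Points x dimensions matrices (>= 2 points each, equal width).
#' @param eps Diagonal loading applied when a covariance is near-singular.
#' @return Non-negative scalar (clamped at 0 against roundoff).
#' @export
frechet_distance <- function(X, Y, eps = 1e-8) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("embedding dimensions differ")
  if (nrow(X) < 2 || nrow(Y) < 2) stop("need at least 2 points per set")
  mu_x <- colMeans(X); mu_y <- colMeans(Y)
  sx <- stats::cov(X); sy <- stats::cov(Y)
  d <- ncol(X)
  if (rcond_sym(sx) < 1e-12 || rcond_sym(sy) < 1e-12) {
    message("near-singular covariance: applying diagonal loading")
    sx <- sx + diag(eps, d); sy <- sy + diag(eps, d)
  }
  rx <- sym_sqrt(sx)
  m <- rx %*% sy %*% rx
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  val <- sum((mu_x - mu_y)^2) + sum(diag(sx)) + sum(diag(sy)) - 2 * tr_sqrt
  max(val, 0)
}

sym_sqrt <- function(s) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

rcond_sym <- function(s) {
  ev <- eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Per-ROI mean embedding of a set of maps
#'
#' The default pluggable embedding for [frechet_distance()] comparisons of
#' generated versus real surface maps: each map becomes its vector of ROI
#' means.
#' @param maps List of per-vertex maps.
#' @param parcellation A `parcellation`.
#' @return length(maps) x n_rois matrix.
#' @export
embed_roi_means <- function(maps, parcellation) {
  t(vapply(maps, roi_means, numeric(parcellation$n_rois),
           parcellation = parcellation))
}
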