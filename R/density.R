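# Analytic Gaussian-mixture densities and gridded (CUBE-backed) densities.
# All internal lengths are bohr, momenta bohr^-1, entropies nats.

#' Isotropic Gaussian-mixture probability density
#'
#' A unit-normalized three-dimensional probability density written as a
#' weighted sum of isotropic Gaussians, the analytic surrogate used in place
#' of ab initio electron densities. Lives either in position space (bohr) or
#' momentum space (bohr^-1).
#'
#' @param centers Numeric matrix, one row per component, columns x,y,z (bohr
#'   or bohr^-1 according to `space`).
#' @param sigmas Positive per-component widths.
#' @param weights Non-negative component masses; normalized to sum to one.
#' @param space `"position"` or `"momentum"`.
#' @return An object of class `gaussian_mixture`.
#' @examples
#' g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
#' evaluate_density(g, rbind(c(0, 0, 0)))  # (2*pi)^(-3/2)
#' @export
gaussian_mixture <- function(centers, sigmas, weights = NULL,
                             space = c("position", "momentum")) {
  space <- match.arg(space)
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  sigmas <- rep_len(as.numeric(sigmas), n)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- rep_len(as.numeric(weights), n)
  stopifnot(all(is.finite(centers)), all(sigmas > 0), all(weights >= 0))
  total <- sum(weights)
  if (total <= 0) stop("mixture weights must have positive total mass",
                       call. = FALSE)
  structure(list(centers = centers, sigmas = sigmas,
                 weights = weights / total, space = space),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("<gaussian_mixture> %d component(s), %s space\n",
              nrow(x$centers), x$space))
  invisible(x)
}

#' Density on a regular Cartesian grid
#'
#' Volumetric non-negative density sampled on a regular axis-aligned grid,
#' the numerical carrier for densities read from Gaussian CUBE files.
#' Values are normalized so that the Riemann sum times the voxel volume is 1.
#'
#' @param origin Grid origin (bohr), length 3.
#' @param spacing Per-axis grid step (bohr), length 3, positive.
#' @param values 3D numeric array of non-negative density values.
#' @param normalize Renormalize to unit mass (default `TRUE`).
#' @return An object of class `grid_density`.
#' @export
grid_density <- function(origin, spacing, values, normalize = TRUE) {
  stopifnot(length(origin) == 3, length(spacing) == 3, all(spacing > 0),
            is.array(values), length(dim(values)) == 3)
  if (any(values < 0)) stop("grid density values must be non-negative",
                            call. = FALSE)
  voxel <- prod(spacing)
  mass <- sum(values) * voxel
  if (mass <= 0) stop("grid density has zero mass", call. = FALSE)
  if (normalize) values <- values / mass
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 shape = dim(values), values = values),
            class = "grid_density")
}

.grid_axes <- function(g) {
  lapply(1:3, function(k) g$origin[k] + g$spacing[k] * (seq_len(g$shape[k]) - 1))
}

#' Evaluate a density at points
#'
#' Exact analytic evaluation for Gaussian mixtures; trilinear interpolation
#' for grid densities.
#'
#' @param density A [gaussian_mixture()] or [grid_density()].
#' @param points Numeric matrix of evaluation points, one row per point.
#' @param outside For grids, what to do with points outside the grid
#'   support: `"zero"` (default) or `"error"`.
#' @return Numeric vector of non-negative density values.
#' @export
evaluate_density <- function(density, points, outside = c("zero", "error")) {
  UseMethod("evaluate_density")
}

#' @export
evaluate_density.gaussian_mixture <- function(density, points,
                                              outside = c("zero", "error")) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(all(is.finite(points)))
  out <- numeric(nrow(points))
  for (c_ in seq_along(density$sigmas)) {
    s2 <- density$sigmas[c_]^2
    d2 <- (points[, 1] - density$centers[c_, 1])^2 +
          (points[, 2] - density$centers[c_, 2])^2 +
          (points[, 3] - density$centers[c_, 3])^2
    out <- out + density$weights[c_] * (2 * pi * s2)^(-1.5) * exp(-d2 / (2 * s2))
  }
  out
}

# Trilinear interpolation of an arbitrary 3D array on a regular grid.
.trilinear <- function(origin, spacing, shape, v, points, outside) {
  n <- nrow(points)
  fx <- sweep(sweep(points, 2, origin, "-"), 2, spacing, "/")
  lo <- floor(fx)
  inside <- rep(TRUE, n)
  for (k in 1:3) {
    inside <- inside & fx[, k] >= 0 & fx[, k] <= shape[k] - 1
  }
  if (outside == "error" && any(!inside)) {
    stop("point(s) outside grid support", call. = FALSE)
  }
  lo <- pmin(pmax(lo, 0), matrix(rep(shape - 2, each = n), n))
  t_ <- fx - lo
  out <- numeric(n)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (ifelse(dx == 1, t_[, 1], 1 - t_[, 1]) *
          ifelse(dy == 1, t_[, 2], 1 - t_[, 2]) *
          ifelse(dz == 1, t_[, 3], 1 - t_[, 3]))
    out <- out + w * v[cbind(lo[, 1] + 1 + dx, lo[, 2] + 1 + dy,
                             lo[, 3] + 1 + dz)]
  }
  out[!inside] <- 0
  out
}

#' @export
evaluate_density.grid_density <- function(density, points,
                                          outside = c("zero", "error")) {
  outside <- match.arg(outside)
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(all(is.finite(points)))
  .trilinear(density$origin, density$spacing, density$shape,
             density$values, points, outside)
}

#' Gradient of a density at points
#'
#' Analytic gradients for Gaussian mixtures; second-order central finite
#' differences (one-sided at the boundary) sampled at the nearest grid node
#' for grid densities.
#'
#' @inheritParams evaluate_density
#' @return Numeric matrix, one gradient row (d/dx, d/dy, d/dz) per point.
#' @export
gradient_density <- function(density, points, outside = c("zero", "error")) {
  UseMethod("gradient_density")
}

#' @export
gradient_density.gaussian_mixture <- function(density, points,
                                              outside = c("zero", "error")) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(all(is.finite(points)))
  out <- matrix(0, nrow(points), 3)
  for (c_ in seq_along(density$sigmas)) {
    s2 <- density$sigmas[c_]^2
    diff <- sweep(points, 2, density$centers[c_, ], "-")
    d2 <- rowSums(diff^2)
    rho_c <- density$weights[c_] * (2 * pi * s2)^(-1.5) * exp(-d2 / (2 * s2))
    out <- out - diff * (rho_c / s2)
  }
  out
}

#' @export
gradient_density.grid_density <- function(density, points,
                                          outside = c("zero", "error")) {
  outside <- match.arg(outside)
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(all(is.finite(points)))
  g <- .grid_gradient_field(density)
  out <- matrix(0, nrow(points), 3)
  for (k in 1:3) {
    out[, k] <- .trilinear(density$origin, density$spacing, density$shape,
                           g[[k]], points, outside)
  }
  out
}

# Central-difference gradient arrays of a grid density (one-sided at edges).
.grid_gradient_field <- function(density) {
  v <- density$values
  dims <- dim(v)
  out <- vector("list", 3)
  for (k in 1:3) {
    n <- dims[k]
    h <- density$spacing[k]
    ip <- c(2:n, n)      # forward neighbour (clamped)
    im <- c(1, 1:(n - 1))  # backward neighbour (clamped)
    denom <- (ip - im) * h
    slice <- function(i) {
      idx <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
      idx[[k]] <- i
      do.call(`[`, c(list(v), idx, list(drop = FALSE)))
    }
    d <- (slice(ip) - slice(im))
    # divide by the per-plane denominator along axis k
    denom_arr <- array(0, dims)
    perm <- array(rep(denom, times = prod(dims[-k])), dim = c(n, dims[-k]))
    denom_arr <- aperm(perm, order(c(k, (1:3)[-k])))
    out[[k]] <- d / denom_arr
  }
  out
}

#' Momentum-space conjugate of a position-space mixture
#'
#' Maps each isotropic position-space Gaussian component to its momentum
#' density under the three-dimensional Fourier transform of the underlying
#' s-type primitive: the modulus of the transform of a displaced isotropic
#' Gaussian is displacement-independent, so each component becomes an
#' origin-centred Gaussian of width `1/(2*sigma)` with its weight preserved.
#'
#' @param density A position-space [gaussian_mixture()].
#' @return A momentum-space [gaussian_mixture()].
#' @examples
#' g <- gaussian_mixture(rbind(c(1, 2, 3)), sigmas = 0.5, weights = 1)
#' momentum_conjugate(g)$sigmas  # 1.0
#' @export
momentum_conjugate <- function(density) {
  stopifnot(inherits(density, "gaussian_mixture"))
  if (density$space != "position") {
    stop("momentum_conjugate() requires a position-space mixture",
         call. = FALSE)
  }
  sig_p <- 1 / (2 * density$sigmas)
  # components of equal width coincide at the origin: merge them exactly
  key <- factor(match(sig_p, unique(sig_p)),
                levels = seq_along(unique(sig_p)))
  w <- vapply(split(density$weights, key), sum, numeric(1))
  gaussian_mixture(matrix(0, length(unique(sig_p)), 3),
                   sigmas = unique(sig_p),
                   weights = w,
                   space = "momentum")
}
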