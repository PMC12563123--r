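# Tensor-product quadrature for smooth, fast-decaying Gaussian mixtures.
#
# The integration box covers all component centers plus a tail margin chosen
# from the requested omitted tail mass; trapezoid sums converge
# super-algebraically for Gaussians, so refinement is by doubling the number
# of points per axis until the integrals stabilise.

#' Quadrature settings
#'
#' @param base_points_per_axis Points per axis at the coarsest level
#'   (minimum 16).
#' @param refinement_levels Maximum number of point-doubling refinements.
#' @param tolerance Relative change between successive levels at which the
#'   quadrature is accepted.
#' @param tail_mass Per-component Gaussian tail mass allowed outside the
#'   integration box; sets the box margin `k*sigma` with
#'   `k = qnorm(1 - tail_mass/2)`.
#' @return An object of class `quadrature_spec`.
#' @export
quadrature_spec <- function(base_points_per_axis = 32L,
                            refinement_levels = 3L,
                            tolerance = 1e-6,
                            tail_mass = 1e-8) {
  stopifnot(base_points_per_axis >= 16, refinement_levels >= 1,
            tolerance > 0, tail_mass > 0, tail_mass < 1)
  structure(list(base_points_per_axis = as.integer(base_points_per_axis),
                 refinement_levels = as.integer(refinement_levels),
                 tolerance = tolerance, tail_mass = tail_mass),
            class = "quadrature_spec")
}

# Axis-aligned box covering all centers +- k*sigma.
.quad_box <- function(density, tail_mass) {
  k <- stats::qnorm(1 - tail_mass / 2)
  lo <- apply(density$centers - k * density$sigmas, 2, min)
  hi <- apply(density$centers + k * density$sigmas, 2, max)
  list(lo = lo, hi = hi)
}

# Evaluate mixture density (and optionally its gradient) on a tensor grid.
# Exploits separability of isotropic Gaussians: each component is an outer
# product of three 1D factors. Returns arrays of dim (nx, ny, nz).
.mixture_fields <- function(density, xs, ys, zs, gradient = FALSE) {
  dims <- c(length(xs), length(ys), length(zs))
  rho <- array(0, dims)
  gx <- gy <- gz <- if (gradient) array(0, dims) else NULL
  for (c_ in seq_along(density$sigmas)) {
    s2 <- density$sigmas[c_]^2
    ctr <- density$centers[c_, ]
    norm1 <- (2 * pi * s2)^(-0.5)
    fx <- density$weights[c_] * norm1 * exp(-(xs - ctr[1])^2 / (2 * s2))
    fy <- norm1 * exp(-(ys - ctr[2])^2 / (2 * s2))
    fz <- norm1 * exp(-(zs - ctr[3])^2 / (2 * s2))
    axy <- outer(fx, fy)
    a <- outer(axy, fz)
    rho <- rho + a
    if (gradient) {
      gx <- gx + a * ((ctr[1] - xs) / s2)  # recycles along dim 1
      gy <- gy + outer(outer(fx, fy * ((ctr[2] - ys) / s2)), fz)
      gz <- gz + outer(axy, fz * ((ctr[3] - zs) / s2))
    }
  }
  list(rho = rho, gx = gx, gy = gy, gz = gz)
}

.RHO_FLOOR <- 1e-300

# Joint trapezoid integrals of mass, -rho*log(rho), |grad rho|^2/rho, rho^2
# at one resolution; the hot loop lives in compiled code.
.quad_level <- function(density, n, box, need_gradient = TRUE) {
  .quad_level_cpp(density$centers, density$sigmas, density$weights,
                  box$lo, box$hi, as.integer(n), need_gradient)
}

# Pure-R reference for the compiled level evaluation (kept as the
# independent cross-check used by the tests).
.quad_level_r <- function(density, n, box, need_gradient = TRUE) {
  axes <- lapply(1:3, function(k) seq(box$lo[k], box$hi[k], length.out = n))
  h <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  f <- .mixture_fields(density, axes[[1]], axes[[2]], axes[[3]],
                       gradient = need_gradient)
  wts <- lapply(axes, function(a) {
    w <- rep(1, length(a)); w[c(1, length(a))] <- 0.5; w
  })
  w3 <- outer(outer(wts[[1]], wts[[2]]), wts[[3]])
  voxel <- prod(h)
  rho <- f$rho
  pos <- rho > .RHO_FLOOR
  slog <- array(0, dim(rho))
  slog[pos] <- -rho[pos] * log(rho[pos])
  out <- c(mass = sum(w3 * rho) * voxel,
           S = sum(w3 * slog) * voxel,
           I = NA_real_,
           D = sum(w3 * rho^2) * voxel)
  if (need_gradient) {
    fisher <- array(0, dim(rho))
    fisher[pos] <- (f$gx[pos]^2 + f$gy[pos]^2 + f$gz[pos]^2) / rho[pos]
    out["I"] <- sum(w3 * fisher) * voxel
  }
  out
}

# Refine until S, I, D and mass all stabilise; returns values, a relative
# error estimate (change at the accepted level) and the final points/axis.
.quad_integrals <- function(density, quad = quadrature_spec(),
                            need_gradient = TRUE) {
  box <- .quad_box(density, quad$tail_mass)
  n <- quad$base_points_per_axis
  prev <- .quad_level(density, n, box, need_gradient)
  for (lev in seq_len(quad$refinement_levels)) {
    n <- n * 2L
    cur <- .quad_level(density, n, box, need_gradient)
    keep <- !is.na(cur)
    rel <- abs(cur[keep] - prev[keep]) / pmax(abs(cur[keep]), 1e-12)
    err <- max(rel)
    if (err <= quad$tolerance) {
      return(list(values = cur, error = err, points_per_axis = n,
                  converged = TRUE))
    }
    prev <- cur
  }
  stop(structure(class = c("hydroinfo_quadrature_error", "error", "condition"),
                 list(message = sprintf(
                   paste0("quadrature did not converge within %d refinement",
                          " levels (last relative change %.3g); last two",
                          " estimates attached"),
                   quad$refinement_levels, err),
                   call = NULL, last = cur, previous = prev)))
}

#' Integrate a functional of a density
#'
#' Integrates one of the standard information functionals (or a custom
#' pointwise functional of the density values) by tensor-product trapezoid
#' quadrature with point-doubling refinement. For Gaussian mixtures the
#' integrand is evaluated analytically; for grid densities the stored voxel
#' values are summed directly (no refinement possible).
#'
#' @param density A [gaussian_mixture()] or [grid_density()].
#' @param functional `"mass"` (plain normalization integral),
#'   `"density_sq"`, `"neg_rho_log_rho"`, `"grad_sq_over_rho"`, or a
#'   function mapping density values to integrand values.
#' @param quad A [quadrature_spec()].
#' @return A list with `value`, `error` (relative change at the accepted
#'   refinement level; `NA` for grids) and `points_per_axis`.
#' @examples
#' g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
#' integrate_density(g, "density_sq")$value  # (4*pi)^(-3/2)
#' @export
integrate_density <- function(density,
                              functional = c("mass", "density_sq",
                                             "neg_rho_log_rho",
                                             "grad_sq_over_rho"),
                              quad = quadrature_spec()) {
  if (inherits(density, "grid_density")) {
    return(.grid_integrals(density, functional))
  }
  stopifnot(inherits(density, "gaussian_mixture"))
  if (is.function(functional)) {
    return(.integrate_custom(density, functional, quad))
  }
  functional <- match.arg(functional)
  key <- switch(functional, mass = "mass", density_sq = "D",
                neg_rho_log_rho = "S", grad_sq_over_rho = "I")
  res <- .quad_integrals(density, quad,
                         need_gradient = functional == "grad_sq_over_rho")
  list(value = unname(res$values[key]), error = res$error,
       points_per_axis = res$points_per_axis)
}

.integrate_custom <- function(density, fn, quad) {
  box <- .quad_box(density, quad$tail_mass)
  n <- quad$base_points_per_axis
  level <- function(n) {
    axes <- lapply(1:3, function(k) seq(box$lo[k], box$hi[k], length.out = n))
    h <- vapply(axes, function(a) a[2] - a[1], numeric(1))
    f <- .mixture_fields(density, axes[[1]], axes[[2]], axes[[3]])
    sum(fn(f$rho)) * prod(h)
  }
  prev <- level(n)
  for (lev in seq_len(quad$refinement_levels)) {
    n <- n * 2L
    cur <- level(n)
    err <- abs(cur - prev) / max(abs(cur), 1e-12)
    if (err <= quad$tolerance) {
      return(list(value = cur, error = err, points_per_axis = n))
    }
    prev <- cur
  }
  stop("custom-functional quadrature did not converge", call. = FALSE)
}

# Riemann sums over a stored grid; gradient via central differences.
.grid_integrals <- function(density, functional) {
  if (is.function(functional)) {
    voxel <- prod(density$spacing)
    return(list(value = sum(functional(density$values)) * voxel,
                error = NA_real_, points_per_axis = max(density$shape)))
  }
  functional <- match.arg(functional,
                          c("mass", "density_sq", "neg_rho_log_rho",
                            "grad_sq_over_rho"))
  v <- density$values
  voxel <- prod(density$spacing)
  val <- switch(functional,
    mass = sum(v) * voxel,
    density_sq = sum(v^2) * voxel,
    neg_rho_log_rho = {
      pos <- v > .RHO_FLOOR
      -sum(v[pos] * log(v[pos])) * voxel
    },
    grad_sq_over_rho = {
      g <- .grid_gradient_field(density)
      pos <- v > .RHO_FLOOR
      sum((g[[1]][pos]^2 + g[[2]][pos]^2 + g[[3]][pos]^2) / v[pos]) * voxel
    })
  list(value = val, error = NA_real_, points_per_axis = max(density$shape))
}
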