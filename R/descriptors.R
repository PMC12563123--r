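# The five information-theoretic descriptors of a probability density:
# Shannon entropy S, Fisher information I, disequilibrium D, and the LMC and
# Fisher-Shannon complexities built from them. All in atomic units / nats.

#' Shannon entropy of a density
#'
#' `S = -integral rho ln rho`: global measure of the dispersion
#' (delocalization) of the density. For an isotropic Gaussian of width sigma,
#' `S = (3/2) ln(2 pi e) + 3 ln sigma`.
#'
#' @param density A [gaussian_mixture()] or [grid_density()].
#' @param quad A [quadrature_spec()].
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(density, quad = quadrature_spec()) {
  integrate_density(density, "neg_rho_log_rho", quad)$value
}

#' Fisher information of a density
#'
#' `I = integral |grad rho|^2 / rho`: local, gradient-sensitive measure of
#' the sharpness of the density. For an isotropic Gaussian, `I = 3/sigma^2`.
#'
#' @inheritParams shannon_entropy
#' @return Fisher information in atomic units.
#' @export
fisher_information <- function(density, quad = quadrature_spec()) {
  integrate_density(density, "grad_sq_over_rho", quad)$value
}

#' Disequilibrium of a density
#'
#' `D = integral rho^2` (self-similarity / information energy): distance of
#' the density from uniformity. For an isotropic Gaussian,
#' `D = (4 pi sigma^2)^(-3/2)`.
#'
#' @inheritParams shannon_entropy
#' @return Disequilibrium in atomic units.
#' @export
disequilibrium <- function(density, quad = quadrature_spec()) {
  integrate_density(density, "density_sq", quad)$value
}

#' LMC statistical complexity
#'
#' Lopez-Ruiz--Mancini--Calbet complexity `C_LMC = D * exp(S)`, the product
#' of disequilibrium and the exponential Shannon entropy. Dimensionless,
#' invariant under translation and scaling, and bounded below by 1 for any
#' three-dimensional probability density (an isotropic Gaussian gives
#' `(e/2)^(3/2)`).
#'
#' @param D Disequilibrium (must be positive).
#' @param S Shannon entropy in nats.
#' @return Dimensionless complexity.
#' @export
lmc_complexity <- function(D, S) {
  stopifnot(all(D > 0))
  D * exp(S)
}

#' Fisher-Shannon complexity
#'
#' `C_FS = I * J` where `J = (1/(2 pi e)) exp(2 S / 3)` is the Shannon power
#' entropy. Dimensionless, scale invariant, bounded below by 3 for any
#' three-dimensional probability density, with equality exactly for
#' isotropic Gaussians.
#'
#' @param I Fisher information (must be positive).
#' @param S Shannon entropy in nats.
#' @return Dimensionless complexity.
#' @export
fs_complexity <- function(I, S) {
  stopifnot(all(I > 0))
  I * exp(2 * S / 3) / (2 * pi * exp(1))
}

#' Full descriptor set of a position-space density
#'
#' Computes the five descriptors in position space and, for analytic
#' mixtures, also in momentum space via [momentum_conjugate()]. Grid
#' densities have no momentum conjugate available, so the momentum leg is
#' reported as `NA` rather than silently zero.
#'
#' @param density_r Position-space [gaussian_mixture()] or [grid_density()].
#' @param quad A [quadrature_spec()].
#' @return An object of class `descriptor_set`: a named list with
#'   `S_r, I_r, D_r, C_LMC_r, C_FS_r`, the `_p` momentum counterparts, and
#'   `quad_error` (the larger of the two legs' relative quadrature error
#'   estimates).
#' @examples
#' g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
#' ds <- descriptor_set(g)
#' ds$S_r + ds$S_p  # 3 * (1 + log(pi))
#' @export
descriptor_set <- function(density_r, quad = quadrature_spec()) {
  leg <- function(d) {
    if (inherits(d, "gaussian_mixture")) {
      res <- .quad_integrals(d, quad, need_gradient = TRUE)
      vals <- res$values
      list(S = unname(vals["S"]), I = unname(vals["I"]),
           D = unname(vals["D"]), error = res$error)
    } else {
      list(S = integrate_density(d, "neg_rho_log_rho", quad)$value,
           I = integrate_density(d, "grad_sq_over_rho", quad)$value,
           D = integrate_density(d, "density_sq", quad)$value,
           error = NA_real_)
    }
  }
  r <- leg(density_r)
  if (inherits(density_r, "gaussian_mixture")) {
    if (density_r$space != "position") {
      stop("descriptor_set() expects a position-space density", call. = FALSE)
    }
    p <- leg(momentum_conjugate(density_r))
    quad_error <- max(r$error, p$error)
  } else {
    p <- list(S = NA_real_, I = NA_real_, D = NA_real_, error = NA_real_)
    quad_error <- NA_real_
  }
  pc <- function(l) {
    if (is.na(l$S)) list(C_LMC = NA_real_, C_FS = NA_real_)
    else list(C_LMC = lmc_complexity(l$D, l$S), C_FS = fs_complexity(l$I, l$S))
  }
  rc <- pc(r); pcx <- pc(p)
  structure(list(S_r = r$S, I_r = r$I, D_r = r$D,
                 C_LMC_r = rc$C_LMC, C_FS_r = rc$C_FS,
                 S_p = p$S, I_p = p$I, D_p = p$D,
                 C_LMC_p = pcx$C_LMC, C_FS_p = pcx$C_FS,
                 quad_error = quad_error),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("<descriptor_set> (a.u. / nats)\n")
  m <- rbind(r = unlist(x[c("S_r", "I_r", "D_r", "C_LMC_r", "C_FS_r")]),
             p = unlist(x[c("S_p", "I_p", "D_p", "C_LMC_p", "C_FS_p")]))
  colnames(m) <- c("S", "I", "D", "C_LMC", "C_FS")
  print(signif(m, 6))
  cat(sprintf("quadrature error estimate: %.3g\n", x$quad_error))
  invisible(x)
}

#' @export
as.data.frame.descriptor_set <- function(x, ...) {
  data.frame(measure = rep(c("S", "I", "D", "C_LMC", "C_FS"), 2),
             space = rep(c("r", "p"), each = 5),
             value = unlist(x[c("S_r", "I_r", "D_r", "C_LMC_r", "C_FS_r",
                                "S_p", "I_p", "D_p", "C_LMC_p", "C_FS_p")],
                            use.names = FALSE),
             stringsAsFactors = FALSE)
}
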