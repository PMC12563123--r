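# Rigid three-site water models and the site-site pair potential.
#
# Conventions: lengths in angstrom and energies in kelvin (epsilon/kB) at the
# user interface; density work elsewhere in the package is in atomic units.

# physical constants
.BOHR_PER_ANGSTROM <- 1.8897261254578281
# e^2/(4 pi eps0) / kB, in K * angstrom
.COULOMB_K_ANGSTROM <- 167100.97

#' Rigid water geometry
#'
#' @param r_OH O-H bond length in angstrom.
#' @param theta_HOH H-O-H angle in degrees.
#' @return An object of class `water_geometry`.
#' @export
water_geometry <- function(r_OH, theta_HOH) {
  stopifnot(is.numeric(r_OH), length(r_OH) == 1L, r_OH > 0,
            is.numeric(theta_HOH), length(theta_HOH) == 1L,
            theta_HOH > 0, theta_HOH < 180)
  structure(list(r_OH = r_OH, theta_HOH = theta_HOH),
            class = "water_geometry")
}

#' Three-site water force field parameters
#'
#' A rigid water model: fixed geometry, point charges on all three sites and
#' a single Lennard-Jones site on the oxygen.
#'
#' @param name Model label.
#' @param geometry A [water_geometry()].
#' @param q_H,q_O Site charges in units of the elementary charge; the
#'   molecule must be neutral (`q_O + 2 q_H = 0`).
#' @param sigma_OO Lennard-Jones diameter for an O-O pair, angstrom.
#' @param eps_OO_over_kB Lennard-Jones well depth divided by the Boltzmann
#'   constant, kelvin.
#' @return An object of class `force_field`.
#' @export
force_field <- function(name, geometry, q_H, q_O, sigma_OO, eps_OO_over_kB) {
  stopifnot(inherits(geometry, "water_geometry"),
            is.numeric(q_H), is.numeric(q_O),
            abs(q_O + 2 * q_H) < 1e-12,
            sigma_OO > 0, eps_OO_over_kB > 0)
  structure(list(name = name, geometry = geometry, q_H = q_H, q_O = q_O,
                 sigma_OO = sigma_OO, eps_OO_over_kB = eps_OO_over_kB),
            class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat(sprintf(
    "<force_field> %s: rOH = %g A, theta = %g deg, qH = %+g e, qO = %+g e,\n  sigmaOO = %g A, epsOO/kB = %g K\n",
    x$name, x$geometry$r_OH, x$geometry$theta_HOH, x$q_H, x$q_O,
    x$sigma_OO, x$eps_OO_over_kB))
  invisible(x)
}

#' Built-in water models
#'
#' Parameter sets for the rigid three-site models TIP3P, SPC and SPCE
#' (SPC/epsilon, written SPCE throughout to keep labels file-safe).
#'
#' @param names Which models to return; default all three.
#' @return A named list of [force_field()] objects.
#' @examples
#' water_models("TIP3P")$TIP3P
#' @export
water_models <- function(names = c("TIP3P", "SPC", "SPCE")) {
  all <- list(
    TIP3P = force_field("TIP3P", water_geometry(0.9572, 104.52),
                        q_H = +0.417, q_O = -0.834,
                        sigma_OO = 3.1506, eps_OO_over_kB = 76.54),
    SPC   = force_field("SPC", water_geometry(1.0, 109.45),
                        q_H = +0.410, q_O = -0.820,
                        sigma_OO = 3.1660, eps_OO_over_kB = 78.20),
    SPCE  = force_field("SPCE", water_geometry(1.0, 109.45),
                        q_H = +0.445, q_O = -0.890,
                        sigma_OO = 3.1785, eps_OO_over_kB = 84.90)
  )
  names <- match.arg(names, choices = names(all), several.ok = TRUE)
  all[names]
}

#' Lorentz-Berthelot mixing rules
#'
#' Cross-interaction Lennard-Jones parameters for an O-O pair of two models:
#' arithmetic mean for sigma, geometric mean for epsilon.
#'
#' @param ff_i,ff_j [force_field()] objects.
#' @return A list with `sigma` (angstrom) and `eps_over_kB` (kelvin).
#' @export
lorentz_berthelot <- function(ff_i, ff_j) {
  list(sigma = (ff_i$sigma_OO + ff_j$sigma_OO) / 2,
       eps_over_kB = sqrt(ff_i$eps_OO_over_kB * ff_j$eps_OO_over_kB))
}

#' Site-site pair potential
#'
#' Lennard-Jones plus Coulomb energy of the O-O site pair of two water
#' models at separation `r`, with cross LJ parameters from the
#' Lorentz-Berthelot rules and the O charges in the Coulomb term.
#'
#' @param r O-O separation in angstrom; must be positive.
#' @param ff_i,ff_j [force_field()] objects (may be the same model).
#' @param terms Which contributions to include; default both.
#' @return Energy in kelvin (i.e. V/kB), vectorised over `r`.
#' @examples
#' tip3p <- water_models("TIP3P")$TIP3P
#' pair_potential(2^(1/6) * tip3p$sigma_OO, tip3p, tip3p, terms = "lj")
#' @export
pair_potential <- function(r, ff_i, ff_j = ff_i,
                           terms = c("lj", "coulomb")) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("pair separation `r` must be positive and finite", call. = FALSE)
  }
  terms <- match.arg(terms, several.ok = TRUE)
  mix <- lorentz_berthelot(ff_i, ff_j)
  v <- numeric(length(r))
  if ("lj" %in% terms) {
    sr6 <- (mix$sigma / r)^6
    v <- v + 4 * mix$eps_over_kB * (sr6^2 - sr6)
  }
  if ("coulomb" %in% terms) {
    v <- v + ff_i$q_O * ff_j$q_O * .COULOMB_K_ANGSTROM / r
  }
  v
}

# Site template of a rigid monomer, angstrom, rows O, H1, H2.
# O at the origin, H's in the xy-plane symmetric about the x axis.
.water_sites <- function(ff) {
  th <- ff$geometry$theta_HOH * pi / 180
  r <- ff$geometry$r_OH
  rbind(O  = c(0, 0, 0),
        H1 = r * c(cos(th / 2),  sin(th / 2), 0),
        H2 = r * c(cos(th / 2), -sin(th / 2), 0))
}
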