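# Seeded synthetic inputs: force-field-conditioned monomer densities,
# rigid-body cluster configurations, jittered ensembles and the per-frame
# descriptor sample tables they produce. Everything downstream of this file
# is testable without molecular dynamics or DFT.

# Run code under a given seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Uniform random rotation matrix (random unit quaternion).
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Ensemble generation settings
#'
#' @param n_molecules Number of water molecules per configuration.
#' @param n_frames Number of frames (independent jittered snapshots);
#'   at least 3 so the frames support normality testing.
#' @param jitter_sigma Isotropic Gaussian positional noise applied to every
#'   atomic center per frame, angstrom. Default 0.01 A, emulating the small
#'   constraint/numerical geometric variability of rigid-model trajectories.
#' @param oo_distance_range Interval (angstrom) in which nearest-neighbour
#'   O-O distances of generated clusters must lie. Default 2.6-3.2 A, the
#'   first coordination shell of liquid water.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_molecules, n_frames = 30L, jitter_sigma = 0.01,
                          oo_distance_range = c(2.6, 3.2), seed = 1L) {
  stopifnot(n_molecules >= 1, n_frames >= 3, jitter_sigma >= 0,
            length(oo_distance_range) == 2, oo_distance_range[1] > 0,
            oo_distance_range[2] >= oo_distance_range[1])
  structure(list(n_molecules = as.integer(n_molecules),
                 n_frames = as.integer(n_frames),
                 jitter_sigma = jitter_sigma,
                 oo_distance_range = as.numeric(oo_distance_range),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# default atomic-center widths (bohr); only relative model differences matter
.DEFAULT_WIDTHS <- c(O = 0.45, H = 0.65)

# Per-atom mixture weights for one molecule under a weighting mode.
.atom_weights <- function(ff, weight_mode) {
  switch(weight_mode,
    electron_count = c(8, 1, 1),
    charge_perturbed = c(8 - ff$q_O, 1 - ff$q_H, 1 - ff$q_H),
    stop("unknown weight_mode: ", weight_mode, call. = FALSE))
}

#' Surrogate monomer electron density
#'
#' Builds a unit-normalized Gaussian-mixture density with one isotropic
#' component per atom, placed at the rigid geometry of the force field.
#' `electron_count` weighting uses the atomic electron counts (8, 1, 1)/10,
#' so models sharing a geometry (SPC and SPCE) give identical densities;
#' `charge_perturbed` weighting uses the effective electron populations
#' `Z - q` (a linear shift by the site charge), a surrogate that lets
#' equal-geometry models differ through their charges. It is a device for
#' sensitivity analysis, not a claim about real electron density.
#'
#' @param ff A [force_field()].
#' @param widths Named per-element Gaussian widths in bohr
#'   (default O 0.45, H 0.65).
#' @param weight_mode `"electron_count"` or `"charge_perturbed"`.
#' @return A position-space [gaussian_mixture()] (centers in bohr).
#' @export
make_monomer_density <- function(ff, widths = .DEFAULT_WIDTHS,
                                 weight_mode = c("electron_count",
                                                 "charge_perturbed")) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(all(widths > 0), all(c("O", "H") %in% names(widths)))
  sites <- .water_sites(ff) * .BOHR_PER_ANGSTROM
  gaussian_mixture(sites,
                   sigmas = widths[c("O", "H", "H")],
                   weights = .atom_weights(ff, weight_mode))
}

#' Molecular coordinate frame
#'
#' A set of rigid water molecules: per-atom coordinates (angstrom), element
#' labels in O,H,H record order per molecule, the molecule index of each
#' atom, an optional orthorhombic periodic box, and a frame index.
#'
#' @param coords Numeric matrix (3*n_molecules rows, 3 columns), angstrom.
#' @param molecule Integer molecule index per atom row.
#' @param elements Element label per atom row (`"O"`/`"H"`).
#' @param box Optional periodic box lengths (length 3, angstrom).
#' @param time Frame index.
#' @return An object of class `water_frame`.
#' @export
water_frame <- function(coords, molecule, elements, box = NULL, time = 0L) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  stopifnot(nrow(coords) == length(molecule),
            nrow(coords) == length(elements))
  tab <- table(molecule)
  if (any(tab != 3)) stop("each molecule must have exactly 3 sites",
                          call. = FALSE)
  if (!is.null(box)) stopifnot(length(box) == 3, all(box > 0))
  structure(list(coords = coords, molecule = as.integer(molecule),
                 elements = as.character(elements), box = box,
                 time = as.integer(time)),
            class = "water_frame")
}

#' @export
print.water_frame <- function(x, ...) {
  cat(sprintf("<water_frame> %d molecule(s), %s, t = %d\n",
              length(unique(x$molecule)),
              if (is.null(x$box)) "non-periodic"
              else sprintf("box %s A", paste(signif(x$box, 4), collapse = "x")),
              x$time))
  invisible(x)
}

# Oxygen positions of a frame (one row per molecule, molecule order).
.oxygen_positions <- function(frame) {
  frame$coords[frame$elements == "O", , drop = FALSE]
}

#' Seeded rigid-body water cluster configuration
#'
#' Places `n_molecules` rigid waters by sequential attachment: each new
#' molecule is attached at a sampled O-O distance inside
#' `oo_distance_range` from a randomly chosen placed molecule, with a random
#' rigid-body orientation, and accepted only if no O-O distance falls below
#' the range minimum. Deterministic for a fixed `spec$seed`.
#'
#' @param ff A [force_field()] providing the rigid monomer geometry.
#' @param spec An [ensemble_spec()].
#' @param max_attempts Retry budget per molecule before failing (default
#'   1000).
#' @return A [water_frame()] (non-periodic).
#' @export
make_cluster_configuration <- function(ff, spec, max_attempts = 1000L) {
  stopifnot(inherits(spec, "ensemble_spec"))
  sites <- .water_sites(ff)
  .with_seed(spec$seed, {
    o_pos <- matrix(0, spec$n_molecules, 3)
    mols <- vector("list", spec$n_molecules)
    mols[[1]] <- sites  # first molecule at origin, reference orientation
    if (spec$n_molecules > 1) {
      for (i in 2:spec$n_molecules) {
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          anchor <- o_pos[sample.int(i - 1, 1), ]
          u <- stats::rnorm(3)
          u <- u / sqrt(sum(u^2))
          d <- stats::runif(1, spec$oo_distance_range[1],
                            spec$oo_distance_range[2])
          cand <- anchor + d * u
          dmin <- min(sqrt(rowSums(
            sweep(o_pos[seq_len(i - 1), , drop = FALSE], 2, cand)^2)))
          if (dmin >= spec$oo_distance_range[1]) {
            o_pos[i, ] <- cand
            rot <- .random_rotation()
            mols[[i]] <- sweep(sites %*% t(rot), 2, cand, "+")
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf(
            "cluster placement failed for molecule %d after %d attempts",
            i, max_attempts), call. = FALSE)
        }
      }
    }
    coords <- do.call(rbind, mols)
    water_frame(coords,
                molecule = rep(seq_len(spec$n_molecules), each = 3),
                elements = rep(c("O", "H", "H"), spec$n_molecules))
  })
}

# Frame (angstrom) -> position-space mixture (bohr).
.frame_density <- function(frame, ff, widths = .DEFAULT_WIDTHS,
                           weight_mode = "electron_count") {
  w1 <- .atom_weights(ff, weight_mode)
  n_mol <- length(unique(frame$molecule))
  gaussian_mixture(frame$coords * .BOHR_PER_ANGSTROM,
                   sigmas = widths[frame$elements],
                   weights = rep(w1, n_mol))
}

#' Per-frame descriptor sample table
#'
#' Generates a seeded ensemble for one force field: builds the base
#' configuration, then for each frame jitters every atomic center with
#' isotropic Gaussian noise of width `spec$jitter_sigma`, rebuilds the
#' surrogate density, and computes the full [descriptor_set()]. The result
#' is a long-format table with one row per
#' (frame, space, measure) combination.
#'
#' @param ff A [force_field()].
#' @param spec An [ensemble_spec()].
#' @param widths,weight_mode Passed to the density construction; see
#'   [make_monomer_density()].
#' @param quad A [quadrature_spec()].
#' @return A `data.frame` with columns `model`, `n_molecules`, `space`
#'   (`"r"`/`"p"`), `measure` (`S`, `I`, `D`, `C_LMC`, `C_FS`), `frame`,
#'   `value`, plus a `quad_error` column.
#' @export
make_descriptor_samples <- function(ff, spec, widths = .DEFAULT_WIDTHS,
                                    weight_mode = c("electron_count",
                                                    "charge_perturbed"),
                                    quad = quadrature_spec()) {
  weight_mode <- match.arg(weight_mode)
  base <- make_cluster_configuration(ff, spec)
  n_atoms <- nrow(base$coords)
  rows <- vector("list", spec$n_frames)
  .with_seed(spec$seed + 1L, {
    for (fr in seq_len(spec$n_frames)) {
      jitter <- matrix(stats::rnorm(n_atoms * 3, sd = spec$jitter_sigma),
                       n_atoms, 3)
      frame <- base
      frame$coords <- base$coords + jitter
      frame$time <- fr
      ds <- descriptor_set(.frame_density(frame, ff, widths, weight_mode),
                           quad)
      df <- as.data.frame(ds)
      df$frame <- fr
      df$quad_error <- ds$quad_error
      rows[[fr]] <- df
    }
  })
  out <- do.call(rbind, rows)
  out <- data.frame(model = ff$name, n_molecules = spec$n_molecules,
                    out[c("space", "measure", "frame", "value",
                          "quad_error")],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Seeded random Gaussian-mixture density
#'
#' Draws a random unit-normalized 3D mixture: component centers uniform in
#' `center_range` per axis, widths uniform in `sigma_range`, weights uniform
#' then normalized. Used for property sweeps over the complexity bounds.
#'
#' @param n_components Number of components.
#' @param seed Integer seed.
#' @param center_range,sigma_range Sampling intervals (bohr).
#' @return A position-space [gaussian_mixture()].
#' @export
random_gaussian_mixture <- function(n_components, seed,
                                    center_range = c(-1.5, 1.5),
                                    sigma_range = c(0.3, 1.2)) {
  stopifnot(n_components >= 1)
  .with_seed(seed, {
    gaussian_mixture(
      matrix(stats::runif(n_components * 3, center_range[1], center_range[2]),
             n_components, 3),
      sigmas = stats::runif(n_components, sigma_range[1], sigma_range[2]),
      weights = stats::runif(n_components, 0.1, 1))
  })
}
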