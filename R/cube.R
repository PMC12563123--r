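# Gaussian CUBE volumetric I/O (axis-aligned grids only).
#
# Header layout: two comment lines; natoms + origin; three axis records
# (count + axis vector); one record per atom; voxel values with the last
# (z) axis fastest. Positive voxel counts mean bohr units, negative mean
# angstrom, per the CUBE convention.

.parse_cube_nums <- function(line, n, lineno) {
  tok <- strsplit(trimws(line), "\\s+")[[1]]
  vals <- suppressWarnings(as.numeric(tok))
  if (length(vals) < n || any(is.na(vals[seq_len(n)]))) {
    stop(sprintf("malformed CUBE header at line %d: %s", lineno, line),
         call. = FALSE)
  }
  vals
}

#' Read a Gaussian CUBE file
#'
#' Parses an axis-aligned CUBE volumetric density into a [grid_density()].
#' Negative voxel values are clamped to zero (their count is reported via a
#' message) and the grid is renormalized to unit mass. Angstrom-unit files
#' (negative voxel counts) are converted to bohr.
#'
#' @param path CUBE file path.
#' @return A [grid_density()] with an `atoms` attribute (data.frame of
#'   atomic number, charge, x, y, z in bohr) when atoms are present.
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7) stop("malformed CUBE file: fewer than 7 lines",
                              call. = FALSE)
  hdr <- .parse_cube_nums(lines[3], 4, 3)
  natoms <- as.integer(hdr[1])
  origin <- hdr[2:4]
  # negative natoms flags an orbital-id record after the atoms; the density
  # grid itself is unaffected beyond skipping that record
  has_dset <- natoms < 0
  natoms <- abs(natoms)
  counts <- integer(3)
  spacing <- numeric(3)
  scale <- rep(1, 3)
  for (k in 1:3) {
    ax <- .parse_cube_nums(lines[3 + k], 4, 3 + k)
    counts[k] <- abs(as.integer(ax[1]))
    if (ax[1] < 0) scale[k] <- .BOHR_PER_ANGSTROM  # angstrom-unit axis
    vec <- ax[2:4] * scale[k]
    if (sum(vec != 0) != 1 || vec[k] <= 0) {
      stop(sprintf("CUBE axis %d is not a positive axis-aligned vector", k),
           call. = FALSE)
    }
    spacing[k] <- vec[k]
  }
  if (any(scale > 1)) origin <- origin * .BOHR_PER_ANGSTROM
  atom_lines <- lines[6 + seq_len(natoms)]
  atoms <- NULL
  if (natoms > 0) {
    am <- t(vapply(seq_len(natoms),
                   function(i) .parse_cube_nums(atom_lines[i], 5, 6 + i),
                   numeric(5)))
    atoms <- data.frame(z = as.integer(am[, 1]), charge = am[, 2],
                        x = am[, 3], y = am[, 4], z_pos = am[, 5])
  }
  first_val <- 7L + natoms + if (has_dset) 1L else 0L
  vals <- scan(text = paste(lines[first_val:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != prod(counts)) {
    stop(sprintf("CUBE voxel count mismatch: expected %d values, got %d",
                 prod(counts), length(vals)), call. = FALSE)
  }
  n_neg <- sum(vals < 0)
  if (n_neg > 0) {
    message(sprintf("read_cube: clamped %d negative voxel(s) to zero", n_neg))
    vals[vals < 0] <- 0
  }
  # CUBE stores z fastest: value index = ((ix*ny)+iy)*nz + iz
  arr <- aperm(array(vals, dim = rev(counts)), 3:1)
  g <- grid_density(origin, spacing, arr, normalize = TRUE)
  if (!is.null(atoms)) attr(g, "atoms") <- atoms
  g
}

#' Write a grid density as a Gaussian CUBE file
#'
#' @param grid A [grid_density()].
#' @param path Output path.
#' @param atoms Optional data.frame with columns `z`, `charge`, `x`, `y`,
#'   `z_pos` (bohr); defaults to no atoms.
#' @param comment Comment placed on the first header line.
#' @export
write_cube <- function(grid, path, atoms = NULL,
                       comment = "hydroinfo grid density") {
  stopifnot(inherits(grid, "grid_density"))
  con <- file(path, "w")
  on.exit(close(con))
  natoms <- if (is.null(atoms)) 0L else nrow(atoms)
  writeLines(c(comment, "volumetric density, bohr units"), con)
  writeLines(sprintf("%5d %12.6f %12.6f %12.6f", natoms,
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  axes <- diag(grid$spacing)
  for (k in 1:3) {
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f", grid$shape[k],
                       axes[k, 1], axes[k, 2], axes[k, 3]), con)
  }
  if (natoms > 0) {
    writeLines(sprintf("%5d %12.6f %12.6f %12.6f %12.6f", atoms$z,
                       atoms$charge, atoms$x, atoms$y, atoms$z_pos), con)
  }
  # z fastest
  vals <- as.vector(aperm(grid$values, 3:1))
  chunks <- split(vals, ceiling(seq_along(vals) / 6))
  writeLines(vapply(chunks,
                    function(v) paste(sprintf("%13.5e", v), collapse = " "),
                    character(1)), con)
  invisible(path)
}
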