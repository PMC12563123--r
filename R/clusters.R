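# Sevick cluster identification: transitive linkage of water molecules whose
# oxygen-oxygen distance falls below a cutoff, plus harvesting of cluster
# size classes across frames and multi-frame XYZ I/O.

# Pairwise O-O distance matrix, minimum-image on orthorhombic boxes.
.oo_distances <- function(frame) {
  o <- .oxygen_positions(frame)
  n <- nrow(o)
  d <- matrix(0, n, n)
  for (k in 1:3) {
    dk <- outer(o[, k], o[, k], "-")
    if (!is.null(frame$box)) {
      L <- frame$box[k]
      dk <- dk - L * round(dk / L)
    }
    d <- d + dk^2
  }
  sqrt(d)
}

#' Sevick cluster identification
#'
#' Partitions the molecules of a frame into clusters: two molecules are
#' directly linked iff their O-O distance is at most `r_cut` (minimum-image
#' convention when the frame carries an orthorhombic box), and clusters are
#' the connected components of the linkage graph, so membership is
#' transitive.
#'
#' @param frame A [water_frame()].
#' @param r_cut O-O linkage cutoff in angstrom. The default 3.5 A is the
#'   conventional first minimum of the O-O radial distribution function of
#'   liquid water.
#' @return An object of class `cluster_set`: list with `cluster` (integer
#'   cluster id per molecule) and `sizes` (multiset of cluster sizes).
#' @examples
#' ff <- water_models("SPC")$SPC
#' fr <- make_cluster_configuration(ff, ensemble_spec(4, seed = 7))
#' sevick_clusters(fr, r_cut = 3.5)
#' @export
sevick_clusters <- function(frame, r_cut = 3.5) {
  stopifnot(inherits(frame, "water_frame"), r_cut > 0)
  d <- .oo_distances(frame)
  adj <- (d <= r_cut)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  structure(list(cluster = as.integer(comp$membership),
                 sizes = as.integer(comp$csize)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d molecule(s) in %d cluster(s); sizes: %s\n",
              length(x$cluster), length(x$sizes),
              paste(sort(x$sizes, decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Harvest clusters of wanted sizes across frames
#'
#' Runs [sevick_clusters()] on every `stride`-th frame and collects, for
#' each wanted cluster size, every (frame, cluster) occurrence.
#'
#' @param frames List of [water_frame()] objects.
#' @param r_cut O-O linkage cutoff, angstrom.
#' @param wanted_sizes Non-empty set of cluster sizes to collect.
#' @param stride Analyse every `stride`-th frame (default 1 = all).
#' @return A list with `occurrences` (named list, one `data.frame(frame,
#'   cluster_id)` per wanted size; zero-row when a size never occurs) and
#'   `counts` (named integer vector).
#' @export
harvest_by_size <- function(frames, r_cut = 3.5, wanted_sizes,
                            stride = 1L) {
  stopifnot(length(wanted_sizes) >= 1, stride >= 1)
  wanted_sizes <- sort(unique(as.integer(wanted_sizes)))
  empty <- data.frame(frame = integer(), cluster_id = integer())
  occ <- stats::setNames(rep(list(empty), length(wanted_sizes)),
                         as.character(wanted_sizes))
  idx <- seq(1L, length.out = length(frames))
  idx <- idx[(idx - 1L) %% stride == 0L]
  for (i in idx) {
    cs <- sevick_clusters(frames[[i]], r_cut)
    for (s in wanted_sizes) {
      hits <- which(cs$sizes == s)
      if (length(hits)) {
        key <- as.character(s)
        occ[[key]] <- rbind(occ[[key]],
                            data.frame(frame = i, cluster_id = hits))
      }
    }
  }
  list(occurrences = occ,
       counts = vapply(occ, nrow, integer(1)))
}

#' Write frames as multi-frame XYZ
#'
#' Standard XYZ records: atom count, comment line, then `element x y z` per
#' atom, one block per frame, molecules in O,H,H record order.
#'
#' @param frames A [water_frame()] or list of them.
#' @param path Output file path.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "water_frame")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(as.character(nrow(fr$coords)), con)
    writeLines(sprintf("frame %d", fr$time), con)
    writeLines(sprintf("%s %.10f %.10f %.10f", fr$elements,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read multi-frame XYZ as water frames
#'
#' Atoms are grouped into molecules by O,H,H record order; each frame must
#' therefore contain a multiple of three atoms in that order.
#'
#' @param path Input XYZ file.
#' @return A list of [water_frame()] objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  t_ <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i,
                         call. = FALSE)
    if (nat %% 3 != 0) stop("XYZ frame at line ", i,
                            " does not hold whole O,H,H molecules",
                            call. = FALSE)
    block <- lines[(i + 2L):(i + 1L + nat)]
    tok <- strsplit(trimws(block), "\\s+")
    el <- vapply(tok, `[`, character(1), 1)
    xyz <- t(vapply(tok, function(tt) as.numeric(tt[2:4]), numeric(3)))
    expected <- rep(c("O", "H", "H"), nat / 3)
    if (!all(el == expected)) {
      stop("XYZ frame at line ", i, " is not in O,H,H molecule order",
           call. = FALSE)
    }
    t_ <- t_ + 1L
    frames[[t_]] <- water_frame(xyz, molecule = rep(seq_len(nat / 3),
                                                    each = 3),
                                elements = el, time = t_)
    i <- i + 2L + nat
  }
  frames
}

#' Write cluster assignments as CSV
#'
#' One row per (frame, molecule) with its cluster id.
#'
#' @param frames List of [water_frame()] objects.
#' @param r_cut O-O linkage cutoff, angstrom.
#' @param path Output CSV path.
#' @return The assignment `data.frame`, invisibly.
#' @export
write_cluster_assignments <- function(frames, r_cut = 3.5, path) {
  rows <- lapply(seq_along(frames), function(i) {
    cs <- sevick_clusters(frames[[i]], r_cut)
    data.frame(frame = i, molecule = seq_along(cs$cluster),
               cluster_id = cs$cluster)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
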