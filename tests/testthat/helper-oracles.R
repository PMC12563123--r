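# Independent oracles used across the suite.

# Closed forms for an isotropic 3D Gaussian of width sigma.
gauss_S <- function(sigma) 1.5 * log(2 * pi * exp(1)) + 3 * log(sigma)
gauss_I <- function(sigma) 3 / sigma^2
gauss_D <- function(sigma) (4 * pi * sigma^2)^(-1.5)

# Brute-force O(n^2) connected components by breadth-first search over the
# O-O linkage graph (minimum image on orthorhombic boxes).
brute_force_clusters <- function(frame, r_cut) {
  o <- frame$coords[frame$elements == "O", , drop = FALSE]
  n <- nrow(o)
  linked <- function(i, j) {
    d <- o[i, ] - o[j, ]
    if (!is.null(frame$box)) d <- d - frame$box * round(d / frame$box)
    sqrt(sum(d^2)) <= r_cut
  }
  id <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (id[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    id[s] <- cur
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      for (j in seq_len(n)) {
        if (id[j] == 0L && linked(i, j)) {
          id[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  list(cluster = id, sizes = as.integer(table(id)))
}

# A frame of n random rigid waters scattered in a cube of the given edge.
random_water_frame <- function(n, edge = 10, seed = 1, box = NULL) {
  ff <- water_models("SPC")$SPC
  set.seed(seed)
  sites <- hydroinfo:::.water_sites(ff)
  mols <- lapply(seq_len(n), function(i) {
    sweep(sites, 2, runif(3, 0, edge), "+")
  })
  water_frame(do.call(rbind, mols), molecule = rep(seq_len(n), each = 3),
              elements = rep(c("O", "H", "H"), n), box = box)
}

# Slow pure-R Riemann quadrature of a functional of a mixture, used as an
# independent check on the compiled quadrature path.
riemann_integral <- function(density, fn, n = 81, pad = 7) {
  lo <- apply(density$centers - pad * density$sigmas, 2, min)
  hi <- apply(density$centers + pad * density$sigmas, 2, max)
  axes <- lapply(1:3, function(k) seq(lo[k], hi[k], length.out = n))
  h <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]]))
  rho <- evaluate_density(density, pts)
  if (identical(fn, "fisher")) {
    g <- gradient_density(density, pts)
    keep <- rho > 1e-300
    sum(rowSums(g[keep, ]^2) / rho[keep]) * prod(h)
  } else {
    sum(fn(rho)) * prod(h)
  }
}
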