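test_that("mixture evaluation matches analytic values", {
  g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
  expect_equal(evaluate_density(g, rbind(c(0, 0, 0))), (2 * pi)^(-1.5))
  expect_lt(evaluate_density(g, rbind(c(50, 0, 0))), 1e-100)
  # two-component mixture at the midpoint is the hand sum of components
  m <- gaussian_mixture(rbind(c(-1, 0, 0), c(1, 0, 0)),
                        sigmas = c(0.8, 1.2), weights = c(0.3, 0.7))
  hand <- 0.3 * (2 * pi * 0.8^2)^(-1.5) * exp(-1 / (2 * 0.8^2)) +
          0.7 * (2 * pi * 1.2^2)^(-1.5) * exp(-1 / (2 * 1.2^2))
  expect_equal(evaluate_density(m, rbind(c(0, 0, 0))), hand)
})

test_that("weights are normalized and validated", {
  g <- gaussian_mixture(rbind(c(0, 0, 0), c(1, 1, 1)), sigmas = 1,
                        weights = c(2, 6))
  expect_equal(g$weights, c(0.25, 0.75))
  expect_error(gaussian_mixture(rbind(c(0, 0, 0)), sigmas = -1, weights = 1))
  expect_error(gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 0),
               "positive total mass")
})

test_that("mixture gradient is the analytic gradient", {
  g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
  expect_equal(gradient_density(g, rbind(c(0, 0, 0))), matrix(0, 1, 3))
  # at (1,0,0): direction -x, magnitude rho(1,0,0)/sigma^2
  gr <- gradient_density(g, rbind(c(1, 0, 0)))
  rho <- evaluate_density(g, rbind(c(1, 0, 0)))
  expect_equal(gr[1, ], c(-rho, 0, 0))
  # finite-difference cross-check on a 3-component mixture
  m <- random_gaussian_mixture(3, seed = 11)
  p <- c(0.3, -0.2, 0.5)
  h <- 1e-6
  fd <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- h
    (evaluate_density(m, rbind(p + e)) -
     evaluate_density(m, rbind(p - e))) / (2 * h)
  }, numeric(1))
  expect_equal(gradient_density(m, rbind(p))[1, ], fd, tolerance = 1e-6)
})

test_that("momentum conjugation maps widths, keeps weights, centres at 0", {
  g <- gaussian_mixture(rbind(c(1, 2, 3)), sigmas = 0.5, weights = 1)
  p <- momentum_conjugate(g)
  expect_equal(p$sigmas, 1.0)
  expect_equal(p$space, "momentum")
  expect_equal(unname(p$centers), matrix(0, 1, 3))
  # distinct widths keep their weights component-wise
  m <- gaussian_mixture(rbind(c(0, 0, 0), c(2, 0, 0)),
                        sigmas = c(0.5, 1), weights = c(0.25, 0.75))
  mp <- momentum_conjugate(m)
  expect_equal(sort(mp$sigmas), c(0.5, 1.0))
  # sigma_r 0.5 (weight 0.25) -> sigma_p 1; sigma_r 1 (0.75) -> sigma_p 0.5
  expect_equal(mp$weights[order(mp$sigmas)], c(0.75, 0.25))
  expect_equal(sum(mp$weights), 1)
  # conjugate of a conjugate is refused (contract: position space only)
  expect_error(momentum_conjugate(mp), "position-space")
})

test_that("momentum conjugate preserves normalization", {
  m <- random_gaussian_mixture(5, seed = 3)
  p <- momentum_conjugate(m)
  expect_equal(integrate_density(p, "mass")$value, 1, tolerance = 1e-6)
})

test_that("grid densities interpolate and match the analytic mixture", {
  g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
  xs <- seq(-6, 6, length.out = 61)
  vals <- array(evaluate_density(
    g, as.matrix(expand.grid(xs, xs, xs))), dim = c(61, 61, 61))
  gd <- grid_density(rep(-6, 3), rep(xs[2] - xs[1], 3), vals)
  on_node <- evaluate_density(gd, rbind(c(0, 0, 0)))
  expect_equal(on_node, (2 * pi)^(-1.5), tolerance = 1e-3)
  # outside-support handling is configurable
  expect_equal(evaluate_density(gd, rbind(c(100, 0, 0))), 0)
  expect_error(evaluate_density(gd, rbind(c(100, 0, 0)),
                                outside = "error"), "outside")
  # central-difference gradient tracks the analytic one (FD + interpolation
  # error on a 0.2-bohr grid stays below 5e-3 in absolute terms)
  pts <- rbind(c(0.5, -0.3, 0.2), c(1, 1, 1))
  expect_lt(max(abs(gradient_density(gd, pts) - gradient_density(g, pts))),
            5e-3)
})

test_that("negative grid values are rejected at construction", {
  expect_error(grid_density(rep(0, 3), rep(1, 3),
                            array(c(-1, rep(1, 7)), c(2, 2, 2))),
               "non-negative")
})
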