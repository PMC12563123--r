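test_that("descriptors of an isotropic Gaussian match their closed forms", {
  g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
  expect_equal(shannon_entropy(g), gauss_S(1), tolerance = 1e-6)
  expect_equal(fisher_information(g), gauss_I(1), tolerance = 1e-6)
  expect_equal(disequilibrium(g), gauss_D(1), tolerance = 1e-6)
  g2 <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 2, weights = 1)
  expect_equal(shannon_entropy(g2), gauss_S(1) + 3 * log(2),
               tolerance = 1e-6)
  expect_equal(disequilibrium(g2), gauss_D(1) / 8, tolerance = 1e-6)
  ghalf <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 0.5, weights = 1)
  expect_equal(fisher_information(ghalf), 12, tolerance = 1e-6)
})

test_that("complexities from Gaussian inputs hit the analytic values", {
  expect_equal(lmc_complexity(gauss_D(1), gauss_S(1)), (exp(1) / 2)^1.5)
  expect_equal(fs_complexity(gauss_I(1), gauss_S(1)), 3)
  expect_error(lmc_complexity(-1, 0))
  expect_error(fs_complexity(0, 0))
})

test_that("well-separated equal mixture gains ln 2 of entropy", {
  m <- gaussian_mixture(rbind(c(0, 0, 0), c(10, 0, 0)), sigmas = 1,
                        weights = c(0.5, 0.5))
  expect_equal(shannon_entropy(m), gauss_S(1) + log(2), tolerance = 1e-4)
})

test_that("mixture descriptors agree with an independent Riemann oracle", {
  m <- random_gaussian_mixture(3, seed = 14, sigma_range = c(0.5, 1.2))
  expect_equal(disequilibrium(m),
               riemann_integral(m, function(r) r^2), tolerance = 1e-4)
  expect_equal(shannon_entropy(m),
               riemann_integral(m, function(r) {
                 out <- numeric(length(r))
                 pos <- r > 1e-300
                 out[pos] <- -r[pos] * log(r[pos])
                 out
               }), tolerance = 1e-4)
  expect_equal(fisher_information(m), riemann_integral(m, "fisher"),
               tolerance = 1e-3)
})

test_that("descriptor sets are translation invariant and scale covariant", {
  m <- random_gaussian_mixture(4, seed = 8)
  shifted <- gaussian_mixture(sweep(m$centers, 2, c(3, -2, 5), "+"),
                              m$sigmas, m$weights)
  d0 <- descriptor_set(m)
  d1 <- descriptor_set(shifted)
  for (f in c("S_r", "I_r", "D_r", "C_LMC_r", "C_FS_r")) {
    expect_equal(d1[[f]], d0[[f]], tolerance = 1e-5)
  }
  lambda <- 1.7
  scaled <- gaussian_mixture(m$centers * lambda, m$sigmas * lambda,
                             m$weights)
  d2 <- descriptor_set(scaled)
  expect_equal(d2$S_r, d0$S_r + 3 * log(lambda), tolerance = 1e-5)
  expect_equal(d2$I_r, d0$I_r / lambda^2, tolerance = 1e-5)
  expect_equal(d2$D_r, d0$D_r / lambda^3, tolerance = 1e-5)
  expect_equal(d2$C_LMC_r, d0$C_LMC_r, tolerance = 1e-5)
  expect_equal(d2$C_FS_r, d0$C_FS_r, tolerance = 1e-5)
})

test_that("full descriptor set combines both legs coherently", {
  g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
  ds <- descriptor_set(g)
  expect_equal(ds$S_r, gauss_S(1), tolerance = 1e-4)
  expect_equal(ds$I_r, 3, tolerance = 1e-4)
  expect_equal(ds$D_r, gauss_D(1), tolerance = 1e-4)
  expect_equal(ds$C_LMC_r, (exp(1) / 2)^1.5, tolerance = 1e-4)
  expect_equal(ds$C_FS_r, 3, tolerance = 1e-4)
  expect_equal(ds$S_r + ds$S_p, 3 * (1 + log(pi)), tolerance = 1e-4)
  # momentum leg of sigma = 1 is a Gaussian of width 1/2
  expect_equal(ds$I_p, gauss_I(0.5), tolerance = 1e-4)
  expect_true(is.finite(ds$quad_error) && ds$quad_error >= 0)
})

test_that("momentum descriptors are absent, not zero, for grid input", {
  g <- gaussian_mixture(rbind(c(0, 0, 0)), sigmas = 1, weights = 1)
  xs <- seq(-6, 6, length.out = 81)
  vals <- array(evaluate_density(
    g, as.matrix(expand.grid(xs, xs, xs))), dim = rep(81, 3))
  gd <- grid_density(rep(-6, 3), rep(xs[2] - xs[1], 3), vals)
  ds <- descriptor_set(gd)
  expect_equal(ds$S_r, gauss_S(1), tolerance = 1e-2)
  expect_true(is.na(ds$S_p) && is.na(ds$C_FS_p))
})

test_that("monomer densities order force fields by geometry", {
  ff <- water_models()
  d_spc <- descriptor_set(make_monomer_density(ff$SPC))
  d_spce <- descriptor_set(make_monomer_density(ff$SPCE))
  d_tip3p <- descriptor_set(make_monomer_density(ff$TIP3P))
  # identical geometry + electron-count weights -> identical sets
  expect_equal(unclass(d_spc), unclass(d_spce))
  # TIP3P geometry differs, so position-space descriptors differ
  expect_gt(abs(d_tip3p$S_r - d_spc$S_r), 1e-3)
})
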