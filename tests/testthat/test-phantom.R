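test_that("identical spec and seed give bit-identical volumes, different seeds differ", {
  sp <- phantom_spec(grid_shape = c(64, 64, 64), n_closed_pores = 2,
                     pore_radius_range = c(6, 8), noise_sigma = 5, seed = 11)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$truth$labels$values, b$truth$labels$values)
  sp2 <- sp; sp2$seed <- 12L
  expect_false(identical(generate_phantom(sp2)$volume$values, a$volume$values))
})

test_that("featureless noiseless spec yields a uniform scaffold-level volume", {
  sp <- phantom_spec(grid_shape = c(32, 32, 32), n_closed_pores = 0,
                     noise_sigma = 0, drift_amplitude = 0, blur_sigma = 0,
                     include_main_pore_space = FALSE)
  ph <- generate_phantom(sp)
  expect_true(all(ph$volume$values == sp$gray_scaffold))
  expect_equal(ph$truth$labels$n_labels, 0L)
})

test_that("without blur, noise or drift the histogram holds exactly the configured levels", {
  sp <- phantom_spec(grid_shape = c(72, 72, 72), n_closed_pores = 3,
                     pore_radius_range = c(6, 8), blur_sigma = 0,
                     noise_sigma = 0, drift_amplitude = 0, gray_bone = 60,
                     seed = 4)
  ph <- generate_phantom(sp)
  expect_setequal(unique(as.vector(ph$volume$values)), c(60, 100, 200))
})

test_that("closed pores keep at least twice the blur support radius between surfaces", {
  ph <- small_phantom(seed = 7, n_closed_pores = 8, grid_shape = c(150, 150, 150))
  p <- ph$truth$pores
  sup <- ph$truth$blur_support_radius
  if (nrow(p) > 1) {
    dd <- as.matrix(dist(p[, c("x", "y", "z")]))
    surf_sep <- outer(p$radius, p$radius, `+`)
    gaps <- (dd - surf_sep)[upper.tri(dd)]
    expect_true(all(gaps >= 2 * sup))
  }
  # and none touch the boundary or the main channel
  expect_equal(ph$truth$labels$n_labels, 8L)
  lab <- ph$truth$labels$values
  d <- dim(lab)
  expect_true(all(lab[c(1, d[1]), , ] == 0))
  expect_true(all(lab[, c(1, d[2]), ] == 0))
  expect_true(all(lab[, , c(1, d[3])] == 0))
})

test_that("pore-centre gray values match an independent direct convolution and the continuum ball-Gaussian oracle", {
  sp <- phantom_spec(grid_shape = c(160, 160, 160), n_closed_pores = 20,
                     pore_radius_range = c(6, 10), blur_sigma = 2,
                     noise_sigma = 0, drift_amplitude = 0, seed = 5)
  ph <- generate_phantom(sp)
  p <- ph$truth$pores
  expect_equal(nrow(p), 20)
  # unblurred three-level field rebuilt from ground truth for the direct sum
  raw <- array(sp$gray_scaffold, sp$grid_shape)
  raw[ph$truth$pore_space_mask$values] <- sp$gray_pore
  for (i in seq_len(nrow(p))) {
    at <- c(p$x[i], p$y[i], p$z[i])
    got <- ph$volume$values[at[1], at[2], at[3]]
    # exact agreement with a brute-force (non-separable) discrete convolution
    expect_equal(got, direct_conv_value(raw, sp$blur_sigma, at), tolerance = 1e-9)
    # continuum oracle: voxelization limits the agreement
    cont <- sp$gray_scaffold + (sp$gray_pore - sp$gray_scaffold) *
      ball_gauss_value(0, p$radius[i], sp$blur_sigma)
    expect_lt(abs(got - cont) / (sp$gray_pore - sp$gray_scaffold), 2e-2)
  }
})

test_that("drift amplitude is the stated fraction of the scaffold gray level", {
  sp <- phantom_spec(grid_shape = c(80, 80, 80), n_closed_pores = 0,
                     include_main_pore_space = FALSE, noise_sigma = 0,
                     drift_amplitude = 0.2, seed = 9)
  ph <- generate_phantom(sp)
  bg <- ph$truth$drift_field * sp$gray_scaffold  # noiseless scaffold background
  expect_equal(diff(range(bg)) / sp$gray_scaffold, 0.2, tolerance = 0.01)
})

test_that("drift does not perturb the RNG stream shared with placement and noise", {
  a <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                     n_closed_pores = 2, seed = 3,
                                     pore_radius_range = c(6, 8),
                                     drift_amplitude = 0))
  b <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64),
                                     n_closed_pores = 2, seed = 3,
                                     pore_radius_range = c(6, 8),
                                     drift_amplitude = 0.2))
  expect_identical(a$truth$pores, b$truth$pores)
})

test_that("impossible placements and invalid specs error", {
  expect_error(generate_phantom(
    phantom_spec(grid_shape = c(40, 40, 40), n_closed_pores = 50,
                 pore_radius_range = c(8, 10)), max_tries = 50),
    "placement failed")
  expect_error(phantom_spec(gray_pore = 90, gray_scaffold = 100), "exceed")
  expect_error(phantom_spec(grid_shape = c(0, 10, 10)), "positive")
  expect_error(phantom_spec(pore_radius_range = c(1, 5)), ">= 2")
  expect_error(phantom_spec(drift_amplitude = 1), "drift_amplitude")
})

test_that("analytic planar edge profile matches the erf oracle and its limits", {
  expect_equal(analytic_edge_profile(2, 0), 0.5)
  expect_equal(analytic_edge_profile(2, 1e6), 1.0)
  expect_equal(analytic_edge_profile(2, 2),
               0.5 * (1 + erf_quad(1 / sqrt(2))), tolerance = 1e-9)
  expect_equal(analytic_edge_profile(0, c(-3, 0, 4)), c(0, 0.5, 1))
  # approaches the continuum sphere profile in the planar limit: the
  # curvature shift is ~sigma^2/R, i.e. ~0.016 voxel at R = 250
  d <- seq(-4, 4, by = 1)
  planar <- analytic_edge_profile(2, d)
  sphere <- ball_gauss_value(250 - d, 250, 2)
  expect_lt(max(abs(planar - sphere)), 5e-3)
})
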