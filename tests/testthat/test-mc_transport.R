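geo <- detection_geometry()

test_that("type constructors enforce their invariants", {
  expect_error(optical_properties(anisotropy_g = 1), "anisotropy_g")
  expect_error(optical_properties(mu_s_reduced = -1))
  expect_error(optical_properties(thickness = 0))
  expect_error(detection_geometry(forward_na = 1.4), "immersion_index")
  expect_error(detection_geometry(calibration_factor = 0))
  expect_error(mc_config(photons_per_condition = 10))
  expect_error(mc_config(ratio_grid = c(2, 1)))
  # printed inversion grid: 1 to 20 in 0.3 steps is 64 values, 1.0 .. 19.9
  cfg <- mc_config()
  expect_length(cfg$ratio_grid, 64)
  expect_equal(cfg$ratio_grid[1], 1.0)
  expect_equal(cfg$ratio_grid[64], 19.9)
})

test_that("ballistic limit: measured F/B equals the creation ratio", {
  opt0 <- test_optics(mus = 0)
  cfg <- mc_config(photons_per_condition = 2e4, rng_seed = 7)
  for (r in c(1, 5, 19.9)) {
    for (d in c(0, 75)) {
      s <- simulate_emission(d, r, opt0, geo, cfg)
      expect_lt(abs(s$measured_fb - r), 3 * s$se)
      # nothing escapes or is absorbed without scattering
      expect_equal(s$escaped, 0)
      expect_equal(s$absorbed, 0)
    }
  }
  # symmetric launch at the surface
  s1 <- simulate_emission(0, 1, opt0, geo, cfg)
  expect_lt(abs(s1$measured_fb - 1), 3 * s1$se)
})

test_that("photon weight is conserved exactly, including with absorption", {
  opt <- optical_properties(mu_s_reduced = 1.5, anisotropy_g = 0.85,
                            refractive_index = 1.4, mu_a = 0.3,
                            thickness = 120)
  cfg <- mc_config(photons_per_condition = 5e3, rng_seed = 3)
  s <- simulate_emission(40, 4, opt, geo, cfg)
  total <- s$collected_forward + s$collected_backward + s$escaped + s$absorbed
  expect_lt(abs(total - 1), 1e-9)
  expect_gt(s$absorbed, 0)
})

test_that("simulation is reproducible for a fixed seed and rejects bad input", {
  opt <- test_optics()
  cfg <- mc_config(photons_per_condition = 2e3, rng_seed = 99)
  a <- simulate_emission(30, 6, opt, geo, cfg)
  b <- simulate_emission(30, 6, opt, geo, cfg)
  expect_identical(a, b)
  expect_error(simulate_emission(-1, 5, opt, geo, cfg), "depth")
  expect_error(simulate_emission(500, 5, opt, geo, cfg), "depth")
  expect_error(simulate_emission(30, 0.5, opt, geo, cfg), "creation_ratio")
})

test_that("production core matches the naive per-photon reference loop", {
  # independent oracle: plain R loop with its own scattering-frame algebra
  # and R's RNG; agreement within 3 combined MC standard errors
  cfg <- mc_config(photons_per_condition = 2e4, rng_seed = 5)
  conditions <- list(
    list(mus = 0.5, g = 0.9, d = 30, r = 3),
    list(mus = 1.0, g = 0.9, d = 50, r = 5),
    list(mus = 2.0, g = 0.8, d = 20, r = 10),
    list(mus = 1.0, g = 0.0, d = 75, r = 2),
    list(mus = 3.0, g = 0.95, d = 100, r = 7))
  set.seed(1234)
  for (cn in conditions) {
    opt <- optical_properties(mu_s_reduced = cn$mus, anisotropy_g = cn$g,
                              refractive_index = 1.4, thickness = 150)
    prod <- simulate_emission(cn$d, cn$r, opt, geo, cfg)
    ref <- simulate_emission_reference(cn$d, cn$r, opt, geo, cfg,
                                       n_photons = 3000)
    tol <- 3 * sqrt(prod$se^2 + ref$se^2)
    expect_lt(abs(prod$measured_fb - ref$measured_fb), tol)
  }
})

test_that("lookup table build enforces monotonicity and is reproducible", {
  opt <- test_optics()
  cfg <- mc_config(photons_per_condition = 2e3, rng_seed = 17,
                   ratio_grid = seq(1, 19, by = 2),
                   depth_grid = c(0, 25, 50))
  lut <- build_lookup_table(opt, geo, cfg)
  expect_equal(dim(lut$measured_fb), c(10, 3))
  expect_true(all(lut$measured_fb > 0))
  # monotone within the enforced gate by construction
  for (j in 1:3) {
    d <- diff(lut$measured_fb[, j])
    tol <- 3 * sqrt(lut$standard_errors[-1, j]^2 +
                    lut$standard_errors[-10, j]^2)
    expect_true(all(d >= -tol))
  }
  # identical config and seed give identical tables
  lut2 <- build_lookup_table(opt, geo, cfg)
  expect_identical(lut$measured_fb, lut2$measured_fb)
  # a different seed gives a different (but close) table
  cfg3 <- cfg; cfg3$rng_seed <- 18L
  lut3 <- build_lookup_table(opt, geo, cfg3)
  expect_false(identical(lut$measured_fb, lut3$measured_fb))
})

test_that("ballistic table is the identity in the creation ratio", {
  opt0 <- test_optics(mus = 0)
  cfg <- mc_config(photons_per_condition = 5e3, rng_seed = 21,
                   ratio_grid = c(1, 4, 10, 19.9), depth_grid = c(0, 60))
  lut <- build_lookup_table(opt0, geo, cfg)
  for (j in 1:2)
    expect_true(all(abs(lut$measured_fb[, j] - cfg$ratio_grid) <
                    3 * lut$standard_errors[, j]))
})

test_that("inversion returns table nodes, clamps, and round-trips off-grid", {
  lut <- analytic_lut(depths = 0:5, slope = c(1, 1, 0.9, 0.9, 0.8, 0.8))
  # exact node identity at a clean (strictly monotone) table
  for (k in c(1, 20, 64)) {
    inv <- invert_measured_fb(lut$measured_fb[k, 3], lut$depth_axis[3], lut)
    expect_equal(inv$creation_ratio, lut$ratio_axis[k], tolerance = 1e-9)
    expect_equal(inv$flag, "ok")
  }
  # boundary clamping with flags
  low <- invert_measured_fb(0.1, 0, lut)
  expect_equal(low$creation_ratio, 1.0)
  expect_equal(low$flag, "clamped_low")
  high <- invert_measured_fb(100, 0, lut)
  expect_equal(high$creation_ratio, 19.9)
  expect_equal(high$flag, "clamped_high")
  # off-grid value at a sloped depth row: measured 7.45*0.9 inverts to 7.45
  inv2 <- invert_measured_fb(7.45 * 0.9, 2, lut)
  expect_equal(inv2$creation_ratio, 7.45, tolerance = 1e-9)
  # errors
  expect_error(invert_measured_fb(NaN, 0, lut), "finite")
  expect_error(invert_measured_fb(-2, 0, lut), "nonnegative")
  expect_error(invert_measured_fb(5, 300, lut), "depth")
})

test_that("Monte Carlo round trip recovers an off-grid ratio within the grid", {
  # forward-simulate at creation ratio 7.45 and invert through an
  # independently built table at the spec's default photon budget
  opt <- test_optics()
  cfg <- mc_config(photons_per_condition = 1e5, rng_seed = 31,
                   depth_grid = c(0, 10, 20, 30))
  lut <- build_lookup_table(opt, geo, cfg)
  cfg2 <- mc_config(photons_per_condition = 1e5, rng_seed = 77)
  s <- simulate_emission(20, 7.45, opt, geo, cfg2)
  inv <- invert_measured_fb(s$measured_fb, 20, lut)
  expect_lt(abs(inv$creation_ratio - 7.45), 0.3)
  expect_equal(inv$flag, "ok")
})

test_that("lookup tables round-trip losslessly through JSON and export CSV", {
  opt <- test_optics()
  cfg <- mc_config(photons_per_condition = 2e3, rng_seed = 41,
                   ratio_grid = c(1, 5, 10), depth_grid = c(0, 40))
  lut <- build_lookup_table(opt, geo, cfg)
  path <- tempfile(fileext = ".json")
  save_lut(lut, path)
  back <- read_lut(path)
  expect_equal(back$ratio_axis, lut$ratio_axis, tolerance = 0)
  expect_equal(back$measured_fb, lut$measured_fb, tolerance = 0)
  expect_equal(back$standard_errors, lut$standard_errors, tolerance = 0)
  expect_identical(back$optics_fingerprint, lut$optics_fingerprint)
  df <- as.data.frame(lut)
  expect_equal(nrow(df), 6)
  expect_equal(df$fb, as.vector(lut$measured_fb))
  unlink(path)
})

test_that("fingerprint changes with any simulation condition", {
  opt <- test_optics(); cfg <- mc_config()
  f0 <- shgdir:::optics_fingerprint(opt, geo, cfg)
  expect_identical(f0, shgdir:::optics_fingerprint(opt, geo, cfg))
  opt2 <- test_optics(mus = 2.5)
  expect_false(identical(f0, shgdir:::optics_fingerprint(opt2, geo, cfg)))
})
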