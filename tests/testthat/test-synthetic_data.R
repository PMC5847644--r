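test_that("default class profiles carry the published cohort moments", {
  p <- default_profiles()
  expect_named(p, c("normal", "benign", "endometrioid", "LGS", "HGS"))
  expect_equal(p$HGS$ratio_mean, 2.7)
  expect_equal(p$HGS$ratio_sd, 1.7)
  expect_equal(p$benign$ratio_mean, 8.8)
  expect_equal(p$normal$ratio_mean, 4.0)
  expect_equal(p$LGS$ratio_sd, 3.5)
  # all presets satisfy the type invariants (constructor enforces them)
  for (pp in p) {
    expect_s3_class(pp, "tissue_class_profile")
    expect_true(pp$fiber_density > 0 && pp$fiber_density <= 1)
    expect_gt(pp$ratio_mean, 1)
    expect_lt(pp$ratio_mean, directionality_map()$r_max)
  }
  # LGS carries the widest width dispersion, HGS the narrowest
  expect_gt(p$LGS$width_sd, p$HGS$width_sd)
})

test_that("fiber fields are deterministic, dense as configured, labelled", {
  profile <- default_profiles()$normal
  t1 <- generate_fiber_field(profile, c(128, 128), seed = 5)
  t2 <- generate_fiber_field(profile, c(128, 128), seed = 5)
  expect_identical(t1$fiber_labels, t2$fiber_labels)
  expect_identical(t1$width_um, t2$width_um)
  # realized density close to target
  expect_gt(t1$density, profile$fiber_density - 0.02)
  # labels index the per-fiber tables
  expect_true(max(t1$fiber_labels) <= length(t1$width_um))
  expect_true(all(t1$width_um > 0))
})

test_that("unreachable density warns and reports what was achieved", {
  profile <- tissue_profile("x", fiber_density = 0.9, width_mean = 1,
                            width_sd = 0.1, length_mean = 10,
                            orientation_kappa = 0, waviness_amp = 0,
                            ratio_mean = 4, ratio_sd = 2)
  expect_warning(
    t0 <- generate_fiber_field(profile, c(64, 64), seed = 1, max_fibers = 5),
    "unreachable")
  expect_lt(t0$density, 0.9)
})

test_that("mismatch assignment calibrates the pixel-weighted mean ratio", {
  map <- directionality_map()
  for (cls in c("normal", "benign", "endometrioid", "LGS", "HGS")) {
    profile <- default_profiles()[[cls]]
    truth <- generate_fiber_field(profile, c(192, 192), seed = 3)
    truth <- assign_dk_and_ratio(truth, profile, map, seed = 4, n_blocks = 4)
    v <- truth$ratio_field[!is.na(truth$ratio_field)]
    expect_lt(abs(mean(v) - profile$ratio_mean), 0.1)
    expect_true(all(v >= 1))
    # dk field nonnegative on fibers, NA on background
    expect_true(all(truth$dk_field >= 0, na.rm = TRUE))
    expect_true(all(is.na(truth$ratio_field[, , 1][truth$fiber_labels == 0])))
  }
})

test_that("zero mismatch dispersion gives a constant ratio field", {
  profile <- tissue_profile("const", fiber_density = 0.3, width_mean = 2,
                            width_sd = 0.2, length_mean = 40,
                            orientation_kappa = 0, waviness_amp = 0,
                            ratio_mean = 5, ratio_sd = 1, dk_sd = 0)
  truth <- generate_fiber_field(profile, c(128, 128), seed = 2)
  truth <- assign_dk_and_ratio(truth, profile, seed = 3)
  v <- truth$ratio_field[!is.na(truth$ratio_field)]
  expect_equal(diff(range(v)), 0)
  expect_equal(mean(v), 5, tolerance = 0.1)
})

test_that("class dispersion calibration orders LGS above HGS in ratio units", {
  map <- directionality_map()
  profs <- default_profiles()
  # realized ratio SDs follow the configured targets
  set.seed(10)
  for (cls in c("LGS", "HGS")) {
    truth <- generate_fiber_field(profs[[cls]], c(256, 256), seed = 11)
    truth <- assign_dk_and_ratio(truth, profs[[cls]], map, seed = 12,
                                 n_blocks = 8)
    v <- truth$ratio_field[!is.na(truth$ratio_field)]
    assign(paste0("sd_", cls), sd(v))
  }
  expect_gt(sd_LGS, sd_HGS)
  # an unattainable dispersion target falls back with a warning
  wild <- tissue_profile("wild", 0.3, 2, 0.2, 40, 0, 0,
                         ratio_mean = 18, ratio_sd = 10)
  expect_warning(calibrate_dk_sd(wild, map), "unattainable")
})

test_that("rendered stacks are deterministic and carry provenance", {
  lut <- analytic_lut(depths = 0:15)
  profile <- default_profiles()$HGS
  truth <- generate_fiber_field(profile, c(96, 96), seed = 6)
  truth <- assign_dk_and_ratio(truth, profile, seed = 7, n_blocks = 2)
  v1 <- render_stack(truth, profile, lut, n_sections = 8, mean_counts = 150,
                     seed = 8)
  v2 <- render_stack(truth, profile, lut, n_sections = 8, mean_counts = 150,
                     seed = 8)
  expect_identical(v1$pair$forward, v2$pair$forward)
  expect_identical(v1$pair$backward, v2$pair$backward)
  expect_equal(v1$pair$metadata$lut_fingerprint, "analytic-test")
  expect_equal(dim(v1$pair$forward), c(96, 96, 8))
  # Poisson counts are nonnegative integers
  expect_true(all(v1$pair$forward >= 0))
  expect_true(all(v1$pair$forward == round(v1$pair$forward)))
})

test_that("noise-free uniform-ratio rendering round-trips through extraction", {
  lut <- analytic_lut(depths = 0:15)
  profile <- tissue_profile("u", fiber_density = 0.5, width_mean = 2.2,
                            width_sd = 0.2, length_mean = 50,
                            orientation_kappa = 1, waviness_amp = 1,
                            ratio_mean = 5, ratio_sd = 1, dk_sd = 0)
  truth <- generate_fiber_field(profile, c(120, 120), seed = 9)
  truth <- assign_dk_and_ratio(truth, profile, seed = 10)
  vol <- render_stack(truth, profile, lut, n_sections = 4,
                      mean_counts = 500, seed = 11, noise = FALSE,
                      jitter_px = 0, dark_fraction = 0)
  hm <- extract_ratio_heatmaps(vol$pair, lut, patch_size = 30)
  vals <- hm$ratios[hm$flags != "invalid"]
  # uniform ground truth ~5 (dk_sd 0): every patch inverts to ~5
  expect_lt(max(abs(vals - 5)), 0.3)
})

test_that("per-patch ratio variance falls as counts rise (shot-noise law)", {
  lut <- analytic_lut(depths = 0:15)
  profile <- tissue_profile("n", fiber_density = 0.6, width_mean = 2.2,
                            width_sd = 0.2, length_mean = 50,
                            orientation_kappa = 1, waviness_amp = 1,
                            ratio_mean = 5, ratio_sd = 1, dk_sd = 0)
  truth <- generate_fiber_field(profile, c(120, 120), seed = 12)
  truth <- assign_dk_and_ratio(truth, profile, seed = 13)
  spread <- vapply(c(30, 300, 3000), function(mc) {
    vol <- render_stack(truth, profile, lut, n_sections = 6,
                        mean_counts = mc, seed = 14, jitter_px = 0,
                        dark_fraction = 0)
    hm <- extract_ratio_heatmaps(vol$pair, lut, 30)
    stats::var(hm$ratios[hm$flags == "ok"])
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("cohort generation is deterministic with a full manifest", {
  lut <- analytic_lut(depths = 0:7)
  profs <- default_profiles()[c("normal", "HGS")]
  ch1 <- generate_cohort(profs, n_volumes_per_class = 2, shape = c(96, 96),
                         seed = 21, table = lut, n_sections = 4,
                         mean_counts = 100)
  expect_length(ch1$volumes, 4)
  expect_length(ch1$manifest$volumes, 4)
  expect_equal(vapply(ch1$volumes, `[[`, character(1), "class"),
               rep(c("normal", "HGS"), each = 2))
  ch2 <- generate_cohort(profs, n_volumes_per_class = 2, shape = c(96, 96),
                         seed = 21, table = lut, n_sections = 4,
                         mean_counts = 100)
  expect_identical(ch1$manifest, ch2$manifest)
  expect_identical(ch1$volumes[[3]]$pair$forward,
                   ch2$volumes[[3]]$pair$forward)
  # manifest records the calibration actually used
  m1 <- ch1$manifest$volumes[[1]]
  expect_true(all(c("seed", "realized_ratio_mean", "dk_center", "dk_sd")
                  %in% names(m1)))
})
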