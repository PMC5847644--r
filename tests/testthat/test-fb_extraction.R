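test_that("preprocessing trims sections, pairs saturation, updates depth", {
  set.seed(1)
  ns <- 120
  fwd <- array(rpois(16 * 16 * ns, 50), c(16, 16, ns))
  bwd <- array(rpois(16 * 16 * ns, 20), c(16, 16, ns))
  fwd[3, 4, 11] <- 5000 # saturated in forward only
  pair <- image_stack_pair(fwd, bwd)
  out <- preprocess_stack(pair, saturation_level = 4095,
                          noise_filter = "none", trim_sections = 10)
  expect_equal(dim(out$forward)[3], 100)
  expect_equal(out$depth_offset, 10)
  # the saturated pixel (now section 1 after trimming) is NA in BOTH channels
  expect_true(is.na(out$forward[3, 4, 1]))
  expect_true(is.na(out$backward[3, 4, 1]))

  expect_error(preprocess_stack(uniform_pair(ns = 15), trim_sections = 10),
               "sections")
  expect_error(preprocess_stack(pair, saturation_level = 0), "positive")

  # all-zero stack: unchanged except trimming
  z <- uniform_pair(0, 0, ns = 25)
  zo <- preprocess_stack(z, 100, "none", 10)
  expect_true(all(zo$forward == 0))
  expect_equal(dim(zo$forward)[3], 5)
})

test_that("median denoise removes isolated outliers identically per channel", {
  fwd <- array(10, c(9, 9, 1)); fwd[5, 5, 1] <- 1000
  bwd <- array(4, c(9, 9, 1));  bwd[5, 5, 1] <- 400
  pair <- image_stack_pair(fwd, bwd)
  out <- preprocess_stack(pair, saturation_level = 1e6,
                          noise_filter = "median3", trim_sections = 0)
  expect_equal(out$forward[5, 5, 1], 10)
  expect_equal(out$backward[5, 5, 1], 4)
})

test_that("background subtraction clamps at zero", {
  pair <- uniform_pair(10, 3, ns = 1)
  out <- preprocess_stack(pair, 1e6, "none", 0, background = 5)
  expect_true(all(out$forward == 5))
  expect_true(all(out$backward == 0))
})

test_that("calibration divides the forward channel and commutes with patching", {
  pair <- uniform_pair(10, 5, ns = 1)
  geo <- detection_geometry(calibration_factor = 2)
  cal <- apply_calibration(pair, geo)
  g <- compute_patch_grid(cal$forward[, , 1], cal$backward[, , 1],
                          patch_size = 16)
  expect_equal(unique(as.vector(g$measured_fb)), 1) # factor 2, F=10, B=5

  # identity factor
  id <- apply_calibration(pair, detection_geometry(calibration_factor = 1))
  expect_equal(id$forward, pair$forward)

  # scalar factor commutes with patch means: calibrate-then-patch equals
  # patch-then-divide
  set.seed(2)
  f <- matrix(rpois(64 * 64, 40), 64, 64)
  b <- matrix(rpois(64 * 64, 10), 64, 64)
  p2 <- image_stack_pair(array(f, c(64, 64, 1)), array(b, c(64, 64, 1)))
  g_pre <- compute_patch_grid(apply_calibration(p2, geo)$forward[, , 1],
                              p2$backward[, , 1], 16)
  g_post <- compute_patch_grid(f, b, 16)
  expect_equal(g_pre$measured_fb, g_post$measured_fb / 2, tolerance = 1e-12)
})

test_that("patch grid tiles from the top-left and discards margins", {
  f <- matrix(8, 512, 512)
  b <- matrix(2, 512, 512)
  g <- compute_patch_grid(f, b, patch_size = 30)
  expect_equal(dim(g$measured_fb), c(17, 17)) # 512 %/% 30, 2-px margins dropped
  expect_true(all(g$measured_fb == 4))
  expect_true(all(g$valid))

  # tile with zero backward is invalid
  b2 <- b; b2[1:30, 1:30] <- 0
  g2 <- compute_patch_grid(f, b2, 30)
  expect_false(g2$valid[1, 1])
  expect_true(is.na(g2$measured_fb[1, 1]))
  expect_true(all(g2$valid[-1, ]))

  # validity fraction: > half the pixels NA fails the tile
  f3 <- f; f3[1:30, 1:16] <- NA; b3 <- b; b3[1:30, 1:16] <- NA
  g3 <- compute_patch_grid(f3, b3, 30, min_valid_fraction = 0.5)
  expect_false(g3$valid[1, 1])

  expect_error(compute_patch_grid(f[1:20, 1:20], b[1:20, 1:20], 30), "larger")
})

test_that("frame-averaged F/B equals the patch-weighted mean on valid sections", {
  set.seed(4)
  f <- matrix(rpois(90 * 90, 60), 90, 90)
  b <- matrix(rpois(90 * 90, 15), 90, 90)
  g <- compute_patch_grid(f, b, 30)
  # every tile fully valid: mean(F)/mean(B) over the tiled area equals the
  # mean of per-tile F sums over per-tile B sums weighted by tile B totals
  frame_fb <- mean(f) / mean(b)
  weighted <- sum(g$mean_forward) / sum(g$mean_backward)
  expect_equal(weighted, frame_fb, tolerance = 1e-12)
})

test_that("heat-map extraction inverts exactly through an analytic table", {
  lut <- analytic_lut(depths = 0:5)
  # uniform ground truth ratio 5: forward = 5 x backward everywhere
  pair <- uniform_pair(50, 10, nr = 90, nc = 90, ns = 2)
  hm <- extract_ratio_heatmaps(pair, lut, patch_size = 30)
  expect_equal(dim(hm$ratios), c(3, 3, 2))
  expect_true(all(abs(hm$ratios - 5) < 1e-9))
  expect_true(all(hm$flags == "ok"))
  expect_equal(hm$provenance, "analytic-test")

  # two-region ground truth: left 3, right 9, step recovered at the boundary
  f <- cbind(matrix(30, 90, 45), matrix(90, 90, 45))
  b <- matrix(10, 90, 90)
  pr <- image_stack_pair(array(f, c(90, 90, 1)), array(b, c(90, 90, 1)))
  hm2 <- extract_ratio_heatmaps(pr, lut, 30)
  expect_equal(as.vector(hm2$ratios[, 1, 1]), rep(3, 3))
  expect_equal(as.vector(hm2$ratios[, 3, 1]), rep(9, 3))

  # all-invalid stack
  pz <- uniform_pair(0, 0, nr = 90, nc = 90, ns = 1)
  hmz <- extract_ratio_heatmaps(pz, lut, 30)
  expect_true(all(hmz$flags == "invalid"))
  expect_true(all(is.na(hmz$ratios)))
})

test_that("flag accounting is conserved and clamps are flagged", {
  lut <- analytic_lut(depths = 0:3)
  f <- matrix(10, 60, 60)
  f[1:30, 1:30] <- 0.5   # measured fb 0.05: below grid -> clamped_low
  f[1:30, 31:60] <- 500  # measured fb 50: above grid -> clamped_high
  b <- matrix(10, 60, 60)
  b[31:60, 1:30] <- 0    # invalid tile
  pr <- image_stack_pair(array(f, c(60, 60, 1)), array(b, c(60, 60, 1)))
  hm <- extract_ratio_heatmaps(pr, lut, 30)
  counts <- table(factor(hm$flags,
                         c("ok", "clamped_low", "clamped_high", "invalid")))
  expect_equal(sum(counts), 4)
  expect_equal(unname(counts["clamped_low"]), 1L)
  expect_equal(unname(counts["clamped_high"]), 1L)
  expect_equal(unname(counts["invalid"]), 1L)
  expect_equal(hm$ratios[1, 1, 1], 1)     # clamped to the grid floor
  expect_equal(hm$ratios[1, 2, 1], 19.9)  # clamped to the grid ceiling
})

test_that("patch-size sweep reproduces the failure-rate diagnostic", {
  set.seed(6)
  lut <- analytic_lut(depths = 0:3)
  # Poisson stack at low counts: single-pixel patches fail (zero backward)
  # far more often than 30-px patches
  lam_b <- 1.5
  f <- matrix(rpois(90 * 90, 5 * lam_b), 90, 90)
  b <- matrix(rpois(90 * 90, lam_b), 90, 90)
  pr <- image_stack_pair(array(f, c(90, 90, 1)), array(b, c(90, 90, 1)))
  sweep <- patch_size_sweep(pr, lut, sizes = c(1, 30))
  ff <- sweep$fit_failure
  expect_gt(ff$failure_fraction[ff$patch_size == 1],
            ff$failure_fraction[ff$patch_size == 30])

  # sizes [30] reproduces extract_ratio_heatmaps exactly
  hm30 <- extract_ratio_heatmaps(pr, lut, 30)
  expect_equal(sweep$heatmaps[["30"]]$ratios, hm30$ratios)

  # noiseless uniform stack: identical mean ratio at every size
  pu <- uniform_pair(40, 10, nr = 90, nc = 90, ns = 1)
  sw2 <- patch_size_sweep(pu, lut, sizes = c(1, 10, 30))
  means <- vapply(sw2$heatmaps, function(h) mean(h$ratios), numeric(1))
  expect_true(all(abs(means - 4) < 1e-9))
})

test_that("heat-map long-format export has one row per patch-section", {
  lut <- analytic_lut(depths = 0:2)
  pr <- uniform_pair(20, 10, nr = 60, nc = 60, ns = 2)
  hm <- extract_ratio_heatmaps(pr, lut, 30)
  df <- as.data.frame(hm)
  expect_equal(nrow(df), 2 * 2 * 2)
  expect_named(df, c("section", "row", "col", "depth_um", "ratio", "flag"))
  expect_true(all(abs(df$ratio - 2) < 1e-9))
})
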