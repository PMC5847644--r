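# shared fixtures: analytic lookup tables, tiny optics, synthetic bars

# noiseless analytic lookup table: measured F/B = creation ratio times a
# depth-dependent slope; isolates inversion logic from Monte Carlo noise
analytic_lut <- function(ratios = seq(1, 19.9, by = 0.3), depths = 0:10,
                         slope = rep(1, length(depths))) {
  fb <- outer(ratios, seq_along(depths), function(r, j) r * slope[j])
  structure(list(ratio_axis = ratios, depth_axis = depths,
                 measured_fb = fb,
                 standard_errors = matrix(0, length(ratios), length(depths)),
                 optics_fingerprint = "analytic-test"),
            class = "emission_lut")
}

test_optics <- function(mus = 1, thickness = 150)
  optical_properties(mu_s_reduced = mus, anisotropy_g = 0.9,
                     refractive_index = 1.4, thickness = thickness)

# uniform two-channel stack pair with optional per-channel values
uniform_pair <- function(f = 8, b = 2, nr = 64, nc = 64, ns = 3, ...) {
  image_stack_pair(array(f, c(nr, nc, ns)), array(b, c(nr, nc, ns)), ...)
}

# pixel-centre rasterisation of a rotated bar of given width/length (px),
# centred in an image of side n
bar_mask <- function(n = 80, width = 5, length = 60, theta = 0) {
  ctr <- (n + 1) / 2
  idx <- expand.grid(r = seq_len(n), c = seq_len(n))
  dx <- idx$c - ctr
  dy <- idx$r - ctr
  along <- dx * cos(theta) + dy * sin(theta)
  across <- -dx * sin(theta) + dy * cos(theta)
  m <- abs(across) <= width / 2 & abs(along) <= length / 2
  matrix(m, n, n)
}
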