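#' Tissue class generative profile
#'
#' Generative parameters for one synthetic tissue class: fiber-field
#' morphology (coverage density, width and length moments, orientation
#' concentration, waviness), the target ground-truth creation-ratio moments
#' the class must realise, the phase-mismatch dispersion that generates
#' them, and the slab optics.
#'
#' @param label Class label.
#' @param fiber_density Target fraction of the field covered by fibers,
#'   in (0, 1].
#' @param width_mean,width_sd Fiber width moments, um (truncated > 0).
#' @param length_mean Mean fiber length, um.
#' @param orientation_kappa von Mises concentration of fiber axes (0 =
#'   isotropic mesh; large = aligned).
#' @param waviness_amp Sinusoidal centerline undulation amplitude, um.
#' @param ratio_mean,ratio_sd Target ground-truth F_SHG/B_SHG mean and
#'   within-volume SD.
#' @param dk_sd Phase-mismatch dispersion (rad/um), or `NA` to calibrate it
#'   from `ratio_sd` at generation time.
#' @param optics [optical_properties()] of the slab.
#' @return An object of class `tissue_class_profile`.
#' @export
tissue_profile <- function(label, fiber_density, width_mean, width_sd,
                           length_mean, orientation_kappa, waviness_amp,
                           ratio_mean, ratio_sd, dk_sd = NA_real_,
                           optics = optical_properties()) {
  stopifnot(fiber_density > 0, fiber_density <= 1, width_sd >= 0,
            width_mean > 0, length_mean > 0, orientation_kappa >= 0,
            waviness_amp >= 0, ratio_mean > 1, ratio_sd >= 0,
            is.na(dk_sd) || dk_sd >= 0)
  structure(list(label = label, fiber_density = fiber_density,
                 width_mean = width_mean, width_sd = width_sd,
                 length_mean = length_mean,
                 orientation_kappa = orientation_kappa,
                 waviness_amp = waviness_amp,
                 ratio_mean = ratio_mean, ratio_sd = ratio_sd,
                 dk_sd = dk_sd, optics = optics),
            class = "tissue_class_profile")
}

#' Default five-class ovarian tissue profiles
#'
#' Presets for normal stroma, benign tumor, endometrioid (type I), low-grade
#' serous (LGS, type I) and high-grade serous (HGS, type II) tissue. The
#' ground-truth creation-ratio moments are the published cohort values
#' (means 4.0 / 8.8 / 3.0 / 5.1 / 2.7 with within-volume SDs 2.0 / 3.9 /
#' 1.7 / 3.5 / 1.7); widths use the published class means and the
#' morphology follows the qualitative class descriptions: normal is a
#' loose isotropic mesh, benign densely fibrotic with thick bundles,
#' endometrioid sparse with long straight aligned fibers, LGS a tightly
#' packed matrix of shorter fibers with the widest width dispersion, HGS
#' densely packed, aligned and wavy with narrow dispersion.
#'
#' @param optics [optical_properties()] shared by all presets (per-class
#'   bulk optics are configurable but default to one set).
#' @return Named list of five [tissue_profile()] objects.
#' @export
default_profiles <- function(optics = optical_properties()) {
  list(
    normal = tissue_profile("normal", fiber_density = 0.60,
      width_mean = 2.13, width_sd = 0.40, length_mean = 60,
      orientation_kappa = 0.3, waviness_amp = 1.5,
      ratio_mean = 4.0, ratio_sd = 2.0, optics = optics),
    benign = tissue_profile("benign", fiber_density = 0.80,
      width_mean = 2.19, width_sd = 0.55, length_mean = 80,
      orientation_kappa = 1.5, waviness_amp = 2.0,
      ratio_mean = 8.8, ratio_sd = 3.9, optics = optics),
    endometrioid = tissue_profile("endometrioid", fiber_density = 0.50,
      width_mean = 2.13, width_sd = 0.35, length_mean = 100,
      orientation_kappa = 8, waviness_amp = 0.5,
      ratio_mean = 3.0, ratio_sd = 1.7, optics = optics),
    LGS = tissue_profile("LGS", fiber_density = 0.78,
      width_mean = 2.14, width_sd = 0.90, length_mean = 40,
      orientation_kappa = 1, waviness_amp = 1.0,
      ratio_mean = 5.1, ratio_sd = 3.5, optics = optics),
    HGS = tissue_profile("HGS", fiber_density = 0.75,
      width_mean = 2.20, width_sd = 0.25, length_mean = 70,
      orientation_kappa = 6, waviness_amp = 3.0,
      ratio_mean = 2.7, ratio_sd = 1.7, optics = optics))
}

# von Mises sampler (Best & Fisher 1979 rejection); mu = 0
rvonmises0 <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c <- kappa * (r - f)
      if (c * (2 - c) - u[2] > 0 || log(c / u[2]) + 1 - c >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

#' Generate a synthetic fiber field
#'
#' Places wavy line-segment fibers with circular (disc-stamped) cross
#' sections at random positions until the target coverage density is
#' reached. Per-fiber widths are Normal(`width_mean`, `width_sd`) truncated
#' positive, axial orientations von Mises(`orientation_kappa`), lengths
#' Normal around `length_mean`, and centerlines undulate sinusoidally with
#' amplitude `waviness_amp`. Overlaps resolve first-wins so each pixel has
#' one fiber id.
#'
#' @param profile A [tissue_profile()].
#' @param shape `c(rows, cols)` in px (>= 64).
#' @param seed Integer seed (field is identical on rerun).
#' @param pixel_size um per pixel.
#' @param max_fibers Placement attempts before giving up on the density.
#' @return An `shg_ground_truth` object: integer `fiber_labels` (0 =
#'   background), per-fiber `width_um`, `theta`, `length_um` vectors,
#'   `pixel_size`, `profile_label`, realized `density`; `dk_field` and
#'   `ratio_field` are filled by [assign_dk_and_ratio()].
#' @export
generate_fiber_field <- function(profile, shape = c(256, 256), seed = 1,
                                 pixel_size = 170 / 512, max_fibers = 20000) {
  stopifnot(inherits(profile, "tissue_class_profile"),
            length(shape) == 2, all(shape >= 64))
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]
  labels <- matrix(0L, nr, nc)
  width_um <- numeric(0); theta <- numeric(0); length_um <- numeric(0)
  n_px <- nr * nc
  covered <- 0L
  id <- 0L
  while (covered / n_px < profile$fiber_density && id < max_fibers) {
    id <- id + 1L
    w <- 0
    while (w <= 0.3) w <- stats::rnorm(1, profile$width_mean, profile$width_sd)
    th <- rvonmises0(1, profile$orientation_kappa) / 2 # axial: mod pi
    len <- max(5, stats::rnorm(1, profile$length_mean,
                               0.25 * profile$length_mean))
    len_px <- len / pixel_size
    amp_px <- profile$waviness_amp / pixel_size
    cr <- stats::runif(1, 1, nr); cc <- stats::runif(1, 1, nc)
    tt <- seq(-len_px / 2, len_px / 2, by = 0.5)
    phase <- stats::runif(1, 0, 2 * pi)
    lat <- amp_px * sin(2 * pi * tt / (len_px / 1.5) + phase)
    rows <- cr + tt * cos(th) - lat * sin(th)
    cols <- cc + tt * sin(th) + lat * cos(th)
    .stamp_fiber_cpp(labels, rows, cols, (w / pixel_size) / 2, id)
    width_um <- c(width_um, w); theta <- c(theta, th)
    length_um <- c(length_um, len)
    covered <- sum(labels > 0L)
  }
  realized <- covered / n_px
  if (realized < profile$fiber_density - 0.02)
    warning(sprintf("target density %.2f unreachable; realized %.3f",
                    profile$fiber_density, realized))
  # visible-pixel centroids, used to tie fibers to spatial dk domains
  centroid <- matrix(NA_real_, max(id, 1L), 2)
  if (id > 0L) {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    centroid[, 1] <- as.numeric(tapply(idx[, 1], factor(lab, levels = 1:id),
                                       mean))
    centroid[, 2] <- as.numeric(tapply(idx[, 2], factor(lab, levels = 1:id),
                                       mean))
  }
  structure(list(fiber_labels = labels, width_um = width_um, theta = theta,
                 centroid = centroid,
                 length_um = length_um, pixel_size = pixel_size,
                 profile_label = profile$label, density = realized,
                 dk_field = NULL, ratio_field = NULL,
                 fiber_dk = NULL, fiber_ratio = NULL),
            class = "shg_ground_truth")
}

#' Assign the phase-mismatch field and creation ratios
#'
#' Phase mismatch reflects fibril size and packing, which varies between
#' spatially coherent micrometre-scale domains rather than per whole
#' fiber: the field draws one standard-normal value per domain (cells of
#' `domain_size_um`) and every collagen pixel takes the folded value
#' `|dk_center + dk_sd * z(domain)|`, mapped to a creation ratio through
#' the [directionality_map()]. `dk_center` is solved numerically on the
#' realized domain draws (pixel-weighted) so the realized mean ratio
#' equals the profile's `ratio_mean` (tolerance 0.1); when the profile's
#' `dk_sd` is `NA` it too is calibrated so the realized ratio SD matches
#' `ratio_sd` (a target SD beyond what the bounded map can realise falls
#' back to the widest attainable with a warning). Per-fiber summaries
#' (pixel-mean dk and ratio along each fiber) are recorded alongside the
#' per-pixel fields.
#'
#' @param truth An `shg_ground_truth` from [generate_fiber_field()].
#' @param profile The same [tissue_profile()].
#' @param map A [directionality_map()].
#' @param seed Integer seed for the mismatch draws.
#' @param domain_size_um Spatial coherence scale of the mismatch field, um
#'   (default 25: a few patches per domain, and enough domains per field
#'   to realise the configured dispersion): fibers within the same domain
#'   share a latent draw, emulating the spatially coherent fibril-packing
#'   domains visible as multi-patch regions in real heat maps.
#' @param n_blocks Number of independent axial domain realisations
#'   (default 1): fibril packing decorrelates over a few um of depth, so a
#'   deep stack is rendered from several independent domain fields while
#'   the fiber geometry persists.
#' @return The `shg_ground_truth` with `fiber_dk`, `fiber_ratio` (block-1
#'   per-fiber summaries), `dk_field` and `ratio_field` (per-pixel
#'   `rows x cols x n_blocks` arrays, NA on background) filled, and the
#'   calibrated `dk_center`/`dk_sd` recorded.
#' @export
assign_dk_and_ratio <- function(truth, profile, map = directionality_map(),
                                seed = 1, domain_size_um = 25,
                                n_blocks = 1) {
  stopifnot(inherits(truth, "shg_ground_truth"),
            inherits(profile, "tissue_class_profile"),
            inherits(map, "directionality_map"))
  nf <- length(truth$width_um)
  if (nf == 0) stop("ground truth has no fibers")
  if (profile$ratio_mean <= 1 || profile$ratio_mean >= map$r_max)
    stop("ratio_mean outside the directionality map range (1, r_max)")
  set.seed(seed)
  # Spatially coherent mismatch: one standard-normal value per domain cell,
  # read per pixel, so the mismatch is a sub-fiber (fibril-domain) property
  # and patch-scale dispersion matches the configured class dispersion
  # instead of averaging out along fibers. The domain field is drawn
  # independently for each axial block (fibril packing decorrelates over a
  # few um of depth even where fiber geometry persists).
  fiber_px <- truth$fiber_labels > 0L
  dom <- domain_grid(truth, domain_size_um)
  n_cells <- length(dom$z)
  z_blocks <- matrix(stats::rnorm(n_cells * n_blocks), n_cells, n_blocks)
  z_blocks[, 1] <- dom$z
  z_all <- as.vector(z_blocks)                   # one draw per cell x block
  # pixel-count weights per cell: the analysis measures patch/pixel-weighted
  # moments, so the calibration targets those rather than fiber-weighted ones
  w_cell <- tabulate(dom$cell[fiber_px], nbins = n_cells)
  w_all <- rep(w_cell, times = n_blocks)
  occupied <- w_all > 0
  z <- z_all[occupied]
  w <- w_all[occupied]

  mean_at <- function(center, s) {
    r <- dk_to_creation_ratio(abs(center + s * z), map)
    sum(w * r) / sum(w)
  }
  sd_at <- function(center, s) {
    r <- dk_to_creation_ratio(abs(center + s * z), map)
    mw <- sum(w * r) / sum(w)
    sqrt(sum(w * (r - mw)^2) / sum(w))
  }
  solve_center <- function(s) {
    h <- function(cc) mean_at(cc, s) - profile$ratio_mean
    if (h(0) <= 0) return(0)
    hi <- map$decay
    while (h(hi) > 0 && hi < 1e4 * map$decay) hi <- hi * 2
    stats::uniroot(h, c(0, hi), tol = 1e-10)$root
  }

  # dispersion is a class property: calibrate it once against the
  # population folded-Normal (deterministic quadrature sample), not the few
  # domain draws of one volume, so every volume of a class shares dk_sd
  s <- profile$dk_sd
  if (is.na(s)) s <- calibrate_dk_sd(profile, map)
  center <- solve_center(s)
  dk_cells <- abs(center + s * z_all)
  ratio_cells <- dk_to_creation_ratio(dk_cells, map)
  realized_mean <- sum(w * ratio_cells[occupied]) / sum(w)
  if (abs(realized_mean - profile$ratio_mean) > 0.1)
    warning(sprintf(
      "realized mean ratio %.3f misses target %.3f by > 0.1 (unlucky domain draws?)",
      realized_mean, profile$ratio_mean))
  nr <- nrow(truth$fiber_labels); nc <- ncol(truth$fiber_labels)
  dk_by_block <- matrix(dk_cells, n_cells, n_blocks)
  ratio_by_block <- matrix(ratio_cells, n_cells, n_blocks)
  dk_field <- array(NA_real_, c(nr, nc, n_blocks))
  ratio_field <- array(NA_real_, c(nr, nc, n_blocks))
  for (b in seq_len(n_blocks)) {
    dkm <- matrix(dk_by_block[dom$cell, b], nr, nc)
    rtm <- matrix(ratio_by_block[dom$cell, b], nr, nc)
    dkm[!fiber_px] <- NA_real_
    rtm[!fiber_px] <- NA_real_
    dk_field[, , b] <- dkm
    ratio_field[, , b] <- rtm
  }
  lab <- truth$fiber_labels[fiber_px]
  fl <- factor(lab, levels = seq_len(nf))
  truth$fiber_dk <- as.numeric(tapply(dk_field[, , 1][fiber_px], fl, mean))
  truth$fiber_ratio <- as.numeric(tapply(ratio_field[, , 1][fiber_px], fl,
                                         mean))
  truth$dk_field <- dk_field
  truth$ratio_field <- ratio_field
  truth$n_blocks <- n_blocks
  truth$dk_center <- center
  truth$dk_sd <- s
  truth
}

#' Render a forward/backward stack pair from ground truth
#'
#' Forward model of the whole instrument: per-fiber SHG intensity follows
#' the sinc phase-matching law with the local fiber width as interaction
#' length; the created signal splits into detected forward and backward
#' channels using the Monte Carlo table's measured F/B at (creation ratio,
#' section depth); the forward channel is multiplied by the detector
#' calibration factor; counts are scaled so fiber pixels average
#' `mean_counts`; background receives dark counts (1% of `mean_counts`);
#' independent Poisson shot noise is added per channel. Fibers persist
#' across sections with a small seeded lateral jitter emulating the ~2.5-um
#' axial resolution.
#'
#' @param truth An `shg_ground_truth` with ratios assigned.
#' @param profile The [tissue_profile()].
#' @param table An `emission_lut` built for `profile$optics`.
#' @param geometry A [detection_geometry()].
#' @param n_sections Number of optical sections (default 64).
#' @param mean_counts Mean photon counts over fiber pixels (default 200).
#' @param seed Integer seed (stacks are bit-identical on rerun).
#' @param noise Add Poisson noise (default TRUE).
#' @param jitter_px SD of per-section integer lateral jitter (default 0.5).
#' @param dark_fraction Background dark level as a fraction of
#'   `mean_counts` (default 0.01).
#' @param depth_offset Depth of the first section, um (default 0).
#' @param section_spacing um between sections (default 1).
#' @return List with `pair` (an [image_stack_pair()], metadata recording
#'   the table fingerprint) and `truth`.
#' @export
render_stack <- function(truth, profile, table, geometry = detection_geometry(),
                         n_sections = 64, mean_counts = 200, seed = 1,
                         noise = TRUE, jitter_px = 0.5, dark_fraction = 0.01,
                         depth_offset = 0, section_spacing = 1) {
  stopifnot(inherits(truth, "shg_ground_truth"),
            inherits(table, "emission_lut"),
            !is.null(truth$fiber_ratio))
  max_depth <- depth_offset + (n_sections - 1) * section_spacing
  if (max_depth > max(table$depth_axis) + max(diff(table$depth_axis)))
    stop("stack depths exceed the lookup table depth range")
  set.seed(seed)
  labels <- truth$fiber_labels
  nr <- nrow(labels); nc <- ncol(labels)
  fiber_mask <- labels > 0L
  n_blocks <- if (is.null(truth$n_blocks)) 1L else truth$n_blocks
  # per-pixel created intensity per axial block: sinc^2 with the local
  # fiber width as the interaction length and the local (domain) mismatch
  w_px <- matrix(c(NA_real_, truth$width_um)[labels + 1L], nr, nc)
  counts_b <- vector("list", n_blocks)
  rat_fib_b <- vector("list", n_blocks)
  mI <- 0
  for (b in seq_len(n_blocks)) {
    I_px <- sinc(truth$dk_field[, , b] * w_px / 2)^2
    I_px[!fiber_mask] <- 0
    counts_b[[b]] <- I_px
    rat_fib_b[[b]] <- pmin(pmax(truth$ratio_field[, , b][fiber_mask],
                                min(table$ratio_axis)),
                           max(table$ratio_axis))
    mI <- mI + mean(I_px[fiber_mask]) / n_blocks
  }
  if (any(truth$ratio_field > max(table$ratio_axis) |
          truth$ratio_field < min(table$ratio_axis), na.rm = TRUE))
    warning("ground-truth ratios outside the table grid were clamped")
  if (mI <= 0) stop("all fiber intensities are zero (all dk at sinc zeros?)")
  scale <- mean_counts / mI
  dark <- dark_fraction * mean_counts
  block_of <- pmin(n_blocks,
                   ceiling(seq_len(n_sections) / (n_sections / n_blocks)))
  fwd <- array(0, c(nr, nc, n_sections))
  bwd <- array(0, c(nr, nc, n_sections))
  for (s in seq_len(n_sections)) {
    depth <- depth_offset + (s - 1) * section_spacing
    b <- block_of[s]
    counts <- counts_b[[b]] * scale
    msplit <- matrix(1, nr, nc)
    msplit[fiber_mask] <- lut_forward(table, rat_fib_b[[b]], depth)
    F2 <- counts * msplit / (1 + msplit) * geometry$calibration_factor + dark
    B2 <- counts / (1 + msplit) + dark
    if (jitter_px > 0) {
      dr <- as.integer(round(stats::rnorm(1, 0, jitter_px)))
      dc <- as.integer(round(stats::rnorm(1, 0, jitter_px)))
      F2 <- shift_pad(F2, dr, dc, fill = dark)
      B2 <- shift_pad(B2, dr, dc, fill = dark)
    }
    if (noise) {
      F2 <- matrix(stats::rpois(nr * nc, F2), nr, nc)
      B2 <- matrix(stats::rpois(nr * nc, B2), nr, nc)
    }
    fwd[, , s] <- F2
    bwd[, , s] <- B2
  }
  pair <- image_stack_pair(fwd, bwd, pixel_size = truth$pixel_size,
                           section_spacing = section_spacing,
                           depth_offset = depth_offset,
                           metadata = list(
                             lut_fingerprint = table$optics_fingerprint,
                             class = truth$profile_label,
                             mean_counts = mean_counts, seed = seed))
  list(pair = pair, truth = truth)
}

#' Calibrate the class phase-mismatch dispersion
#'
#' Solves for the folded-Normal dispersion `dk_sd` (and the matching
#' centre) such that the population distribution of
#' `ratio = map(|dk_center + dk_sd Z|)`, `Z ~ N(0,1)`, has the profile's
#' target mean and SD. Uses a deterministic normal quadrature sample, so
#' the result is a fixed class constant. A target SD beyond what the
#' bounded map can realise falls back to the widest attainable with a
#' warning.
#'
#' @param profile A [tissue_profile()].
#' @param map A [directionality_map()].
#' @param n_quad Quadrature sample size.
#' @return The calibrated `dk_sd` (rad/um).
#' @export
calibrate_dk_sd <- function(profile, map = directionality_map(),
                            n_quad = 4096) {
  zq <- stats::qnorm(stats::ppoints(n_quad))
  mean_at <- function(center, s)
    mean(dk_to_creation_ratio(abs(center + s * zq), map))
  sd_at <- function(center, s)
    stats::sd(dk_to_creation_ratio(abs(center + s * zq), map))
  solve_center <- function(s) {
    h <- function(cc) mean_at(cc, s) - profile$ratio_mean
    if (h(0) <= 0) return(0)
    hi <- map$decay
    while (h(hi) > 0 && hi < 1e4 * map$decay) hi <- hi * 2
    stats::uniroot(h, c(0, hi), tol = 1e-10)$root
  }
  # widest usable dispersion: where even centre 0 just meets the mean
  m0 <- function(s) mean_at(0, s) - profile$ratio_mean
  hi <- map$decay
  while (m0(hi) > 0 && hi < 1e4 * map$decay) hi <- hi * 2
  s_hi <- stats::uniroot(m0, c(1e-9, hi), tol = 1e-10)$root
  g <- function(s) sd_at(solve_center(s), s) - profile$ratio_sd
  # g need not be monotone; take the smallest dispersion realising the
  # target SD (first sign change on a scan, then refine)
  grid <- seq(1e-6, s_hi, length.out = 64)
  gv <- vapply(grid, g, numeric(1))
  cross <- which(gv[-1] >= 0 & gv[-length(gv)] < 0)
  if (gv[1] >= 0) return(grid[1])
  if (length(cross) == 0) {
    warning(sprintf(
      "ratio_sd %.2f unattainable for mean %.2f; using widest %.2f",
      profile$ratio_sd, profile$ratio_mean, sd_at(solve_center(s_hi), s_hi)))
    return(s_hi)
  }
  stats::uniroot(g, grid[c(cross[1], cross[1] + 1)], tol = 1e-10)$root
}

# spatial domain grid: square cells of `domain_size_um`, one iid N(0,1) per
# cell; returns the per-pixel cell index matrix and the cell draws
domain_grid <- function(truth, domain_size_um) {
  cell_px <- max(1, round(domain_size_um / truth$pixel_size))
  nr <- nrow(truth$fiber_labels); nc <- ncol(truth$fiber_labels)
  gr <- max(1, ceiling(nr / cell_px)); gc <- max(1, ceiling(nc / cell_px))
  ri <- pmin(gr, ceiling(seq_len(nr) / cell_px))
  ci <- pmin(gc, ceiling(seq_len(nc) / cell_px))
  cell <- matrix(ri, nr, nc) + (matrix(ci, nr, nc, byrow = TRUE) - 1L) * gr
  list(cell = cell, z = stats::rnorm(gr * gc))
}

# shift a matrix by integer offsets, padding with a fill value
shift_pad <- function(m, dr, dc, fill = 0) {
  if (dr == 0 && dc == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Generate a synthetic multi-class cohort
#'
#' Generates `n_volumes_per_class` volumes for each profile with
#' deterministic per-volume child seeds and a manifest recording every
#' parameter and realized calibration. Volumes are returned in memory;
#' see [run_full_analysis()] for a streaming analysis that bounds memory.
#'
#' @param profiles Named list of [tissue_profile()] objects.
#' @param n_volumes_per_class Volumes per class (>= 1).
#' @param shape `c(rows, cols)` px.
#' @param seed Root seed.
#' @param table An `emission_lut` shared by all classes.
#' @param geometry A [detection_geometry()].
#' @param map A [directionality_map()].
#' @param n_sections,mean_counts,noise Passed to [render_stack()].
#' @return List with `volumes` (each: `class`, `pair`, `truth`, `seed`) and
#'   `manifest` (parameters + per-volume seeds and realized moments).
#' @export
generate_cohort <- function(profiles, n_volumes_per_class = 3,
                            shape = c(256, 256), seed = 1, table,
                            geometry = detection_geometry(),
                            map = directionality_map(), n_sections = 64,
                            mean_counts = 200, noise = TRUE) {
  stopifnot(n_volumes_per_class >= 1)
  volumes <- list()
  entries <- list()
  k <- 0L
  for (cls in names(profiles)) {
    for (v in seq_len(n_volumes_per_class)) {
      k <- k + 1L
      child <- cohort_child_seed(seed, k)
      vol <- generate_volume(profiles[[cls]], shape, n_sections, table,
                             geometry, map, child, mean_counts, noise)
      volumes[[k]] <- c(list(class = cls, seed = child), vol)
      rf <- vol$truth$ratio_field[!is.na(vol$truth$ratio_field)]
      entries[[k]] <- list(class = cls, volume = v, seed = child,
                           realized_density = vol$truth$density,
                           realized_ratio_mean = mean(rf),
                           realized_ratio_sd = stats::sd(rf),
                           dk_center = vol$truth$dk_center,
                           dk_sd = vol$truth$dk_sd)
    }
  }
  manifest <- list(seed = seed, shape = shape, n_sections = n_sections,
                   mean_counts = mean_counts, noise = noise,
                   n_volumes_per_class = n_volumes_per_class,
                   classes = names(profiles),
                   lut_fingerprint = table$optics_fingerprint,
                   map = unclass(map), volumes = entries)
  list(volumes = volumes, manifest = manifest)
}

# deterministic child seeds below 2^31
cohort_child_seed <- function(root, k) {
  as.integer((as.numeric(root) * 7919 + 104729 * as.numeric(k)) %% 2147483647)
}

# one volume: fiber field -> dk/ratio assignment (one independent domain
# realisation per ~8 um of depth) -> rendered stack
generate_volume <- function(profile, shape, n_sections, table, geometry,
                            map, seed, mean_counts, noise,
                            axial_persistence_um = 8) {
  truth <- generate_fiber_field(profile, shape, seed = seed)
  n_blocks <- max(1L, as.integer(floor(n_sections / axial_persistence_um)))
  truth <- assign_dk_and_ratio(truth, profile, map, seed = seed + 1L,
                               n_blocks = n_blocks)
  render_stack(truth, profile, table, geometry, n_sections = n_sections,
               mean_counts = mean_counts, seed = seed + 2L, noise = noise)
}
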