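#' Paired forward/backward image stacks
#'
#' Co-registered forward- and backward-channel 3-D intensity stacks (photon
#' counts) stored as `rows x cols x sections` arrays with physical
#' calibration metadata. Invalid pixels (e.g. saturated) are `NA` in both
#' channels.
#'
#' @param forward,backward Numeric arrays `rows x cols x sections` (a matrix
#'   is promoted to one section); identical shape, intensities >= 0.
#' @param pixel_size um per pixel (default 170/512, the 170-um field at
#'   512 px).
#' @param section_spacing um between optical sections (default 1).
#' @param depth_offset Depth (um, from the backward-collection face) of the
#'   first retained section.
#' @param metadata Free-form list (acquisition notes, provenance).
#' @return An object of class `image_stack_pair`.
#' @export
image_stack_pair <- function(forward, backward, pixel_size = 170 / 512,
                             section_spacing = 1, depth_offset = 0,
                             metadata = list()) {
  if (is.matrix(forward)) forward <- array(forward, c(dim(forward), 1))
  if (is.matrix(backward)) backward <- array(backward, c(dim(backward), 1))
  stopifnot(is.array(forward), is.array(backward),
            length(dim(forward)) == 3,
            identical(dim(forward), dim(backward)),
            pixel_size > 0, section_spacing > 0, depth_offset >= 0)
  if (any(forward < 0, na.rm = TRUE) || any(backward < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  structure(list(forward = forward, backward = backward,
                 pixel_size = pixel_size,
                 section_spacing = section_spacing,
                 depth_offset = depth_offset, metadata = metadata),
            class = "image_stack_pair")
}

#' @export
print.image_stack_pair <- function(x, ...) {
  d <- dim(x$forward)
  cat(sprintf(
    "Image stack pair: %d x %d px x %d sections, %.3f um/px, %g um spacing, depth offset %g um\n",
    d[1], d[2], d[3], x$pixel_size, x$section_spacing, x$depth_offset))
  invisible(x)
}

#' Preprocess a stack pair: trim, desaturate, denoise
#'
#' Drops the first and last `trim_sections` optical sections (boundary
#' effects), marks pixels at or above the saturation level in either
#' channel invalid (`NA`) in both, and optionally applies a 3x3 median
#' denoise identically to both channels. The depth offset advances by the
#' leading trim.
#'
#' @param pair An [image_stack_pair()].
#' @param saturation_level Counts at/above which a pixel is saturated (> 0).
#' @param noise_filter `"median3"` (default) or `"none"`.
#' @param trim_sections Sections to drop at each end (default 10).
#' @param background Dark-count level (counts) subtracted from both
#'   channels (clamped at zero); default 0. Dark counts contribute equally
#'   to F and B and drag low-signal patch ratios toward 1 if left in.
#' @return The preprocessed `image_stack_pair`.
#' @export
preprocess_stack <- function(pair, saturation_level = 4095,
                             noise_filter = c("median3", "none"),
                             trim_sections = 10, background = 0) {
  stopifnot(inherits(pair, "image_stack_pair"))
  noise_filter <- match.arg(noise_filter)
  if (saturation_level <= 0) stop("saturation_level must be positive")
  ns <- dim(pair$forward)[3]
  if (ns <= 2 * trim_sections)
    stop("stack has ", ns, " sections; need more than ", 2 * trim_sections,
         " to trim ", trim_sections, " from each end")
  keep <- if (trim_sections > 0)
    (trim_sections + 1):(ns - trim_sections) else seq_len(ns)
  fwd <- pair$forward[, , keep, drop = FALSE]
  bwd <- pair$backward[, , keep, drop = FALSE]
  sat <- (fwd >= saturation_level) | (bwd >= saturation_level)
  sat[is.na(sat)] <- TRUE
  fwd[sat] <- NA_real_
  bwd[sat] <- NA_real_
  if (noise_filter == "median3") {
    for (s in seq_len(dim(fwd)[3])) {
      fwd[, , s] <- .median3_cpp(fwd[, , s])
      bwd[, , s] <- .median3_cpp(bwd[, , s])
    }
  }
  if (background > 0) {
    fwd <- pmax(fwd - background, 0)
    bwd <- pmax(bwd - background, 0)
  }
  pair$forward <- fwd
  pair$backward <- bwd
  pair$depth_offset <- pair$depth_offset + trim_sections * pair$section_spacing
  pair
}

#' Apply the detector-path calibration
#'
#' Divides the forward channel by the calibration factor (the F/B
#' collection-efficiency ratio measured with isotropic emitters) so that an
#' isotropic source in a non-scattering mount yields measured F/B = 1.
#' Because the factor is a scalar, calibrating before or after patch
#' averaging is equivalent.
#'
#' @param pair An [image_stack_pair()].
#' @param geometry A [detection_geometry()] carrying `calibration_factor`.
#' @return The calibrated `image_stack_pair`.
#' @export
apply_calibration <- function(pair, geometry) {
  stopifnot(inherits(pair, "image_stack_pair"),
            inherits(geometry, "detection_geometry"))
  pair$forward <- pair$forward / geometry$calibration_factor
  pair$metadata$calibration_applied <- geometry$calibration_factor
  pair
}

#' Patch-wise channel means and measured F/B for one section
#'
#' Tiles the section into non-overlapping `patch_size`-square tiles from
#' the top-left (trailing partial rows/columns are discarded), averages
#' each channel over the valid (non-`NA`) pixels of each tile, and forms
#' the measured ratio mean(F)/mean(B) — the photon-count estimator, robust
#' to near-zero pixels. A tile is valid when at least `min_valid_fraction`
#' of its pixels are valid and its mean backward signal is positive.
#'
#' @param section_forward,section_backward 2-D intensity matrices.
#' @param patch_size Patch edge in px (default 30).
#' @param min_valid_fraction Minimum valid-pixel fraction per tile
#'   (default 0.5).
#' @param min_signal Minimum mean backward-channel signal (counts) for a
#'   tile to count as containing material (default 0: any positive signal).
#' @return A `patch_grid`: matrices `mean_forward`, `mean_backward`,
#'   `measured_fb` (NA where invalid) and logical `valid`.
#' @export
compute_patch_grid <- function(section_forward, section_backward,
                               patch_size = 30, min_valid_fraction = 0.5,
                               min_signal = 0) {
  stopifnot(is.matrix(section_forward),
            identical(dim(section_forward), dim(section_backward)),
            patch_size >= 1)
  nr <- nrow(section_forward); nc <- ncol(section_forward)
  if (patch_size > nr || patch_size > nc)
    stop("patch_size ", patch_size, " larger than image ", nr, "x", nc)
  pr <- nr %/% patch_size; pc <- nc %/% patch_size
  crop_f <- section_forward[seq_len(pr * patch_size),
                            seq_len(pc * patch_size), drop = FALSE]
  crop_b <- section_backward[seq_len(pr * patch_size),
                             seq_len(pc * patch_size), drop = FALSE]
  tile_stat <- function(m, fun) {
    a <- array(m, c(patch_size, pr, patch_size, pc))
    apply(a, c(2, 4), fun)
  }
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  mf <- tile_stat(crop_f, mean_na)
  mb <- tile_stat(crop_b, mean_na)
  frac_valid <- tile_stat(crop_f, function(v) mean(!is.na(v)))
  valid <- frac_valid >= min_valid_fraction & !is.na(mb) & mb > 0 &
    mb > min_signal
  fb <- ifelse(valid, mf / mb, NA_real_)
  structure(list(patch_size = patch_size, mean_forward = mf,
                 mean_backward = mb, measured_fb = fb, valid = valid),
            class = "patch_grid")
}

#' Extract local creation-ratio heat maps from a stack pair
#'
#' The pipeline's central product: for every optical section, patch-wise
#' measured F/B values are computed ([compute_patch_grid()]) and inverted
#' through the Monte Carlo lookup table at that section's depth
#' ([invert_measured_fb()]), yielding a per-section grid of local
#' F_SHG/B_SHG creation ratios with validity/clamp flags.
#'
#' @param pair A preprocessed, calibrated [image_stack_pair()].
#' @param table An `emission_lut`.
#' @param patch_size Patch edge in px (default 30).
#' @param min_valid_fraction,min_signal Passed to [compute_patch_grid()].
#' @return A `ratio_heatmap_stack`: array `ratios`
#'   (patch-rows x patch-cols x sections, NA where invalid), character
#'   array `flags` (`ok`, `clamped_low`, `clamped_high`, `invalid`),
#'   `depth_per_section`, `patch_size`, `mean_forward` array (per-patch
#'   forward intensity, for correlation analyses) and table `provenance`.
#' @export
extract_ratio_heatmaps <- function(pair, table, patch_size = 30,
                                   min_valid_fraction = 0.5,
                                   min_signal = 0) {
  stopifnot(inherits(pair, "image_stack_pair"),
            inherits(table, "emission_lut"))
  fp <- pair$metadata$lut_fingerprint
  if (!is.null(fp) && !identical(fp, table$optics_fingerprint))
    warning("stack metadata records lookup table ", fp,
            " but table is ", table$optics_fingerprint)
  ns <- dim(pair$forward)[3]
  depths <- pair$depth_offset + (seq_len(ns) - 1) * pair$section_spacing
  first <- compute_patch_grid(pair$forward[, , 1], pair$backward[, , 1],
                              patch_size, min_valid_fraction, min_signal)
  pr <- nrow(first$measured_fb); pc <- ncol(first$measured_fb)
  ratios <- array(NA_real_, c(pr, pc, ns))
  flags <- array("invalid", c(pr, pc, ns))
  mf <- array(NA_real_, c(pr, pc, ns))
  for (s in seq_len(ns)) {
    g <- if (s == 1) first else
      compute_patch_grid(pair$forward[, , s], pair$backward[, , s],
                         patch_size, min_valid_fraction, min_signal)
    mf[, , s] <- g$mean_forward
    idx <- which(g$valid)
    if (length(idx) > 0) {
      inv <- invert_measured_fb(g$measured_fb[idx], depths[s], table)
      rs <- matrix(NA_real_, pr, pc); fs <- matrix("invalid", pr, pc)
      rs[idx] <- inv$creation_ratio
      fs[idx] <- inv$flag
      ratios[, , s] <- rs
      flags[, , s] <- fs
    }
  }
  structure(list(ratios = ratios, flags = flags,
                 depth_per_section = depths, patch_size = patch_size,
                 mean_forward = mf,
                 provenance = table$optics_fingerprint),
            class = "ratio_heatmap_stack")
}

#' @export
print.ratio_heatmap_stack <- function(x, ...) {
  d <- dim(x$ratios)
  ok <- mean(x$flags == "ok")
  cat(sprintf(
    "Ratio heat-map stack: %d x %d patches x %d sections (patch %d px, %.0f%% ok, lut %s)\n",
    d[1], d[2], d[3], x$patch_size, 100 * ok, x$provenance))
  invisible(x)
}

#' Patch-size optimisation sweep
#'
#' Re-runs the heat-map extraction at several patch sizes and reports, per
#' size, the heat-map stack and the fraction of patches that fail (invalid:
#' too few valid pixels or no backward signal). Single-pixel "patches" are
#' dominated by Poisson noise and fail most often; the fraction falls with
#' patch size, motivating the default 30 px (~10 um), which spans whole
#' fiber structures.
#'
#' @param pair A preprocessed, calibrated [image_stack_pair()].
#' @param table An `emission_lut`.
#' @param sizes Integer patch sizes (default `c(1, 10, 20, 30, 50)`).
#' @param min_valid_fraction,min_signal Passed through.
#' @return A list with `heatmaps` (named list of `ratio_heatmap_stack`) and
#'   `fit_failure` data frame (`patch_size`, `failure_fraction`).
#' @export
patch_size_sweep <- function(pair, table, sizes = c(1, 10, 20, 30, 50),
                             min_valid_fraction = 0.5, min_signal = 0) {
  stopifnot(all(sizes >= 1))
  heatmaps <- list()
  fail <- numeric(length(sizes))
  for (k in seq_along(sizes)) {
    hm <- extract_ratio_heatmaps(pair, table, patch_size = sizes[k],
                                 min_valid_fraction = min_valid_fraction,
                                 min_signal = min_signal)
    heatmaps[[as.character(sizes[k])]] <- hm
    fail[k] <- mean(hm$flags == "invalid")
  }
  list(heatmaps = heatmaps,
       fit_failure = data.frame(patch_size = sizes, failure_fraction = fail))
}

#' Flatten a heat-map stack to a long-format data frame
#'
#' One row per patch per section with columns `section`, `row`, `col`,
#' `depth_um`, `ratio`, `flag` — the CSV export view.
#'
#' @param x A `ratio_heatmap_stack`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.ratio_heatmap_stack <- function(x, ...) {
  d <- dim(x$ratios)
  data.frame(section = rep(seq_len(d[3]), each = d[1] * d[2]),
             row = rep(rep(seq_len(d[1]), times = d[2]), times = d[3]),
             col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
             depth_um = rep(x$depth_per_section, each = d[1] * d[2]),
             ratio = as.vector(x$ratios),
             flag = as.vector(x$flags))
}
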