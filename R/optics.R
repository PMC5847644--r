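#' Optical properties of a tissue slab
#'
#' Bulk optical properties at the SHG wavelength (494 nm) used by the Monte
#' Carlo transport model. Scattering is parameterised by the reduced
#' scattering coefficient `mu_s_reduced` (mm^-1) and the Henyey-Greenstein
#' anisotropy `g`; the full scattering coefficient is derived as
#' `mu_s = mu_s_reduced / (1 - g)`. Absorption is negligible in ovarian
#' stroma at this wavelength and defaults to zero.
#'
#' @param mu_s_reduced Reduced scattering coefficient mu_s' in mm^-1 (>= 0).
#' @param anisotropy_g Scattering anisotropy (mean cosine), in `[0, 1)`.
#' @param refractive_index Tissue refractive index (> 1).
#' @param mu_a Absorption coefficient in mm^-1 (>= 0, default 0).
#' @param thickness Slab thickness in micrometres (> 0).
#' @return An object of class `optical_properties`.
#' @examples
#' optical_properties(mu_s_reduced = 2, anisotropy_g = 0.9,
#'                    refractive_index = 1.4, thickness = 150)
#' @export
optical_properties <- function(mu_s_reduced = 2.0, anisotropy_g = 0.9,
                               refractive_index = 1.4, mu_a = 0.0,
                               thickness = 150) {
  stopifnot(is.numeric(mu_s_reduced), length(mu_s_reduced) == 1L,
            mu_s_reduced >= 0,
            is.numeric(anisotropy_g), anisotropy_g >= 0, anisotropy_g < 1,
            is.numeric(refractive_index), refractive_index > 1,
            is.numeric(mu_a), mu_a >= 0,
            is.numeric(thickness), thickness > 0)
  mu_s <- mu_s_reduced / (1 - anisotropy_g)
  if (!is.finite(mu_s)) stop("derived mu_s is not finite")
  structure(list(mu_s_reduced = mu_s_reduced,
                 anisotropy_g = anisotropy_g,
                 refractive_index = refractive_index,
                 mu_a = mu_a,
                 thickness = thickness),
            class = "optical_properties")
}

#' Detection geometry of the forward/backward collection paths
#'
#' The forward (condenser-side) and backward (objective-side) collection
#' numerical apertures, the immersion index, and the detector calibration
#' factor: the F/B collection-efficiency ratio measured with isotropic
#' emitters (fluorescent microspheres), used to baseline the two detection
#' paths so that an isotropic source yields measured F/B = 1.
#'
#' @param forward_na Forward (condenser) collection NA, default 0.9.
#' @param backward_na Backward (objective) collection NA, default 0.8.
#' @param immersion_index Index of the immersion/mounting medium
#'   (water, 1.33).
#' @param calibration_factor F-path/B-path collection-efficiency ratio (> 0).
#' @return An object of class `detection_geometry`.
#' @export
detection_geometry <- function(forward_na = 0.9, backward_na = 0.8,
                               immersion_index = 1.33,
                               calibration_factor = 1.0) {
  stopifnot(forward_na > 0, forward_na < immersion_index,
            backward_na > 0, backward_na < immersion_index,
            calibration_factor > 0)
  structure(list(forward_na = forward_na, backward_na = backward_na,
                 immersion_index = immersion_index,
                 calibration_factor = calibration_factor),
            class = "detection_geometry")
}

#' Monte Carlo simulation configuration
#'
#' The inversion grid of candidate creation ratios spans 1 to 20 in 0.3
#' increments (64 values, 1.0 to 19.9); depths default to a 1-um grid over
#' the slab when the table is built. `emission_half_angle` is the half-angle
#' (radians, tissue side) of the launch cone about the +/- z axis; `NA`
#' (the default) derives it from the excitation NA via NA invariance,
#' `asin(backward_na / refractive_index)`, which keeps ballistic photons
#' inside both acceptance cones.
#'
#' @param photons_per_condition Photons per (ratio, depth) grid node
#'   (>= 1000; default 1e5).
#' @param rng_seed Integer root seed; per-condition streams are derived
#'   deterministically from it.
#' @param ratio_grid Strictly increasing creation-ratio grid (all >= 1).
#' @param depth_grid Depth grid in um, or `NULL` for 1-um spacing over the
#'   slab at table-build time.
#' @param emission_half_angle Launch cone half-angle in radians, or `NA` to
#'   derive from the detection geometry and tissue index.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(photons_per_condition = 1e5, rng_seed = 1L,
                      ratio_grid = seq(1, 19.9, by = 0.3),
                      depth_grid = NULL,
                      emission_half_angle = NA_real_) {
  stopifnot(photons_per_condition >= 1e3,
            all(diff(ratio_grid) > 0), all(ratio_grid >= 1))
  if (!is.null(depth_grid)) {
    stopifnot(all(depth_grid >= 0), !is.unsorted(depth_grid))
  }
  structure(list(photons_per_condition = as.numeric(photons_per_condition),
                 rng_seed = as.integer(rng_seed),
                 ratio_grid = as.numeric(ratio_grid),
                 depth_grid = depth_grid,
                 emission_half_angle = emission_half_angle),
            class = "mc_config")
}

# tissue-side launch cone half-angle: NA-invariant image of the excitation
# aperture (n sin(theta) conserved across the planar interface)
launch_half_angle <- function(config, optics, geometry) {
  if (is.finite(config$emission_half_angle)) return(config$emission_half_angle)
  asin(geometry$backward_na / optics$refractive_index)
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "Optical properties: mu_s' = %g mm^-1, g = %g, n = %g, mu_a = %g mm^-1, thickness = %g um\n",
    x$mu_s_reduced, x$anisotropy_g, x$refractive_index, x$mu_a, x$thickness))
  invisible(x)
}

#' @export
print.detection_geometry <- function(x, ...) {
  cat(sprintf(
    "Detection geometry: forward NA %g / backward NA %g (immersion n = %g), calibration factor %g\n",
    x$forward_na, x$backward_na, x$immersion_index, x$calibration_factor))
  invisible(x)
}

# stable fingerprint of the simulation conditions, recorded in tables and
# heat-map provenance
optics_fingerprint <- function(optics, geometry, config) {
  key <- list(optics = unclass(optics), geometry = unclass(geometry),
              config = unclass(config)[c("photons_per_condition", "rng_seed",
                                         "ratio_grid", "depth_grid",
                                         "emission_half_angle")])
  json <- jsonlite::toJSON(key, digits = NA, auto_unbox = TRUE, null = "null")
  # small FNV-1a style hash; stability across sessions matters, crypto does not
  bytes <- utf8ToInt(as.character(json))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("optics-%08x", as.integer(h))
}
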