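#' Phase-matching parameters for the sinc SHG intensity model
#'
#' Under relaxed phase matching the second-harmonic field generated over an
#' interaction length L with wavevector mismatch dk is
#' `E_2w = kappa * E_w^2 * sinc(dk * L / 2)` with `sinc(x) = sin(x)/x`:
#' smaller mismatch gives brighter and more forward-directed SHG. kappa and
#' the fundamental amplitude are arbitrary-unit constants; only ratios and
#' correlations are used downstream.
#'
#' @param delta_k Wavevector mismatch in rad/um (may be negative).
#' @param interaction_length_L Interaction length in um (> 0); in the
#'   synthetic generator this is the local fiber width.
#' @param kappa Amplitude constant (arbitrary units).
#' @param e_omega Fundamental field amplitude (arbitrary units, >= 0).
#' @param lambda_shg SHG wavelength in nm (494).
#' @return An object of class `phase_match_params`.
#' @export
phase_match_params <- function(delta_k, interaction_length_L, kappa = 1,
                               e_omega = 1, lambda_shg = 494) {
  stopifnot(interaction_length_L > 0, e_omega >= 0, lambda_shg > 0)
  structure(list(delta_k = delta_k,
                 interaction_length_L = interaction_length_L,
                 kappa = kappa, e_omega = e_omega, lambda_shg = lambda_shg),
            class = "phase_match_params")
}

# sin(x)/x with the removable singularity handled
sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

#' Second-harmonic field amplitude and intensity
#'
#' Evaluates `E_2w = kappa * E_w^2 * sinc(dk L / 2)`; the intensity is the
#' squared amplitude. Vectorised over `delta_k`.
#'
#' @param params A [phase_match_params()] object.
#' @return Numeric amplitude(s) `E_2w`.
#' @examples
#' p <- phase_match_params(delta_k = 0, interaction_length_L = 2)
#' shg_field(p) # kappa * E_w^2 = 1
#' @export
shg_field <- function(params) {
  stopifnot(inherits(params, "phase_match_params"))
  x <- params$delta_k * params$interaction_length_L / 2
  params$kappa * params$e_omega^2 * sinc(x)
}

#' @rdname shg_field
#' @export
shg_intensity <- function(params) shg_field(params)^2

#' Monotone map from phase mismatch to creation ratio
#'
#' The physics fixes only the qualitative shape: zero mismatch gives the
#' most forward-directed emission, large mismatch approaches isotropy
#' (ratio 1). The default map is the simplest monotone form,
#' `ratio(|dk|) = 1 + (r_max - 1) * exp(-|dk| / decay)`, with the decay
#' constant calibrated by the synthetic generator so class-mean mismatches
#' reproduce the target class-mean ratios.
#'
#' @param r_max Ratio at zero mismatch (upper bound; default 19.9, the top
#'   of the inversion grid).
#' @param decay Exponential decay constant in rad/um (> 0).
#' @return An object of class `directionality_map`.
#' @export
directionality_map <- function(r_max = 19.9, decay = 0.5) {
  stopifnot(r_max > 1, decay > 0)
  structure(list(r_max = r_max, decay = decay, ratio_bounds = c(1, r_max)),
            class = "directionality_map")
}

#' Convert |dk| values to creation ratios
#'
#' @param abs_dk Absolute phase mismatch(es), rad/um (>= 0); vectorised.
#' @param map A [directionality_map()].
#' @return Creation ratio(s) in `[1, r_max]`, nonincreasing in `abs_dk`.
#' @export
dk_to_creation_ratio <- function(abs_dk, map = directionality_map()) {
  stopifnot(inherits(map, "directionality_map"))
  if (any(abs_dk < 0)) stop("abs_dk must be nonnegative")
  1 + (map$r_max - 1) * exp(-abs_dk / map$decay)
}

#' Predicted correlation between SHG intensity and creation ratio
#'
#' For a sample of dk values, computes the sinc-model intensity and the
#' mapped creation ratio and returns their Pearson correlation. Narrow dk
#' distributions (uniform fibril size/packing) stay inside the monotone
#' sinc lobe where both quantities fall together with mismatch, giving r
#' near 1; wide distributions cross sinc zeros and decorrelate — the
#' theoretical analogue of the tissue-class ordering of heat-map/intensity
#' correlations.
#'
#' @param dk_samples Numeric vector of dk values (>= 3, non-constant).
#' @param params A [phase_match_params()]; its `delta_k` is ignored in
#'   favour of `dk_samples`.
#' @param map A [directionality_map()].
#' @return Pearson correlation coefficient.
#' @export
predicted_intensity_ratio_correlation <- function(dk_samples, params, map) {
  if (length(dk_samples) < 3) stop("need at least 3 dk samples")
  if (stats::sd(dk_samples) == 0)
    stop("zero-variance dk samples: correlation undefined")
  p <- params
  p$delta_k <- dk_samples
  intensity <- shg_intensity(p)
  ratio <- dk_to_creation_ratio(abs(dk_samples), map)
  if (stats::sd(intensity) == 0 || stats::sd(ratio) == 0)
    stop("zero variance in intensity or ratio: correlation undefined")
  stats::cor(intensity, ratio)
}
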