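#' Simulate SHG emission and transport for one condition
#'
#' Launches photons at a given depth inside the slab with forward/backward
#' probabilities `r/(1+r)` and `1/(1+r)` (the creation ratio r), propagates
#' them through Henyey-Greenstein scattering, and scores the fractions
#' collected by the NA-limited forward and backward detectors (Snell
#' refraction applied at the exit face). Absorption is handled by weight
#' attenuation, so photon weight is conserved exactly:
#' collected_F + collected_B + escaped + absorbed = launched.
#'
#' @param depth Emission depth in um from the backward (objective-side)
#'   face, in `[0, thickness]`.
#' @param creation_ratio Intrinsic F_SHG/B_SHG creation ratio (>= 1).
#' @param optics [optical_properties()].
#' @param geometry [detection_geometry()].
#' @param config [mc_config()]; `photons_per_condition` and `rng_seed` are
#'   used here.
#' @param stream Integer pair identifying the RNG stream (used internally by
#'   [build_lookup_table()] so each grid node has its own deterministic
#'   stream); leave default for one-off calls.
#' @return List with collected fractions `collected_forward`,
#'   `collected_backward`, their binomial standard errors, the measured
#'   ratio `measured_fb` with `se`, and the weight ledger
#'   (`escaped`, `absorbed`, `launched`).
#' @seealso [simulate_emission_reference()] for the naive per-photon R
#'   implementation used as an independent oracle.
#' @export
simulate_emission <- function(depth, creation_ratio, optics, geometry,
                              config = mc_config(), stream = c(0L, 0L)) {
  stopifnot(inherits(optics, "optical_properties"),
            inherits(geometry, "detection_geometry"),
            inherits(config, "mc_config"))
  if (!is.finite(depth) || depth < 0 || depth > optics$thickness)
    stop("depth outside slab [0, ", optics$thickness, "] um")
  if (!is.finite(creation_ratio) || creation_ratio < 1)
    stop("creation_ratio below the grid floor of 1")

  mus_um <- optics$mu_s_reduced / (1 - optics$anisotropy_g) / 1000 # mm^-1 -> um^-1
  mua_um <- optics$mu_a / 1000
  half <- launch_half_angle(config, optics, geometry)
  seed <- condition_seed(config$rng_seed, stream[1], stream[2])
  raw <- .mc_transport_cpp(depth, creation_ratio, mus_um,
                           optics$anisotropy_g, optics$refractive_index,
                           mua_um, optics$thickness,
                           geometry$forward_na, geometry$backward_na,
                           cos(half), config$photons_per_condition, seed)
  n <- raw[5]
  pF <- raw[1] / n
  pB <- raw[2] / n
  seF <- sqrt(pmax(pF * (1 - pF), 0) / n)
  seB <- sqrt(pmax(pB * (1 - pB), 0) / n)
  fb <- if (raw[2] > 0) raw[1] / raw[2] else Inf
  # delta-method SE of the ratio of multinomial fractions; the -2cov term
  # (cov(pF, pB) = -pF pB / n) adds +2/n in relative variance
  fb_se <- if (raw[2] > 0 && raw[1] > 0)
    fb * sqrt((seF / pF)^2 + (seB / pB)^2 + 2 / n) else Inf
  list(collected_forward = pF, collected_backward = pB,
       se_forward = seF, se_backward = seB,
       measured_fb = fb, se = fb_se,
       escaped = raw[3] / n, absorbed = raw[4] / n, launched = 1)
}

# deterministic 64-bit-safe stream seed per grid node; offsets stay far below
# the 2^20 stream spacing (<= 64 ratios x <= ~1000 depths)
condition_seed <- function(root, i, j) {
  as.numeric(root) * 2^20 + as.numeric(i) * 1024 + as.numeric(j)
}

#' Naive per-photon reference transport loop (oracle)
#'
#' A deliberately plain R implementation of the same slab transport model,
#' written independently of the production C++ core and driven by R's own
#' RNG. It is slow and intended only as a cross-check at small photon
#' counts: the production core must agree with it within combined Monte
#' Carlo error.
#'
#' @inheritParams simulate_emission
#' @param n_photons Number of photons to trace.
#' @return Same structure as [simulate_emission()].
#' @export
simulate_emission_reference <- function(depth, creation_ratio, optics,
                                        geometry, config = mc_config(),
                                        n_photons = 2000) {
  stopifnot(depth >= 0, depth <= optics$thickness, creation_ratio >= 1)
  mus <- optics$mu_s_reduced / (1 - optics$anisotropy_g) / 1000
  mua <- optics$mu_a / 1000
  mut <- mus + mua
  g <- optics$anisotropy_g
  n_t <- optics$refractive_index
  Tk <- optics$thickness
  cos_half <- cos(launch_half_angle(config, optics, geometry))
  p_fwd <- creation_ratio / (1 + creation_ratio)

  nF <- 0; nB <- 0; esc <- 0; absb <- 0
  for (ph in seq_len(n_photons)) {
    ct <- cos_half + (1 - cos_half) * runif(1)
    st <- sqrt(1 - ct^2)
    phi <- 2 * pi * runif(1)
    dir <- c(st * cos(phi), st * sin(phi),
             if (runif(1) < p_fwd) ct else -ct)
    z <- depth
    w <- 1
    repeat {
      s <- if (mut > 0) -log(runif(1)) / mut else 2 * Tk + 1
      zn <- z + dir[3] * s
      if (dir[3] > 0 && zn >= Tk) {
        sin_in <- sqrt(max(0, 1 - dir[3]^2))
        if (n_t * sin_in <= geometry$forward_na) nF <- nF + w else esc <- esc + w
        break
      }
      if (dir[3] < 0 && zn <= 0) {
        sin_in <- sqrt(max(0, 1 - dir[3]^2))
        if (n_t * sin_in <= geometry$backward_na) nB <- nB + w else esc <- esc + w
        break
      }
      z <- zn
      if (mua > 0) {
        absb <- absb + w * mua / mut
        w <- w * mus / mut
        if (w < 1e-12) { absb <- absb + w; break }
      }
      # Henyey-Greenstein deflection, rotated into the photon frame via an
      # explicit orthonormal basis (independent of the MCML-style update)
      u <- runif(1)
      cth <- if (g < 1e-12) 2 * u - 1 else {
        f <- (1 - g^2) / (1 - g + 2 * g * u)
        max(-1, min(1, (1 + g^2 - f^2) / (2 * g)))
      }
      sth <- sqrt(1 - cth^2)
      ph2 <- 2 * pi * runif(1)
      a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a - sum(a * dir) * dir
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      dir <- cth * dir + sth * (cos(ph2) * e1 + sin(ph2) * e2)
      dir <- dir / sqrt(sum(dir^2))
      if (dir[3] == 0) dir[3] <- 1e-12
    }
  }
  pF <- nF / n_photons; pB <- nB / n_photons
  seF <- sqrt(max(pF * (1 - pF), 0) / n_photons)
  seB <- sqrt(max(pB * (1 - pB), 0) / n_photons)
  fb <- if (nB > 0) nF / nB else Inf
  fb_se <- if (nB > 0 && nF > 0)
    fb * sqrt((seF / pF)^2 + (seB / pB)^2 + 2 / n_photons) else Inf
  list(collected_forward = pF, collected_backward = pB,
       se_forward = seF, se_backward = seB,
       measured_fb = fb, se = fb_se,
       escaped = esc / n_photons, absorbed = absb / n_photons, launched = 1)
}

#' Build the emission-ratio lookup table
#'
#' Runs the forward Monte Carlo model over the full creation-ratio grid
#' (default 1 to 19.9 in 0.3 increments, 64 values) and depth grid (default
#' 1-um spacing through the slab) and stores the measured (collected) F/B
#' ratio and its standard error at every node. The table is the instrument
#' model inverted by [invert_measured_fb()]. Measured F/B must be
#' nondecreasing in the creation ratio at every depth; violations beyond
#' 3 combined standard errors abort with advice to raise the photon count.
#'
#' @inheritParams simulate_emission
#' @return An `emission_lut` object: `ratio_axis`, `depth_axis`,
#'   `measured_fb` and `standard_errors` matrices (ratio x depth), and the
#'   `optics_fingerprint` of the conditions that produced it.
#' @export
build_lookup_table <- function(optics, geometry, config = mc_config()) {
  depth_grid <- config$depth_grid
  if (is.null(depth_grid)) depth_grid <- seq(0, optics$thickness, by = 1)
  stopifnot(all(depth_grid >= 0), all(depth_grid <= optics$thickness))
  ratios <- config$ratio_grid
  fb <- matrix(NA_real_, length(ratios), length(depth_grid))
  se <- matrix(NA_real_, length(ratios), length(depth_grid))
  for (j in seq_along(depth_grid)) {
    for (i in seq_along(ratios)) {
      sim <- simulate_emission(depth_grid[j], ratios[i], optics, geometry,
                               config, stream = c(i, j))
      fb[i, j] <- sim$measured_fb
      se[i, j] <- sim$se
    }
  }
  # monotonicity gate: a true decrease signals an under-sampled or broken
  # simulation. The per-pair threshold is 3 combined SEs, raised for the
  # number of comparisons in the table so the expected false-alarm rate
  # stays ~1e-3 per build (a plain 3-SE gate would misfire on ~1 in 750
  # healthy pairs by chance alone).
  n_pairs <- (length(ratios) - 1) * length(depth_grid)
  z_thr <- max(3, stats::qnorm(1 - 0.00135 / n_pairs))
  for (j in seq_along(depth_grid)) {
    d <- diff(fb[, j])
    tol <- z_thr * sqrt(se[-1, j]^2 + se[-length(ratios), j]^2)
    bad <- which(d < -tol)
    if (length(bad) > 0)
      stop("measured F/B not monotone in creation ratio at depth ",
           depth_grid[j], " um (beyond MC error); increase photons_per_condition")
  }
  cfg <- config
  cfg$depth_grid <- depth_grid
  lut <- structure(
    list(ratio_axis = ratios, depth_axis = depth_grid,
         measured_fb = fb, standard_errors = se,
         optics_fingerprint = optics_fingerprint(optics, geometry, cfg)),
    class = "emission_lut")
  lut$mixing_coefs <- vapply(seq_along(depth_grid),
                             function(j) fit_mixing_column(lut, j),
                             numeric(4))
  lut
}

# Transport is linear in the up/down launch components, so the measured
# ratio is exactly Moebius in the creation ratio:
#   fb(r) = (A r + B) / (C r + D),
# with A, B (C, D) the forward (backward) collection probabilities for
# up- and down-launched photons. Fitting this 4-parameter model to the
# grid pools the Monte Carlo noise of all 64 nodes; the fit is solved as
# the null vector of the weighted homogeneous system
#   A r + B - fb C r - fb D = 0.
fit_mixing_column <- function(table, j) {
  r <- table$ratio_axis
  fb <- table$measured_fb[, j]
  se <- table$standard_errors[, j]
  ok <- is.finite(fb) & is.finite(se)
  w <- if (all(se[ok] == 0)) rep(1, sum(ok)) else
    1 / pmax(se[ok], min(se[ok][se[ok] > 0]) / 10)
  M <- cbind(r[ok], 1, -fb[ok] * r[ok], -fb[ok]) * w
  # null vector via the normal matrix (works for any number of grid nodes)
  e <- eigen(crossprod(M), symmetric = TRUE)
  v <- e$vectors[, 4]
  if (v[1] < 0) v <- -v
  v
}

# expected measured F/B at arbitrary creation ratios for one depth column
mixing_forward <- function(coefs, r)
  (coefs[1] * r + coefs[2]) / (coefs[3] * r + coefs[4])

# analytic inverse of the mixing model
mixing_inverse <- function(coefs, fb)
  (coefs[4] * fb - coefs[2]) / (coefs[1] - coefs[3] * fb)

# per-depth coefficients, fitted on demand for tables built elsewhere
lut_mixing <- function(table, j) {
  if (!is.null(table$mixing_coefs)) return(table$mixing_coefs[, j])
  fit_mixing_column(table, j)
}

#' @export
print.emission_lut <- function(x, ...) {
  cat(sprintf(
    "Emission lookup table: %d ratios [%g..%g] x %d depths [%g..%g um] (%s)\n",
    length(x$ratio_axis), min(x$ratio_axis), max(x$ratio_axis),
    length(x$depth_axis), min(x$depth_axis), max(x$depth_axis),
    x$optics_fingerprint))
  invisible(x)
}

#' Invert a measured F/B ratio to a creation ratio
#'
#' Selects the table column nearest the requested depth and inverts the
#' measured-F/B-versus-creation-ratio relation through the fitted
#' two-component mixing model: transport is linear in the up/down launch
#' components, so `fb(r) = (Ar+B)/(Cr+D)` exactly, and the fit pools the
#' Monte Carlo noise of the whole ratio grid (a single-node
#' piecewise-linear inversion would carry the full node noise divided by
#' the local slope). Values outside the tabulated range clamp to the grid
#' ends and are flagged.
#'
#' @param measured_fb Measured (calibrated) F/B value(s); vectorised.
#' @param depth Emission depth in um (single value).
#' @param table An `emission_lut` from [build_lookup_table()].
#' @return List with numeric `creation_ratio` and character `flag`
#'   (`"ok"`, `"clamped_low"`, `"clamped_high"`), each the length of
#'   `measured_fb`.
#' @export
invert_measured_fb <- function(measured_fb, depth, table) {
  stopifnot(inherits(table, "emission_lut"))
  if (length(table$ratio_axis) == 0) stop("empty lookup table")
  if (length(depth) != 1 || !is.finite(depth)) stop("depth must be one finite value")
  spacing <- if (length(table$depth_axis) > 1)
    max(diff(table$depth_axis)) else 1
  if (depth < min(table$depth_axis) - spacing ||
      depth > max(table$depth_axis) + spacing)
    stop("depth ", depth, " um outside table depth range")
  if (any(!is.finite(measured_fb)))
    stop("measured_fb must be finite")
  if (any(measured_fb < 0)) stop("measured_fb must be nonnegative")

  j <- which.min(abs(table$depth_axis - depth))
  coefs <- lut_mixing(table, j)
  ratios <- table$ratio_axis
  lo <- mixing_forward(coefs, ratios[1])
  hi <- mixing_forward(coefs, ratios[length(ratios)])
  eps <- 1e-9 * max(1, hi)
  flag <- rep("ok", length(measured_fb))
  flag[measured_fb < lo - eps] <- "clamped_low"
  flag[measured_fb > hi + eps] <- "clamped_high"
  x <- pmin(pmax(measured_fb, lo), hi)
  cr <- mixing_inverse(coefs, x)
  cr <- pmin(pmax(cr, ratios[1]), ratios[length(ratios)])
  list(creation_ratio = cr, flag = flag)
}

#' Save / load an emission lookup table
#'
#' The table is persisted as a single hierarchical JSON document holding the
#' axes, value and standard-error matrices at full floating-point precision,
#' and the optics fingerprint; the round trip is lossless.
#'
#' @param table An `emission_lut`.
#' @param path File path (`.json`).
#' @return `save_lut` returns `path` invisibly; `read_lut` the table.
#' @export
save_lut <- function(table, path) {
  stopifnot(inherits(table, "emission_lut"))
  obj <- list(ratio_axis = table$ratio_axis, depth_axis = table$depth_axis,
              measured_fb = table$measured_fb,
              standard_errors = table$standard_errors,
              mixing_coefs = table$mixing_coefs,
              optics_fingerprint = table$optics_fingerprint)
  # I(17) = 17 significant digits: exact round trip for IEEE doubles
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_lut
#' @export
read_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lut <- structure(
    list(ratio_axis = as.numeric(obj$ratio_axis),
         depth_axis = as.numeric(obj$depth_axis),
         measured_fb = matrix(as.numeric(obj$measured_fb),
                              nrow = length(obj$ratio_axis)),
         standard_errors = matrix(as.numeric(obj$standard_errors),
                                  nrow = length(obj$ratio_axis)),
         optics_fingerprint = obj$optics_fingerprint),
    class = "emission_lut")
  if (!is.null(obj$mixing_coefs))
    lut$mixing_coefs <- matrix(as.numeric(obj$mixing_coefs), nrow = 4)
  lut
}

#' Export a lookup table as a long-format data frame
#'
#' One row per (ratio, depth) node with columns `ratio`, `depth_um`, `fb`,
#' `se` — the CSV-friendly view of the table.
#'
#' @param x An `emission_lut`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.emission_lut <- function(x, ...) {
  data.frame(ratio = rep(x$ratio_axis, times = length(x$depth_axis)),
             depth_um = rep(x$depth_axis, each = length(x$ratio_axis)),
             fb = as.vector(x$measured_fb),
             se = as.vector(x$standard_errors))
}

# measured F/B expected at arbitrary (creation ratio, depth) through the
# fitted mixing model: the forward direction of the table, used by the
# synthetic renderer
lut_forward <- function(table, creation_ratio, depth) {
  j <- which.min(abs(table$depth_axis - depth))
  r <- pmin(pmax(creation_ratio, min(table$ratio_axis)),
            max(table$ratio_axis))
  mixing_forward(lut_mixing(table, j), r)
}
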