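#' Assemble a run configuration
#'
#' Collects every knob of the end-to-end analysis into one validated list:
#' tissue profiles, cohort size, image geometry, Monte Carlo settings, the
#' directionality map, patch size and preprocessing thresholds, and the
#' root seed. A frozen copy travels with every report for provenance.
#'
#' @param profiles Named list of [tissue_profile()] objects.
#' @param n_volumes_per_class Volumes per class.
#' @param shape Image `c(rows, cols)` px.
#' @param n_sections Sections per stack.
#' @param mean_counts Mean fiber-pixel counts (Poisson level).
#' @param noise Add shot noise.
#' @param patch_size Heat-map patch edge, px.
#' @param trim_sections Sections trimmed at each stack end during
#'   preprocessing (default 0: synthetic stacks have no boundary
#'   artifacts; use 10 for instrument-style stacks).
#' @param saturation_level Saturation threshold in counts.
#' @param noise_filter `"median3"` or `"none"`.
#' @param geometry [detection_geometry()].
#' @param mc [mc_config()] used to build the lookup table when none is
#'   supplied.
#' @param map [directionality_map()].
#' @param seed Root seed; all child seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(profiles = default_profiles(),
                       n_volumes_per_class = 3, shape = c(256, 256),
                       n_sections = 64, mean_counts = 200, noise = TRUE,
                       patch_size = 30, trim_sections = 0,
                       saturation_level = 1e9, noise_filter = "none",
                       geometry = detection_geometry(),
                       mc = mc_config(), map = directionality_map(),
                       seed = 1) {
  stopifnot(length(profiles) >= 1, n_volumes_per_class >= 1,
            all(shape >= 64), n_sections >= 1, patch_size >= 1)
  structure(list(profiles = profiles,
                 n_volumes_per_class = n_volumes_per_class, shape = shape,
                 n_sections = n_sections, mean_counts = mean_counts,
                 noise = noise, patch_size = patch_size,
                 trim_sections = trim_sections,
                 saturation_level = saturation_level,
                 noise_filter = noise_filter, geometry = geometry,
                 mc = mc, map = map, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full local-directionality analysis on a synthetic cohort
#'
#' The composition of the whole workflow: build (or accept) the Monte Carlo
#' lookup table; for each class and volume generate a fiber field, assign
#' phase mismatches and ground-truth creation ratios, render the
#' forward/backward stack, preprocess and calibrate it, extract the local
#' creation-ratio heat maps, and accumulate heterogeneity, correlation,
#' fiber-width and GLCM statistics. Volumes are processed one at a time so
#' memory stays bounded. Deterministic for a fixed config and seed.
#'
#' @param config A [run_config()].
#' @param table Optional prebuilt `emission_lut`; built from
#'   `config$mc` and the first profile's optics when `NULL`.
#' @param keep_heatmaps Keep the per-volume heat-map stacks in the report
#'   (default TRUE; they are small).
#' @return An `shg_report` list: `heterogeneity` (Table-1-style volume and
#'   group summaries), `ratio_tests` (pairwise t-tests on volume mean
#'   ratios), `correlations` (per-volume mean Pearson r and group
#'   summary with pairwise tests), `fiber_widths` (per-group width
#'   summary + tests), `glcm` (per-volume texture features),
#'   `ground_truth` (per-volume realized generator moments), `heatmaps`,
#'   `config`, and `lut_fingerprint`.
#' @export
run_full_analysis <- function(config, table = NULL, keep_heatmaps = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(table)) {
    optics <- config$profiles[[1]]$optics
    mc <- config$mc
    if (is.null(mc$depth_grid)) {
      max_depth <- (config$n_sections - 1) * 1 + 1
      mc$depth_grid <- seq(0, min(optics$thickness, max_depth), length.out = 20)
    }
    table <- build_lookup_table(optics, config$geometry, mc)
  }
  heatmaps <- list()
  groups <- character()
  vol_rows <- list()
  widths_all <- numeric(); widths_grp <- character()
  glcm_rows <- list()
  corr_means <- numeric(); corr_ses <- numeric()
  k <- 0L
  for (cls in names(config$profiles)) {
    profile <- config$profiles[[cls]]
    for (v in seq_len(config$n_volumes_per_class)) {
      k <- k + 1L
      child <- cohort_child_seed(config$seed, k)
      vol <- generate_volume(profile, config$shape, config$n_sections,
                             table, config$geometry, config$map, child,
                             config$mean_counts, config$noise)
      # dark-frame handling: the renderer adds 1% of mean_counts as dark
      # level; subtract it and require patches to carry real signal
      dark <- 0.01 * config$mean_counts
      pair <- preprocess_stack(vol$pair, config$saturation_level,
                               config$noise_filter, config$trim_sections,
                               background = dark)
      pair <- apply_calibration(pair, config$geometry)
      hm <- extract_ratio_heatmaps(pair, table, config$patch_size,
                                   min_signal = dark)
      heatmaps[[k]] <- hm
      groups[k] <- cls
      sc <- stack_correlation(hm)
      corr_means[k] <- sc$mean_r
      corr_ses[k] <- sc$se
      mid <- pair$forward[, , ceiling(dim(pair$forward)[3] / 2)]
      mask <- segment_fibers(mid)
      fw <- extract_fiber_widths(mask, pair$pixel_size)
      if (nrow(fw) > 0) {
        widths_all <- c(widths_all, fw$mean_width_um)
        widths_grp <- c(widths_grp, rep(cls, nrow(fw)))
      }
      gf <- glcm_features(mid)
      glcm_rows[[k]] <- data.frame(group = cls, volume = k,
                                   energy = gf$energy, entropy = gf$entropy,
                                   homogeneity = gf$homogeneity)
      vol_rows[[k]] <- data.frame(
        group = cls, volume = k, seed = child,
        truth_ratio_mean = sum_weighted_mean(vol$truth),
        truth_ratio_sd = sum_weighted_sd(vol$truth),
        dk_center = vol$truth$dk_center, dk_sd = vol$truth$dk_sd,
        density = vol$truth$density)
    }
  }
  het <- heterogeneity_summary(heatmaps, groups)
  ratio_tests <- pairwise_ttests(het$volumes$mean_ratio, het$volumes$group)
  corr <- group_correlations(corr_means, groups)
  fib <- if (length(widths_all) > 0)
    summarize_widths(widths_all, widths_grp) else NULL
  structure(list(
    heterogeneity = het,
    ratio_tests = ratio_tests,
    correlations = c(corr, list(
      volumes = data.frame(group = groups, volume = seq_along(corr_means),
                           mean_r = corr_means, se = corr_ses))),
    fiber_widths = fib,
    glcm = do.call(rbind, glcm_rows),
    ground_truth = do.call(rbind, vol_rows),
    heatmaps = if (keep_heatmaps) heatmaps else NULL,
    heatmap_groups = groups,
    config = config,
    lut_fingerprint = table$optics_fingerprint), class = "shg_report")
}

# pixel-weighted ground-truth moments of one volume (what the heat maps see)
sum_weighted_mean <- function(truth) {
  v <- truth$ratio_field[!is.na(truth$ratio_field)]
  mean(v)
}
sum_weighted_sd <- function(truth) {
  v <- truth$ratio_field[!is.na(truth$ratio_field)]
  stats::sd(v)
}

#' @export
print.shg_report <- function(x, ...) {
  cat("Local SHG directionality analysis report\n")
  cat("\nGroup mean F_SHG/B_SHG (Table-1 style):\n")
  print(x$heterogeneity$groups, row.names = FALSE)
  cat("\nGroup heat-map/intensity Pearson r (Fig.-5 style):\n")
  print(x$correlations$groups, row.names = FALSE)
  if (!is.null(x$fiber_widths)) {
    cat("\nFiber widths:\n")
    print(x$fiber_widths$summary, row.names = FALSE)
  }
  invisible(x)
}

#' Write the report tables as CSV files
#'
#' Exports the Table-1-style heterogeneity summary, the Fig.-5-style
#' correlation summary, pairwise tests, fiber widths, GLCM features, the
#' realized ground truth, and the long-format heat maps into a directory.
#'
#' @param report An `shg_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_report_csv <- function(report, dir) {
  stopifnot(inherits(report, "shg_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(df, name) {
    if (is.null(df)) return()
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE)
    files <<- c(files, f)
  }
  put(report$heterogeneity$groups, "heterogeneity_groups.csv")
  put(report$heterogeneity$volumes, "heterogeneity_volumes.csv")
  put(report$ratio_tests, "ratio_pairwise_tests.csv")
  put(report$correlations$groups, "correlation_groups.csv")
  put(report$correlations$volumes, "correlation_volumes.csv")
  put(report$correlations$tests, "correlation_pairwise_tests.csv")
  if (!is.null(report$fiber_widths)) {
    put(report$fiber_widths$summary, "fiber_width_summary.csv")
    put(report$fiber_widths$tests, "fiber_width_tests.csv")
  }
  put(report$glcm, "glcm_features.csv")
  put(report$ground_truth, "ground_truth.csv")
  if (!is.null(report$heatmaps)) {
    hm_long <- do.call(rbind, lapply(seq_along(report$heatmaps), function(i) {
      df <- as.data.frame(report$heatmaps[[i]])
      df$volume <- i
      df$group <- report$heatmap_groups[i]
      df
    }))
    put(hm_long, "heatmaps_long.csv")
  }
  invisible(files)
}
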