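#' Heterogeneity summary of creation-ratio heat maps
#'
#' Per volume: the mean and standard deviation of all valid (ok or clamped)
#' patch ratios through the image stack. Per group: the mean of volume
#' means +/- SE, and the mean of within-volume SDs +/- SE. The within-volume
#' SD is the heterogeneity metric: wide local F_SHG/B_SHG distributions mark
#' heterogeneous collagen remodeling.
#'
#' @param heatmaps List of `ratio_heatmap_stack` objects, one per volume.
#' @param groups Character/factor vector of group labels per volume.
#' @return List with `volumes` (one row per volume: `group`, `volume`,
#'   `mean_ratio`, `sd_ratio`, `n_patches`) and `groups` (one row per
#'   group: `group`, `mean_ratio`, `mean_ratio_se`, `within_volume_sd`,
#'   `within_volume_sd_se`, `n_volumes`).
#' @export
heterogeneity_summary <- function(heatmaps, groups) {
  stopifnot(length(heatmaps) == length(groups))
  groups <- as.character(groups)
  vols <- list()
  for (v in seq_along(heatmaps)) {
    hm <- heatmaps[[v]]
    stopifnot(inherits(hm, "ratio_heatmap_stack"))
    vals <- hm$ratios[hm$flags != "invalid" & !is.na(hm$ratios)]
    if (length(vals) == 0) {
      warning("volume ", v, " has no valid patches; excluded")
      next
    }
    vols[[length(vols) + 1]] <- data.frame(
      group = groups[v], volume = v, mean_ratio = mean(vals),
      sd_ratio = stats::sd(vals), n_patches = length(vals))
  }
  if (length(vols) == 0) stop("no volumes with valid patches")
  volumes <- do.call(rbind, vols)
  gs <- unique(volumes$group)
  grp <- do.call(rbind, lapply(gs, function(g) {
    sub <- volumes[volumes$group == g, ]
    n <- nrow(sub)
    se <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
    data.frame(group = g,
               mean_ratio = mean(sub$mean_ratio),
               mean_ratio_se = se(sub$mean_ratio),
               within_volume_sd = mean(sub$sd_ratio),
               within_volume_sd_se = se(sub$sd_ratio),
               n_volumes = n)
  }))
  list(volumes = volumes, groups = grp)
}

#' Pearson correlation of a heat map with intensity, per section
#'
#' Correlates the patch-wise creation-ratio matrix of one optical section
#' with the corresponding patch-reduced SHG intensity. Both matrices are
#' self-normalised (min-max to `[0, 1]`) per section before the
#' correlation; Pearson r is affine-invariant so this cannot change r, but
#' keeps exported maps comparable. If `intensity_image` is at full pixel
#' resolution it is reduced to per-patch means first.
#'
#' @param ratio_patches 2-D matrix of patch ratios (NA = invalid).
#' @param intensity_image 2-D intensity matrix, either already patch-sized
#'   or at pixel resolution.
#' @param patch_size Patch edge in px used for reduction (default 30).
#' @param normalization `"minmax_per_section"` (only option).
#' @return Pearson r in `[-1, 1]`, or `NA` when fewer than 3 valid patches
#'   or either matrix has zero variance over them.
#' @export
section_pearson <- function(ratio_patches, intensity_image, patch_size = 30,
                            normalization = "minmax_per_section") {
  stopifnot(is.matrix(ratio_patches), is.matrix(intensity_image))
  normalization <- match.arg(normalization, "minmax_per_section")
  if (!identical(dim(intensity_image), dim(ratio_patches))) {
    intensity_image <- reduce_to_patches(intensity_image, patch_size)
    if (!identical(dim(intensity_image), dim(ratio_patches)))
      stop("intensity image does not reduce to the heat-map grid")
  }
  ok <- !is.na(ratio_patches) & !is.na(intensity_image)
  if (sum(ok) < 3) return(NA_real_)
  r <- minmax(ratio_patches[ok])
  i <- minmax(intensity_image[ok])
  if (stats::sd(r) == 0 || stats::sd(i) == 0) return(NA_real_)
  stats::cor(r, i)
}

minmax <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

reduce_to_patches <- function(m, patch_size) {
  pr <- nrow(m) %/% patch_size; pc <- ncol(m) %/% patch_size
  a <- array(m[seq_len(pr * patch_size), seq_len(pc * patch_size)],
             c(patch_size, pr, patch_size, pc))
  apply(a, c(2, 4), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
}

#' Stack-level heat-map/intensity correlation
#'
#' Applies [section_pearson()] to every optical section of a heat-map
#' stack, using the stack's stored per-patch forward-channel intensity, and
#' averages the per-section coefficients.
#'
#' @param heatmaps A `ratio_heatmap_stack` (from [extract_ratio_heatmaps()],
#'   which records per-patch forward intensity).
#' @param pair Optional [image_stack_pair()]; when given, intensity is
#'   recomputed from its forward channel instead of the stored patch means.
#' @return List `per_section_r` (NA where undefined), `mean_r`, `se`
#'   (SE over sections), `n_sections`.
#' @export
stack_correlation <- function(heatmaps, pair = NULL) {
  stopifnot(inherits(heatmaps, "ratio_heatmap_stack"))
  ns <- dim(heatmaps$ratios)[3]
  rs <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    intensity <- if (is.null(pair)) heatmaps$mean_forward[, , s]
      else reduce_to_patches(pair$forward[, , s], heatmaps$patch_size)
    ratio <- heatmaps$ratios[, , s]
    ratio[heatmaps$flags[, , s] == "invalid"] <- NA_real_
    rs[s] <- section_pearson(ratio, intensity, heatmaps$patch_size)
  }
  good <- rs[!is.na(rs)]
  if (length(good) == 0) {
    warning("no section had a defined correlation")
    return(list(per_section_r = rs, mean_r = NA_real_, se = NA_real_,
                n_sections = 0L))
  }
  list(per_section_r = rs, mean_r = mean(good),
       se = if (length(good) > 1) stats::sd(good) / sqrt(length(good))
            else NA_real_,
       n_sections = length(good))
}

#' Group comparison of per-stack correlation means
#'
#' Aggregates per-stack mean Pearson coefficients by group (mean +/- SE
#' across stacks) and performs pairwise two-sample t-tests (Welch by
#' default) on the per-stack means.
#'
#' @param stack_means Numeric vector: one mean r per image stack.
#' @param groups Group label per stack.
#' @param pooled Use pooled-variance t-tests.
#' @return List with `groups` (one row per group: `group`, `mean_r`, `se`,
#'   `n_stacks`) and `tests` (pairwise t-test table). Groups with fewer
#'   than 2 stacks are summarised but skipped in tests with a warning.
#' @export
group_correlations <- function(stack_means, groups, pooled = FALSE) {
  stopifnot(length(stack_means) == length(groups))
  keep <- !is.na(stack_means)
  stack_means <- stack_means[keep]
  groups <- as.character(groups)[keep]
  gs <- unique(groups)
  summ <- do.call(rbind, lapply(gs, function(g) {
    v <- stack_means[groups == g]
    data.frame(group = g, mean_r = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                    else NA_real_,
               n_stacks = length(v))
  }))
  small <- summ$group[summ$n_stacks < 2]
  if (length(small) > 0)
    warning("groups with < 2 stacks skipped in t-tests: ",
            paste(small, collapse = ", "))
  big <- groups %in% summ$group[summ$n_stacks >= 2]
  tests <- pairwise_ttests(stack_means[big], groups[big], pooled = pooled)
  list(groups = summ, tests = tests)
}

#' Gray-level co-occurrence texture features
#'
#' Quantises the image to `levels` equal-width gray bins over its finite
#' range, accumulates the symmetric co-occurrence matrix P averaged over
#' the given offsets, normalises it to sum 1, and returns energy
#' (sum P^2), entropy (-sum P log2 P, with 0 log 0 = 0) and homogeneity
#' (sum P / (1 + |i - j|)). These second-order intensity statistics are the
#' negative control: they do not see the sub-resolution fibril information
#' carried by the emission directionality.
#'
#' @param image 2-D matrix (NA ignored).
#' @param levels Number of gray levels (default 16).
#' @param offsets List of integer `c(dr, dc)` offsets (default the four
#'   standard directions `(0,1), (1,0), (1,1), (1,-1)`).
#' @return List `energy`, `entropy`, `homogeneity`, and the matrix `P`.
#' @export
glcm_features <- function(image, levels = 16,
                          offsets = list(c(0, 1), c(1, 0), c(1, 1),
                                         c(1, -1))) {
  stopifnot(is.matrix(image), levels >= 2)
  v <- image
  rng <- range(v, na.rm = TRUE)
  q <- if (rng[1] == rng[2]) {
    matrix(1L, nrow(v), ncol(v))
  } else {
    matrix(pmin(levels, 1L + as.integer(floor(
      (v - rng[1]) / (rng[2] - rng[1]) * levels))), nrow(v), ncol(v))
  }
  q[is.na(image)] <- NA_integer_
  P <- matrix(0, levels, levels)
  nr <- nrow(q); nc <- ncol(q)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + dr, c1 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = seq_len(levels)),
                 factor(b[ok], levels = seq_len(levels)))
    P <- P + tab + t(tab) # symmetric accumulation
  }
  if (sum(P) == 0) stop("no valid pixel pairs for the given offsets")
  P <- P / sum(P)
  idx <- abs(outer(seq_len(levels), seq_len(levels), "-"))
  nz <- P > 0
  list(energy = sum(P^2),
       entropy = -sum(P[nz] * log2(P[nz])),
       homogeneity = sum(P / (1 + idx)),
       P = P)
}
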