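# ---------------------------------------------------------------------------
# Synthetic cohort generator.
#
# Emulates the statistical character of smoothed, Jacobian-modulated
# gray-matter maps: a nonnegative baseline, group effects planted in named
# ROIs as Cohen's d relative to TD, and spatially autocorrelated noise
# (white Gaussian noise convolved with an isotropic Gaussian kernel). The
# smoothed noise field is variance-normalized per voxel so its marginal SD
# is exactly noise_sd everywhere; this makes a planted shift of
# d * noise_sd correspond to a true voxel-wise Cohen's d of d.
# ---------------------------------------------------------------------------

# 1D Gaussian smoothing matrix for an axis of length n: row i holds the
# truncated (3 sigma), renormalized kernel centered at i. sum(row) == 1.
gaussian_axis_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  rad <- max(1L, ceiling(3 * sigma_vox))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - rad):min(n, i + rad)
    k <- exp(-((j - i)^2) / (2 * sigma_vox^2))
    K[i, j] <- k / sum(k)
  }
  K
}

apply_axis_matrix <- function(arr, K, ax) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = d[ax])
  aperm(array(m, c(nrow(K), d[perm][-1L])), order(perm))
}

#' Gaussian-smooth a 3D field
#'
#' Separable convolution with an isotropic Gaussian kernel of the given
#' full-width at half-maximum, truncated at 3 sigma and renormalized at the
#' edges. With `normalize_variance = TRUE` the output of smoothing
#' unit-variance white noise has exactly unit marginal variance at every
#' voxel (the spatial autocorrelation is retained, only the marginal scale
#' is restored).
#'
#' @param arr 3D numeric array.
#' @param fwhm_mm kernel FWHM in mm; 0 disables smoothing.
#' @param spacing voxel edge lengths in mm.
#' @param normalize_variance divide by the per-voxel standard-deviation
#'   shrinkage factor of the kernel (default FALSE).
#' @return 3D array of the same extents.
#' @export
smooth_gaussian <- function(arr, fwhm_mm, spacing = c(1, 1, 1),
                            normalize_variance = FALSE) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  if (fwhm_mm <= 0) return(arr)
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  d <- dim(arr)
  Ks <- lapply(1:3, function(ax) gaussian_axis_matrix(d[ax], sig[ax]))
  out <- arr
  for (ax in 1:3) out <- apply_axis_matrix(out, Ks[[ax]], ax)
  if (normalize_variance) {
    v <- lapply(Ks, function(K) rowSums(K^2))
    sd_shrink <- sqrt(outer(outer(v[[1L]], v[[2L]]), v[[3L]]))
    dim(sd_shrink) <- d
    out <- out / sd_shrink
  }
  out
}

#' Default box ROI set on a synthetic grid
#'
#' Places small disjoint box ROIs named after the regions the analysis
#' targets (superior parietal / intraparietal, orbitofrontal, fusiform,
#' amygdala; left/right) inside a grid of the given extents. Purely
#' geometric stand-ins for atlas regions: positions are arbitrary but fixed
#' and disjoint.
#'
#' @param dim grid extents (length 3).
#' @param size ROI box edge in voxels; the default is 6 (12 mm on the
#'   default 2 mm grid — the scale of the smaller anatomical regions the
#'   set stands in for), shrunk automatically on grids too small to hold
#'   seven disjoint boxes of that size.
#' @return A [roi_set].
#' @export
default_roi_set <- function(dim = c(32, 32, 32),
                            size = min(6, floor(min(dim) / 4))) {
  stopifnot(size >= 1, all(dim >= 4 * size))
  box <- function(orig) {
    a <- array(FALSE, dim)
    a[orig[1]:(orig[1] + size - 1),
      orig[2]:(orig[2] + size - 1),
      orig[3]:(orig[3] + size - 1)] <- TRUE
    a
  }
  q1 <- floor(dim / 8) + 1          # near corner
  q3 <- floor(5 * dim / 8)          # far side
  mid <- floor(dim / 2) - floor(size / 2)
  roi_set(list(
    L_SPL       = box(c(q1[1], q3[2], q3[3])),
    R_SPL       = box(c(q3[1], q3[2], q3[3])),
    R_OFC       = box(c(q3[1], q1[2], q1[3])),
    L_FG        = box(c(q1[1], q1[2], q3[3])),
    R_FG        = box(c(q3[1], q1[2], q3[3])),
    L_amygdala  = box(c(q1[1], mid[2], q1[3])),
    R_amygdala  = box(c(q3[1], mid[2], mid[3]))
  ))
}

#' Parameterization of a synthetic cohort
#'
#' Fixes every ingredient of a simulated study: grid geometry, planted
#' regional group effects, noise level and smoothing, group sizes, family
#' structure, behavioral distributions, and the seed. Identical specs
#' regenerate identical cohorts.
#'
#' @param dim,spacing grid extents and voxel edge lengths (mm); default
#'   32x32x32 at 2 mm, a desk-scale stand-in for a registered brain volume.
#' @param rois a [roi_set] on this grid; default [default_roi_set].
#' @param roi_effects named numeric vector: Cohen's d of WS relative to TD
#'   inside each named ROI. The default plants the canonical pattern —
#'   parietal gray matter reduced in WS, orbitofrontal / fusiform / amygdala
#'   increased — at |d| = 2.
#' @param baseline mean tissue value (arbitrary modulated-map units).
#' @param noise_sd marginal SD of the voxel noise (> 0).
#' @param smoothing_fwhm mm; default 8, emulating smoothed VBM output.
#' @param n_ws,n_td reference group sizes; default 42 and 40, the 1.5T
#'   reference cohort sizes.
#' @param family_k number of members in a simulated family sharing one
#'   deletion profile (default 6).
#' @param white_d whole-brain Cohen's d (WS relative to TD) for white-matter
#'   maps (default -2).
#' @param behavioral data.frame as [ws_td_reference] giving per-measure
#'   group normal laws.
#' @param seed integer seed; all generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(dim = c(32, 32, 32), spacing = c(2, 2, 2),
                           rois = default_roi_set(dim),
                           roi_effects = c(L_SPL = -2, R_SPL = -2, R_OFC = 2,
                                           L_FG = 2, R_FG = 2,
                                           L_amygdala = 2, R_amygdala = 2),
                           baseline = 0.5, noise_sd = 0.05,
                           smoothing_fwhm = 8, n_ws = 42, n_td = 40,
                           family_k = 6, white_d = -2,
                           behavioral = ws_td_reference(), seed = 1) {
  stopifnot(noise_sd > 0, all(is.finite(roi_effects)), family_k >= 1,
            n_ws >= 2, n_td >= 2, inherits(rois, "roi_set"))
  dim <- as.integer(dim)
  if (!all(names(roi_effects) %in% names(rois$labels)))
    stop("roi_effects names must be ROIs in `rois`")
  for (nm in names(rois$labels))
    if (!identical(dim(rois$labels[[nm]]), dim))
      stop(sprintf("ROI '%s' lies outside the grid", nm))
  structure(list(dim = dim, spacing = as.numeric(spacing), rois = rois,
                 roi_effects = roi_effects, baseline = baseline,
                 noise_sd = noise_sd, smoothing_fwhm = smoothing_fwhm,
                 n_ws = as.integer(n_ws), n_td = as.integer(n_td),
                 family_k = as.integer(family_k), white_d = white_d,
                 behavioral = behavioral, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %s @ %g mm; %d WS + %d TD; effects: %s; fwhm %g mm; seed %d\n",
    paste(x$dim, collapse = "x"), x$spacing[1], x$n_ws, x$n_td,
    paste(sprintf("%s %+g", names(x$roi_effects), x$roi_effects),
          collapse = ", "),
    x$smoothing_fwhm, x$seed))
  invisible(x)
}

# signed mean shift map for a group/profile. `membership[nm]` is "WS" or
# "TD" per ROI: TD is the baseline law, WS adds d * noise_sd inside the ROI.
effect_map <- function(spec, membership) {
  eff <- array(0, spec$dim)
  for (nm in names(spec$roi_effects)) {
    if (identical(membership[[nm]], "WS")) {
      eff[spec$rois$labels[[nm]]] <-
        eff[spec$rois$labels[[nm]]] + spec$roi_effects[[nm]] * spec$noise_sd
    }
  }
  eff
}

# One subject's pair of maps from a single white-noise draw, mirroring how
# VBM produces a non-smoothed segmentation output and its smoothed version:
# `raw` adds the white noise directly; `smoothed` adds the same noise field
# convolved with the Gaussian kernel and variance-normalized. Both are
# baseline + shift + noise_sd * field, clipped at zero (baseline >>
# noise_sd keeps clipping negligible), so the planted voxel-wise Cohen's d
# is identical in both.
draw_image <- function(spec, shift, subject_id, tissue = "gray") {
  noise <- array(stats::rnorm(prod(spec$dim)), spec$dim)
  smoothed <- smooth_gaussian(noise, spec$smoothing_fwhm, spec$spacing,
                              normalize_variance = TRUE)
  mk <- function(field)
    voxel_image(pmax(spec$baseline + shift + spec$noise_sd * field, 0),
                spacing = spec$spacing, subject_id = subject_id,
                tissue = tissue)
  list(smoothed = mk(smoothed), raw = mk(noise))
}

draw_scalars <- function(spec, group_per_measure, subject_id, group_label) {
  beh <- spec$behavioral
  vals <- vapply(seq_len(nrow(beh)), function(i) {
    g <- group_per_measure[[beh$measure[i]]]
    if (is.null(g)) g <- group_label
    if (g == "WS") stats::rnorm(1, beh$mean_ws[i], beh$sd_ws[i])
    else stats::rnorm(1, beh$mean_td[i], beh$sd_td[i])
  }, numeric(1))
  rec <- as.list(vals)
  names(rec) <- beh$measure
  cbind(data.frame(subject_id = subject_id, group = group_label,
                   stringsAsFactors = FALSE),
        as.data.frame(rec))
}

#' Generate a synthetic reference cohort
#'
#' Draws `n_ws + n_td` subjects. Each gray-matter image is the baseline plus
#' the group's planted ROI shifts plus smoothed, variance-normalized
#' Gaussian noise; white-matter images carry a single whole-volume WS-vs-TD
#' shift of `white_d`. Scalar measures are drawn from the per-group normal
#' laws in `spec$behavioral`. Fully deterministic given the spec (including
#' its seed).
#'
#' @param spec a [synthetic_spec].
#' @param tissues which image sets to generate (`"gray"`, `"white"`).
#' @return An object of class `synthetic_cohort`: `gray` / `white` (lists of
#'   smoothed [voxel_image], the univariate stage's input), `gray_raw` /
#'   `white_raw` (the matching non-smoothed maps, the multivariate stage's
#'   input; same noise draw per subject), `scalars` (data.frame), `mask`
#'   (all-grid [brain_mask]), `truth` (the spec).
#' @export
generate_cohort <- function(spec, tissues = c("gray", "white")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  tissues <- match.arg(tissues, several.ok = TRUE)
  set.seed(spec$seed)
  groups <- c(rep("WS", spec$n_ws), rep("TD", spec$n_td))
  ids <- sprintf("%s-%02d", tolower(groups),
                 c(seq_len(spec$n_ws), seq_len(spec$n_td)))
  ws_membership <- as.list(stats::setNames(rep("WS", length(spec$roi_effects)),
                                           names(spec$roi_effects)))
  shift_ws <- effect_map(spec, ws_membership)
  shift_white_ws <- array(spec$white_d * spec$noise_sd, spec$dim)
  gray <- white <- gray_raw <- white_raw <- NULL
  if ("gray" %in% tissues) {
    pairs <- lapply(seq_along(ids), function(i)
      draw_image(spec, if (groups[i] == "WS") shift_ws else 0, ids[i], "gray"))
    gray <- lapply(pairs, `[[`, "smoothed")
    gray_raw <- lapply(pairs, `[[`, "raw")
  }
  if ("white" %in% tissues) {
    pairs <- lapply(seq_along(ids), function(i)
      draw_image(spec, if (groups[i] == "WS") shift_white_ws else 0,
                 ids[i], "white"))
    white <- lapply(pairs, `[[`, "smoothed")
    white_raw <- lapply(pairs, `[[`, "raw")
  }
  scalars <- do.call(rbind, lapply(seq_along(ids), function(i)
    draw_scalars(spec, list(), ids[i], groups[i])))
  structure(list(gray = gray, white = white, gray_raw = gray_raw,
                 white_raw = white_raw, scalars = scalars,
                 mask = brain_mask(array(TRUE, spec$dim),
                                   spacing = spec$spacing),
                 truth = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d WS + %d TD subjects on a %s grid (seed %d)\n",
              x$truth$n_ws, x$truth$n_td,
              paste(x$truth$dim, collapse = "x"), x$truth$seed))
  invisible(x)
}

#' Generate an atypical case with a mosaic deletion profile
#'
#' The case's image follows the TD generative law inside ROIs marked
#' `"TD_like"` and the WS law (planted shift) inside ROIs marked
#' `"WS_like"`; unlisted effect ROIs default to TD. Scalars follow
#' `scalar_profile` the same way. Uses its own seed stream (`spec$seed +
#' seed_offset`) so cases are independent of the reference cohort draw.
#'
#' @param spec a [synthetic_spec].
#' @param profile named character vector, ROI -> `"WS_like"` / `"TD_like"`.
#' @param case_id subject identifier.
#' @param scalar_profile optional named vector, measure -> `"WS"` / `"TD"`;
#'   unlisted measures follow the TD law.
#' @param tissue `"gray"` or `"white"`; a white case uses the whole-volume
#'   WS shift when `white_like = "WS_like"`.
#' @param white_like profile for white-matter tissue.
#' @param seed_offset integer added to the spec seed (default 1000).
#' @return list: `image` (smoothed [voxel_image]), `image_raw` (the
#'   matching non-smoothed map for the multivariate stage), `scalars`
#'   (one-row data.frame), `profile`.
#' @export
generate_case <- function(spec, profile = NULL, case_id = "case-01",
                          scalar_profile = NULL, tissue = "gray",
                          white_like = "TD_like", seed_offset = 1000L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  profile <- as.list(profile %||% character())
  if (!all(names(profile) %in% names(spec$rois$labels)))
    stop("unknown ROI in profile")
  bad <- !vapply(profile, function(p) p %in% c("WS_like", "TD_like"), logical(1))
  if (any(bad)) stop("profile values must be 'WS_like' or 'TD_like'")
  set.seed(spec$seed + as.integer(seed_offset))
  if (tissue == "gray") {
    membership <- lapply(names(spec$roi_effects), function(nm)
      if (identical(profile[[nm]], "WS_like")) "WS" else "TD")
    names(membership) <- names(spec$roi_effects)
    shift <- effect_map(spec, membership)
  } else {
    shift <- if (identical(white_like, "WS_like"))
      array(spec$white_d * spec$noise_sd, spec$dim) else 0
  }
  pair <- draw_image(spec, shift, case_id, tissue)
  sp <- lapply(as.list(scalar_profile %||% character()), function(g)
    if (g %in% c("WS", "WS_like")) "WS" else "TD")
  scalars <- draw_scalars(spec, sp, case_id, "AWSdel")
  list(image = pair$smoothed, image_raw = pair$raw, scalars = scalars,
       profile = profile)
}

#' Generate a synthetic family sharing one deletion profile
#'
#' Draws `spec$family_k` members, each an independent case with the same
#' ROI profile (distinct seed offsets).
#'
#' @inheritParams generate_case
#' @param seed_offsets integer offsets, one per member; default
#'   `2000 + 1:k`.
#' @return list of [generate_case] results, length `spec$family_k`.
#' @export
generate_family <- function(spec, profile = NULL,
                            seed_offsets = 2000L + seq_len(spec$family_k)) {
  stopifnot(length(seed_offsets) == spec$family_k)
  lapply(seq_len(spec$family_k), function(i)
    generate_case(spec, profile = profile,
                  case_id = sprintf("family-%02d", i),
                  seed_offset = seed_offsets[i]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
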