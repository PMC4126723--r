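# ---------------------------------------------------------------------------
# Univariate stage: scalar and voxel-wise z-deviation of a single case
# against a reference cohort, threshold decisions, the resemblance rule,
# and family-level probabilistic maps.
#
# The deviation maps are descriptive: a fixed +/- threshold is applied per
# voxel with no correction across voxels, so they localize where a case sits
# relative to a reference distribution rather than perform group inference.
# ---------------------------------------------------------------------------

#' Reference statistics for one group
#'
#' Per-measure or per-voxel mean and sample standard deviation (n-1
#' denominator: the case is external to the reference sample) of a reference
#' cohort.
#'
#' @param x numeric vector (one scalar measure across subjects), a
#'   subjects-by-voxels matrix, or a list of congruent [voxel_image]s.
#' @param group `"WS"` or `"TD"`.
#' @param mask required when `x` is a list of images.
#' @return An object of class `reference_stats` with fields `mean`, `sd`,
#'   `n`, `group`, and `valid` (`sd > 0`). For image input, `mean`/`sd` are
#'   3D arrays and the grid geometry is carried along.
#' @export
reference_stats <- function(x, group = c("WS", "TD"), mask = NULL) {
  group <- match.arg(group)
  if (is.list(x) && !is.data.frame(x)) {
    stopifnot(inherits(mask, "brain_mask"))
    vec <- vectorize(x, mask)
    if (nrow(vec$X) < 2L) stop("reference cohort must have n >= 2")
    mu <- colMeans(vec$X)
    sdv <- apply(vec$X, 2L, stats::sd)
    out <- list(mean = devectorize(mu, vec), sd = devectorize(sdv, vec),
                n = nrow(vec$X), group = group,
                valid = devectorize(sdv > 0, vec, fill = FALSE),
                voxel_index = vec$voxel_index, dim = vec$dim,
                spacing = vec$spacing, kind = "map")
  } else {
    x <- as.numeric(x)
    x <- x[!is.na(x)]
    if (length(x) < 2L) stop("reference cohort must have n >= 2")
    sdv <- stats::sd(x)
    out <- list(mean = mean(x), sd = sdv, n = length(x), group = group,
                valid = sdv > 0, kind = "scalar")
  }
  structure(out, class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  if (x$kind == "scalar")
    cat(sprintf("<reference_stats> %s (n=%d): mean %.3f, sd %.3f\n",
                x$group, x$n, x$mean, x$sd))
  else
    cat(sprintf("<reference_stats> %s (n=%d): %s voxel map, %d valid voxels\n",
                x$group, x$n, paste(x$dim, collapse = "x"), sum(x$valid)))
  invisible(x)
}

#' Z-score of a scalar case value against a reference group
#'
#' `z = (x_case - mean_ref) / sd_ref`, returned unrounded; round at the
#' reporting layer (conventionally 2 decimals).
#'
#' @param case_value numeric scalar in the measure's units.
#' @param ref a scalar [reference_stats] (or anything with `$mean`, `$sd`).
#' @return numeric z (dimensionless).
#' @export
zscore_scalar <- function(case_value, ref) {
  if (is.na(ref$sd) || ref$sd <= 0)
    stop("reference SD is zero: measure is invalid for z-scoring")
  (case_value - ref$mean) / ref$sd
}

# shared builder for threshold decisions.
# tail: "two" flags both z > theta and z < -theta;
#       "upper"/"lower" flag only the stated tail (one-tailed behavioral rule).
# Comparisons are strict (z exactly at theta does not exceed).
make_deviation <- function(z, valid, threshold, tail, geometry = NULL) {
  exceed_pos <- valid & !is.na(z) & z > threshold
  exceed_neg <- valid & !is.na(z) & z < -threshold
  if (tail == "upper") exceed_neg[] <- FALSE
  if (tail == "lower") exceed_pos[] <- FALSE
  structure(c(list(z = z, threshold = threshold, tail = tail,
                   exceed_pos = exceed_pos, exceed_neg = exceed_neg,
                   valid = valid), geometry),
            class = "deviation_result")
}

#' Scalar deviation of a case with threshold decision
#'
#' Applies the z threshold to a single measure. Brain-derived scalars use a
#' two-sided threshold of 1.96; behavioral measures conventionally use 1.65
#' one-tailed in the direction of the known group difference (pass
#' `tail = "upper"` or `"lower"`).
#'
#' @param case_value scalar measure value.
#' @param ref scalar [reference_stats].
#' @param threshold z cutoff (default 1.96).
#' @param tail `"two"`, `"upper"`, or `"lower"`.
#' @return A `deviation_result` with scalar fields.
#' @export
scalar_deviation <- function(case_value, ref, threshold = 1.96,
                             tail = c("two", "upper", "lower")) {
  tail <- match.arg(tail)
  z <- zscore_scalar(case_value, ref)
  make_deviation(z, valid = TRUE, threshold = threshold, tail = tail)
}

#' Voxel-wise z-deviation map of a case against a reference cohort
#'
#' Computes per-voxel `z = (case - mean)/sd` using the cohort's per-voxel
#' mean and sample SD, and flags voxels beyond the threshold in each
#' direction. Voxels with zero cohort SD are marked invalid and excluded
#' from all exceed counts.
#'
#' @param case a [voxel_image].
#' @param cohort list of >= 2 congruent [voxel_image]s, or a precomputed map
#'   [reference_stats].
#' @param mask a [brain_mask] (required unless `cohort` is `reference_stats`).
#' @param threshold z cutoff, default 1.96 (two-sided p < 0.05).
#' @param tail `"two"` (default for brain maps), `"upper"`, or `"lower"`.
#' @return A `deviation_result` whose `z`, `exceed_pos`, `exceed_neg`,
#'   `valid` are 3D arrays.
#' @export
zscore_map <- function(case, cohort, mask = NULL, threshold = 1.96,
                       tail = c("two", "upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(inherits(case, "voxel_image"))
  if (!inherits(cohort, "reference_stats"))
    cohort <- reference_stats(cohort, group = "WS", mask = mask)
  if (cohort$kind != "map") stop("`cohort` must be voxel-wise reference stats")
  check_congruent(dim(case$data), case$spacing, cohort$dim, cohort$spacing,
                  "case and reference")
  idx <- cohort$voxel_index
  z <- array(NA_real_, cohort$dim)
  sdv <- cohort$sd[idx]
  ok <- sdv > 0
  z[idx[ok]] <- (case$data[idx][ok] - cohort$mean[idx][ok]) / sdv[ok]
  make_deviation(z, valid = cohort$valid, threshold = threshold, tail = tail,
                 geometry = list(voxel_index = idx, dim = cohort$dim,
                                 spacing = cohort$spacing,
                                 group = cohort$group,
                                 case_id = case$subject_id))
}

#' @export
print.deviation_result <- function(x, ...) {
  if (length(x$z) == 1L)
    cat(sprintf("<deviation_result> z = %.2f (theta = %.2f, %s-tailed)%s\n",
                x$z, x$threshold, if (x$tail == "two") "two" else "one",
                if (x$exceed_pos) " [exceeds +]"
                else if (x$exceed_neg) " [exceeds -]" else ""))
  else
    cat(sprintf(
      "<deviation_result> %s map vs %s: %d valid voxels, %d > +%.2f, %d < -%.2f\n",
      paste(x$dim, collapse = "x"),
      if (!is.null(x$group)) x$group else "?",
      sum(x$valid), sum(x$exceed_pos), x$threshold, sum(x$exceed_neg),
      x$threshold))
  invisible(x)
}

# the four-way call from the two exceed indicators
resemblance_call <- function(exceeds_ws, exceeds_td) {
  if (exceeds_ws && exceeds_td) "deviant_from_both"
  else if (exceeds_ws) "TD_like"
  else if (exceeds_td) "WS_like"
  else "within_both"
}

#' Resemblance call from deviations against both reference groups
#'
#' A case that deviates from one group (`|z|` beyond threshold) but not the
#' other resembles the latter: exceeding vs WS only is `"TD_like"`,
#' exceeding vs TD only is `"WS_like"`, both is `"deviant_from_both"`,
#' neither is `"within_both"`. For voxel maps the call is made per ROI using
#' whether any valid voxel in the ROI exceeds; the per-ROI peak `|z|` (and
#' mean z) are also reported.
#'
#' @param vs_ws,vs_td `deviation_result`s of the same case against the WS
#'   and TD references, computed with the same threshold.
#' @param rois optional [roi_set]; required for map results.
#' @return For scalars, a character call. For maps, a data.frame with one
#'   row per ROI: `roi`, `n_valid`, `peak_z_vs_WS`, `peak_z_vs_TD`,
#'   `mean_z_vs_WS`, `mean_z_vs_TD`, `call`.
#' @export
resemblance <- function(vs_ws, vs_td, rois = NULL) {
  stopifnot(inherits(vs_ws, "deviation_result"),
            inherits(vs_td, "deviation_result"))
  if (abs(vs_ws$threshold - vs_td$threshold) > 1e-12)
    stop("threshold mismatch between the two deviation results")
  if (length(vs_ws$z) == 1L && length(vs_td$z) == 1L) {
    return(resemblance_call(vs_ws$exceed_pos || vs_ws$exceed_neg,
                            vs_td$exceed_pos || vs_td$exceed_neg))
  }
  if (is.null(rois))
    stop("`rois` is required for voxel-wise resemblance calls")
  stopifnot(inherits(rois, "roi_set"))
  check_congruent(vs_ws$dim, vs_ws$spacing, vs_td$dim, vs_td$spacing,
                  "the two deviation maps")
  rows <- lapply(names(rois$labels), function(nm) {
    roi <- rois$labels[[nm]]
    in_ws <- roi & vs_ws$valid
    in_td <- roi & vs_td$valid
    exc_ws <- any(vs_ws$exceed_pos[roi]) || any(vs_ws$exceed_neg[roi])
    exc_td <- any(vs_td$exceed_pos[roi]) || any(vs_td$exceed_neg[roi])
    peak_signed <- function(z, sel) {
      v <- z[sel]
      if (!length(v)) return(NA_real_)
      v[which.max(abs(v))]
    }
    data.frame(
      roi = nm, n_valid = sum(in_ws),
      peak_z_vs_WS = peak_signed(vs_ws$z, in_ws),
      peak_z_vs_TD = peak_signed(vs_td$z, in_td),
      mean_z_vs_WS = if (any(in_ws)) mean(vs_ws$z[in_ws]) else NA_real_,
      mean_z_vs_TD = if (any(in_td)) mean(vs_td$z[in_td]) else NA_real_,
      call = resemblance_call(exc_ws, exc_td),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Family-level probabilistic deviation map
#'
#' For k family members with thresholded deviation maps against the same
#' reference, computes per voxel the proportion of members exceeding the
#' threshold in each direction. Values are exact multiples of 1/k.
#'
#' @param results list of k map `deviation_result`s on congruent grids with
#'   identical thresholds.
#' @return An object of class `probabilistic_map` with 3D arrays `prop_pos`,
#'   `prop_neg` and field `k`.
#' @export
probabilistic_map <- function(results) {
  if (!length(results)) stop("need at least one deviation result (k >= 1)")
  stopifnot(all(vapply(results, inherits, logical(1), "deviation_result")))
  k <- length(results)
  first <- results[[1L]]
  if (length(first$z) == 1L) stop("probabilistic maps require voxel-wise results")
  th <- vapply(results, `[[`, numeric(1), "threshold")
  if (max(th) - min(th) > 1e-12)
    stop("mixed thresholds across family members")
  for (r in results)
    check_congruent(first$dim, first$spacing, r$dim, r$spacing, "family maps")
  pos <- Reduce(`+`, lapply(results, function(r) r$exceed_pos + 0))
  neg <- Reduce(`+`, lapply(results, function(r) r$exceed_neg + 0))
  structure(list(prop_pos = pos / k, prop_neg = neg / k, k = k,
                 threshold = first$threshold, dim = first$dim,
                 spacing = first$spacing),
            class = "probabilistic_map")
}

#' @export
print.probabilistic_map <- function(x, ...) {
  cat(sprintf(
    "<probabilistic_map> k=%d members, theta=%.2f; max prop +: %.3f, -: %.3f\n",
    x$k, x$threshold, max(x$prop_pos), max(x$prop_neg)))
  invisible(x)
}
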