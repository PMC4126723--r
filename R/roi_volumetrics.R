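# ---------------------------------------------------------------------------
# Scalar volumetrics: adjustment of regional volumes for total cranium gray
# matter, group comparisons on scalar measures, and case z-scores on the
# adjusted volumes.
#
# Cohort tables are plain data.frames with columns subject_id, group
# (WS / TD / AWSdel), optionally sex, and one column per measure; regional
# volumes and total_gm are in ml. Missing values are NA and handled listwise
# per measure.
# ---------------------------------------------------------------------------

ref_groups <- c("WS", "TD")

#' Adjust a regional volume for total cranium gray matter
#'
#' Removes the dependence of a regional volume on global gray-matter volume
#' before single-case comparison, so a case is not called deviant merely for
#' having a small or large head. The default (`"residual"`) fits a single
#' linear trend of the ROI volume on total gray matter over the pooled WS+TD
#' reference and returns each subject's residual from that trend plus the
#' reference grand mean; this preserves units and the reference mean, and
#' makes the adjusted reference values exactly uncorrelated with total gray
#' matter. Cases (and any non-reference subjects) are always adjusted using
#' the reference fit, never their own. The `"ratio"` alternative scales each
#' ROI volume by `mean(total_gm_ref) / total_gm`.
#'
#' @param records data.frame with columns `group`, `total_gm`, and the
#'   measure named by `roi_measure`.
#' @param roi_measure column name of the regional volume to adjust.
#' @param method `"residual"` (default) or `"ratio"`.
#' @return numeric vector of adjusted volumes (ml), aligned with
#'   `records` rows; NA where inputs are missing.
#' @export
adjust_volume <- function(records, roi_measure, method = c("residual", "ratio")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(records),
            all(c("group", "total_gm", roi_measure) %in% names(records)))
  y <- records[[roi_measure]]
  g <- records$total_gm
  is_ref <- records$group %in% ref_groups & !is.na(y) & !is.na(g)
  if (sum(is_ref) < 3L)
    stop("need at least 3 reference (WS/TD) subjects with complete data")
  if (stats::sd(g[is_ref]) == 0)
    stop("zero variance in total_gm among reference subjects")
  out <- rep(NA_real_, nrow(records))
  usable <- !is.na(y) & !is.na(g)
  if (method == "residual") {
    fit <- stats::lm(y ~ g, data = data.frame(y = y[is_ref], g = g[is_ref]))
    pred <- stats::predict(fit, newdata = data.frame(g = g[usable]))
    out[usable] <- y[usable] - pred + mean(y[is_ref])
  } else {
    gm_ref <- mean(g[is_ref])
    out[usable] <- y[usable] * gm_ref / g[usable]
  }
  out
}

#' Compare WS and TD groups on one measure
#'
#' Continuous measures get a Welch (unequal-variance) two-sample t-test,
#' two-sided. A dichotomous measure (e.g. sex) gets a chi-square test on the
#' 2x2 contingency table with Yates continuity correction. Missing values
#' are dropped listwise for the measure at hand.
#'
#' @param records cohort data.frame (see [adjust_volume]).
#' @param measure column name.
#' @return one-row data.frame: `measure`, `mean_ws`, `sd_ws`, `n_ws`,
#'   `mean_td`, `sd_td`, `n_td`, `test` ("welch_t" or "chi_square"),
#'   `statistic`, `p`.
#' @export
compare_groups <- function(records, measure) {
  stopifnot(is.data.frame(records), measure %in% names(records),
            "group" %in% names(records))
  x <- records[[measure]]
  ws <- x[records$group == "WS"]
  td <- x[records$group == "TD"]
  ws <- ws[!is.na(ws)]; td <- td[!is.na(td)]
  if (length(ws) < 2L || length(td) < 2L)
    stop("need >= 2 subjects per group with this measure")
  dichotomous <- is.character(x) || is.factor(x) || is.logical(x)
  if (dichotomous) {
    tab <- table(factor(records$group[records$group %in% ref_groups],
                        levels = ref_groups),
                 droplevels(factor(x[records$group %in% ref_groups])))
    if (ncol(tab) != 2L) stop("dichotomous measure must have exactly 2 levels")
    ts <- stats::chisq.test(tab, correct = TRUE)
    return(data.frame(measure = measure,
                      mean_ws = NA_real_, sd_ws = NA_real_, n_ws = length(ws),
                      mean_td = NA_real_, sd_td = NA_real_, n_td = length(td),
                      test = "chi_square",
                      statistic = unname(ts$statistic), p = ts$p.value,
                      stringsAsFactors = FALSE))
  }
  if (stats::sd(ws) == 0 && stats::sd(td) == 0) {
    if (mean(ws) == mean(td))
      return(data.frame(measure = measure,
                        mean_ws = mean(ws), sd_ws = 0, n_ws = length(ws),
                        mean_td = mean(td), sd_td = 0, n_td = length(td),
                        test = "welch_t", statistic = 0, p = 1,
                        stringsAsFactors = FALSE))
    stop("degenerate (zero) variance in both groups")
  }
  ts <- stats::t.test(ws, td, var.equal = FALSE)
  data.frame(measure = measure,
             mean_ws = mean(ws), sd_ws = stats::sd(ws), n_ws = length(ws),
             mean_td = mean(td), sd_td = stats::sd(td), n_td = length(td),
             test = "welch_t", statistic = unname(ts$statistic),
             p = ts$p.value, stringsAsFactors = FALSE)
}

#' Case z-scores on an adjusted regional volume
#'
#' Applies [adjust_volume] across the pooled table (reference fit only),
#' then z-scores the case's adjusted volume against each reference group's
#' adjusted distribution via [zscore_scalar].
#'
#' @param records cohort data.frame containing both reference groups and the
#'   case row.
#' @param case_id subject_id of the case.
#' @param roi_measure regional volume column to adjust and score.
#' @param method adjustment method, see [adjust_volume].
#' @return one-row data.frame: `case_id`, `measure`, `adjusted`, `z_vs_WS`,
#'   `z_vs_TD`.
#' @export
case_volume_z <- function(records, case_id, roi_measure,
                          method = c("residual", "ratio")) {
  method <- match.arg(method)
  stopifnot("subject_id" %in% names(records))
  i <- which(records$subject_id == case_id)
  if (length(i) != 1L) stop(sprintf("case '%s' not found exactly once", case_id))
  adj <- adjust_volume(records, roi_measure, method = method)
  if (is.na(adj[i])) stop("case has missing volume or total_gm")
  zs <- vapply(ref_groups, function(gr) {
    ref <- reference_stats(adj[records$group == gr], group = gr)
    zscore_scalar(adj[i], ref)
  }, numeric(1))
  data.frame(case_id = case_id, measure = roi_measure, adjusted = adj[i],
             z_vs_WS = zs[["WS"]], z_vs_TD = zs[["TD"]],
             stringsAsFactors = FALSE)
}

#' Voxel-wise Welch t-map between two image groups
#'
#' A plain two-sample (unequal-variance) t statistic per voxel, WS minus TD.
#' Intended for defining data-driven ROIs on synthetic cohorts and for null
#' calibration checks, not for corrected group inference.
#'
#' @param ws_imgs,td_imgs lists of congruent [voxel_image]s (>= 2 each).
#' @param mask a [brain_mask].
#' @return list: `t` (3D array, NA outside mask or where both variances are
#'   zero), `df` (Welch-Satterthwaite degrees of freedom array).
#' @export
group_tmap <- function(ws_imgs, td_imgs, mask) {
  vw <- vectorize(ws_imgs, mask)
  vt <- vectorize(td_imgs, mask)
  n1 <- nrow(vw$X); n2 <- nrow(vt$X)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 images per group")
  m1 <- colMeans(vw$X); m2 <- colMeans(vt$X)
  v1 <- apply(vw$X, 2L, stats::var); v2 <- apply(vt$X, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tval <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               NA_real_)
  list(t = devectorize(tval, vw), df = devectorize(df, vw))
}
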