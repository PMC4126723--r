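# ---------------------------------------------------------------------------
# Orchestration: run configuration with the analysis's canonical defaults,
# the three report-producing stages, and a reproducibility manifest.
# ---------------------------------------------------------------------------

#' Run configuration
#'
#' Collects every tunable parameter of the pipeline with its canonical
#' default: brain z threshold 1.96 (two-sided p < .05), behavioral threshold
#' 1.65 (one-tailed), SVM cost C = 1, RFE elimination fraction 0.30, 4 mm
#' down-sampling for the multivariate stage, residual-based volume
#' adjustment, leakage-free per-fold standardization, and a seed governing
#' simulation and permutation only (training is deterministic).
#' Non-default thresholds trigger a warning so accidental misconfiguration
#' is visible in logs.
#'
#' @param theta_brain z threshold for voxel maps (default 1.96).
#' @param theta_behav z threshold for behavioral scalars (default 1.65,
#'   one-tailed).
#' @param C SVM soft-margin cost (default 1).
#' @param rfe_fraction fraction of features eliminated per RFE level
#'   (default 0.30).
#' @param downsample_edge MVPA voxel edge in mm (default 4).
#' @param adjustment `"residual"` or `"ratio"` (default `"residual"`).
#' @param standardize per-fold feature standardization (default TRUE).
#' @param seed integer.
#' @return An object of class `run_config`.
#' @export
run_config <- function(theta_brain = 1.96, theta_behav = 1.65, C = 1,
                       rfe_fraction = 0.30, downsample_edge = 4,
                       adjustment = c("residual", "ratio"),
                       standardize = TRUE, seed = 1) {
  adjustment <- match.arg(adjustment)
  if (theta_brain != 1.96)
    warning(sprintf("non-default brain threshold theta = %g (canonical: 1.96)",
                    theta_brain))
  if (theta_behav != 1.65)
    warning(sprintf("non-default behavioral threshold theta = %g (canonical: 1.65)",
                    theta_behav))
  if (C != 1)
    warning(sprintf("non-default SVM cost C = %g (canonical: 1)", C))
  structure(list(theta_brain = theta_brain, theta_behav = theta_behav, C = C,
                 rfe_fraction = rfe_fraction,
                 downsample_edge = downsample_edge, adjustment = adjustment,
                 standardize = standardize, seed = as.integer(seed)),
            class = "run_config")
}

# stable fingerprint of a config (base tools::md5sum works offline)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[order(names(config))], file = f)
  unname(tools::md5sum(f))
}

manifest <- function(config) {
  list(package = "casemap",
       version = as.character(utils::packageVersion("casemap")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       config = unclass(config), config_hash = config_hash(config),
       seed = config$seed)
}

#' Univariate deviation report for a set of cases
#'
#' For each case image: voxel-wise z maps against the WS and TD references
#' at `theta_brain`, per-ROI peak/mean z and the resemblance call. When
#' `family_ids` names two or more cases, their thresholded maps are
#' additionally combined into family probabilistic maps.
#'
#' @param cases list of [voxel_image] cases.
#' @param ws_imgs,td_imgs reference cohorts (lists of [voxel_image]).
#' @param mask a [brain_mask].
#' @param rois a [roi_set].
#' @param config a [run_config].
#' @param family_ids optional character vector of case subject ids forming a
#'   family.
#' @return list of class `univariate_report`: `table` (one row per case x
#'   ROI), `deviations` (per-case list with `vs_ws`, `vs_td`),
#'   `family_map_vs_ws` / `family_map_vs_td` ([probabilistic_map] or NULL),
#'   `manifest`.
#' @export
run_univariate <- function(cases, ws_imgs, td_imgs, mask, rois,
                           config = run_config(), family_ids = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(cases, "voxel_image")) cases <- list(cases)
  ref_ws <- reference_stats(ws_imgs, group = "WS", mask = mask)
  ref_td <- reference_stats(td_imgs, group = "TD", mask = mask)
  devs <- lapply(cases, function(cs) {
    list(vs_ws = zscore_map(cs, ref_ws, threshold = config$theta_brain),
         vs_td = zscore_map(cs, ref_td, threshold = config$theta_brain))
  })
  names(devs) <- vapply(cases, `[[`, character(1), "subject_id")
  tab <- do.call(rbind, lapply(names(devs), function(id) {
    r <- resemblance(devs[[id]]$vs_ws, devs[[id]]$vs_td, rois)
    cbind(data.frame(case_id = id, stringsAsFactors = FALSE), r)
  }))
  fam_ws <- fam_td <- NULL
  if (!is.null(family_ids)) {
    if (!all(family_ids %in% names(devs)))
      stop("family_ids must name provided cases")
    fam <- devs[family_ids]
    fam_ws <- probabilistic_map(lapply(fam, `[[`, "vs_ws"))
    fam_td <- probabilistic_map(lapply(fam, `[[`, "vs_td"))
  }
  structure(list(table = tab, deviations = devs,
                 family_map_vs_ws = fam_ws, family_map_vs_td = fam_td,
                 manifest = manifest(config)),
            class = "univariate_report")
}

#' Scalar deviation table for case records
#'
#' Z-scores each case's scalar measures against the WS and TD reference
#' laws with the behavioral one-tailed rule: threshold `theta_behav` applied
#' in the direction of the known WS-TD group difference for that measure
#' (the tail toward the *other* group), then makes the resemblance call.
#'
#' @param case_records data.frame, one row per case, columns `case_id` plus
#'   measures (as [awsdel_cases]).
#' @param reference data.frame as [ws_td_reference].
#' @param config a [run_config].
#' @return data.frame: `case_id`, `measure`, `z_vs_WS`, `z_vs_TD`, `call`.
#' @export
run_scalar_deviation <- function(case_records, reference = ws_td_reference(),
                                 config = run_config()) {
  measures <- intersect(names(case_records), reference$measure)
  rows <- list()
  for (i in seq_len(nrow(case_records))) {
    for (m in measures) {
      ref_row <- reference[reference$measure == m, ]
      val <- case_records[[m]][i]
      if (is.na(val)) next
      # tail toward the other group: vs WS test the TD-ward tail and
      # vice versa; direction is sign(WS - TD)
      tail_vs_ws <- if (ref_row$direction < 0) "upper" else "lower"
      tail_vs_td <- if (ref_row$direction < 0) "lower" else "upper"
      dws <- scalar_deviation(val,
                              list(mean = ref_row$mean_ws, sd = ref_row$sd_ws),
                              threshold = config$theta_behav, tail = tail_vs_ws)
      dtd <- scalar_deviation(val,
                              list(mean = ref_row$mean_td, sd = ref_row$sd_td),
                              threshold = config$theta_behav, tail = tail_vs_td)
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case_records$case_id[i], measure = m,
        z_vs_WS = dws$z, z_vs_TD = dtd$z,
        call = resemblance(dws, dtd), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Volumetrics report
#'
#' Group comparisons (Welch t / chi-square) for every numeric measure and
#' any `sex` column, plus adjusted-volume case z-scores for the requested
#' regional volumes.
#'
#' @param records cohort data.frame (`subject_id`, `group`, measures,
#'   `total_gm`).
#' @param roi_measures character vector of regional-volume columns to adjust
#'   and case-score (default any column matching "amygdala").
#' @param config a [run_config].
#' @return list of class `volumetrics_report`: `comparisons`, `case_z`,
#'   `manifest`.
#' @export
run_volumetrics <- function(records,
                            roi_measures = grep("amygdala", names(records),
                                                value = TRUE),
                            config = run_config()) {
  skip <- c("subject_id", "group")
  meas <- setdiff(names(records), skip)
  comp <- do.call(rbind, lapply(meas, function(m)
    tryCatch(compare_groups(records, m), error = function(e) NULL)))
  case_ids <- records$subject_id[!(records$group %in% c("WS", "TD"))]
  cz <- NULL
  if (length(case_ids) && length(roi_measures)) {
    cz <- do.call(rbind, lapply(case_ids, function(cid)
      do.call(rbind, lapply(roi_measures, function(m)
        case_volume_z(records, cid, m, method = config$adjustment)))))
  }
  structure(list(comparisons = comp, case_z = cz,
                 manifest = manifest(config)),
            class = "volumetrics_report")
}

#' Multivariate classification report over named region sets
#'
#' For each region set (e.g. visuo-spatial ROIs, social ROIs, whole gray
#' matter, whole white matter): down-samples the subject maps to
#' `downsample_edge` mm, vectorizes over the down-sampled set mask, trains
#' the LOO SVM ensemble with RFE, and applies each fold classifier of the
#' chosen level to every case to get fold-fraction group probabilities.
#'
#' @param cohort a [generate_cohort] result, or a list with `gray` /
#'   `white` image lists and `scalars$group`. Lists named `gray_raw` /
#'   `white_raw` (non-smoothed maps, the stage's canonical input) are
#'   preferred over `gray` / `white` when present.
#' @param cases list of case [voxel_image]s (tissue must match the region
#'   set's tissue; pass non-smoothed case maps, e.g. `image_raw` from
#'   [generate_case]).
#' @param region_sets named list; each element is a list with `mask` (a
#'   [brain_mask] at source resolution) and `tissue` ("gray" or "white").
#' @param config a [run_config].
#' @return list of class `mvpa_report`: per-set `loo_accuracy`,
#'   `rfe_trace`, `case_probabilities`, `n_features`; plus `manifest`.
#' @export
run_mvpa <- function(cohort, cases = list(), region_sets,
                     config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  groups <- cohort$scalars$group
  out <- list()
  for (set_name in names(region_sets)) {
    rs <- region_sets[[set_name]]
    tissue <- rs$tissue %||% "gray"
    # the multivariate stage runs on non-smoothed maps when the cohort
    # provides them (as synthetic cohorts do); otherwise the caller is
    # expected to supply non-smoothed maps directly
    imgs <- cohort[[paste0(tissue, "_raw")]] %||% cohort[[tissue]]
    if (is.null(imgs))
      stop(sprintf("region set '%s' needs %s-matter maps but the cohort has none",
                   set_name, tissue))
    dmask <- downsample_mask(rs$mask, config$downsample_edge)
    dimgs <- lapply(imgs, downsample, target_edge = config$downsample_edge)
    vec <- vectorize(dimgs, dmask)
    fm <- feature_matrix(vec$X, groups, voxel_index = vec$voxel_index)
    sel <- rfe(fm, C = config$C, r = config$rfe_fraction,
               standardize = config$standardize)
    probs <- NULL
    set_cases <- Filter(function(cs) cs$tissue == tissue, cases)
    if (length(set_cases)) {
      probs <- do.call(rbind, lapply(set_cases, function(cs) {
        dc <- downsample(cs, config$downsample_edge)
        classify_case(sel$ensemble, dc$data[vec$voxel_index],
                      case_id = cs$subject_id)
      }))
      rownames(probs) <- NULL
    }
    out[[set_name]] <- list(loo_accuracy = sel$ensemble$loo_accuracy,
                            rfe_trace = sel$trace,
                            n_features = length(sel$features),
                            case_probabilities = probs)
  }
  structure(c(out, list(manifest = manifest(config))), class = "mvpa_report")
}

#' Canonical region sets for a synthetic cohort
#'
#' The four analyses the pipeline reports: bilateral superior parietal
#' (visuo-spatial), orbitofrontal + amygdala + fusiform (social), whole
#' gray matter, whole white matter.
#'
#' @param spec a [synthetic_spec].
#' @return named list of region sets for [run_mvpa].
#' @export
default_region_sets <- function(spec) {
  lab <- spec$rois$labels
  union_of <- function(names) {
    Reduce(`|`, lab[names])
  }
  sp <- spec$spacing
  list(
    visuo_spatial = list(mask = brain_mask(union_of(c("L_SPL", "R_SPL")), sp),
                         tissue = "gray"),
    social = list(mask = brain_mask(union_of(c("R_OFC", "L_FG", "R_FG",
                                               "L_amygdala", "R_amygdala")), sp),
                  tissue = "gray"),
    whole_gray = list(mask = brain_mask(array(TRUE, spec$dim), sp),
                      tissue = "gray"),
    whole_white = list(mask = brain_mask(array(TRUE, spec$dim), sp),
                       tissue = "white")
  )
}

#' Write a report as JSON
#'
#' Serializes a report's tables and manifest (not the voxel maps) to a JSON
#' file; maps should be written with [write_volume].
#'
#' @param report a report object from `run_*`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  keep <- Filter(function(x) !inherits(x, c("deviation_result",
                                            "probabilistic_map")) &&
                   !is.function(x),
                 report)
  keep$deviations <- NULL
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, force = TRUE)
  invisible(path)
}
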