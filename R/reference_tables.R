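# ---------------------------------------------------------------------------
# Published reference summaries and case scores used as worked-example inputs
# and as the synthetic generator's behavioral defaults.
# ---------------------------------------------------------------------------

#' Reference group summaries for behavioral and volumetric measures
#'
#' Published means and standard deviations of the 1.5T Williams-syndrome
#' (n = 42) and typically-developing (n = 40) reference cohorts on the
#' scalar measures the pipeline handles: Wechsler IQ subscales (standard
#' scores), Beery Visuo-Motor Integration (standard score), Benton Judgment
#' of Line Orientation (age/gender-adjusted raw), Wechsler Block Design
#' (standard score), social approachability (raw), and manually delineated
#' amygdala gray-matter volumes (ml, adjusted for total cranium gray
#' matter). `direction` is the sign of the known WS-minus-TD group
#' difference, which fixes the tail for one-tailed behavioral cutoffs.
#'
#' The `total_gm` row is a synthetic default for the cohort generator (total
#' cranium gray matter in ml is not part of the published summary table);
#' it encodes the well-replicated global gray-matter reduction in WS.
#'
#' @return data.frame with columns `measure`, `mean_ws`, `sd_ws`, `mean_td`,
#'   `sd_td`, `direction`, `synthetic`.
#' @export
ws_td_reference <- function() {
  data.frame(
    measure = c("verbal_iq", "performance_iq", "full_scale_iq", "beery_vmi",
                "benton_jlo", "block_design", "approachability",
                "lt_amygdala", "rt_amygdala", "total_gm"),
    mean_ws = c(71.90, 67.55, 68.55, 49.81, 11.54, 4.32, 17.62, 1.80, 1.65, 620),
    sd_ws   = c(7.43, 8.55, 8.34, 7.86, 6.64, 1.68, 7.77, 0.34, 0.26, 60),
    mean_td = c(103.31, 104.56, 104.25, 91.07, 26.18, 12.25, 7.81, 1.60, 1.46, 700),
    sd_td   = c(11.03, 12.72, 12.42, 9.91, 2.35, 2.32, 7.47, 0.33, 0.29, 65),
    direction = c(-1, -1, -1, -1, -1, -1, +1, +1, +1, -1),
    synthetic = c(rep(FALSE, 9), TRUE),
    stringsAsFactors = FALSE
  )
}

#' Published scalar scores of the atypical-deletion cases
#'
#' Raw scores of the three atypical 7q11.23-deletion index cases on the
#' measures in [ws_td_reference] (amygdala volumes already adjusted for
#' total cranium gray matter). These are the worked-example inputs for the
#' scalar deviation stage.
#'
#' @return data.frame with columns `case_id` and one column per measure.
#' @export
awsdel_cases <- function() {
  data.frame(
    case_id = c("AWSdel-01", "AWSdel-02", "AWSdel-03i"),
    verbal_iq = c(90, 84, 88),
    performance_iq = c(87, 78, 82),
    full_scale_iq = c(88, 79, 84),
    beery_vmi = c(75, 54, 81),
    benton_jlo = c(25, 15, 17),
    block_design = c(9, 10, 7),
    approachability = c(21, 26, 28),
    lt_amygdala_adj = c(2.26, 2.27, 2.33),
    rt_amygdala_adj = c(1.67, 2.19, 1.77),
    stringsAsFactors = FALSE
  )
}
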