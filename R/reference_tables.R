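# Published reference series used as inputs by the validation and analytics
# layers: the observed Shanghai public-hospital expense series (2011-2016),
# the model-validation pairs for 2015/2016, and the three-year baseline
# simulation results, all as printed in the source study's tables.

#' Observed per-capita expense series, Shanghai public hospitals 2011-2016
#'
#' Outpatient and inpatient medical expenses per capita (CNY) with the
#' published annual growth rates (percent; NA for the first year).
#'
#' @return Data frame with columns `year`, `outpatient_pc`,
#'   `outpatient_growth`, `inpatient_pc`, `inpatient_growth`.
#' @export
shanghai_expense_series <- function() {
  data.frame(
    year = 2011:2016,
    outpatient_pc = c(252.8, 265.9, 276.0, 289.0, 306.9, 330.2),
    outpatient_growth = c(NA, 5.2, 4.1, 4.4, 6.2, 7.6),
    inpatient_pc = c(12897.7, 13498.2, 14243.2, 14862.2, 15935.7, 16942.5),
    inpatient_growth = c(NA, 4.7, 5.5, 4.3, 7.2, 6.3))
}

#' Model-validation reference pairs (2015 and 2016)
#'
#' Simulated and observed values of the ten validation metrics for each
#' validation year, with the published percent-difference column. Ratio
#' metrics are in percent, expense metrics in CNY.
#'
#' @return Data frame with columns `metric`, `year`, `simulated`, `actual`,
#'   `published_difference`.
#' @export
validation_reference <- function() {
  m <- c("outpatient_total", "outpatient_medicine", "outpatient_exam",
         "ratio_outpatient_medicine", "ratio_outpatient_exam",
         "inpatient_total", "inpatient_medicine", "inpatient_exam",
         "ratio_inpatient_medicine", "ratio_inpatient_exam")
  data.frame(
    metric = rep(m, 2),
    year = rep(c(2015L, 2016L), each = 10),
    simulated = c(304.2, 176.5, 35.6, 58.0, 11.7,
                  15789.0, 5382.1, 1005.3, 37.0, 6.4,
                  311.0, 178.1, 36.4, 57.3, 11.7,
                  15487.4, 5166.4, 1019.1, 33.4, 6.6),
    actual = c(306.9, 168.5, 34.4, 54.9, 11.2,
               15935.7, 5523.7, 933.9, 34.1, 5.9,
               330.2, 173.0, 39.0, 52.4, 11.8,
               16942.5, 5584.0, 1033.1, 33.0, 6.1),
    published_difference = c(-0.9, 4.7, 3.5, 5.6, 4.5,
                             -0.9, -2.6, 7.6, 1.7, 8.5,
                             -5.8, 2.9, -6.7, 9.4, -0.8,
                             -8.6, -7.5, -1.4, 1.2, 8.2),
    stringsAsFactors = FALSE)
}

#' Published baseline simulation results (three years)
#'
#' The baseline three-year simulation outputs as printed: per-capita expense
#' components (CNY), component ratios, subsidy proportions, patient shares
#' per institution type, and the over-prescription probability (all
#' percentage metrics in percent).
#'
#' @return Data frame with columns `metric`, `year1`, `year2`, `year3`.
#' @export
baseline_reference <- function() {
  data.frame(
    metric = c("outpatient_total", "outpatient_medicine", "outpatient_exam",
               "ratio_outpatient_medicine", "ratio_outpatient_exam",
               "inpatient_total", "inpatient_medicine", "inpatient_exam",
               "ratio_inpatient_medicine", "ratio_inpatient_exam",
               "subsidy_tertiary_comprehensive", "subsidy_specialized",
               "subsidy_district_hospital", "subsidy_community_center",
               "share_tertiary_comprehensive", "share_specialized",
               "share_district_hospital", "share_community_center",
               "overrx_rate"),
    year1 = c(304.2, 176.5, 35.6, 58.0, 11.7,
              15789.0, 5382.1, 1005.3, 37.0, 6.4,
              6.2, 9.3, 9.7, 15.2, 40.2, 1.9, 44.0, 13.8, 50.0),
    year2 = c(311.0, 178.1, 36.4, 57.3, 11.7,
              15487.4, 5166.4, 1019.1, 33.4, 6.6,
              6.2, 9.2, 9.7, 15.6, 40.2, 2.0, 44.0, 13.9, 50.2),
    year3 = c(314.5, 176.1, 37.4, 56.0, 11.9,
              14662.1, 4753.9, 1033.8, 32.4, 7.1,
              6.2, 9.1, 9.7, 16.3, 40.2, 1.9, 44.0, 14.0, 50.0),
    stringsAsFactors = FALSE)
}
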