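# Doctor agents: the expected-income workload regression, the two-regime
# over-prescription decision, annual income/workload dynamics, and the
# government-subsidy -> public-welfare responsibility index that damps
# over-prescription.

#' Expected income from weekly workload
#'
#' The linear expectation `intercept + slope * weekly_hours` with the
#' published coefficients (intercept -12,685.5 CNY, slope 678.13 CNY per
#' weekly hour); strictly increasing in hours. Only the sign of the
#' comparison with actual income matters to the over-prescription rule, so
#' the output is kept on whatever scale actual incomes use.
#'
#' @param weekly_hours Positive weekly working hours.
#' @param params `doctor_params` list from the configuration.
#' @return Expected income in CNY.
#' @export
expected_income <- function(weekly_hours, params) {
  if (any(weekly_hours <= 0)) stop("weekly_hours must be > 0")
  params$expectation_intercept + params$expectation_slope * weekly_hours
}

#' Instantiate the doctor roster
#'
#' One doctor per professional title per institution, with title-level
#' incomes and weekly hours from the configuration.
#'
#' @param config A validated `hospexp_config`.
#' @return Data frame of doctor agents: `id`, `institution_id`, `title`,
#'   `actual_income`, `weekly_hours`, `over_prescribing`.
#' @export
make_doctors <- function(config) {
  dp <- config$doctor_params
  inst <- config$institutions
  titles <- names(dp$income_by_title)
  df <- expand.grid(title = titles, institution_id = inst$id,
                    stringsAsFactors = FALSE)
  data.frame(id = seq_len(nrow(df)),
             institution_id = df$institution_id,
             title = df$title,
             actual_income = unname(dp$income_by_title[df$title]),
             weekly_hours = unname(dp$weekly_hours_by_title[df$title]),
             over_prescribing = FALSE,
             stringsAsFactors = FALSE)
}

#' Over-prescription probability for a doctor
#'
#' Base probability is `p_expectation_met` when
#' `expected_income(weekly_hours) >= actual_income` XOR
#' `condition_swapped`, otherwise `p_expectation_unmet`; the base is then
#' damped by the institution's public-welfare responsibility index:
#' `base * (1 - responsibility_index)`. The more social responsibility an
#' institution undertakes, the lower the over-prescription probability, down
#' to zero at full responsibility.
#'
#' @param doctor Doctor row(s) with `actual_income` and `weekly_hours`.
#' @param params `doctor_params` list (for the expectation regression).
#' @param rule An [over_prescription_rule()].
#' @param responsibility_index Value(s) in `[0, 1]`.
#' @return Probability vector in `[0, 1]`.
#' @export
over_prescription_probability <- function(doctor, params, rule,
                                          responsibility_index) {
  if (any(responsibility_index < 0 | responsibility_index > 1))
    stop("responsibility_index must lie in [0, 1]")
  cond <- expected_income(doctor$weekly_hours, params) >= doctor$actual_income
  if (isTRUE(rule$condition_swapped)) cond <- !cond
  base <- ifelse(cond, rule$p_expectation_met, rule$p_expectation_unmet)
  base * (1 - responsibility_index)
}

#' Bernoulli over-prescription decision
#'
#' @param prob Probability vector in `[0, 1]`.
#' @return Logical vector of decisions.
#' @export
decide_over_prescription <- function(prob) {
  if (any(prob < 0 | prob > 1)) stop("probability must lie in [0, 1]")
  stats::runif(length(prob)) < prob
}

#' Advance doctors by one year
#'
#' Actual income grows by the shared annual income growth rate; weekly hours
#' change by the annual hours-change rate, clamped to the (0, 60] range (60
#' hours is the workload cap).
#'
#' @param doctor Doctor data frame (or single row).
#' @param params `doctor_params` list.
#' @return Updated doctor data frame.
#' @export
advance_doctor_year <- function(doctor, params) {
  doctor$actual_income <- doctor$actual_income * (1 + params$income_growth)
  doctor$weekly_hours <- pmin(doctor$weekly_hours * (1 + params$hours_change), 60)
  doctor
}

#' Public-welfare responsibility index from government subsidy
#'
#' Piecewise-linear in the subsidy ratio `subsidy / baseline`:
#' `clamp((ratio - r0) / (rmax - r0), 0, 1)`, with the saturation ratio
#' `rmax` taken per institution type from the policy (1.75 for community
#' health service centers: at 175% of the baseline subsidy, public-welfare
#' responsibility is undertaken perfectly). Monotone non-decreasing in the
#' subsidy.
#'
#' @param subsidy_proportion Current subsidy proportion(s).
#' @param baseline_subsidy Baseline (year-0) subsidy proportion(s); must be
#'   positive.
#' @param policy Policy list with `r0` and per-type `rmax`.
#' @param type Institution type name(s) selecting `rmax`.
#' @return Index value(s) in `[0, 1]`.
#' @export
responsibility_index <- function(subsidy_proportion, baseline_subsidy, policy,
                                 type = "community_center") {
  if (any(subsidy_proportion < 0) || any(baseline_subsidy < 0))
    stop("subsidies must be non-negative")
  if (any(baseline_subsidy == 0))
    stop("baseline_subsidy must be positive")
  rmax <- unname(policy$rmax[type])
  ratio <- subsidy_proportion / baseline_subsidy
  unname(pmin(pmax((ratio - policy$r0) / (rmax - policy$r0), 0), 1))
}
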