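# Expense engine: care-event draws, schedule growth, episode pricing with
# over-prescription inflation and adherence scaling, and annual aggregation
# into Table-style summaries.

#' Draw the care events for one patient episode
#'
#' Independent Bernoulli draws for an outpatient visit and a hospitalization
#' (at least one of the two is forced: a generated patient seeks care),
#' surgery conditional on hospitalization, and a physical examination with
#' its own probability.
#'
#' @param disease One row of the disease-profile table.
#' @return Named logical list: `outpatient`, `hospitalized`, `surgery`,
#'   `physical_exam`.
#' @export
draw_care_events <- function(disease) {
  u <- stats::runif(4)
  outpatient <- u[1] < disease$p_outpatient
  hospitalized <- u[2] < disease$p_hospitalization
  if (!outpatient && !hospitalized) outpatient <- TRUE
  surgery <- hospitalized && (u[3] < disease$p_surgery)
  physical_exam <- u[4] < disease$p_physical_exam
  list(outpatient = outpatient, hospitalized = hospitalized,
       surgery = surgery, physical_exam = physical_exam)
}

#' Compound a base expense over time
#'
#' `base * (1 + growth)^year`, exactly.
#'
#' @param base Base amount in CNY at year 0.
#' @param growth Annual growth rate (fraction, > -1).
#' @param year Non-negative integer year.
#' @return Grown amount in CNY.
#' @export
grown_expense <- function(base, growth, year) {
  if (any(year < 0)) stop("year must be >= 0")
  if (any(growth <= -1)) stop("growth must be > -1")
  base * (1 + growth)^year
}

#' Prescription adherence from insurance reimbursement
#'
#' Adherence is measured by the reimbursement proportion: one minus the
#' scheme's out-of-pocket copay at the institution's level. Uninsured
#' patients (copay 1 everywhere) have adherence 0 and accept none of the
#' over-prescribed extras.
#'
#' @param scheme One row of the insurance table (fields `copay_primary`,
#'   `copay_secondary`, `copay_tertiary`).
#' @param level `"primary"`, `"secondary"` or `"tertiary"`.
#' @return Adherence fraction in `[0, 1]`.
#' @export
adherence_factor <- function(scheme, level) {
  col <- paste0("copay_", level)
  if (!col %in% names(scheme)) stop("unknown institution level: ", level)
  1 - scheme[[col]]
}

# Vectorized episode pricing. `df` has one row per episode with columns
# disease_id, institution_type, institution_level, insurance, outpatient,
# hospitalized, surgery_event, physical_exam, over_prescribed, degree
# (the event flag is `surgery_event` so it cannot shadow the surgery expense
# component in assembled records). Returns the
# nine final components plus adherence, extra (accepted over-prescription
# inflation) and total.
episode_components <- function(df, config, year) {
  comps <- expense_components()
  key <- paste(config$expense_base$disease_id,
               config$expense_base$institution_type)
  idx <- match(paste(df$disease_id, df$institution_type), key)
  if (anyNA(idx))
    stop("missing expense schedule entry for disease/institution type pair")
  base <- as.matrix(config$expense_base[comps])[idx, , drop = FALSE]
  grw <- as.matrix(config$expense_growth[comps])[idx, , drop = FALSE]
  M <- grown_expense(base, grw, year)

  out <- df$outpatient
  hosp <- df$hospitalized
  exam <- df$physical_exam
  M[, "outpatient_base"] <- M[, "outpatient_base"] * out
  M[, "outpatient_medicine"] <- M[, "outpatient_medicine"] * out
  M[, "outpatient_exam"] <- M[, "outpatient_exam"] * (out & exam)
  M[, "inpatient_base"] <- M[, "inpatient_base"] * hosp
  M[, "inpatient_medicine"] <- M[, "inpatient_medicine"] * hosp
  M[, "inpatient_exam"] <- M[, "inpatient_exam"] * (hosp & exam)
  M[, "treatment"] <- M[, "treatment"] * hosp
  M[, "material"] <- M[, "material"] * hosp
  M[, "surgery"] <- M[, "surgery"] * df$surgery_event

  ins <- config$insurance
  irow <- match(df$insurance, ins$name)
  if (anyNA(irow)) stop("unknown insurance scheme in episode data")
  copay <- as.matrix(ins[c("copay_primary", "copay_secondary",
                           "copay_tertiary")])
  lvl <- match(df$institution_level, c("primary", "secondary", "tertiary"))
  adherence <- 1 - copay[cbind(irow, lvl)]

  med_base <- M[, "outpatient_medicine"] + M[, "inpatient_medicine"]
  exam_base <- M[, "outpatient_exam"] + M[, "inpatient_exam"]
  inflatable <- med_base + exam_base
  extra <- ifelse(df$over_prescribed, df$degree * inflatable, 0) * adherence
  # Allocate the accepted extra across the inflatable components in
  # proportion to their base amounts, so outpatient/inpatient splits and the
  # medicine/exam split are preserved.
  scale <- ifelse(inflatable > 0, 1 + extra / inflatable, 1)
  for (cmp in c("outpatient_medicine", "inpatient_medicine",
                "outpatient_exam", "inpatient_exam"))
    M[, cmp] <- M[, cmp] * scale

  res <- as.data.frame(M)
  res$adherence <- adherence
  res$extra <- extra
  res$total <- rowSums(M)
  res
}

#' Price a single patient episode
#'
#' Applies the disease's expense schedule at the assigned institution's type,
#' compounded to the given year; if the doctor over-prescribed, the medicine
#' and physical-examination components are inflated by
#' `degree * (medicine + exam base)`, of which the patient accepts the
#' adherence fraction (their insurance reimbursement proportion at the
#' institution's level). Components not touched by over-prescription are
#' unchanged, and the record's total is the exact component sum.
#'
#' @param patient One patient row (field `insurance`).
#' @param institution One institution row (fields `id`, `type`, `level`).
#' @param decision Logical: did the doctor over-prescribe?
#' @param degree Inflation degree (used only when `decision` is `TRUE`).
#' @param events Event list from [draw_care_events()].
#' @param config A validated `hospexp_config`.
#' @param year Simulated year (growth exponent).
#' @return One-row expense-record data frame.
#' @export
episode_expense <- function(patient, institution, decision, degree, events,
                            config, year) {
  df <- data.frame(disease_id = patient$disease_id,
                   institution_type = institution$type,
                   institution_level = institution$level,
                   insurance = patient$insurance,
                   outpatient = events$outpatient,
                   hospitalized = events$hospitalized,
                   surgery_event = events$surgery,
                   physical_exam = events$physical_exam,
                   over_prescribed = isTRUE(decision),
                   degree = degree,
                   stringsAsFactors = FALSE)
  res <- episode_components(df, config, year)
  cbind(data.frame(patient_id = patient$id, institution_id = institution$id,
                   year = year, stringsAsFactors = FALSE),
        df, res)
}

#' Aggregate episode records into an annual summary
#'
#' Per-capita outpatient figures average the outpatient components over
#' episodes with an outpatient event; per-capita inpatient figures average
#' the inpatient components (including treatment, surgery and material) over
#' hospitalized episodes — the yearbook's per-visit / per-admission
#' convention. Ratios divide the component per-capita by the corresponding
#' total per-capita; patient shares count episodes per institution type; the
#' over-prescription rate is the fraction of episodes whose doctor
#' over-prescribed; subsidy proportions are the policy state for the year.
#'
#' @param records Episode-record data frame (rows from [episode_expense()] or
#'   an internal simulation year).
#' @param config A validated `hospexp_config`.
#' @param year Simulated year.
#' @return One-row annual-summary data frame.
#' @export
aggregate_year <- function(records, config, year) {
  if (is.null(records) || nrow(records) == 0)
    stop("aggregate_year needs at least one episode record")
  out <- records$outpatient
  hosp <- records$hospitalized
  op_tot <- records$outpatient_base + records$outpatient_medicine +
    records$outpatient_exam
  ip_tot <- records$inpatient_base + records$inpatient_medicine +
    records$inpatient_exam + records$treatment + records$surgery +
    records$material

  pc <- function(x, mask) if (any(mask)) mean(x[mask]) else NA_real_
  outpatient_total <- pc(op_tot, out)
  outpatient_medicine <- pc(records$outpatient_medicine, out)
  outpatient_exam <- pc(records$outpatient_exam, out)
  inpatient_total <- pc(ip_tot, hosp)
  inpatient_medicine <- pc(records$inpatient_medicine, hosp)
  inpatient_exam <- pc(records$inpatient_exam, hosp)

  inst <- config$institutions
  g <- config$policy$subsidy_growth
  subsidy_now <- inst$subsidy_proportion * (1 + g[inst$type])^year
  sub_by_type <- tapply(subsidy_now, inst$type, mean)

  share <- table(factor(records$institution_type,
                        levels = institution_types()))
  share <- as.numeric(share) / nrow(records)

  s <- data.frame(
    year = year,
    outpatient_total = outpatient_total,
    outpatient_medicine = outpatient_medicine,
    outpatient_exam = outpatient_exam,
    ratio_outpatient_medicine = outpatient_medicine / outpatient_total,
    ratio_outpatient_exam = outpatient_exam / outpatient_total,
    inpatient_total = inpatient_total,
    inpatient_medicine = inpatient_medicine,
    inpatient_exam = inpatient_exam,
    ratio_inpatient_medicine = inpatient_medicine / inpatient_total,
    ratio_inpatient_exam = inpatient_exam / inpatient_total,
    subsidy_tertiary_comprehensive = unname(sub_by_type["tertiary_comprehensive"]),
    subsidy_specialized = unname(sub_by_type["specialized"]),
    subsidy_district_hospital = unname(sub_by_type["district_hospital"]),
    subsidy_community_center = unname(sub_by_type["community_center"]),
    share_tertiary_comprehensive = share[1],
    share_specialized = share[2],
    share_district_hospital = share[3],
    share_community_center = share[4],
    overrx_rate = mean(records$over_prescribed),
    overall_total = mean(records$total),
    n_episodes = nrow(records),
    n_outpatient = sum(out),
    n_inpatient = sum(hosp))
  class(s) <- c("hospexp_summary", "data.frame")
  s
}
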