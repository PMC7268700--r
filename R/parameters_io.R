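# Configuration schema, synthetic parameter generator, and config/summary I/O.
#
# A `hospexp_config` is a named list holding every input the simulator needs:
# 30 disease profiles, per-disease/per-institution-type expense schedules with
# annual growth rates, 16 district rectangles with population shares, an
# institution roster, insurance schemes with level-dependent copays, government
# policy (subsidies, first-visit promotion), doctor income/workload parameters,
# the over-prescription rule, demographic marginals and a care-seeking
# preference lookup. The real study's parameter table is not public, so
# `generate_fixture()` builds a complete synthetic configuration with the same
# structure and plausibly-scaled values.

#' Institution types of the tiered public-hospital system
#'
#' The four facility categories, ordered as used throughout the package:
#' tertiary comprehensive hospitals, specialized hospitals (both tertiary
#' level), district hospitals (secondary) and community health service centers
#' (primary).
#'
#' @return Character vector of the four institution type names.
#' @export
institution_types <- function() {
  c("tertiary_comprehensive", "specialized", "district_hospital",
    "community_center")
}

#' Map institution types to care levels
#'
#' @param type Character vector of institution types.
#' @return Character vector of levels (`"primary"`, `"secondary"`,
#'   `"tertiary"`).
#' @export
institution_level <- function(type) {
  map <- c(tertiary_comprehensive = "tertiary", specialized = "tertiary",
           district_hospital = "secondary", community_center = "primary")
  bad <- setdiff(type, names(map))
  if (length(bad)) stop("unknown institution type: ", paste(bad, collapse = ", "))
  unname(map[type])
}

#' Expense schedule components
#'
#' The nine per-episode expense components priced by the schedule, in CNY.
#'
#' @return Character vector of component names.
#' @export
expense_components <- function() {
  c("outpatient_base", "outpatient_medicine", "outpatient_exam",
    "inpatient_base", "inpatient_medicine", "inpatient_exam",
    "treatment", "surgery", "material")
}

severity_classes <- function() c("minor", "common", "severe")

doctor_titles <- function() c("resident", "attending", "associate_chief", "chief")

#' Over-prescription decision rule
#'
#' Builds the two-regime over-prescription rule. Doctors over-prescribe with
#' probability `p_expectation_met` in one income regime and
#' `p_expectation_unmet` in the other; which regime the comparison
#' `expected income >= actual income` selects is controlled by
#' `condition_swapped`. With the default `condition_swapped = FALSE`,
#' `expected >= actual` selects `p_expectation_met` — the literal published
#' wording of the rule. Setting `condition_swapped = TRUE` gives the
#' economically coherent direction in which a doctor whose expectation is not
#' met by their actual income (expected > actual) over-prescribes more; the
#' synthetic fixture uses that orientation so that income/workload
#' interventions move over-prescription the way the intervention experiments
#' report (see the methods vignette).
#'
#' @param p_expectation_met Over-prescription probability in the
#'   expectation-met regime (default 0.10).
#' @param p_expectation_unmet Probability in the expectation-unmet regime
#'   (default 0.50).
#' @param degree_range Length-2 interval from which the multiplicative
#'   inflation degree applied to medicine and physical-exam components is
#'   drawn.
#' @param condition_swapped Logical; see Details.
#' @return A list of class `hospexp_overrx_rule`.
#' @export
over_prescription_rule <- function(p_expectation_met = 0.10,
                                   p_expectation_unmet = 0.50,
                                   degree_range = c(0.1, 0.5),
                                   condition_swapped = FALSE) {
  if (!(p_expectation_met >= 0 && p_expectation_met <= p_expectation_unmet &&
        p_expectation_unmet <= 1))
    stop("over-prescription probabilities must satisfy 0 <= p_expectation_met <= p_expectation_unmet <= 1")
  if (length(degree_range) != 2 || any(degree_range <= 0) ||
      degree_range[1] > degree_range[2])
    stop("degree_range must be an interval within (0, Inf)")
  structure(list(p_expectation_met = p_expectation_met,
                 p_expectation_unmet = p_expectation_unmet,
                 degree_range = as.numeric(degree_range),
                 condition_swapped = isTRUE(condition_swapped)),
            class = "hospexp_overrx_rule")
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of the configuration schema: probability
#' ranges, 30 complete disease profiles with schedules for all four
#' institution types, district/insurance/demographic shares summing to one,
#' institution type/level consistency, copay ordering, and positive population
#' and horizon. Errors name the offending field (and disease/district id where
#' applicable).
#'
#' @param config A `hospexp_config` list.
#' @return `config`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_config <- function(config) {
  need <- c("diseases", "expense_base", "expense_growth", "districts",
            "institutions", "insurance", "policy", "doctor_params",
            "overrx_rule", "preference", "demographics", "population_size",
            "years", "cycles_per_year", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("configuration is missing fields: ", paste(miss, collapse = ", "))

  dis <- config$diseases
  if (nrow(dis) != 30L)
    stop("diseases: a full configuration requires exactly 30 disease profiles, got ", nrow(dis))
  if (!identical(sort(dis$id), 1:30))
    stop("diseases: ids must be exactly 1..30")
  for (p in c("two_week_prevalence", "p_outpatient", "p_hospitalization",
              "p_surgery", "p_physical_exam")) {
    bad <- which(dis[[p]] < 0 | dis[[p]] > 1)
    if (length(bad))
      stop(sprintf("disease %d: field %s = %.4g is outside [0, 1]",
                   dis$id[bad[1]], p, dis[[p]][bad[1]]))
  }
  if (!all(dis$severity_class %in% severity_classes()))
    stop("diseases: severity_class must be one of ",
         paste(severity_classes(), collapse = ", "))

  comps <- expense_components()
  for (nm in c("expense_base", "expense_growth")) {
    eb <- config[[nm]]
    if (!all(c("disease_id", "institution_type", comps) %in% names(eb)))
      stop(nm, ": missing required columns")
    key <- paste(eb$disease_id, eb$institution_type)
    want <- paste(rep(1:30, each = 4), rep(institution_types(), 30))
    if (!all(want %in% key))
      stop(nm, ": every disease needs a schedule for all four institution types")
  }
  if (any(as.matrix(config$expense_base[comps]) < 0))
    stop("expense_base: base amounts must be >= 0")
  if (any(as.matrix(config$expense_growth[comps]) <= -1))
    stop("expense_growth: growth rates must be > -1")

  dd <- config$districts
  if (abs(sum(dd$population_share) - 1) > 1e-9)
    stop(sprintf("normalization error: district population shares sum to %.6f, not 1",
                 sum(dd$population_share)))
  if (any(dd$lat_min >= dd$lat_max | dd$lon_min >= dd$lon_max))
    stop("districts: degenerate bounding rectangle")

  inst <- config$institutions
  if (!all(inst$type %in% institution_types()))
    stop("institutions: unknown type")
  if (!identical(inst$level, institution_level(inst$type)))
    stop("institutions: level inconsistent with type (community_center => primary, district_hospital => secondary, tertiary/specialized => tertiary)")
  if (!all(institution_types() %in% inst$type))
    stop("institutions: all four institution types must be represented")
  if (any(inst$subsidy_proportion < 0 | inst$subsidy_proportion > 1))
    stop("institutions: subsidy_proportion must lie in [0, 1]")

  ins <- config$insurance
  if (abs(sum(ins$population_share) - 1) > 1e-9)
    stop(sprintf("normalization error: insurance scheme shares sum to %.6f, not 1",
                 sum(ins$population_share)))
  cop <- as.matrix(ins[c("copay_primary", "copay_secondary", "copay_tertiary")])
  if (any(cop < 0 | cop > 1))
    stop("insurance: copay proportions must lie in [0, 1]")
  if (any(ins$copay_primary > ins$copay_tertiary))
    stop("insurance: copay_primary must not exceed copay_tertiary within a scheme")

  pol <- config$policy
  if (pol$promotion_degree < 0) stop("policy: promotion_degree must be >= 0")
  if (!all(institution_types() %in% names(pol$subsidy_growth)))
    stop("policy: subsidy_growth needs a rate per institution type")
  if (!all(institution_types() %in% names(pol$rmax)))
    stop("policy: rmax needs a saturation ratio per institution type")
  if (any(pol$rmax <= pol$r0)) stop("policy: rmax must exceed r0")

  dp <- config$doctor_params
  if (any(dp$income_by_title <= 0)) stop("doctor_params: incomes must be > 0")
  hrs <- dp$weekly_hours_by_title
  if (any(hrs <= 0 | hrs > 60))
    stop("doctor_params: weekly hours must lie in (0, 60]")
  if (abs(sum(dp$title_mix) - 1) > 1e-9)
    stop("normalization error: doctor title mix sums to ", sum(dp$title_mix))

  rule <- config$overrx_rule
  if (!(rule$p_expectation_met >= 0 &&
        rule$p_expectation_met <= rule$p_expectation_unmet &&
        rule$p_expectation_unmet <= 1))
    stop("overrx_rule: need 0 <= p_expectation_met <= p_expectation_unmet <= 1")

  for (f in names(config$demographics)) {
    s <- sum(config$demographics[[f]])
    if (abs(s - 1) > 1e-9)
      stop(sprintf("normalization error: demographic distribution '%s' sums to %.6f, not 1", f, s))
  }

  pref <- config$preference
  wcols <- institution_types()
  if (!all(wcols %in% names(pref))) stop("preference: missing weight columns")
  W <- as.matrix(pref[wcols])
  if (any(W < 0)) stop("preference: weights must be non-negative")
  if (any(rowSums(W) <= 0)) stop("preference: every row needs a positive weight")
  sev0 <- pref$community_center[pref$severity_class == "severe"]
  if (any(sev0 != 0))
    stop("preference: severe rows must give zero weight to community centers")

  if (config$population_size <= 0) stop("population_size must be > 0")
  if (config$years < 1) stop("years must be >= 1")
  if (config$cycles_per_year < 1) stop("cycles_per_year must be >= 1")
  invisible(config)
}

# Demographic band levels used by the fixture and the preference lookup.
demographic_levels <- function() {
  list(gender = c("male", "female"),
       age_band = c("age_0_14", "age_15_44", "age_45_64", "age_65plus"),
       occupation = c("employed", "student", "retired", "other"),
       marital_status = c("single", "married", "other"),
       education = c("primary", "secondary", "tertiary"),
       income_band = c("low", "middle", "high"))
}

#' Generate a complete synthetic parameter set
#'
#' Builds a full, validated configuration emulating the structure of the
#' study's initial-parameter table: 30 disease profiles with two-week
#' prevalences drawn log-uniformly in 0.0005–0.05, severity classes (12 minor,
#' 12 common, 6 severe), care-event probabilities, and per-institution-type
#' expense schedules ordered tertiary > district > community in every
#' component; 16 districts tiling a rectangle approximating Shanghai's
#' latitude/longitude extent with gamma-distributed population shares; an
#' institution roster with all four types; insurance schemes with primary
#' copay 0.30 and tertiary copay 0.50 (uninsured pay everything out of
#' pocket); doctor income/workload parameters on the scale of the expected-
#' income regression so that titles straddle the regime boundary; and a
#' care-seeking preference lookup that concentrates first choices on district
#' and tertiary comprehensive hospitals. Identical seeds give identical
#' configurations, field for field.
#'
#' @param seed Integer seed; the generator seeds the RNG itself.
#' @param population_size Number of residents the simulator draws patients
#'   from each two-week cycle.
#' @param years Default simulation horizon in years.
#' @return A validated `hospexp_config`.
#' @export
generate_fixture <- function(seed, population_size = 100000L, years = 3L) {
  if (population_size <= 0) stop("population_size must be > 0")
  set.seed(as.integer(seed))
  types <- institution_types()
  comps <- expense_components()

  ## --- diseases ------------------------------------------------------------
  n_dis <- 30L
  severity <- rep(severity_classes(), times = c(12L, 12L, 6L))
  prevalence <- 10^stats::runif(n_dis, log10(5e-4), log10(0.05))
  p_out <- ifelse(severity == "severe", stats::runif(n_dis, 0.55, 0.70),
                  stats::runif(n_dis, 0.85, 0.95))
  p_hosp <- c(stats::runif(12, 0.01, 0.05), stats::runif(12, 0.05, 0.15),
              stats::runif(6, 0.30, 0.60))
  p_surg <- ifelse(severity == "severe", stats::runif(n_dis, 0.20, 0.70),
                   stats::runif(n_dis, 0.00, 0.40))
  p_exam <- stats::runif(n_dis, 0.20, 0.60)
  specialized_eligible <- seq_len(n_dis) %in% sample.int(n_dis, 5L)
  diseases <- data.frame(
    id = seq_len(n_dis),
    name = sprintf("disease_%02d", seq_len(n_dis)),
    two_week_prevalence = prevalence,
    severity_class = severity,
    p_outpatient = p_out,
    p_hospitalization = p_hosp,
    p_surgery = p_surg,
    p_physical_exam = p_exam,
    specialized_eligible = specialized_eligible,
    stringsAsFactors = FALSE)

  ## --- expense schedules ---------------------------------------------------
  # Community base per component, then multiplicative mark-ups by tier so that
  # tertiary (both categories) > district > community in every component.
  lo <- c(outpatient_base = 8, outpatient_medicine = 30, outpatient_exam = 8,
          inpatient_base = 800, inpatient_medicine = 1200, inpatient_exam = 200,
          treatment = 300, surgery = 1500, material = 200)
  hi <- c(outpatient_base = 15, outpatient_medicine = 60, outpatient_exam = 20,
          inpatient_base = 1500, inpatient_medicine = 2500, inpatient_exam = 500,
          treatment = 800, surgery = 4000, material = 600)
  base_rows <- vector("list", n_dis)
  for (d in seq_len(n_dis)) {
    cc <- stats::runif(length(comps), lo, hi)
    dh <- cc * stats::runif(length(comps), 1.5, 2.5)
    sp <- dh * stats::runif(length(comps), 1.3, 2.2)
    tc <- dh * stats::runif(length(comps), 1.5, 2.5)
    m <- rbind(tc, sp, dh, cc)
    df <- data.frame(disease_id = d, institution_type = types,
                     stringsAsFactors = FALSE)
    df[comps] <- as.data.frame(m)
    base_rows[[d]] <- df
  }
  expense_base <- do.call(rbind, base_rows)
  rownames(expense_base) <- NULL
  expense_growth <- expense_base
  expense_growth[comps] <- matrix(stats::runif(nrow(expense_base) * length(comps),
                                               0.03, 0.08),
                                  nrow = nrow(expense_base))

  ## --- districts (4 x 4 tiling of the metropolitan extent) -----------------
  lat_rng <- c(30.70, 31.87)
  lon_rng <- c(120.85, 122.20)
  lat_cuts <- seq(lat_rng[1], lat_rng[2], length.out = 5)
  lon_cuts <- seq(lon_rng[1], lon_rng[2], length.out = 5)
  grid <- expand.grid(row = 1:4, col = 1:4)
  share <- stats::rgamma(16, shape = 2)
  share <- share / sum(share)
  districts <- data.frame(
    id = 1:16,
    name = sprintf("district_%02d", 1:16),
    population_share = share,
    lat_min = lat_cuts[grid$row], lat_max = lat_cuts[grid$row + 1],
    lon_min = lon_cuts[grid$col], lon_max = lon_cuts[grid$col + 1],
    stringsAsFactors = FALSE)

  ## --- institution roster --------------------------------------------------
  n_inst <- c(tertiary_comprehensive = 20L, specialized = 12L,
              district_hospital = 18L, community_center = 50L)
  inst_type <- rep(names(n_inst), n_inst)
  subsidy0 <- c(tertiary_comprehensive = 0.062, specialized = 0.093,
                district_hospital = 0.097, community_center = 0.152)
  institutions <- data.frame(
    id = seq_along(inst_type),
    name = sprintf("%s_%02d", inst_type, stats::ave(seq_along(inst_type),
                                                    inst_type, FUN = seq_along)),
    type = inst_type,
    level = institution_level(inst_type),
    lat = stats::runif(length(inst_type), lat_rng[1], lat_rng[2]),
    lon = stats::runif(length(inst_type), lon_rng[1], lon_rng[2]),
    subsidy_proportion = subsidy0[inst_type] *
      stats::runif(length(inst_type), 0.9, 1.1),
    stringsAsFactors = FALSE)

  ## --- insurance schemes ---------------------------------------------------
  insurance <- data.frame(
    name = c("urban_worker", "urban_rural_resident", "uninsured"),
    population_share = c(0.55, 0.35, 0.10),
    copay_primary = c(0.30, 0.30, 1.00),
    copay_secondary = c(0.40, 0.45, 1.00),
    copay_tertiary = c(0.50, 0.55, 1.00),
    stringsAsFactors = FALSE)

  ## --- government policy ---------------------------------------------------
  policy <- list(
    subsidy_growth = c(tertiary_comprehensive = 0.002, specialized = 0.002,
                       district_hospital = 0.006, community_center = 0.035),
    promotion_degree = 1.0,
    r0 = 0.0,
    rmax = c(tertiary_comprehensive = 3.0, specialized = 3.0,
             district_hospital = 3.0, community_center = 1.75),
    specialized_boost = 8.0,
    rationalized = FALSE)

  ## --- doctors -------------------------------------------------------------
  # Incomes sit on the scale of the expected-income regression so that senior
  # titles are above, junior titles below, the expectation line at baseline
  # workloads; interventions can then flip regimes in either direction.
  doctor_params <- list(
    income_by_title = c(resident = 9500, attending = 14000,
                        associate_chief = 21000, chief = 27000),
    income_growth = 0.03,
    weekly_hours_by_title = c(resident = 46, attending = 44,
                              associate_chief = 42, chief = 40),
    hours_change = 0.01,
    expectation_intercept = -12685.5,
    expectation_slope = 678.13,
    title_mix = c(resident = 0.25, attending = 0.40,
                  associate_chief = 0.22, chief = 0.13))

  ## --- demographics --------------------------------------------------------
  demographics <- list(
    gender = c(male = 0.49, female = 0.51),
    age_band = c(age_0_14 = 0.12, age_15_44 = 0.42, age_45_64 = 0.30,
                 age_65plus = 0.16),
    occupation = c(employed = 0.55, student = 0.12, retired = 0.20,
                   other = 0.13),
    marital_status = c(single = 0.28, married = 0.60, other = 0.12),
    education = c(primary = 0.25, secondary = 0.45, tertiary = 0.30),
    income_band = c(low = 0.30, middle = 0.50, high = 0.20))

  ## --- care-seeking preference lookup --------------------------------------
  preference <- build_preference_table()

  config <- structure(list(
    diseases = diseases,
    expense_base = expense_base,
    expense_growth = expense_growth,
    districts = districts,
    institutions = institutions,
    insurance = insurance,
    policy = policy,
    doctor_params = doctor_params,
    overrx_rule = over_prescription_rule(condition_swapped = TRUE),
    preference = preference,
    demographics = demographics,
    population_size = as.integer(population_size),
    years = as.integer(years),
    cycles_per_year = 26L,
    seed = as.integer(seed)), class = "hospexp_config")
  validate_config(config)
}

# Deterministic preference lookup keyed on (severity, age band, income band).
# Severe rows never weight community centers; district + tertiary
# comprehensive dominate everywhere, mirroring observed first-choice shares.
build_preference_table <- function() {
  lv <- demographic_levels()
  grid <- expand.grid(severity_class = severity_classes(),
                      age_band = lv$age_band,
                      income_band = lv$income_band,
                      stringsAsFactors = FALSE)
  base <- list(minor = c(0.30, 0.02, 0.46, 0.22),
               common = c(0.38, 0.02, 0.46, 0.14),
               severe = c(0.60, 0.05, 0.35, 0.00))
  W <- t(vapply(seq_len(nrow(grid)), function(i) {
    w <- base[[grid$severity_class[i]]]
    sev <- grid$severity_class[i] == "severe"
    if (grid$age_band[i] == "age_65plus" && !sev) {
      w[4] <- w[4] + 0.05; w[1] <- max(w[1] - 0.05, 0)
    }
    if (grid$income_band[i] == "high") {
      if (sev) { w[1] <- w[1] + 0.06; w[3] <- max(w[3] - 0.06, 0) }
      else     { w[1] <- w[1] + 0.06; w[4] <- max(w[4] - 0.06, 0) }
    }
    if (grid$income_band[i] == "low" && !sev) {
      w[4] <- w[4] + 0.04; w[1] <- max(w[1] - 0.04, 0)
    }
    w / sum(w)
  }, numeric(4)))
  colnames(W) <- institution_types()
  cbind(grid, as.data.frame(W))
}

#' @export
print.hospexp_config <- function(x, ...) {
  cat("<hospexp_config>\n")
  cat(sprintf("  %d diseases, %d districts, %d institutions, %d insurance schemes\n",
              nrow(x$diseases), nrow(x$districts), nrow(x$institutions),
              nrow(x$insurance)))
  cat(sprintf("  population %d, %d years x %d cycles, seed %d\n",
              x$population_size, x$years, x$cycles_per_year, x$seed))
  cat(sprintf("  promotion degree %.2f, over-prescription %g/%g (swapped: %s)\n",
              x$policy$promotion_degree, x$overrx_rule$p_expectation_met,
              x$overrx_rule$p_expectation_unmet,
              x$overrx_rule$condition_swapped))
  invisible(x)
}

## ---- config (de)serialization ---------------------------------------------

df_to_records <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    lapply(r, function(v) if (is.factor(v)) as.character(v) else unname(v))
  })
}

records_to_df <- function(recs) {
  do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a configuration to a YAML file
#'
#' @param config A `hospexp_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [load_config()]
#' @export
write_config <- function(config, path) {
  validate_config(config)
  obj <- list(
    diseases = df_to_records(config$diseases),
    expense_base = df_to_records(config$expense_base),
    expense_growth = df_to_records(config$expense_growth),
    districts = df_to_records(config$districts),
    institutions = df_to_records(config$institutions),
    insurance = df_to_records(config$insurance),
    policy = lapply(config$policy, function(v)
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    doctor_params = lapply(config$doctor_params, function(v)
      if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
    overrx_rule = unclass(config$overrx_rule),
    preference = df_to_records(config$preference),
    demographics = lapply(config$demographics, as.list),
    population_size = config$population_size,
    years = config$years,
    cycles_per_year = config$cycles_per_year,
    seed = config$seed)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration written by [write_config()] (or assembled by
#' hand to the same schema) and runs the full invariant validation; errors
#' name the offending field.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `hospexp_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file does not exist: ", path)
  obj <- yaml::read_yaml(path)
  unlist_named <- function(x) unlist(x)
  pol <- obj$policy
  pol$subsidy_growth <- unlist_named(pol$subsidy_growth)
  pol$rmax <- unlist_named(pol$rmax)
  dp <- obj$doctor_params
  for (f in c("income_by_title", "weekly_hours_by_title", "title_mix"))
    dp[[f]] <- unlist_named(dp[[f]])
  rule <- do.call(over_prescription_rule, obj$overrx_rule)
  config <- structure(list(
    diseases = records_to_df(obj$diseases),
    expense_base = records_to_df(obj$expense_base),
    expense_growth = records_to_df(obj$expense_growth),
    districts = records_to_df(obj$districts),
    institutions = records_to_df(obj$institutions),
    insurance = records_to_df(obj$insurance),
    policy = pol,
    doctor_params = dp,
    overrx_rule = rule,
    preference = records_to_df(obj$preference),
    demographics = lapply(obj$demographics, unlist_named),
    population_size = as.integer(obj$population_size),
    years = as.integer(obj$years),
    cycles_per_year = as.integer(obj$cycles_per_year),
    seed = as.integer(obj$seed)), class = "hospexp_config")
  validate_config(config)
}

## ---- annual summary I/O ----------------------------------------------------

summary_metric_labels <- function() {
  c(outpatient_total = "Outpatient total medical expenses (CNY)",
    outpatient_medicine = "Outpatient medicine expenses (CNY)",
    outpatient_exam = "Outpatient physical examination expenses (CNY)",
    ratio_outpatient_medicine = "Ratio of outpatient medicine to total medical expenses (%)",
    ratio_outpatient_exam = "Ratio of outpatient physical examinations to total medical expenses (%)",
    inpatient_total = "Inpatient total medical expenses (CNY)",
    inpatient_medicine = "Inpatient medicine expenses (CNY)",
    inpatient_exam = "Inpatient physical examination expenses (CNY)",
    ratio_inpatient_medicine = "Ratio of inpatient medicine to total medical expenses (%)",
    ratio_inpatient_exam = "Ratio of inpatient physical examinations to total medical expenses (%)",
    subsidy_tertiary_comprehensive = "Subsidy proportion: tertiary comprehensive hospital (%)",
    subsidy_specialized = "Subsidy proportion: specialized hospital (%)",
    subsidy_district_hospital = "Subsidy proportion: district hospital (%)",
    subsidy_community_center = "Subsidy proportion: community health service center (%)",
    share_tertiary_comprehensive = "Patient share: tertiary comprehensive hospital (%)",
    share_specialized = "Patient share: specialized hospital (%)",
    share_district_hospital = "Patient share: district hospital (%)",
    share_community_center = "Patient share: community health service center (%)",
    overrx_rate = "Probability of over-prescription (%)",
    overall_total = "Per-episode total medical expenses (CNY)")
}

# Metrics stored as fractions internally but reported as percentages.
percent_metrics <- function() {
  nm <- names(summary_metric_labels())
  nm[grepl("^ratio_|^subsidy_|^share_|^overrx", nm)]
}

#' Write annual summaries as a metric-by-year table
#'
#' Emits a CSV with one row per reported metric and one column per simulated
#' year. Expenses are reported to 0.1 CNY; ratios, shares and the
#' over-prescription rate as percentages to 0.1 point.
#'
#' @param summaries Annual summary data frame from [run_simulation()]
#'   (one row per year).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summaries, path) {
  if (is.null(summaries) || nrow(summaries) < 1)
    stop("write_summary needs at least one annual summary")
  labs <- summary_metric_labels()
  pc <- percent_metrics()
  vals <- vapply(names(labs), function(m) {
    v <- summaries[[m]]
    if (m %in% pc) v <- 100 * v
    round(v, 1)
  }, numeric(nrow(summaries)))
  vals <- matrix(vals, nrow = length(labs), byrow = TRUE,
                 dimnames = list(NULL, paste0("year_", summaries$year)))
  out <- data.frame(metric = unname(labs), vals, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a metric-by-year summary table written by [write_summary()]
#'
#' @param path CSV path.
#' @return Data frame with a `metric` column and one numeric column per year.
#' @export
read_summary <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
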