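# Orchestration: multi-year runs, the ten policy-intervention scenario
# presets as pure configuration transforms, growth-rate and validation
# arithmetic, and baseline-vs-scenario comparison.

#' Scenario presets
#'
#' @return Character vector of available scenario names.
#' @export
scenario_names <- function() {
  c("baseline", "patient_test1", "patient_test2", "patient_test3",
    "doctor_test1", "doctor_test2", "doctor_test3",
    "government_test1", "government_test2", "government_test3", "combined")
}

#' Build a policy-intervention scenario
#'
#' Returns one of the ten preset intervention scenarios (plus the baseline)
#' as a scenario object consumed by [apply_scenario()] and
#' [run_simulation()]. Patient tests scale the community first-visit
#' promotion degree (x0.5 / x1.5 / x2.0; tests 2–3 also rationalize
#' preferences); doctor tests scale incomes, income growth, weekly hours
#' (test 1 maximizes them at 60 h) and the hours-change rate; government
#' tests scale the annual subsidy growth rates per institution type. The
#' combined scenario stacks patient test 2, doctor test 2 and government
#' test 2 — the marginal-value settings of the three independent experiment
#' groups.
#'
#' @param name One of [scenario_names()].
#' @return A list of class `hospexp_scenario`.
#' @export
scenario_preset <- function(name) {
  base <- list(name = name, promotion_multiplier = NULL, rationalize = FALSE,
               income_multiplier = NULL, income_growth_multiplier = NULL,
               hours_multiplier = NULL, hours_set_max = FALSE,
               hours_growth_multiplier = NULL,
               subsidy_growth_multipliers = NULL)
  gmult <- function(tert, comm) {
    c(tertiary_comprehensive = tert, specialized = tert,
      district_hospital = tert, community_center = comm)
  }
  mods <- switch(name,
    baseline = list(),
    patient_test1 = list(promotion_multiplier = 0.5),
    patient_test2 = list(promotion_multiplier = 1.5, rationalize = TRUE),
    patient_test3 = list(promotion_multiplier = 2.0, rationalize = TRUE),
    doctor_test1 = list(income_multiplier = 0.5,
                        income_growth_multiplier = 0.5,
                        hours_set_max = TRUE,
                        hours_growth_multiplier = 1.5),
    doctor_test2 = list(income_multiplier = 2.0,
                        income_growth_multiplier = 1.5,
                        hours_multiplier = 0.75,
                        hours_growth_multiplier = 0.5),
    doctor_test3 = list(income_multiplier = 3.0,
                        income_growth_multiplier = 2.0,
                        hours_multiplier = 0.5,
                        hours_growth_multiplier = 0.2),
    government_test1 = list(subsidy_growth_multipliers = gmult(0.5, 0.5)),
    government_test2 = list(subsidy_growth_multipliers = gmult(2.0, 1.75)),
    government_test3 = list(subsidy_growth_multipliers = gmult(3.0, 2.0)),
    combined = list(promotion_multiplier = 1.5, rationalize = TRUE,
                    income_multiplier = 2.0, income_growth_multiplier = 1.5,
                    hours_multiplier = 0.75, hours_growth_multiplier = 0.5,
                    subsidy_growth_multipliers = gmult(2.0, 1.75)),
    stop("unknown scenario name: ", name))
  base[names(mods)] <- mods
  structure(base, class = "hospexp_scenario")
}

#' Apply a scenario transform to a configuration
#'
#' Pure transform: the input configuration is not modified, and the baseline
#' scenario is the identity. Multipliers are interpreted against the baseline
#' configuration once, at load time, not compounded year over year.
#'
#' @param config A validated `hospexp_config`.
#' @param scenario An `hospexp_scenario` from [scenario_preset()].
#' @return A new validated `hospexp_config`.
#' @export
apply_scenario <- function(config, scenario) {
  if (!inherits(scenario, "hospexp_scenario"))
    scenario <- scenario_preset(scenario)
  cfg <- config
  if (!is.null(scenario$promotion_multiplier))
    cfg$policy$promotion_degree <-
      cfg$policy$promotion_degree * scenario$promotion_multiplier
  cfg$policy$rationalized <- isTRUE(scenario$rationalize)
  dp <- cfg$doctor_params
  if (!is.null(scenario$income_multiplier))
    dp$income_by_title <- dp$income_by_title * scenario$income_multiplier
  if (!is.null(scenario$income_growth_multiplier))
    dp$income_growth <- dp$income_growth * scenario$income_growth_multiplier
  if (isTRUE(scenario$hours_set_max)) {
    dp$weekly_hours_by_title[] <- 60
  } else if (!is.null(scenario$hours_multiplier)) {
    dp$weekly_hours_by_title <-
      pmin(pmax(dp$weekly_hours_by_title * scenario$hours_multiplier, 1e-9), 60)
  }
  if (!is.null(scenario$hours_growth_multiplier))
    dp$hours_change <- dp$hours_change * scenario$hours_growth_multiplier
  cfg$doctor_params <- dp
  if (!is.null(scenario$subsidy_growth_multipliers)) {
    m <- scenario$subsidy_growth_multipliers
    cfg$policy$subsidy_growth[names(m)] <- cfg$policy$subsidy_growth[names(m)] * m
  }
  validate_config(cfg)
}

# Deterministic per-(year, cycle) substream seed below 2^31.
cycle_seed <- function(seed, year, cycle) {
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2039 +
               year * 104729 + cycle * 7919) %% 2147483629L + 1L
}

#' Run a multi-year simulation
#'
#' Applies the scenario transform, then simulates `config$years` years of
#' `config$cycles_per_year` two-week cycles. Each cycle generates the patient
#' cohort, assigns preference-weighted institution types (with first-visit
#' promotion) and nearest facilities, draws care events, samples an attending
#' doctor title and its over-prescription decision (damped by the
#' institution's responsibility index for the year), and prices every episode
#' through the expense engine. Years are aggregated with [aggregate_year()].
#'
#' Simulated year `y` (1-based) uses growth exponent `y` for expense
#' schedules, doctor incomes/hours and subsidies: the configuration holds
#' year-0 values, and the first reported year is one growth step later —
#' mirroring the validation protocol, where year-0 parameters produce the
#' next calendar year's expenses. All randomness flows through substreams
#' seeded per (year, cycle), so identical `(config, scenario, seed)` give
#' identical output and matched seeds give common random numbers across
#' scenarios.
#'
#' @param config A validated `hospexp_config`.
#' @param scenario Scenario object or name (default `"baseline"`).
#' @param seed Integer seed; defaults to `config$seed`.
#' @param years Optional override of `config$years`.
#' @return Annual summary data frame, one row per year (class
#'   `hospexp_summary`).
#' @export
run_simulation <- function(config, scenario = "baseline", seed = config$seed,
                           years = config$years) {
  cfg <- apply_scenario(config, scenario)
  types <- institution_types()
  inst <- cfg$institutions
  dp <- cfg$doctor_params
  titles <- names(dp$income_by_title)
  mix <- cumsum(dp$title_mix[titles] / sum(dp$title_mix))
  rule <- cfg$overrx_rule
  dr <- rule$degree_range

  summaries <- vector("list", years)
  for (y in seq_len(years)) {
    income_y <- dp$income_by_title * (1 + dp$income_growth)^y
    hours_y <- pmin(dp$weekly_hours_by_title * (1 + dp$hours_change)^y, 60)
    cond <- expected_income(hours_y, dp) >= income_y
    if (isTRUE(rule$condition_swapped)) cond <- !cond
    p_title <- ifelse(cond, rule$p_expectation_met, rule$p_expectation_unmet)

    g <- cfg$policy$subsidy_growth
    subsidy_y <- inst$subsidy_proportion * (1 + g[inst$type])^y
    resp <- responsibility_index(subsidy_y, inst$subsidy_proportion,
                                 cfg$policy, inst$type)

    recs <- vector("list", cfg$cycles_per_year)
    for (cyc in seq_len(cfg$cycles_per_year)) {
      set.seed(cycle_seed(seed, y, cyc))
      pat <- generate_patients(cfg, cycle = (y - 1L) * cfg$cycles_per_year + cyc)
      n <- nrow(pat)
      if (n == 0L) next
      W <- preference_matrix(pat, cfg)
      W <- apply_policy_weights(W, pat$severity_class, cfg$policy)
      u_choice <- stats::runif(n)
      ctype <- choose_type_from_uniform(W, u_choice)
      inst_idx <- assign_institutions(pat$lat, pat$lon, ctype, inst)

      u_ev <- matrix(stats::runif(4L * n), ncol = 4)
      drow <- match(pat$disease_id, cfg$diseases$id)
      outp <- u_ev[, 1] < cfg$diseases$p_outpatient[drow]
      hosp <- u_ev[, 2] < cfg$diseases$p_hospitalization[drow]
      outp[!outp & !hosp] <- TRUE
      surg <- hosp & (u_ev[, 3] < cfg$diseases$p_surgery[drow])
      exam <- u_ev[, 4] < cfg$diseases$p_physical_exam[drow]

      u_title <- stats::runif(n)
      t_idx <- 1L + rowSums(outer(u_title, mix[-length(mix)], ">"))
      p_dec <- p_title[t_idx] * (1 - resp[inst_idx])
      u_dec <- stats::runif(n)
      dec <- u_dec < p_dec
      degree <- dr[1] + stats::runif(n) * (dr[2] - dr[1])

      df <- data.frame(patient_id = pat$id,
                       disease_id = pat$disease_id,
                       institution_id = inst$id[inst_idx],
                       institution_type = inst$type[inst_idx],
                       institution_level = inst$level[inst_idx],
                       insurance = pat$insurance,
                       outpatient = outp, hospitalized = hosp,
                       surgery_event = surg, physical_exam = exam,
                       title = titles[t_idx],
                       over_prescribed = dec, degree = degree,
                       stringsAsFactors = FALSE)
      recs[[cyc]] <- cbind(df, episode_components(df, cfg, y))
    }
    records <- do.call(rbind, recs)
    summaries[[y]] <- aggregate_year(records, cfg, y)
  }
  res <- do.call(rbind, summaries)
  attr(res, "scenario") <- if (inherits(scenario, "hospexp_scenario"))
    scenario$name else scenario
  res
}

#' Annual growth rate in percent
#'
#' `100 * (current - previous) / previous`, reported to 0.1 of a percentage
#' point.
#'
#' @param current,previous Per-capita expense values; `previous` must be
#'   positive.
#' @return Growth rate(s) in percent, rounded to one decimal.
#' @export
growth_rate <- function(current, previous) {
  if (any(previous <= 0)) stop("previous value must be > 0")
  round(100 * (current - previous) / previous, 1)
}

#' Validate simulated values against observed references
#'
#' Computes the percent difference `100 * (simulated - actual) / actual` per
#' metric, to 0.1; the model is considered correct and credible when every
#' difference lies within the -10% to +10% band.
#'
#' @param simulated Named numeric vector of simulated metric values.
#' @param actual Named numeric vector of observed values for the same
#'   metrics.
#' @return Data frame (class `hospexp_validation`) with columns `metric`,
#'   `simulated`, `actual`, `difference`, `within_tolerance`, and a logical
#'   attribute `pass`.
#' @export
validate_summary <- function(simulated, actual) {
  if (is.null(names(simulated)) || is.null(names(actual)))
    stop("simulated and actual must be named")
  if (!setequal(names(simulated), names(actual)))
    stop("metric mismatch between simulated and actual values")
  actual <- actual[names(simulated)]
  diff <- round(100 * (simulated - actual) / actual, 1)
  res <- data.frame(metric = names(simulated),
                    simulated = unname(simulated),
                    actual = unname(actual),
                    difference = unname(diff),
                    within_tolerance = unname(abs(diff) <= 10),
                    stringsAsFactors = FALSE)
  attr(res, "pass") <- all(res$within_tolerance)
  class(res) <- c("hospexp_validation", "data.frame")
  res
}

#' Compare scenario summaries against a baseline
#'
#' Signed differences and percent changes per metric and year, in long
#' format; the basis for direction-of-effect analysis of the intervention
#' experiments.
#'
#' @param baseline,scenario Annual summary data frames of equal length from
#'   [run_simulation()].
#' @return Long data frame with columns `metric`, `year`, `baseline`,
#'   `scenario`, `delta`, `pct_change`.
#' @export
compare_summaries <- function(baseline, scenario) {
  if (nrow(baseline) != nrow(scenario))
    stop("baseline and scenario summaries must cover the same number of years")
  metrics <- setdiff(names(baseline)[vapply(baseline, is.numeric, TRUE)],
                     c("year", "n_episodes", "n_outpatient", "n_inpatient"))
  out <- do.call(rbind, lapply(metrics, function(m) {
    b <- baseline[[m]]
    s <- scenario[[m]]
    data.frame(metric = m, year = baseline$year, baseline = b, scenario = s,
               delta = s - b,
               pct_change = ifelse(b != 0, 100 * (s - b) / b, NA_real_),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
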