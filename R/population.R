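# Patient-agent generation: the simulator's starting point. Each two-week
# cycle draws, per disease, a binomial number of new patient agents from the
# static resident population, assigns demographics by independent categorical
# draws from the configured marginals, an insurance scheme by population
# share, and a home district (with a uniform location inside its rectangle)
# by district population share. All draws use the current RNG state, so a
# caller that seeds the stream gets reproducible cohorts.

#' Draw the number of new patients for one disease and cycle
#'
#' Binomial draw with size `population_size` and the disease's two-week
#' prevalence as success probability; the expected count is
#' `population_size * prevalence`.
#'
#' @param population_size Number of residents at risk.
#' @param prevalence Two-week prevalence in `[0, 1]`.
#' @return Integer patient count.
#' @export
draw_patient_count <- function(population_size, prevalence) {
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalence must lie in [0, 1]")
  stats::rbinom(length(prevalence), size = population_size, prob = prevalence)
}

#' Generate the patient cohort for one two-week cycle
#'
#' For each of the 30 diseases, [draw_patient_count()] patients are created
#' and assigned demographic attributes, an insurance scheme, and a district
#' with a uniform location inside the district's bounding rectangle. District
#' shares and demographic distributions are static across cycles: the
#' population neither moves nor transmits disease.
#'
#' @param config A validated `hospexp_config`.
#' @param cycle Non-negative cycle index, recorded on each agent.
#' @return Data frame with one row per patient agent: `id`, `disease_id`,
#'   `severity_class`, the six demographic fields, `insurance` (scheme name),
#'   `district_id`, `lat`, `lon`, `cycle_created`.
#' @export
generate_patients <- function(config, cycle = 0L) {
  if (cycle < 0) stop("cycle must be >= 0")
  dis <- config$diseases
  counts <- draw_patient_count(config$population_size, dis$two_week_prevalence)
  n <- sum(counts)
  if (n == 0L) {
    return(data.frame(id = integer(), disease_id = integer(),
                      severity_class = character(), gender = character(),
                      age_band = character(), occupation = character(),
                      marital_status = character(), education = character(),
                      income_band = character(), insurance = character(),
                      district_id = integer(), lat = numeric(),
                      lon = numeric(), cycle_created = integer(),
                      stringsAsFactors = FALSE))
  }
  disease_id <- rep.int(dis$id, counts)
  severity <- rep.int(dis$severity_class, counts)

  draw_cat <- function(dist) {
    names(dist)[sample.int(length(dist), n, replace = TRUE, prob = dist)]
  }
  dem <- config$demographics
  gender <- draw_cat(dem$gender)
  age_band <- draw_cat(dem$age_band)
  occupation <- draw_cat(dem$occupation)
  marital <- draw_cat(dem$marital_status)
  education <- draw_cat(dem$education)
  income_band <- draw_cat(dem$income_band)

  ins <- config$insurance
  insurance <- ins$name[sample.int(nrow(ins), n, replace = TRUE,
                                   prob = ins$population_share)]

  dd <- config$districts
  d_idx <- sample.int(nrow(dd), n, replace = TRUE, prob = dd$population_share)
  lat <- stats::runif(n, dd$lat_min[d_idx], dd$lat_max[d_idx])
  lon <- stats::runif(n, dd$lon_min[d_idx], dd$lon_max[d_idx])

  data.frame(id = seq_len(n), disease_id = disease_id,
             severity_class = severity, gender = gender, age_band = age_band,
             occupation = occupation, marital_status = marital,
             education = education, income_band = income_band,
             insurance = insurance, district_id = dd$id[d_idx],
             lat = lat, lon = lon, cycle_created = as.integer(cycle),
             stringsAsFactors = FALSE)
}
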