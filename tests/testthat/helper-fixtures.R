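# Shared fixtures: one moderate synthetic configuration reused across test
# files, plus a constructor for the zero-damping, expectation-unmet
# configuration used by the over-prescription regime checks.

test_cfg <- generate_fixture(seed = 42, population_size = 2000)

# All doctors strictly below the expected-income line (weekly hours 60 =>
# expected income 28,002.3 CNY, above every title income), no income or
# subsidy dynamics, and responsibility index exactly 0 via r0 = 1 with zero
# subsidy growth.
unmet_regime_cfg <- function(seed, population_size = 1500) {
  cfg <- generate_fixture(seed, population_size, years = 1L)
  cfg$doctor_params$weekly_hours_by_title[] <- 60
  cfg$doctor_params$hours_change <- 0
  cfg$doctor_params$income_growth <- 0
  cfg$policy$r0 <- 1
  cfg$policy$subsidy_growth[] <- 0
  validate_config(cfg)
}

# One patient row with chosen attributes, for unit-level care-seeking tests.
make_patient <- function(cfg, disease_id = 1L, severity = NULL,
                         age_band = "age_15_44", income_band = "middle",
                         insurance = "urban_worker", lat = 31.2, lon = 121.5) {
  if (is.null(severity))
    severity <- cfg$diseases$severity_class[match(disease_id, cfg$diseases$id)]
  data.frame(id = 1L, disease_id = disease_id, severity_class = severity,
             gender = "female", age_band = age_band, occupation = "employed",
             marital_status = "married", education = "secondary",
             income_band = income_band, insurance = insurance,
             district_id = 1L, lat = lat, lon = lon, cycle_created = 0L,
             stringsAsFactors = FALSE)
}
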