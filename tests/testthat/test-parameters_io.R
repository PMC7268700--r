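# Configuration schema: fixture generation, validation, YAML round trip,
# and summary table I/O.

test_that("fixture generation is deterministic and seed-sensitive", {
  a <- generate_fixture(1, 10000)
  b <- generate_fixture(1, 10000)
  expect_identical(a, b)
  c2 <- generate_fixture(2, 10000)
  expect_false(identical(a$diseases$two_week_prevalence,
                         c2$diseases$two_week_prevalence))
})

test_that("fixture satisfies the construction constraints", {
  cfg <- test_cfg
  expect_equal(nrow(cfg$diseases), 30)
  expect_equal(nrow(cfg$districts), 16)
  expect_true(all(institution_types() %in% cfg$institutions$type))
  # expense ordering: tertiary (both categories) > district > community in
  # every component of every disease
  eb <- cfg$expense_base
  for (cmp in expense_components()) {
    m <- matrix(eb[[cmp]], nrow = 4)  # rows in type order per disease
    rownames(m) <- institution_types()
    expect_true(all(m["tertiary_comprehensive", ] > m["district_hospital", ]))
    expect_true(all(m["specialized", ] > m["district_hospital", ]))
    expect_true(all(m["district_hospital", ] > m["community_center", ]))
  }
  # default copays: 0.30 primary, 0.50 tertiary, uninsured pays everything
  ins <- cfg$insurance
  expect_equal(ins$copay_primary[ins$name == "urban_worker"], 0.30)
  expect_equal(ins$copay_tertiary[ins$name == "urban_worker"], 0.50)
  expect_true(all(ins[ins$name == "uninsured",
                      c("copay_primary", "copay_secondary", "copay_tertiary")] == 1))
  expect_true(all(cfg$diseases$two_week_prevalence >= 5e-4 &
                    cfg$diseases$two_week_prevalence <= 0.05))
})

test_that("generated fixtures pass full validation (closure property)", {
  for (s in c(1, 7, 99))
    expect_silent(validate_config(generate_fixture(s, 500)))
})

test_that("validation names offending fields", {
  cfg <- test_cfg
  bad <- cfg
  bad$diseases$two_week_prevalence[3] <- 1.3
  expect_error(validate_config(bad), "disease 3.*two_week_prevalence")
  bad <- cfg
  bad$districts$population_share <- bad$districts$population_share * 0.9
  expect_error(validate_config(bad), "normalization error.*district")
  bad <- cfg
  bad$diseases <- cfg$diseases[1:29, ]
  expect_error(validate_config(bad), "30 disease")
  bad <- cfg
  bad$insurance$copay_primary[1] <- 0.9  # above tertiary copay
  expect_error(validate_config(bad), "copay_primary")
  bad <- cfg
  bad$demographics$gender <- c(male = 0.6, female = 0.6)
  expect_error(validate_config(bad), "normalization error.*gender")
})

test_that("configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(test_cfg, path)
  back <- load_config(path)
  expect_equal(back$diseases, test_cfg$diseases, tolerance = 1e-12)
  expect_equal(back$expense_base, test_cfg$expense_base, tolerance = 1e-12)
  expect_equal(back$policy$subsidy_growth, test_cfg$policy$subsidy_growth)
  expect_equal(back$doctor_params, test_cfg$doctor_params, tolerance = 1e-12)
  expect_equal(back$demographics, test_cfg$demographics)
  expect_equal(back$overrx_rule, test_cfg$overrx_rule)
  expect_equal(back$population_size, test_cfg$population_size)
  # a round-tripped config simulates identically
  s1 <- run_simulation(test_cfg, "baseline", seed = 5, years = 1)
  s2 <- run_simulation(back, "baseline", seed = 5, years = 1)
  expect_equal(as.data.frame(s1), as.data.frame(s2), tolerance = 1e-9)
  expect_error(load_config(file.path(tempdir(), "nope.yaml")), "exist")
})

test_that("every model variable has a home field in the schema", {
  cfg <- test_cfg
  accessors <- list(
    total_population = function(c) c$population_size,
    population_distribution = function(c) c$districts$population_share,
    two_week_prevalence = function(c) c$diseases$two_week_prevalence,
    gender = function(c) c$demographics$gender,
    age = function(c) c$demographics$age_band,
    occupation = function(c) c$demographics$occupation,
    marital_status = function(c) c$demographics$marital_status,
    income = function(c) c$demographics$income_band,
    education = function(c) c$demographics$education,
    medical_seeking_preference = function(c) c$preference,
    prescription_adherence = function(c)
      c$insurance[c("copay_primary", "copay_secondary", "copay_tertiary")],
    institution_roster = function(c)
      c$institutions[c("id", "name", "type", "lat", "lon")],
    doctor_title = function(c) names(c$doctor_params$income_by_title),
    doctor_income = function(c) c$doctor_params$income_by_title,
    doctor_income_growth = function(c) c$doctor_params$income_growth,
    weekly_hours = function(c) c$doctor_params$weekly_hours_by_title,
    weekly_hours_change = function(c) c$doctor_params$hours_change,
    over_prescription_probabilities = function(c)
      c(c$overrx_rule$p_expectation_met, c$overrx_rule$p_expectation_unmet),
    government_subsidy_proportion = function(c)
      c$institutions$subsidy_proportion,
    first_visit_promotion_degree = function(c) c$policy$promotion_degree,
    insurance_composition = function(c) c$insurance$population_share,
    expense_schedule = function(c) c$expense_base,
    expense_growth_rates = function(c) c$expense_growth,
    care_event_probabilities = function(c)
      c$diseases[c("p_outpatient", "p_hospitalization", "p_surgery",
                   "p_physical_exam")])
  for (nm in names(accessors)) {
    v <- accessors[[nm]](cfg)
    expect_true(!is.null(v) && length(v) > 0, label = nm)
  }
})

test_that("summary tables are written one metric-row per year-column and round-trip", {
  s <- run_simulation(test_cfg, "baseline", seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary(s, path)
  tab <- read_summary(path)
  expect_equal(ncol(tab), 1 + nrow(s))
  expect_equal(names(tab)[-1], paste0("year_", s$year))
  expect_true("Probability of over-prescription (%)" %in% tab$metric)
  # round trip equals written values to 1 decimal
  row <- tab[tab$metric == "Outpatient total medical expenses (CNY)", -1]
  expect_equal(unlist(row, use.names = FALSE), round(s$outpatient_total, 1))
  row <- tab[tab$metric == "Ratio of outpatient medicine to total medical expenses (%)", -1]
  expect_equal(unlist(row, use.names = FALSE),
               round(100 * s$ratio_outpatient_medicine, 1))
  expect_error(write_summary(s[0, ], path), "at least one")
})
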