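# Expense engine: care events, schedule compounding, episode pricing,
# adherence, and annual aggregation with exact conservation.

test_that("care events respect their conditional structure", {
  d0 <- data.frame(p_outpatient = 0.9, p_hospitalization = 0, p_surgery = 1,
                   p_physical_exam = 0.5)
  set.seed(1)
  for (i in 1:50) {
    ev <- draw_care_events(d0)
    expect_false(ev$hospitalized)
    expect_false(ev$surgery)
    expect_true(ev$outpatient || ev$hospitalized)
  }
  d1 <- data.frame(p_outpatient = 1, p_hospitalization = 0, p_surgery = 0,
                   p_physical_exam = 0)
  ev <- draw_care_events(d1)
  expect_true(ev$outpatient && !ev$hospitalized)
  # surgery share among hospitalized matches its conditional probability
  d2 <- data.frame(p_outpatient = 0, p_hospitalization = 1, p_surgery = 0.3,
                   p_physical_exam = 0)
  set.seed(2)
  surg <- replicate(10000, draw_care_events(d2)$surgery)
  expect_lt(abs(mean(surg) - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("expense growth is exact closed-form compounding", {
  expect_equal(grown_expense(100, 0.05, 0), 100)
  expect_equal(grown_expense(100, 0.05, 2), 110.25)
  expect_equal(grown_expense(100, -0.02, 1), 98)
  base <- runif(20, 10, 500); g <- runif(20, -0.1, 0.2); yr <- sample(0:10, 20, TRUE)
  expect_identical(grown_expense(base, g, yr), base * (1 + g)^yr)
  expect_error(grown_expense(100, -1, 1), "> -1")
  expect_error(grown_expense(100, 0.05, -1), ">= 0")
})

test_that("adherence is the complement of the level copay", {
  ins <- test_cfg$insurance
  worker <- ins[ins$name == "urban_worker", ]
  expect_equal(adherence_factor(worker, "primary"), 0.70)
  expect_equal(adherence_factor(worker, "tertiary"), 0.50)
  unins <- ins[ins$name == "uninsured", ]
  for (lv in c("primary", "secondary", "tertiary"))
    expect_equal(adherence_factor(unins, lv), 0)
  expect_error(adherence_factor(worker, "quaternary"), "unknown")
})

test_that("episode pricing applies inflation only to accepted medicine/exam extras", {
  cfg <- test_cfg
  pat <- make_patient(cfg, disease_id = 1L)
  inst <- cfg$institutions[cfg$institutions$type == "district_hospital", ][1, ]
  ev <- list(outpatient = TRUE, hospitalized = FALSE, surgery = FALSE,
             physical_exam = TRUE)
  # no over-prescription: record equals the pure grown schedule
  rec0 <- episode_expense(pat, inst, FALSE, 0.3, ev, cfg, year = 0)
  eb <- cfg$expense_base
  row <- eb[eb$disease_id == 1 & eb$institution_type == "district_hospital", ]
  expect_equal(rec0$outpatient_medicine, row$outpatient_medicine)
  expect_equal(rec0$outpatient_exam, row$outpatient_exam)
  expect_equal(rec0$inpatient_base, 0)
  expect_equal(rec0$total,
               row$outpatient_base + row$outpatient_medicine + row$outpatient_exam)
  # over-prescription with a worker at a secondary hospital: adherence 0.60
  rec1 <- episode_expense(pat, inst, TRUE, 0.2, ev, cfg, year = 0)
  expect_equal(rec1$adherence, 0.60)
  expected_extra <- 0.2 * (row$outpatient_medicine + row$outpatient_exam) * 0.6
  expect_equal(rec1$extra, expected_extra)
  expect_equal(rec1$total, rec0$total + expected_extra)
  expect_equal(rec1$outpatient_base, rec0$outpatient_base)
  # uninsured patient accepts none of the extras
  pat_u <- make_patient(cfg, insurance = "uninsured")
  rec2 <- episode_expense(pat_u, inst, TRUE, 0.2, ev, cfg, year = 0)
  expect_equal(rec2$extra, 0)
  expect_equal(rec2$total, rec0$total)
})

test_that("a hand-computed over-prescription example reproduces", {
  # degree 0.2, adherence 0.7, base medicine 100, base exam 50:
  # accepted extra = 0.2 * 150 * 0.7 = 21.0 split across medicine + exam
  cfg <- test_cfg
  cfg$expense_base[cfg$expense_base$disease_id == 1 &
                     cfg$expense_base$institution_type == "community_center",
                   expense_components()] <-
    as.list(c(10, 100, 50, 0, 0, 0, 0, 0, 0))
  pat <- make_patient(cfg, disease_id = 1L)  # worker, primary: adherence 0.7
  inst <- cfg$institutions[cfg$institutions$type == "community_center", ][1, ]
  ev <- list(outpatient = TRUE, hospitalized = FALSE, surgery = FALSE,
             physical_exam = TRUE)
  rec <- episode_expense(pat, inst, TRUE, 0.2, ev, cfg, year = 0)
  expect_equal(rec$extra, 21.0)
  expect_equal(rec$outpatient_medicine + rec$outpatient_exam, 150 + 21.0)
  expect_equal(rec$outpatient_medicine / rec$outpatient_exam, 2)  # pro-rata split
})

test_that("annual aggregation conserves expenses against a brute-force sum", {
  cfg <- test_cfg
  s <- run_simulation(cfg, "baseline", seed = 12, years = 1)
  # reconstruct the brute-force totals from the per-capita means
  lhs <- s$n_episodes * s$overall_total
  rhs <- s$n_outpatient * s$outpatient_total + s$n_inpatient * s$inpatient_total
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_true(all(s$ratio_outpatient_medicine >= 0 & s$ratio_outpatient_medicine <= 1))
  expect_true(all(s$ratio_inpatient_medicine + s$ratio_inpatient_exam <= 1))
  shares <- s$share_tertiary_comprehensive + s$share_specialized +
    s$share_district_hospital + s$share_community_center
  expect_equal(shares, 1, tolerance = 1e-9)
})

test_that("aggregation of explicit records matches direct averages", {
  cfg <- test_cfg
  pat <- make_patient(cfg)
  inst <- cfg$institutions[cfg$institutions$type == "community_center", ][1, ]
  ev_o <- list(outpatient = TRUE, hospitalized = FALSE, surgery = FALSE,
               physical_exam = FALSE)
  ev_h <- list(outpatient = FALSE, hospitalized = TRUE, surgery = TRUE,
               physical_exam = TRUE)
  recs <- rbind(episode_expense(pat, inst, FALSE, 0.2, ev_o, cfg, 0),
                episode_expense(pat, inst, TRUE, 0.2, ev_h, cfg, 0))
  s <- aggregate_year(recs, cfg, year = 0)
  expect_equal(s$n_outpatient, 1)
  expect_equal(s$n_inpatient, 1)
  expect_equal(s$share_community_center, 1)
  expect_equal(s$overrx_rate, 0.5)
  expect_equal(s$outpatient_total,
               recs$outpatient_base[1] + recs$outpatient_medicine[1] +
                 recs$outpatient_exam[1])
  expect_error(aggregate_year(recs[0, ], cfg, 0), "at least one")
})

test_that("with zero inflation degree, expense summaries ignore doctor and subsidy parameters", {
  cfg <- test_cfg
  cfg$overrx_rule$degree_range <- c(1e-12, 1e-12)
  alt <- cfg
  alt$doctor_params$income_by_title <- alt$doctor_params$income_by_title * 3
  alt$doctor_params$weekly_hours_by_title[] <- 60
  alt$policy$subsidy_growth[] <- alt$policy$subsidy_growth * 2
  s1 <- run_simulation(cfg, "baseline", seed = 13, years = 1)
  s2 <- run_simulation(alt, "baseline", seed = 13, years = 1)
  cols <- c("outpatient_total", "outpatient_medicine", "outpatient_exam",
            "inpatient_total", "inpatient_medicine", "inpatient_exam")
  expect_equal(as.data.frame(s1)[cols], as.data.frame(s2)[cols],
               tolerance = 1e-6)
})

test_that("per-capita growth tracks the schedule growth rates when behavior is fixed", {
  cfg <- test_cfg
  cfg$overrx_rule$degree_range <- c(1e-12, 1e-12)
  g <- 0.05
  cfg$expense_growth[expense_components()] <- g
  s <- run_simulation(cfg, "baseline", seed = 14, years = 3)
  yoy <- diff(s$outpatient_total) / head(s$outpatient_total, -1)
  # Monte-Carlo error from case-mix resampling, so a loose band around 5%
  expect_true(all(abs(yoy - g) < 0.02))
})
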