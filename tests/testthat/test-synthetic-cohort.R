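test_that("default cohort hits the target crude mortality", {
  coh <- generate_cohort(cohort_config(seed = 1))
  mort <- build_outcome_cohort(coh$admissions, "mortality")
  rate <- mean(mort$cohort$y)
  expect_gt(rate, 0.045)
  expect_lt(rate, 0.085)
})

test_that("zero hospital variance gives exactly zero intercepts", {
  coh <- generate_cohort(cohort_config(n_hospitals = 6,
                                       admissions_per_hospital = c(30, 40),
                                       hospital_sigma = 0, seed = 3))
  expect_identical(unname(coh$truth$hospital_intercepts$mortality),
                   rep(0, 6))
  expect_identical(unname(coh$truth$hospital_intercepts$readmission),
                   rep(0, 6))
})

test_that("generation is deterministic given the config seed", {
  cfg <- cohort_config(n_hospitals = 5, admissions_per_hospital = c(60, 90),
                       seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$truth, b$truth)
})

test_that("invalid configurations are rejected with named problems", {
  expect_error(cohort_config(hospital_sigma = -1), "hospital_sigma")
  expect_error(cohort_config(n_dx_groups = 3,
                             dx_group_weights = c(0.5, 0.2, 0.2)),
               "sum to 1")
  expect_error(cohort_config(calendar_window = as.Date(c("2020-01-01",
                                                         "2019-01-01"))),
               "calendar_window")
  expect_error(cohort_config(target_rates = c(mortality = 1.2,
                                              readmission_30 = 0.1)),
               "probabilities")
})

test_that("realized event rate matches the mean of the true probabilities", {
  coh <- generate_cohort(cohort_config(n_hospitals = 10,
                                       admissions_per_hospital = c(900, 1100),
                                       seed = 21))
  adm <- coh$admissions
  lp <- coh$truth$linear_predictor
  idx <- match(lp$admission_id, adm$admission_id)
  p <- expit(lp$lp_mortality_hosp)
  deaths <- adm$disposition[idx] == "death"
  # 4-SD binomial band around the mean true probability
  se <- sqrt(sum(p * (1 - p))) / length(p)
  expect_lt(abs(mean(deaths) - mean(p)), 4 * se)
})

test_that("realized hospital intercept spread approaches hospital_sigma", {
  cfg <- cohort_config(n_hospitals = 250,
                       admissions_per_hospital = c(2, 4),
                       hospital_sigma = 0.3, outlier_hospital = NA,
                       seed = 5)
  coh <- generate_cohort(cfg)
  s <- sd(coh$truth$hospital_intercepts$mortality)
  expect_lt(abs(s - 0.3), 4 * 0.3 / sqrt(2 * 249))
})

test_that("equity prevalence per hospital follows the configured gradient", {
  shift <- c(-1, 0, 2)
  cfg <- cohort_config(n_hospitals = 3,
                       admissions_per_hospital = c(4000, 4000),
                       equity_gradient = list(
                         homelessness = shift,
                         disability = c(0, 0, 0),
                         onmarg_housing = shift,
                         onmarg_racialized_newcomer = c(0, 0, 0),
                         onmarg_material = c(0, 0, 0),
                         onmarg_age_labor = c(0, 0, 0)),
                       seed = 9)
  coh <- generate_cohort(cfg)
  adm <- coh$admissions[grepl("^A", coh$admissions$admission_id), ]
  for (h in 1:3) {
    rows <- adm$hospital_id == sprintf("H%02d", h)
    p_target <- expit(logit(0.02) + shift[h])
    p_obs <- mean(adm$homelessness[rows])
    se <- sqrt(p_target * (1 - p_target) / sum(rows))
    expect_lt(abs(p_obs - p_target), 4 * se)
    m_obs <- mean(adm$onmarg_housing[rows])
    expect_lt(abs(m_obs - shift[h]), 4 / sqrt(sum(rows)))
  }
})

test_that("true readmission events exist and land inside their window", {
  coh <- generate_cohort(cohort_config(n_hospitals = 6,
                                       admissions_per_hospital = c(400, 500),
                                       seed = 13))
  ev <- coh$truth$readmission_events
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$gap_days >= 1 & ev$gap_days <= 30))
  adm <- coh$admissions
  # realized events have a follow-on admission for the same patient
  realized <- ev[ev$realized, ]
  src <- adm[match(realized$admission_id, adm$admission_id), ]
  followups <- adm[grepl("^R", adm$admission_id), ]
  expect_true(all(src$patient_id %in% followups$patient_id))
})

test_that("exclusion fixtures are injected exactly and tagged", {
  coh <- generate_cohort(cohort_config(n_hospitals = 3,
                                       admissions_per_hospital = c(50, 60),
                                       exclusion_rates = c(
                                         age_gt_120 = 0, los_gt_1yr = 0,
                                         palliative = 0, maid = 0,
                                         missing_da = 0, invalid_id = 0),
                                       seed = 2))
  tab <- coh$admissions
  n0 <- nrow(tab)
  out <- inject_exclusion_fixtures(tab, c(age_gt_120 = 3), seed = 4)
  expect_equal(nrow(out), n0 + 3)
  expect_equal(sum(out$age > 120), 3)
  truth <- attr(out, "exclusion_truth")
  expect_equal(sum(truth$rule == "age_gt_120"), 3)

  expect_identical(inject_exclusion_fixtures(tab, c()), tab)
  expect_error(inject_exclusion_fixtures(tab, c(bogus_rule = 1)),
               "unknown exclusion rule")
  expect_error(inject_exclusion_fixtures(tab, c(maid = -1)),
               "non-negative")
})
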