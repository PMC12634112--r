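clean_cfg <- function(seed = 2) {
  cohort_config(n_hospitals = 3, admissions_per_hospital = c(60, 80),
                exclusion_rates = c(age_gt_120 = 0, los_gt_1yr = 0,
                                    palliative = 0, maid = 0, missing_da = 0,
                                    invalid_id = 0),
                seed = seed)
}

test_that("injected violations are removed exactly, per hidden labels", {
  tab <- generate_cohort(clean_cfg())$admissions
  tab <- inject_exclusion_fixtures(tab, c(palliative = 2, missing_da = 5),
                                   seed = 8)
  res <- apply_mortality_exclusions(tab)
  truth <- attr(tab, "exclusion_truth")
  expect_equal(attr(res$exclusions, "n_removed"), 7)
  expect_equal(nrow(res$cohort), nrow(tab) - 7)
  expect_false(any(truth$admission_id %in% res$cohort$admission_id))
  counts <- setNames(res$exclusions$n, res$exclusions$rule)
  expect_equal(counts[["palliative"]], 2L)
  expect_equal(counts[["missing_da"]], 5L)
  expect_equal(counts[["age_gt_120"]], 0L)
})

test_that("a stay of exactly 365 days is retained (strict > 1 year)", {
  tab <- make_admissions(
    list(admit_dt = ts("2019-01-01 08:00:00"),
         discharge_dt = ts("2019-01-01 08:00:00") + 365 * 86400),
    list(admit_dt = ts("2019-01-01 08:00:00"),
         discharge_dt = ts("2019-01-01 08:00:00") + 365.01 * 86400,
         patient_id = "P2"))
  res <- apply_mortality_exclusions(tab)
  expect_equal(nrow(res$cohort), 1)
  expect_equal(res$cohort$patient_id, "P1")
})

test_that("empty input yields empty cohort and zero counts", {
  tab <- make_admissions(list())[0, ]
  res <- apply_mortality_exclusions(tab)
  expect_equal(nrow(res$cohort), 0)
  expect_true(all(res$exclusions$n == 0))
})

test_that("missing required columns raise a schema error naming them", {
  tab <- make_admissions(list())
  tab$age <- NULL
  expect_error(apply_mortality_exclusions(tab), "age")
})

test_that("contiguous admissions chain into one episode attributed to the last hospital", {
  tab <- make_admissions(
    list(admit_dt = ts("2020-01-01 10:00:00"),
         discharge_dt = ts("2020-01-03 10:00:00"), hospital_id = "H1"),
    list(admit_dt = ts("2020-01-03 12:00:00"),
         discharge_dt = ts("2020-01-06 10:00:00"), hospital_id = "H2"))
  ep <- build_episodes(tab, gap_hours = 6)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$attributed_hospital, "H2")
  expect_equal(ep$n_admissions, 2L)
  expect_equal(ep$episode_discharge_dt, ts("2020-01-06 10:00:00"))
})

test_that("admissions far apart form separate episodes", {
  tab <- make_admissions(
    list(discharge_dt = ts("2020-01-03 10:00:00")),
    list(admit_dt = ts("2020-02-12 10:00:00"),
         discharge_dt = ts("2020-02-14 10:00:00")))
  ep <- build_episodes(tab, gap_hours = 12)
  expect_equal(nrow(ep), 2)
})

test_that("episodes partition the admissions and ignore row order", {
  coh <- generate_cohort(cohort_config(n_hospitals = 5,
                                       admissions_per_hospital = c(150, 200),
                                       seed = 17))
  tab <- coh$admissions
  ep <- build_episodes(tab)
  expect_equal(sum(ep$n_admissions), nrow(tab))
  expect_equal(length(unique(unlist(ep$admission_ids))), nrow(tab))
  set.seed(1)
  shuffled <- tab[sample(nrow(tab)), ]
  ep2 <- build_episodes(shuffled)
  ord1 <- ep[order(ep$first_admission_id), ]
  ord2 <- ep2[order(ep2$first_admission_id), ]
  expect_equal(ord1$attributed_hospital, ord2$attributed_hospital)
  expect_equal(ord1$n_admissions, ord2$n_admissions)
})

test_that("rows with missing patient id become invalid singleton episodes", {
  tab <- make_admissions(
    list(patient_id = NA_character_),
    list(patient_id = NA_character_,
         admit_dt = ts("2020-01-03 11:00:00"),
         discharge_dt = ts("2020-01-05 10:00:00")))
  ep <- build_episodes(tab)
  expect_equal(nrow(ep), 2)
  expect_true(all(!ep$valid_id))
})

test_that("negative contiguity gap is rejected", {
  expect_error(build_episodes(make_admissions(list()), gap_hours = -1),
               "non-negative")
})

test_that("readmission window boundary is inclusive and elective follow-ups do not count", {
  mk <- function(second_admit, elective = FALSE) {
    make_admissions(
      list(discharge_dt = ts("2020-03-01 00:00:00")),
      list(admit_dt = ts(second_admit),
           discharge_dt = ts(second_admit) + 2 * 86400,
           admission_category = if (elective) "elective" else "urgent"))
  }
  # next admission exactly 7 days after discharge counts for the 7-day window
  ep <- label_readmissions(build_episodes(mk("2020-03-08 00:00:00")), 7)
  first <- ep[which.min(ep$episode_admit_dt), ]
  expect_true(first$readmitted_7d)
  # 7 days + 1 hour: outside the 7-day window, inside the 30-day one
  ep <- label_readmissions(build_episodes(mk("2020-03-08 01:00:00")), 7)
  expect_false(ep[which.min(ep$episode_admit_dt), ]$readmitted_7d)
  ep <- label_readmissions(build_episodes(mk("2020-03-08 01:00:00")), 30)
  expect_true(ep[which.min(ep$episode_admit_dt), ]$readmitted_30d)
  # elective follow-up is disqualified
  ep <- label_readmissions(build_episodes(mk("2020-03-05 00:00:00",
                                             elective = TRUE)), 30)
  expect_false(ep[which.min(ep$episode_admit_dt), ]$readmitted_30d)
  # no subsequent episode
  ep <- label_readmissions(build_episodes(make_admissions(list())), 30)
  expect_false(ep$readmitted_30d)
  expect_error(label_readmissions(ep, 14), "7 or 30")
})

test_that("no labeled readmission begins before the episode completes", {
  coh <- generate_cohort(cohort_config(n_hospitals = 4,
                                       admissions_per_hospital = c(300, 350),
                                       seed = 23))
  ep <- label_readmissions(build_episodes(coh$admissions), 30)
  lab <- ep[ep$readmitted_30d, ]
  for (i in seq_len(nrow(lab))) {
    nxt <- ep[ep$patient_id == lab$patient_id[i] &
                ep$episode_admit_dt > lab$episode_discharge_dt[i], ]
    expect_gt(nrow(nxt), 0)
  }
})

test_that("readmission exclusions remove death/self-signout episodes but mortality keeps them", {
  tab <- make_admissions(
    list(disposition = "death"),
    list(patient_id = "P2", disposition = "self_signout"),
    list(patient_id = "P3", disposition = "transfer_out"),
    list(patient_id = "P4", mrdx_mental_health = TRUE),
    list(patient_id = "P5"))
  ep <- label_readmissions(build_episodes(tab), 30)
  res <- apply_readmission_exclusions(ep)
  expect_equal(nrow(res$cohort), 1)
  expect_equal(res$cohort$patient_id, "P5")
  counts <- setNames(res$exclusions$n, res$exclusions$rule)
  expect_equal(counts[["death"]], 1L)
  expect_equal(counts[["self_signout"]], 1L)
  expect_equal(counts[["discharged_out_of_network"]], 1L)
  expect_equal(counts[["mental_health_mrdx"]], 1L)
  # the death admission stays in the mortality cohort
  mort <- apply_mortality_exclusions(tab)
  expect_true("P1" %in% mort$cohort$patient_id)
})

test_that("reporting tail truncation uses each hospital's own window", {
  ep <- data.frame(
    episode_id = c("E1", "E2", "E3"),
    attributed_hospital = c("H1", "H1", "H1"),
    episode_discharge_dt = ts(c("2022-04-20 12:00:00",
                                "2022-04-01 12:00:00",
                                "2022-01-10 12:00:00")),
    stringsAsFactors = FALSE)
  out30 <- truncate_reporting_tail(ep, "readmission_30")
  expect_equal(out30$episode_id, "E3")   # E2 within 60-day tail
  out7 <- truncate_reporting_tail(ep, "readmission_7")
  expect_equal(out7$episode_id, "E3")    # E2 within 37-day tail too
  expect_equal(nrow(truncate_reporting_tail(ep, "mortality")), 3)
})

test_that("mortality cohort contains every readmission-cohort episode patient", {
  coh <- generate_cohort(cohort_config(n_hospitals = 4,
                                       admissions_per_hospital = c(250, 300),
                                       seed = 31))
  mort <- build_outcome_cohort(coh$admissions, "mortality")
  r30 <- build_outcome_cohort(coh$admissions, "readmission_30")
  expect_true(all(unlist(lapply(r30$cohort$patient_id, function(p) {
    p %in% mort$cohort$patient_id
  }))))
  expect_lte(nrow(r30$cohort), nrow(mort$cohort))
})
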