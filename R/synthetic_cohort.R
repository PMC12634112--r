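#' Configuration for the synthetic admission cohort generator
#'
#' Builds and validates the configuration object consumed by
#' [generate_cohort()]. Defaults emulate the structure of a multi-hospital
#' general-medicine cohort: 20 hospitals of heterogeneous size, a dozen
#' diagnosis groups of unequal prevalence, crude in-hospital mortality near
#' 6.3% and 30-/7-day readmission near 13.1%/4.5%, hospital random intercepts
#' on the log-odds scale, and between-hospital gradients in the prevalence of
#' equity-related factors (homelessness, disability, and four continuous
#' neighborhood-marginalization dimensions), including one designated outlier
#' hospital with extreme homelessness and housing marginalization.
#'
#' @param n_hospitals Number of hospitals.
#' @param admissions_per_hospital Length-2 integer range; each hospital's
#'   index-admission count is drawn uniformly from it.
#' @param n_dx_groups Number of diagnosis-group labels.
#' @param dx_group_weights Probability vector over diagnosis groups (must sum
#'   to 1 within 1e-12). Default: geometric decay, mirroring the long tail of
#'   diagnosis prevalence in general medicine.
#' @param true_coefficients Named list with elements `mortality` and
#'   `readmission`, each a named log-odds coefficient vector over the model
#'   features (see [cohort_truth_features()]). Missing names default to 0.
#' @param hospital_sigma SD of hospital random intercepts (log-odds), `>= 0`.
#' @param equity_gradient Either `NULL` (per-hospital shifts drawn from
#'   normals with `equity_gradient_sd`, plus the outlier hospital) or a named
#'   list of numeric vectors of length `n_hospitals` giving logit shifts for
#'   `homelessness`/`disability` and location shifts for the four
#'   `onmarg_*` dimensions.
#' @param equity_gradient_sd SDs used when `equity_gradient` is `NULL`.
#' @param outlier_hospital Index of the designated outlier hospital (extreme
#'   homelessness and housing marginalization), or `NA` for none. Ignored if
#'   `equity_gradient` is supplied.
#' @param target_rates Named probabilities for `mortality` and
#'   `readmission_30`; the 7-day rate is implied by the readmission-gap
#'   distribution (see `readmit_gap_q`).
#' @param calendar_window Length-2 `Date` vector, study start and end.
#' @param exclusion_rates Named proportions of admissions violating each
#'   exclusion rule: `age_gt_120`, `los_gt_1yr`, `palliative`, `maid`,
#'   `missing_da`, `invalid_id`.
#' @param transfer_rate Proportion of index admissions followed by a
#'   contiguous within-network transfer to another hospital.
#' @param out_of_network_rate Proportion discharged out of network
#'   (disposition `transfer_out` with no follow-on record).
#' @param self_signout_rate Proportion leaving against advice.
#' @param mrdx_rates Named proportions of records carrying
#'   `mental_health`/`chemo`/`obstetric` most-responsible-diagnosis flags.
#' @param tail_fraction Proportion of admissions whose discharge is forced
#'   into the final 60 days of the window, to exercise reporting-tail
#'   truncation.
#' @param readmit_gap_q Geometric decay of the readmission-gap distribution
#'   on days 1..30; the default 0.962 puts ~34% of 30-day readmissions inside
#'   7 days, matching the ratio of the target 7- and 30-day rates.
#' @param same_hospital_readmit Probability a readmission returns to the
#'   discharging hospital.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_hospitals = 20L,
                          admissions_per_hospital = c(600L, 1400L),
                          n_dx_groups = 12L,
                          dx_group_weights = NULL,
                          true_coefficients = NULL,
                          hospital_sigma = 0.15,
                          equity_gradient = NULL,
                          equity_gradient_sd = c(homelessness = 0.6,
                                                 disability = 0.25,
                                                 onmarg = 0.4),
                          outlier_hospital = n_hospitals,
                          target_rates = c(mortality = 0.063,
                                           readmission_30 = 0.131),
                          calendar_window = as.Date(c("2018-05-01",
                                                      "2022-04-20")),
                          exclusion_rates = c(age_gt_120 = 0.002,
                                              los_gt_1yr = 0.002,
                                              palliative = 0.010,
                                              maid = 0.002,
                                              missing_da = 0.029,
                                              invalid_id = 0.0098),
                          transfer_rate = 0.04,
                          out_of_network_rate = 0.01,
                          self_signout_rate = 0.01,
                          mrdx_rates = c(mental_health = 0.02,
                                         chemo = 0.01,
                                         obstetric = 0.005),
                          tail_fraction = 0.05,
                          readmit_gap_q = 0.962,
                          same_hospital_readmit = 0.7,
                          seed = 1L) {
  if (is.null(dx_group_weights)) {
    w <- 0.78^seq_len(n_dx_groups)
    dx_group_weights <- w / sum(w)
  }
  cfg <- list(
    n_hospitals = as.integer(n_hospitals),
    admissions_per_hospital = as.integer(admissions_per_hospital),
    n_dx_groups = as.integer(n_dx_groups),
    dx_group_weights = as.numeric(dx_group_weights),
    true_coefficients = resolve_true_coefficients(true_coefficients),
    hospital_sigma = as.numeric(hospital_sigma),
    equity_gradient = equity_gradient,
    equity_gradient_sd = equity_gradient_sd,
    outlier_hospital = outlier_hospital,
    target_rates = target_rates,
    calendar_window = as.Date(calendar_window),
    exclusion_rates = exclusion_rates,
    transfer_rate = transfer_rate,
    out_of_network_rate = out_of_network_rate,
    self_signout_rate = self_signout_rate,
    mrdx_rates = mrdx_rates,
    tail_fraction = tail_fraction,
    readmit_gap_q = readmit_gap_q,
    same_hospital_readmit = same_hospital_readmit,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Feature names of the generator's true coefficient vectors
#'
#' @return Character vector of feature names on which
#'   `cohort_config()$true_coefficients` is defined. `age` is per year,
#'   centered at 70; `mlaps` per point; the remainder are indicator or
#'   standardized-continuous effects on the log-odds scale.
#' @export
cohort_truth_features <- function() {
  c("age", "male", "elective", "charlson1", "charlson2", "mlaps",
    "prior1", "prior2",
    "homelessness", "disability", "onmarg_housing",
    "onmarg_racialized_newcomer", "onmarg_material", "onmarg_age_labor")
}

#' @noRd
resolve_true_coefficients <- function(user) {
  feats <- cohort_truth_features()
  base <- stats::setNames(numeric(length(feats)), feats)
  defaults <- list(
    mortality = replace(base, c("age", "male", "elective", "charlson1",
                                "charlson2", "mlaps"),
                        c(0.035, 0.10, -0.70, 0.25, 0.55, 0.035)),
    readmission = replace(base, c("age", "male", "elective", "charlson1",
                                  "charlson2", "mlaps", "prior1", "prior2",
                                  "homelessness", "onmarg_housing"),
                          c(0.005, 0.05, -0.50, 0.30, 0.60, 0.010,
                            0.50, 0.90, 0.40, 0.12))
  )
  if (is.null(user)) return(defaults)
  for (oc in names(user)) {
    if (!oc %in% c("mortality", "readmission")) {
      stop("true_coefficients names must be 'mortality' and/or 'readmission'",
           call. = FALSE)
    }
    v <- user[[oc]]
    bad <- setdiff(names(v), feats)
    if (length(bad)) {
      stop(sprintf("unknown true_coefficients features: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    out <- base
    out[names(v)] <- as.numeric(v)
    defaults[[oc]] <- out
  }
  defaults
}

#' @noRd
validate_cohort_config <- function(cfg) {
  bad <- character()
  if (cfg$n_hospitals < 1) bad <- c(bad, "n_hospitals must be >= 1")
  if (length(cfg$admissions_per_hospital) != 2L ||
      any(cfg$admissions_per_hospital < 1) ||
      diff(cfg$admissions_per_hospital) < 0) {
    bad <- c(bad, "admissions_per_hospital must be a non-decreasing range of positive counts")
  }
  if (length(cfg$dx_group_weights) != cfg$n_dx_groups) {
    bad <- c(bad, "dx_group_weights length must equal n_dx_groups")
  }
  if (abs(sum(cfg$dx_group_weights) - 1) > 1e-12) {
    bad <- c(bad, "dx_group_weights must sum to 1 (within 1e-12)")
  }
  if (any(cfg$dx_group_weights < 0)) bad <- c(bad, "dx_group_weights must be non-negative")
  if (is.na(cfg$hospital_sigma) || cfg$hospital_sigma < 0) {
    bad <- c(bad, "hospital_sigma must be >= 0")
  }
  probs <- c(cfg$target_rates, cfg$exclusion_rates, cfg$transfer_rate,
             cfg$out_of_network_rate, cfg$self_signout_rate, cfg$mrdx_rates,
             cfg$tail_fraction)
  if (any(probs < 0 | probs > 1)) bad <- c(bad, "all probabilities must lie in [0, 1]")
  if (!all(c("mortality", "readmission_30") %in% names(cfg$target_rates))) {
    bad <- c(bad, "target_rates must name mortality and readmission_30")
  }
  if (length(cfg$calendar_window) != 2L ||
      cfg$calendar_window[2L] <= cfg$calendar_window[1L]) {
    bad <- c(bad, "calendar_window must be an increasing pair of dates")
  }
  if (cfg$readmit_gap_q <= 0 || cfg$readmit_gap_q >= 1) {
    bad <- c(bad, "readmit_gap_q must lie in (0, 1)")
  }
  if (!is.null(cfg$equity_gradient)) {
    lens <- vapply(cfg$equity_gradient, length, 1L)
    if (any(lens != cfg$n_hospitals)) {
      bad <- c(bad, "equity_gradient vectors must have length n_hospitals")
    }
  }
  if (length(bad)) {
    stop(paste0("invalid cohort_config:\n  - ", paste(bad, collapse = "\n  - ")),
         call. = FALSE)
  }
  invisible(cfg)
}

# Per-hospital equity shifts: logit shifts for binary factors, location
# shifts for continuous marginalization dimensions.
#' @noRd
draw_equity_gradient <- function(cfg) {
  if (!is.null(cfg$equity_gradient)) {
    g <- cfg$equity_gradient
  } else {
    k <- cfg$n_hospitals
    sd <- cfg$equity_gradient_sd
    g <- list(
      homelessness = stats::rnorm(k, 0, sd[["homelessness"]]),
      disability = stats::rnorm(k, 0, sd[["disability"]]),
      onmarg_housing = stats::rnorm(k, 0, sd[["onmarg"]]),
      onmarg_racialized_newcomer = stats::rnorm(k, 0, sd[["onmarg"]]),
      onmarg_material = stats::rnorm(k, 0, sd[["onmarg"]]),
      onmarg_age_labor = stats::rnorm(k, 0, sd[["onmarg"]])
    )
    if (!is.na(cfg$outlier_hospital)) {
      oh <- cfg$outlier_hospital
      g$homelessness[oh] <- g$homelessness[oh] + 2.0
      g$onmarg_housing[oh] <- g$onmarg_housing[oh] + 1.5
    }
  }
  for (nm in c("homelessness", "disability", "onmarg_housing",
               "onmarg_racialized_newcomer", "onmarg_material",
               "onmarg_age_labor")) {
    if (is.null(g[[nm]])) g[[nm]] <- numeric(cfg$n_hospitals)
  }
  g
}

#' Generate a synthetic admission-level cohort with known ground truth
#'
#' Draws an admission table emulating a multi-hospital general-medicine
#' cohort: clinical covariates matched to published marginals (age median ~72,
#' IQR 58-83; mLAPS median ~16; Charlson 0/1/2+ at 51/18/30%), hospital
#' random intercepts on the log-odds scale, hospital-specific equity-factor
#' prevalence, in-hospital mortality and 30-day readmission outcomes whose
#' crude rates are calibrated to the configured targets, readmission
#' follow-on admissions constructed so that true 7- and 30-day readmission
#' events exist by design, contiguous interfacility transfer chains, and
#' records violating each study exclusion rule in configured proportions.
#'
#' Outcome intercepts are calibrated deterministically (given the draws) by
#' root-finding so that the population mean of `expit(intercept + lp + u_h)`
#' hits the target rate. Readmission follow-ons are single-level: a generated
#' readmission does not itself spawn a further readmission.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{admissions}{data.frame, one row per admission (index, transfer,
#'       and readmission records), with an `exclusion_truth` attribute
#'       (hidden rule labels for injected violations).}
#'     \item{truth}{list: `hospital_intercepts` (per outcome),
#'       `coefficients`, `equity_gradient`, per-admission `linear_predictor`
#'       table (log-odds excluding and including the hospital intercept), and
#'       `readmission_events` (index admission id, gap days, realized flag).}
#'   }
#' @examples
#' cfg <- cohort_config(n_hospitals = 4, admissions_per_hospital = c(80, 120),
#'                      seed = 7)
#' coh <- generate_cohort(cfg)
#' mean(coh$admissions$disposition == "death")
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) {
    stop("config must be a cohort_config object", call. = FALSE)
  }
  validate_cohort_config(config)
  cfg <- config
  hospitals <- sprintf("H%02d", seq_len(cfg$n_hospitals))
  dx_labels <- sprintf("DX%02d", seq_len(cfg$n_dx_groups))

  set.seed(child_seed(cfg$seed, 0L))
  u_mort <- cfg$hospital_sigma * stats::rnorm(cfg$n_hospitals)
  u_readm <- cfg$hospital_sigma * stats::rnorm(cfg$n_hospitals)
  names(u_mort) <- names(u_readm) <- hospitals
  gradient <- draw_equity_gradient(cfg)

  window_start <- as.POSIXct(paste(cfg$calendar_window[1L], "00:00:00"),
                             tz = "UTC")
  window_end <- as.POSIXct(paste(cfg$calendar_window[2L], "23:59:59"),
                           tz = "UTC")
  window_days <- as.numeric(difftime(window_end, window_start, units = "days"))

  per_hosp <- vector("list", cfg$n_hospitals)
  for (h in seq_len(cfg$n_hospitals)) {
    set.seed(child_seed(cfg$seed, h))
    n <- if (cfg$admissions_per_hospital[1L] == cfg$admissions_per_hospital[2L]) {
      cfg$admissions_per_hospital[1L]
    } else {
      sample(cfg$admissions_per_hospital[1L]:cfg$admissions_per_hospital[2L], 1L)
    }
    age <- round(stats::qnorm(stats::runif(
      n, stats::pnorm(18, 71, 18.5), stats::pnorm(108, 71, 18.5)
    ), 71, 18.5), 1)
    mrdx_cat <- sample(
      c("none", "palliative", "maid", "mental_health", "chemo", "obstetric"),
      n, replace = TRUE,
      prob = c(1 - cfg$exclusion_rates[["palliative"]] -
                 cfg$exclusion_rates[["maid"]] - sum(cfg$mrdx_rates),
               cfg$exclusion_rates[["palliative"]],
               cfg$exclusion_rates[["maid"]],
               cfg$mrdx_rates[["mental_health"]], cfg$mrdx_rates[["chemo"]],
               cfg$mrdx_rates[["obstetric"]]))
    admit_offset <- stats::runif(n, 0, window_days - 2)
    in_tail <- stats::runif(n) < cfg$tail_fraction
    los <- pmax(stats::rgamma(n, shape = 1.3, scale = 5), 0.05)
    # force a configurable fraction of discharges into the last 60 days
    admit_offset[in_tail] <- window_days - stats::runif(sum(in_tail), 0, 60) -
      los[in_tail]
    admit_offset <- pmax(admit_offset, 0)
    cognitive <- stats::runif(n) < expit(logit(0.015) + gradient$disability[h])
    physical <- stats::runif(n) < expit(logit(0.120) + gradient$disability[h])
    sensory <- stats::runif(n) < expit(logit(0.008) + gradient$disability[h])
    tab <- data.frame(
      patient_id = NA_character_,
      hospital_id = hospitals[h],
      admit_dt = window_start + admit_offset * 86400,
      discharge_dt = window_start + (admit_offset + los) * 86400,
      age = age,
      sex = ifelse(stats::runif(n) < 0.503, "male", "female"),
      admission_category = ifelse(stats::runif(n) < 0.021, "elective", "urgent"),
      charlson = sample(c("0", "1", "2+"), n, replace = TRUE,
                        prob = c(0.513, 0.184, 0.303)),
      mlaps = as.integer(round(stats::rexp(n) * 23)),
      prior_discharges_6mo = sample(c("0", "1", "2+"), n, replace = TRUE,
                                    prob = c(0.690, 0.188, 0.122)),
      dx_group = sample(dx_labels, n, replace = TRUE,
                        prob = cfg$dx_group_weights),
      mrdx_palliative = mrdx_cat == "palliative",
      mrdx_maid = mrdx_cat == "maid",
      mrdx_mental_health = mrdx_cat == "mental_health",
      mrdx_chemo = mrdx_cat == "chemo",
      mrdx_obstetric = mrdx_cat == "obstetric",
      disposition = "home",
      transfer_in = FALSE,
      homelessness = stats::runif(n) <
        expit(logit(0.02) + gradient$homelessness[h]),
      cognitive_disability = cognitive,
      physical_disability = physical,
      sensory_disability = sensory,
      disability = cognitive | physical | sensory,
      onmarg_housing = stats::rnorm(n, gradient$onmarg_housing[h], 1),
      onmarg_racialized_newcomer =
        stats::rnorm(n, gradient$onmarg_racialized_newcomer[h], 1),
      onmarg_material = stats::rnorm(n, gradient$onmarg_material[h], 1),
      onmarg_age_labor = stats::rnorm(n, gradient$onmarg_age_labor[h], 1),
      dissemination_area_present = TRUE,
      stringsAsFactors = FALSE
    )
    per_hosp[[h]] <- tab
  }
  adm <- do.call(rbind, per_hosp)
  rownames(adm) <- NULL
  n_all <- nrow(adm)
  adm$admission_id <- sprintf("A%07d", seq_len(n_all))
  adm$patient_id <- sprintf("P%07d", seq_len(n_all))

  # master stream for the cross-hospital stages
  set.seed(child_seed(cfg$seed, cfg$n_hospitals + 1L))

  # injected exclusion-rule violations (age/LOS/DA/id; palliative & MAID come
  # from the mrdx draw above)
  truth_rules <- data.frame(admission_id = character(), rule = character(),
                            stringsAsFactors = FALSE)
  pick <- function(rate, taken) {
    k <- round(rate * n_all)
    if (k == 0) return(integer())
    sample(setdiff(seq_len(n_all), taken), min(k, n_all - length(taken)))
  }
  taken <- integer()
  i_age <- pick(cfg$exclusion_rates[["age_gt_120"]], taken)
  taken <- c(taken, i_age)
  i_los <- pick(cfg$exclusion_rates[["los_gt_1yr"]], taken)
  taken <- c(taken, i_los)
  i_da <- pick(cfg$exclusion_rates[["missing_da"]], taken)
  taken <- c(taken, i_da)
  i_id <- pick(cfg$exclusion_rates[["invalid_id"]], taken)
  adm$age[i_age] <- round(stats::runif(length(i_age), 121, 130))
  adm$discharge_dt[i_los] <- adm$admit_dt[i_los] +
    stats::runif(length(i_los), 370, 500) * 86400
  adm$dissemination_area_present[i_da] <- FALSE
  adm$patient_id[i_id] <- NA_character_
  rule_rows <- function(ids, rule) {
    data.frame(admission_id = ids, rule = rep(rule, length(ids)),
               stringsAsFactors = FALSE)
  }
  truth_rules <- rbind(
    truth_rules,
    rule_rows(adm$admission_id[i_age], "age_gt_120"),
    rule_rows(adm$admission_id[i_los], "los_gt_1yr"),
    rule_rows(adm$admission_id[adm$mrdx_palliative], "palliative"),
    rule_rows(adm$admission_id[adm$mrdx_maid], "maid"),
    rule_rows(adm$admission_id[i_da], "missing_da"),
    rule_rows(adm$admission_id[i_id], "invalid_id")
  )

  # linear predictors (excluding intercept and hospital effect)
  lp_mort <- truth_linear_predictor(adm, cfg$true_coefficients$mortality)
  lp_readm <- truth_linear_predictor(adm, cfg$true_coefficients$readmission)
  h_idx <- match(adm$hospital_id, hospitals)

  # calibrate outcome intercepts to the target crude rates; follow-on
  # transfer/readmission records dilute the final denominator, so the
  # index-admission target is inflated by the expected follow-on fraction
  dilution <- 1 + cfg$transfer_rate + 0.9 * cfg$target_rates[["readmission_30"]]
  a_mort <- calibrate_intercept(
    lp_mort + u_mort[h_idx],
    min(cfg$target_rates[["mortality"]] * dilution, 0.95))
  a_readm <- calibrate_intercept(
    lp_readm + u_readm[h_idx],
    min(cfg$target_rates[["readmission_30"]] *
          (1 + 0.9 * cfg$target_rates[["readmission_30"]]), 0.95))
  p_mort <- expit(a_mort + lp_mort + u_mort[h_idx])
  died <- stats::runif(n_all) < p_mort
  adm$disposition[died] <- "death"

  # 30-day readmission events for surviving index admissions
  p_readm <- expit(a_readm + lp_readm + u_readm[h_idx])
  readmitted <- !died & stats::runif(n_all) < p_readm
  gap_probs <- cfg$readmit_gap_q^(0:29)
  gaps <- rep(NA_integer_, n_all)
  gaps[readmitted] <- sample(1:30, sum(readmitted), replace = TRUE,
                             prob = gap_probs)

  # within-network transfers and other dispositions on non-event admissions
  free <- which(!died & !readmitted)
  n_tr <- round(cfg$transfer_rate * n_all)
  i_tr <- if (length(free)) sample(free, min(n_tr, length(free))) else integer()
  free <- setdiff(free, i_tr)
  n_oon <- round(cfg$out_of_network_rate * n_all)
  i_oon <- if (length(free)) sample(free, min(n_oon, length(free))) else integer()
  free <- setdiff(free, i_oon)
  n_ss <- round(cfg$self_signout_rate * n_all)
  i_ss <- if (length(free)) sample(free, min(n_ss, length(free))) else integer()
  adm$disposition[i_oon] <- "transfer_out"
  adm$disposition[i_ss] <- "self_signout"

  # materialize transfer follow-on records (contiguous, other hospital)
  transfer_rows <- NULL
  if (length(i_tr) && cfg$n_hospitals > 1L) {
    adm$disposition[i_tr] <- "transfer_out"
    src <- adm[i_tr, , drop = FALSE]
    dest <- vapply(src$hospital_id, function(hh) {
      sample(setdiff(hospitals, hh), 1L)
    }, character(1))
    tr <- src
    tr$hospital_id <- dest
    tr$admit_dt <- src$discharge_dt + stats::runif(nrow(src), 0.5, 10) * 3600
    tr$discharge_dt <- tr$admit_dt +
      pmax(stats::rgamma(nrow(src), 1.3, scale = 5), 0.05) * 86400
    tr$transfer_in <- TRUE
    tr$disposition <- "home"
    tr$mlaps <- as.integer(round(stats::rexp(nrow(src)) * 23))
    tr$admission_id <- sprintf("T%07d", seq_len(nrow(src)))
    transfer_rows <- tr
  }

  # materialize readmission follow-on records within the calendar window
  idx_re <- which(readmitted)
  realized <- logical(length(idx_re))
  readm_rows <- NULL
  if (length(idx_re)) {
    re_admit <- adm$discharge_dt[idx_re] + gaps[idx_re] * 86400 +
      stats::runif(length(idx_re), 1, 12) * 3600
    realized <- re_admit <= window_end
    keep <- which(realized)
    if (length(keep)) {
      src <- adm[idx_re[keep], , drop = FALSE]
      same <- stats::runif(length(keep)) < cfg$same_hospital_readmit
      dest <- src$hospital_id
      if (cfg$n_hospitals > 1L && any(!same)) {
        dest[!same] <- vapply(src$hospital_id[!same], function(hh) {
          sample(setdiff(hospitals, hh), 1L)
        }, character(1))
      }
      re <- src
      re$hospital_id <- dest
      re$admit_dt <- re_admit[keep]
      re$discharge_dt <- re$admit_dt +
        pmax(stats::rgamma(length(keep), 1.3, scale = 5), 0.05) * 86400
      re$admission_category <- "urgent"
      re$transfer_in <- FALSE
      re$disposition <- "home"
      re$mlaps <- as.integer(round(stats::rexp(length(keep)) * 23))
      re$prior_discharges_6mo <- ifelse(src$prior_discharges_6mo == "0", "1", "2+")
      re$mrdx_palliative <- re$mrdx_maid <- re$mrdx_mental_health <- FALSE
      re$mrdx_chemo <- re$mrdx_obstetric <- FALSE
      re$admission_id <- sprintf("R%07d", seq_len(length(keep)))
      readm_rows <- re
    }
  }

  all_adm <- rbind(adm, transfer_rows, readm_rows)
  rownames(all_adm) <- NULL
  attr(all_adm, "exclusion_truth") <- truth_rules

  truth <- list(
    hospital_intercepts = list(mortality = u_mort, readmission = u_readm),
    intercepts = c(mortality = a_mort, readmission = a_readm),
    coefficients = cfg$true_coefficients,
    equity_gradient = gradient,
    linear_predictor = data.frame(
      admission_id = adm$admission_id,
      lp_mortality = a_mort + lp_mort,
      lp_readmission = a_readm + lp_readm,
      lp_mortality_hosp = a_mort + lp_mort + u_mort[h_idx],
      lp_readmission_hosp = a_readm + lp_readm + u_readm[h_idx],
      stringsAsFactors = FALSE
    ),
    readmission_events = data.frame(
      admission_id = adm$admission_id[idx_re],
      gap_days = gaps[idx_re],
      realized = realized,
      stringsAsFactors = FALSE
    )
  )
  structure(list(admissions = all_adm, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

# linear predictor (excluding intercept / hospital effect) from a truth
# coefficient vector; age enters per-year centered at 70
#' @noRd
truth_linear_predictor <- function(tab, beta) {
  beta[["age"]] * (tab$age - 70) +
    beta[["male"]] * (tab$sex == "male") +
    beta[["elective"]] * (tab$admission_category == "elective") +
    beta[["charlson1"]] * (tab$charlson == "1") +
    beta[["charlson2"]] * (tab$charlson == "2+") +
    beta[["mlaps"]] * (tab$mlaps - 16) +
    beta[["prior1"]] * (tab$prior_discharges_6mo == "1") +
    beta[["prior2"]] * (tab$prior_discharges_6mo == "2+") +
    beta[["homelessness"]] * tab$homelessness +
    beta[["disability"]] * tab$disability +
    beta[["onmarg_housing"]] * tab$onmarg_housing +
    beta[["onmarg_racialized_newcomer"]] * tab$onmarg_racialized_newcomer +
    beta[["onmarg_material"]] * tab$onmarg_material +
    beta[["onmarg_age_labor"]] * tab$onmarg_age_labor
}

# solve mean(expit(a + lp)) = target for the intercept a
#' @noRd
calibrate_intercept <- function(lp, target) {
  stats::uniroot(function(a) mean(expit(a + lp)) - target,
                 lower = -20, upper = 20, tol = 1e-10)$root
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d admissions at %d hospitals\n",
              nrow(x$admissions), x$config$n_hospitals))
  cat(sprintf("  in-hospital deaths: %.1f%%; window %s .. %s\n",
              100 * mean(x$admissions$disposition == "death"),
              x$config$calendar_window[1], x$config$calendar_window[2]))
  invisible(x)
}

#' Inject additional exclusion-rule violations into an admission table
#'
#' Appends exactly the requested number of rows violating each named study
#' exclusion rule. New rows are copies of randomly chosen existing rows,
#' sanitized so they violate only the requested rule, and tagged in the
#' table's hidden `exclusion_truth` attribute so downstream filter counts can
#' be verified against ground truth.
#'
#' @param table Admission data.frame (as from [generate_cohort()]).
#' @param counts Named non-negative integer vector/list over rules
#'   `age_gt_120`, `los_gt_1yr`, `palliative`, `maid`, `missing_da`,
#'   `invalid_id`.
#' @param seed Integer seed.
#' @return The table with the extra rows appended and the `exclusion_truth`
#'   attribute extended.
#' @export
inject_exclusion_fixtures <- function(table, counts, seed = 1L) {
  rules <- c("age_gt_120", "los_gt_1yr", "palliative", "maid", "missing_da",
             "invalid_id")
  counts <- unlist(counts)
  if (length(counts) == 0) return(table)
  bad <- setdiff(names(counts), rules)
  if (length(bad)) {
    stop(sprintf("unknown exclusion rule(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  set.seed(child_seed(seed, 97L))
  truth <- attr(table, "exclusion_truth") %||%
    data.frame(admission_id = character(), rule = character(),
               stringsAsFactors = FALSE)
  added <- NULL
  serial <- 0L
  for (rule in names(counts)) {
    k <- as.integer(counts[[rule]])
    if (k == 0) next
    src <- table[sample(nrow(table), k, replace = TRUE), , drop = FALSE]
    # sanitize: violate only the requested rule
    src$age <- pmin(src$age, 95)
    src$discharge_dt <- src$admit_dt + stats::runif(k, 1, 20) * 86400
    src$mrdx_palliative <- src$mrdx_maid <- FALSE
    src$dissemination_area_present <- TRUE
    src$admission_id <- sprintf("X%s%06d", substr(rule, 1, 2),
                                serial + seq_len(k))
    src$patient_id <- sprintf("PX%s%06d", substr(rule, 1, 2),
                              serial + seq_len(k))
    serial <- serial + k
    switch(rule,
      age_gt_120 = { src$age <- round(stats::runif(k, 121, 135)) },
      los_gt_1yr = { src$discharge_dt <- src$admit_dt +
        stats::runif(k, 366.01, 450) * 86400 },
      palliative = { src$mrdx_palliative <- TRUE },
      maid = { src$mrdx_maid <- TRUE },
      missing_da = { src$dissemination_area_present <- FALSE },
      invalid_id = { src$patient_id <- NA_character_ }
    )
    truth <- rbind(truth, data.frame(admission_id = src$admission_id,
                                     rule = rule, stringsAsFactors = FALSE))
    added <- rbind(added, src)
  }
  out <- rbind(table, added)
  rownames(out) <- NULL
  attr(out, "exclusion_truth") <- truth
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes the admission table as CSV (ISO-8601 UTC timestamps) and the ground
#' truth as a JSON sidecar.
#'
#' @param cohort A `synthetic_cohort` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  adm <- cohort$admissions
  adm$admit_dt <- format(adm$admit_dt, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  adm$discharge_dt <- format(adm$discharge_dt, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  csv <- file.path(dir, "admissions.csv")
  json <- file.path(dir, "ground_truth.json")
  utils::write.csv(adm, csv, row.names = FALSE)
  jsonlite::write_json(cohort$truth, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(admissions = csv, truth = json))
}

#' Read an admission table written by [write_cohort()]
#'
#' @param path Path to the admissions CSV.
#' @return Admission data.frame with POSIXct timestamps.
#' @export
read_cohort_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$admit_dt <- as.POSIXct(tab$admit_dt, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  tab$discharge_dt <- as.POSIXct(tab$discharge_dt,
                                 format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  tab
}
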