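#' Apply the mortality-cohort exclusion rules
#'
#' Removes admissions with a length of stay longer than 1 year (strictly more
#' than 365 days), age over 120 years, palliative care or medical assistance
#' in dying as most responsible diagnosis, or no recorded census
#' dissemination area. A row failing several rules is counted under every
#' rule it fails but removed once. Admissions without a valid patient id are
#' retained here (they are excluded from readmission cohorts only).
#'
#' @param table Admission data.frame.
#' @return List with `cohort` (retained rows) and `exclusions` (data.frame of
#'   per-rule counts, plus the number of distinct rows removed as attribute
#'   `n_removed`).
#' @export
apply_mortality_exclusions <- function(table) {
  stop_missing_cols(table, c("admit_dt", "discharge_dt", "age",
                             "mrdx_palliative", "mrdx_maid",
                             "dissemination_area_present"),
                    "admission table")
  if (nrow(table) == 0) {
    return(list(cohort = table,
                exclusions = data.frame(
                  rule = c("los_gt_1yr", "age_gt_120", "palliative", "maid",
                           "missing_da"),
                  n = 0L, stringsAsFactors = FALSE)))
  }
  los_days <- as.numeric(difftime(table$discharge_dt, table$admit_dt,
                                  units = "days"))
  viol <- cbind(
    los_gt_1yr = los_days > 365,
    age_gt_120 = table$age > 120,
    palliative = table$mrdx_palliative,
    maid = table$mrdx_maid,
    missing_da = !table$dissemination_area_present
  )
  drop <- rowSums(viol) > 0
  counts <- data.frame(rule = colnames(viol), n = as.integer(colSums(viol)),
                       stringsAsFactors = FALSE)
  attr(counts, "n_removed") <- sum(drop)
  list(cohort = table[!drop, , drop = FALSE], exclusions = counts)
}

#' Link admissions into episodes of care
#'
#' Chains contiguous hospitalizations of the same patient into a single
#' episode of care so that interfacility transfers are not mistaken for
#' readmissions. Two admissions are contiguous when the later one begins
#' within `gap_hours` of the earlier discharge, overlaps it, or carries a
#' `transfer_in` flag. Rows with a missing patient id cannot be linked and
#' become single-admission episodes flagged `invalid_id`. Each episode is
#' attributed to the hospital of its final admission.
#'
#' @param table Admission data.frame.
#' @param gap_hours Maximum admit-to-prior-discharge gap (hours) treated as
#'   contiguous; must be non-negative.
#' @return data.frame with one row per episode: ids, attributed hospital,
#'   episode admit/discharge timestamps, number of admissions, a
#'   list-column `admission_ids`, aggregated diagnosis flags (`any_*`),
#'   first-record admission category, last-record disposition, and validity
#'   flags.
#' @export
build_episodes <- function(table, gap_hours = 12) {
  if (gap_hours < 0) stop("gap_hours must be non-negative", call. = FALSE)
  stop_missing_cols(table, c("admission_id", "patient_id", "hospital_id",
                             "admit_dt", "discharge_dt"), "admission table")
  if (nrow(table) == 0) {
    return(data.frame(episode_id = character(), patient_id = character(),
                      attributed_hospital = character(),
                      stringsAsFactors = FALSE))
  }
  tab <- table
  valid <- !is.na(tab$patient_id)
  # deterministic order regardless of input row order
  ord <- order(ifelse(valid, tab$patient_id, paste0("", tab$admission_id)),
               tab$admit_dt, tab$discharge_dt, tab$admission_id)
  tab <- tab[ord, , drop = FALSE]
  valid <- valid[ord]

  pid <- ifelse(valid, tab$patient_id, paste0("~anon~", tab$admission_id))
  same_patient <- c(FALSE, pid[-1L] == pid[-length(pid)])
  # running maximum discharge within a patient guards against nested stays
  prev_disc <- c(as.POSIXct(NA), tab$discharge_dt[-nrow(tab)])
  gap_ok <- same_patient &
    (as.numeric(difftime(tab$admit_dt, prev_disc, units = "hours")) <=
       gap_hours | (!is.na(tab$transfer_in) & tab$transfer_in))
  gap_ok[is.na(gap_ok)] <- FALSE
  new_episode <- !gap_ok
  ep_index <- cumsum(new_episode)

  split_idx <- split(seq_len(nrow(tab)), ep_index)
  n_ep <- length(split_idx)
  first <- vapply(split_idx, `[`, integer(1), 1L)
  last <- vapply(split_idx, function(i) i[length(i)], integer(1))

  any_flag <- function(col) {
    if (!col %in% names(tab)) return(rep(FALSE, n_ep))
    v <- tab[[col]]
    vapply(split_idx, function(i) any(v[i], na.rm = TRUE), logical(1))
  }
  ep <- data.frame(
    episode_id = sprintf("E%07d", seq_len(n_ep)),
    patient_id = tab$patient_id[first],
    attributed_hospital = tab$hospital_id[last],
    episode_admit_dt = tab$admit_dt[first],
    episode_discharge_dt = tab$discharge_dt[last],
    n_admissions = lengths(split_idx),
    first_admission_id = tab$admission_id[first],
    index_elective = tab$admission_category[first] == "elective",
    last_disposition = tab$disposition[last],
    valid_id = valid[first],
    any_palliative = any_flag("mrdx_palliative"),
    any_maid = any_flag("mrdx_maid"),
    any_mental_health = any_flag("mrdx_mental_health"),
    any_chemo = any_flag("mrdx_chemo"),
    any_obstetric = any_flag("mrdx_obstetric"),
    stringsAsFactors = FALSE
  )
  ep$admission_ids <- I(lapply(split_idx, function(i) tab$admission_id[i]))
  rownames(ep) <- NULL
  ep
}

#' Label episodes with 7- or 30-day readmission outcomes
#'
#' An episode is labeled readmitted when another episode of the same patient
#' begins within the window (in whole days, inclusive of day 7/30) after the
#' episode's discharge and the candidate readmission is not disqualified:
#' episodes whose initial encounter was elective and episodes with any record
#' flagged for chemotherapy, palliative care, obstetric delivery, mental
#' health, or medical assistance in dying do not count as readmissions.
#'
#' @param episodes Episode data.frame from [build_episodes()].
#' @param window_days Either 7 or 30.
#' @return The episode table with a logical column `readmitted_7d` or
#'   `readmitted_30d` added.
#' @export
label_readmissions <- function(episodes, window_days) {
  if (!window_days %in% c(7, 30)) {
    stop("window_days must be 7 or 30", call. = FALSE)
  }
  ep <- episodes
  col <- sprintf("readmitted_%dd", window_days)
  ep[[col]] <- FALSE
  if (nrow(ep) == 0) return(ep)
  disqualified <- ep$index_elective | ep$any_chemo | ep$any_palliative |
    ep$any_obstetric | ep$any_mental_health | ep$any_maid
  ord <- order(ep$patient_id, ep$episode_admit_dt)
  idx <- ord[!is.na(ep$patient_id[ord])]
  if (length(idx) > 1) {
    for (j in seq_len(length(idx) - 1L)) {
      i <- idx[j]
      for (k in (j + 1L):length(idx)) {
        m <- idx[k]
        if (ep$patient_id[m] != ep$patient_id[i]) break
        gap <- as.numeric(difftime(ep$episode_admit_dt[m],
                                   ep$episode_discharge_dt[i],
                                   units = "days"))
        if (gap > window_days) break
        if (gap > 0 && !disqualified[m]) {
          ep[[col]][i] <- TRUE
          break
        }
      }
    }
  }
  ep
}

#' Apply the readmission-cohort exclusion rules to index episodes
#'
#' Removes index episodes that cannot contribute to readmission measurement:
#' episodes ending in death, episodes with palliative care or mental health
#' as most responsible diagnosis on any record, episodes discharged outside
#' the network (disposition `transfer_out` on the last record), episodes
#' whose last record was a self sign-out, and episodes of patients without a
#' valid health card number. Counts are rule attributions (a row failing
#' several rules appears under each) while each episode is removed once.
#'
#' @param episodes Labeled episode data.frame.
#' @return List with `cohort` and `exclusions` (per-rule counts with
#'   attribute `n_removed`).
#' @export
apply_readmission_exclusions <- function(episodes) {
  stop_missing_cols(episodes, c("last_disposition", "any_palliative",
                                "any_mental_health", "valid_id"),
                    "episode table")
  viol <- cbind(
    death = episodes$last_disposition == "death",
    palliative_mrdx = episodes$any_palliative,
    mental_health_mrdx = episodes$any_mental_health,
    discharged_out_of_network = episodes$last_disposition == "transfer_out",
    self_signout = episodes$last_disposition == "self_signout",
    invalid_id = !episodes$valid_id
  )
  drop <- rowSums(viol) > 0
  counts <- data.frame(rule = colnames(viol), n = as.integer(colSums(viol)),
                       stringsAsFactors = FALSE)
  attr(counts, "n_removed") <- sum(drop)
  list(cohort = episodes[!drop, , drop = FALSE], exclusions = counts)
}

#' Truncate the reporting tail for readmission outcomes
#'
#' Readmission status cannot be fully observed near the end of each
#' hospital's data window, so episodes discharged within the most recent 37
#' days (7-day outcome) or 60 days (30-day outcome) of that hospital's own
#' maximum discharge date are removed. The mortality outcome needs no
#' truncation and is returned unchanged.
#'
#' @param table Episode (or admission) data.frame with a discharge timestamp
#'   and hospital column.
#' @param outcome One of `"mortality"`, `"readmission_7"`, `"readmission_30"`.
#' @param discharge_col,hospital_col Column names holding the discharge
#'   timestamp and the hospital id.
#' @return The table with tail rows removed.
#' @export
truncate_reporting_tail <- function(table, outcome,
                                    discharge_col = "episode_discharge_dt",
                                    hospital_col = "attributed_hospital") {
  outcome <- match.arg(outcome, c("mortality", "readmission_7",
                                  "readmission_30"))
  if (outcome == "mortality" || nrow(table) == 0) return(table)
  days <- if (outcome == "readmission_7") 37 else 60
  stop_missing_cols(table, c(discharge_col, hospital_col), "episode table")
  disc <- table[[discharge_col]]
  hosp_max <- tapply(as.numeric(disc), table[[hospital_col]], max)
  cutoff <- hosp_max[as.character(table[[hospital_col]])] - days * 86400
  table[as.numeric(disc) <= cutoff, , drop = FALSE]
}

#' Build analysis cohorts for one outcome
#'
#' Convenience wrapper running the full cohort-construction sequence:
#' mortality exclusions, episode linkage, readmission labeling, readmission
#' exclusions, and reporting-tail truncation. For the mortality outcome the
#' unit of analysis is the admission; for readmission outcomes it is the
#' index episode of care, attributed to the last discharging hospital.
#'
#' @param table Admission data.frame.
#' @param outcome One of `"mortality"`, `"readmission_7"`, `"readmission_30"`.
#' @param gap_hours Episode contiguity gap, see [build_episodes()].
#' @return List with `cohort` (analysis table with columns `y`,
#'   `hospital_id`, covariates), `exclusions` (named list of count tables),
#'   and for readmission outcomes the labeled episode table.
#' @export
build_outcome_cohort <- function(table, outcome, gap_hours = 12) {
  outcome <- match.arg(outcome, c("mortality", "readmission_7",
                                  "readmission_30"))
  mort <- apply_mortality_exclusions(table)
  if (outcome == "mortality") {
    cohort <- mort$cohort
    cohort$y <- as.integer(cohort$disposition == "death")
    return(list(cohort = cohort,
                exclusions = list(mortality = mort$exclusions)))
  }
  window <- if (outcome == "readmission_7") 7 else 30
  episodes <- build_episodes(mort$cohort, gap_hours = gap_hours)
  episodes <- label_readmissions(episodes, window)
  readm <- apply_readmission_exclusions(episodes)
  kept <- truncate_reporting_tail(readm$cohort, outcome)
  # covariates of the first (index) admission drive risk adjustment
  first_idx <- match(kept$first_admission_id, mort$cohort$admission_id)
  covars <- mort$cohort[first_idx, setdiff(names(mort$cohort),
                                           c("hospital_id")), drop = FALSE]
  cohort <- cbind(
    kept[, c("episode_id", "patient_id", "attributed_hospital",
             "episode_admit_dt", "episode_discharge_dt", "n_admissions")],
    covars[, c("age", "sex", "admission_category", "charlson", "mlaps",
               "prior_discharges_6mo", "dx_group", "homelessness",
               "disability", "cognitive_disability", "physical_disability",
               "sensory_disability", "onmarg_housing",
               "onmarg_racialized_newcomer", "onmarg_material",
               "onmarg_age_labor")]
  )
  cohort$hospital_id <- cohort$attributed_hospital
  cohort$y <- as.integer(kept[[sprintf("readmitted_%dd", window)]])
  rownames(cohort) <- NULL
  list(cohort = cohort,
       exclusions = list(mortality = mort$exclusions,
                         readmission = readm$exclusions),
       episodes = episodes)
}
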