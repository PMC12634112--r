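#' Split a cohort into training and reporting periods by discharge date
#'
#' Partitions admissions by discharge date: discharges on or before
#' `training_end` form the training period; later discharges form the
#' reporting period (the boundary date itself is training). Hospitals whose
#' reporting-period data do not span at least `min_coverage` of the reporting
#' calendar window are dropped from the reporting partition, mirroring the
#' exclusion of hospitals with incomplete reporting-year coverage.
#'
#' @param table Admission data.frame with `discharge_dt` and `hospital_id`.
#' @param training_end Date/POSIXct end of the training period (inclusive).
#' @param reporting_end Optional end of the reporting window; default the
#'   maximum discharge date present.
#' @param min_coverage Minimum fraction of the reporting window a hospital's
#'   own discharge span must cover to stay in the reporting partition.
#' @return List with `training`, `reporting`, and `dropped_hospitals`.
#' @export
split_periods <- function(table, training_end, reporting_end = NULL,
                          min_coverage = 0.95) {
  stop_missing_cols(table, c("discharge_dt", "hospital_id"), "cohort")
  training_end <- as.POSIXct(training_end, tz = "UTC")
  if (is.null(reporting_end)) {
    # infer the window end from ordinary stays; year-plus outliers (study
    # exclusions) would otherwise stretch the reporting window
    los <- as.numeric(difftime(table$discharge_dt, table$admit_dt,
                               units = "days"))
    reporting_end <- max(table$discharge_dt[los <= 365])
  } else {
    reporting_end <- as.POSIXct(reporting_end, tz = "UTC")
  }
  if (reporting_end <= training_end) {
    stop("reporting window must follow the training period", call. = FALSE)
  }
  in_train <- table$discharge_dt <= training_end
  training <- table[in_train, , drop = FALSE]
  reporting <- table[!in_train & table$discharge_dt <= reporting_end, ,
                     drop = FALSE]
  if (nrow(training) == 0 || nrow(reporting) == 0) {
    stop("empty training or reporting partition", call. = FALSE)
  }
  # coverage is judged against the typical hospital's window: the median of
  # per-hospital last discharges is robust to a few long stays spilling past
  # the calendar end of the study
  span <- tapply(as.numeric(reporting$discharge_dt), reporting$hospital_id,
                 function(d) (max(d) - min(d)) / 86400)
  hosp_max <- tapply(as.numeric(reporting$discharge_dt),
                     reporting$hospital_id, max)
  window_days <- (stats::median(hosp_max) - as.numeric(training_end)) / 86400
  dropped <- names(span)[span < min_coverage * window_days]
  if (length(dropped)) {
    reporting <- reporting[!reporting$hospital_id %in% dropped, ,
                           drop = FALSE]
  }
  list(training = training, reporting = reporting,
       dropped_hospitals = dropped)
}

#' Run the full hospital-profiling study pipeline
#'
#' Orchestrates the complete analysis for one or more outcomes: simulate (or
#' load) an admission cohort, split into training and reporting periods,
#' build the outcome cohorts, fit base and equity-expanded risk models on the
#' training period, evaluate both by internal-external cross-validation with
#' random-effects pooling, compute risk-standardized reporting-period rates
#' with cluster-bootstrap intervals under both adjustments, classify and
#' compare hospitals, and profile equity gradients. Artifacts are written as
#' CSV/JSON under `outdir` when given.
#'
#' @param config List (or YAML file path, read with the yaml package) with
#'   entries: `cohort` (a [cohort_config()] or arguments for one) or
#'   `cohort_csv` (path to an admission CSV); `training_end` (date);
#'   `outcomes` (subset of mortality/readmission_7/readmission_30);
#'   `n_boot_metrics`, `n_boot_rsr`; `lambda_grid`; `min_events`; `seed`;
#'   `min_coverage`.
#' @param outdir Optional output directory for artifacts.
#' @return List of class `profile_run`: per-outcome results (`pooled`
#'   metrics for both model variants, `profile_base`, `profile_equity`,
#'   `reclassification`, `heatmap`) plus a `manifest` (seeds, sizes, config
#'   echo, stage timings).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a YAML config requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    outcomes = c("mortality", "readmission_30"),
    training_end = "2021-04-30 23:59:59",
    n_boot_metrics = 200, n_boot_rsr = 200,
    lambda_grid = default_lambda_grid(), min_events = 200,
    min_coverage = 0.95, seed = 1L, gap_hours = 12
  ), config)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- force(expr)
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), s,
                                                  units = "secs")), 2)
    out
  }

  if (!is.null(cfg$cohort_csv)) {
    admissions <- stage("load", read_cohort_csv(cfg$cohort_csv))
  } else {
    gen_cfg <- cfg$cohort
    if (is.null(gen_cfg)) gen_cfg <- cohort_config(seed = cfg$seed)
    if (!inherits(gen_cfg, "cohort_config")) {
      gen_cfg <- do.call(cohort_config, gen_cfg)
    }
    admissions <- stage("simulate", generate_cohort(gen_cfg))$admissions
  }
  periods <- stage("split", split_periods(admissions, cfg$training_end,
                                          min_coverage = cfg$min_coverage))

  results <- list()
  for (outcome in cfg$outcomes) {
    oc_seed <- child_seed(cfg$seed, match(outcome, c("mortality",
                                                     "readmission_7",
                                                     "readmission_30")))
    train <- build_outcome_cohort(periods$training, outcome,
                                  gap_hours = cfg$gap_hours)
    report <- build_outcome_cohort(periods$reporting, outcome,
                                   gap_hours = cfg$gap_hours)
    spec_base <- feature_spec(outcome, include_equity = FALSE)
    spec_eq <- feature_spec(outcome, include_equity = TRUE)

    fits <- stage(paste0(outcome, "_fit"), list(
      base = fit_risk_models(train$cohort, spec_base,
                             lambda_grid = cfg$lambda_grid,
                             min_events = cfg$min_events),
      equity = fit_risk_models(train$cohort, spec_eq,
                               lambda_grid = cfg$lambda_grid,
                               min_events = cfg$min_events)))

    eval_res <- stage(paste0(outcome, "_iecv"), list(
      base = iecv(train$cohort, spec_base, lambda_grid = cfg$lambda_grid,
                  min_events = cfg$min_events,
                  n_boot = cfg$n_boot_metrics, seed = oc_seed),
      equity = iecv(train$cohort, spec_eq, lambda_grid = cfg$lambda_grid,
                    min_events = cfg$min_events,
                    n_boot = cfg$n_boot_metrics,
                    seed = child_seed(oc_seed, 2L))))
    pooled <- list(base = pool_iecv(eval_res$base),
                   equity = pool_iecv(eval_res$equity))

    rep_cohort <- report$cohort
    p_base <- suppressMessages(predict(fits$base, rep_cohort))
    p_eq <- suppressMessages(predict(fits$equity, rep_cohort))
    profiles <- stage(paste0(outcome, "_standardize"), list(
      base = hospital_profile(p_base, rep_cohort$y, rep_cohort$hospital_id,
                              n_boot = cfg$n_boot_rsr, seed = oc_seed),
      equity = hospital_profile(p_eq, rep_cohort$y, rep_cohort$hospital_id,
                                n_boot = cfg$n_boot_rsr,
                                seed = oc_seed)))
    recl <- compare_classifications(profiles$base, profiles$equity)
    effects <- stage(paste0(outcome, "_equity"),
                     equity_profile_all(rep_cohort))
    heat <- heatmap_table(effects, recl$relative_change)

    results[[outcome]] <- list(
      exclusions = train$exclusions,
      metrics = eval_res, pooled = pooled,
      profile_base = profiles$base, profile_equity = profiles$equity,
      reclassification = recl, heatmap = heat)
  }

  manifest <- list(
    seed = cfg$seed,
    outcomes = cfg$outcomes,
    n_admissions = nrow(admissions),
    n_training = nrow(periods$training),
    n_reporting = nrow(periods$reporting),
    dropped_hospitals = periods$dropped_hospitals,
    n_boot_metrics = cfg$n_boot_metrics,
    n_boot_rsr = cfg$n_boot_rsr,
    timings = timings,
    total_seconds = round(as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")), 2))
  run <- structure(list(results = results, manifest = manifest),
                   class = "profile_run")
  if (!is.null(outdir)) write_run_artifacts(run, outdir)
  run
}

#' @export
print.profile_run <- function(x, ...) {
  cat(sprintf("Profiling run: %d admissions (%d training / %d reporting)\n",
              x$manifest$n_admissions, x$manifest$n_training,
              x$manifest$n_reporting))
  for (oc in names(x$results)) {
    r <- x$results[[oc]]
    cat(sprintf("  %s: %d hospitals profiled, %d reclassified after equity adjustment\n",
                oc, nrow(r$profile_base$rates),
                r$reclassification$n_reclassified))
  }
  invisible(x)
}

# write per-outcome CSV/JSON artifacts for a pipeline run
#' @noRd
write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (oc in names(run$results)) {
    r <- run$results[[oc]]
    utils::write.csv(rbind(cbind(variant = "base", r$metrics$base),
                           cbind(variant = "equity", r$metrics$equity)),
                     file.path(outdir, paste0(oc, "_metrics.csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(base = r$pooled$base, equity = r$pooled$equity),
                         file.path(outdir, paste0(oc, "_pooled.json")),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    utils::write.csv(r$profile_base$rates,
                     file.path(outdir, paste0(oc, "_caterpillar_base.csv")),
                     row.names = FALSE)
    utils::write.csv(r$profile_equity$rates,
                     file.path(outdir, paste0(oc, "_caterpillar_equity.csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(transition = as.data.frame(r$reclassification$transition),
           movers = r$reclassification$movers,
           relative_change = r$reclassification$relative_change),
      file.path(outdir, paste0(oc, "_reclassification.json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    hm <- as.data.frame(r$heatmap$matrix)
    hm <- cbind(hospital_id = rownames(r$heatmap$matrix),
                relative_change = r$heatmap$relative_change, hm)
    utils::write.csv(hm, file.path(outdir, paste0(oc, "_heatmap.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
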