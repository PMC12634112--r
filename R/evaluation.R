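#' Internal-external (leave-one-hospital-out) cross-validation
#'
#' For each hospital, fits the full risk-model pipeline on all other
#' hospitals' training data, predicts on the held-out hospital, and computes
#' the eight performance metrics with bootstrap standard errors. Hospitals
#' with fewer than `min_n` rows are skipped with a warning; metrics that are
#' undefined at a hospital (e.g., a single-class outcome) are returned as
#' `NA` and skipped at pooling time.
#'
#' @param cohort Analysis cohort with columns `y`, `hospital_id`, `dx_group`,
#'   and the covariates required by `spec`.
#' @param spec A [feature_spec()].
#' @param lambda_grid Penalty grid passed to [fit_risk_models()].
#' @param min_events Small-group pooling threshold.
#' @param n_boot Bootstrap iterations per hospital/metric.
#' @param seed Integer seed for the bootstrap.
#' @param min_n Minimum held-out hospital size.
#' @param span Calibration smoother span.
#' @return data.frame of class `iecv_metrics` with columns `hospital_id`,
#'   `metric`, `value`, `se`, `n`, `n_boot`.
#' @export
iecv <- function(cohort, spec, lambda_grid = default_lambda_grid(),
                 min_events = 200, n_boot = 1000, seed = 1L, min_n = 50,
                 span = 0.75) {
  stop_missing_cols(cohort, c("y", "hospital_id", "dx_group"), "cohort")
  hospitals <- sort(unique(cohort$hospital_id))
  if (length(hospitals) < 3) {
    stop("internal-external cross-validation needs at least 3 hospitals",
         call. = FALSE)
  }
  metric_fns <- list(
    auc = auc,
    brier_skill = function(p, y) brier_skill(p, y, mean(y)),
    calibration_slope = function(p, y) calibration_slope_intercept(p, y)[["slope"]],
    calibration_intercept = function(p, y) calibration_slope_intercept(p, y)[["intercept"]],
    nagelkerke_r2 = nagelkerke_r2,
    discrimination_slope = discrimination_slope,
    ici = function(p, y) ici_e95(p, y, span = span)[["ici"]],
    e95 = function(p, y) ici_e95(p, y, span = span)[["e95"]]
  )
  out <- list()
  folds <- list()
  for (h in hospitals) {
    held <- cohort[cohort$hospital_id == h, , drop = FALSE]
    if (nrow(held) < min_n) {
      warning(sprintf("hospital %s skipped: only %d rows", h, nrow(held)))
      next
    }
    train <- cohort[cohort$hospital_id != h, , drop = FALSE]
    models <- fit_risk_models(train, spec, lambda_grid = lambda_grid,
                              min_events = min_events)
    folds[[h]] <- list(training_hospitals = unique(train$hospital_id),
                       training_dx_groups = unique(train$dx_group),
                       model_groups = names(models$models))
    p <- suppressMessages(predict(models, held))
    vals <- performance_metrics(p, held$y, span = span)
    ses <- rep(NA_real_, length(vals))
    names(ses) <- names(vals)
    for (m in names(metric_fns)) {
      if (is.na(vals[[m]])) next
      ses[[m]] <- tryCatch(
        bootstrap_metric_se(p, held$y, metric_fns[[m]], n_boot = n_boot,
                            seed = child_seed(seed, match(h, hospitals)))$se,
        error = function(e) NA_real_)
    }
    out[[h]] <- data.frame(hospital_id = h, metric = names(vals),
                           value = unname(vals), se = unname(ses),
                           n = nrow(held), n_boot = n_boot,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "folds") <- folds
  class(res) <- c("iecv_metrics", class(res))
  res
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-hospital metric estimates: with fixed-effect weights
#' \eqn{w_i = 1/se_i^2}, heterogeneity
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))} from
#' Cochran's Q, random-effects weights \eqn{1/(se_i^2 + \tau^2)}, and a Wald
#' 95% interval. `method = "REML"` delegates to `metafor::rma` when that
#' package is available.
#'
#' @param values Per-hospital estimates.
#' @param ses Their standard errors (positive).
#' @param method `"DL"` (default) or `"REML"`.
#' @return List of class `pooled_metric`: `pooled`, `ci_low`, `ci_high`,
#'   `se`, `tau2`, `k`, `method`.
#' @export
pool_random_effects <- function(values, ses, method = c("DL", "REML")) {
  method <- match.arg(method)
  keep <- is.finite(values) & is.finite(ses) & ses > 0
  values <- values[keep]
  ses <- ses[keep]
  k <- length(values)
  if (k < 2) stop("meta-analysis needs at least 2 estimates", call. = FALSE)
  if (method == "REML") {
    if (!requireNamespace("metafor", quietly = TRUE)) {
      stop("method = 'REML' requires the metafor package", call. = FALSE)
    }
    fit <- metafor::rma(yi = values, sei = ses, method = "REML")
    out <- list(pooled = as.numeric(fit$beta), ci_low = fit$ci.lb,
                ci_high = fit$ci.ub, se = fit$se, tau2 = fit$tau2, k = k,
                method = "REML")
    class(out) <- "pooled_metric"
    return(out)
  }
  w <- 1 / ses^2
  theta_fe <- sum(w * values) / sum(w)
  q <- sum(w * (values - theta_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_re <- 1 / (ses^2 + tau2)
  pooled <- sum(w_re * values) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  out <- list(pooled = pooled,
              ci_low = pooled - stats::qnorm(0.975) * se,
              ci_high = pooled + stats::qnorm(0.975) * se,
              se = se, tau2 = tau2, k = k, method = "DL")
  class(out) <- "pooled_metric"
  out
}

#' @export
print.pooled_metric <- function(x, ...) {
  cat(sprintf("Pooled estimate (%s, k = %d): %.4f (95%% CI %.4f to %.4f), tau2 = %.5f\n",
              x$method, x$k, x$pooled, x$ci_low, x$ci_high, x$tau2))
  invisible(x)
}

#' Pool every metric of an IECV result table
#'
#' @param estimates An `iecv_metrics` data.frame from [iecv()].
#' @param method Meta-analysis estimator, see [pool_random_effects()].
#' @return data.frame with one row per metric: pooled estimate, 95% CI,
#'   tau-squared, number of hospitals pooled.
#' @export
pool_iecv <- function(estimates, method = "DL") {
  out <- list()
  for (m in unique(estimates$metric)) {
    sub <- estimates[estimates$metric == m, , drop = FALSE]
    pm <- tryCatch(pool_random_effects(sub$value, sub$se, method = method),
                   error = function(e) NULL)
    if (is.null(pm)) next
    out[[m]] <- data.frame(metric = m, pooled = pm$pooled,
                           ci_low = pm$ci_low, ci_high = pm$ci_high,
                           tau2 = pm$tau2, k = pm$k,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
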