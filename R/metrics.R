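#' Area under the ROC curve
#'
#' Probability that a randomly chosen event outranks a randomly chosen
#' non-event, with ties counting one half (the Mann-Whitney estimator).
#'
#' @param p Predicted probabilities (any monotone score works).
#' @param y Binary 0/1 outcomes; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(p, y) {
  y <- as.numeric(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: both outcome classes must be present", call. = FALSE)
  }
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier Skill Score against a constant reference rate
#'
#' `1 - BS(p, y) / BS(ref_rate, y)` with `BS` the mean squared error of the
#' probabilities. In held-out-hospital evaluation the reference is the
#' held-out hospital's own event rate.
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @param ref_rate Reference event rate in (0, 1).
#' @return Skill score (1 = perfect, 0 = no better than the reference).
#' @export
brier_skill <- function(p, y, ref_rate) {
  if (ref_rate <= 0 || ref_rate >= 1) {
    stop("ref_rate must lie strictly in (0, 1)", call. = FALSE)
  }
  y <- as.numeric(y)
  bs_ref <- mean((ref_rate - y)^2)
  if (bs_ref == 0) stop("degenerate reference: reference Brier score is 0",
                        call. = FALSE)
  1 - mean((p - y)^2) / bs_ref
}

#' Calibration slope and intercept
#'
#' Slope: coefficient of `logit(p)` in a logistic regression of `y` on
#' `logit(p)`. Intercept: the offset convention — intercept of a logistic
#' regression of `y` with `logit(p)` as an offset (slope fixed at 1).
#'
#' @param p Predicted probabilities (clipped away from 0/1 internally).
#' @param y Binary outcomes, both classes present.
#' @return Named vector `c(slope =, intercept =)`.
#' @export
calibration_slope_intercept <- function(p, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("calibration undefined for a single-class outcome", call. = FALSE)
  }
  lp <- logit(clip_prob(p))
  # extreme resampled logits can push fitted values to the boundary; the
  # coefficients remain well-defined, so the glm warnings are muted
  slope <- unname(stats::coef(suppressWarnings(
    stats::glm(y ~ lp, family = stats::binomial())))[2L])
  intercept <- unname(stats::coef(suppressWarnings(
    stats::glm(y ~ 1 + offset(lp), family = stats::binomial())))[1L])
  c(slope = slope, intercept = intercept)
}

#' Nagelkerke's R-squared for probability predictions
#'
#' `(1 - exp(2 (l0 - l1) / n)) / (1 - exp(2 l0 / n))` where `l1` is the
#' Bernoulli log-likelihood of the predictions and `l0` that of the constant
#' `mean(y)` model.
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @return R-squared in `[0, 1]` for calibrated predictions.
#' @export
nagelkerke_r2 <- function(p, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2) {
    stop("Nagelkerke R2 undefined for a single-class outcome", call. = FALSE)
  }
  n <- length(y)
  l1 <- bernoulli_loglik(p, y)
  l0 <- bernoulli_loglik(rep(mean(y), n), y)
  (1 - exp(2 * (l0 - l1) / n)) / (1 - exp(2 * l0 / n))
}

#' Discrimination slope
#'
#' Difference in mean predicted probability between events and non-events.
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes, both classes present.
#' @return `mean(p | y = 1) - mean(p | y = 0)`.
#' @export
discrimination_slope <- function(p, y) {
  y <- as.numeric(y)
  if (!any(y == 1) || !any(y == 0)) {
    stop("discrimination slope undefined: both classes must be present",
         call. = FALSE)
  }
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Smoothed calibration curve
#'
#' Local-linear smoother (lowess, default span 0.75) of the binary outcome
#' against the predicted probability, evaluated on a grid and clipped to
#' `[0, 1]`.
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes.
#' @param grid Evaluation points; default an equally spaced grid over the
#'   range of `p`.
#' @param span Smoother span.
#' @return data.frame with columns `p` (grid) and `observed` (smoothed rate).
#' @export
smoothed_calibration <- function(p, y, grid = NULL, span = 0.75) {
  if (length(p) < 50) {
    stop("smoothed calibration needs at least 50 observations", call. = FALSE)
  }
  if (is.null(grid)) grid <- seq(min(p), max(p), length.out = 101L)
  # iter = 0: robustness reweighting is inappropriate for 0/1 outcomes
  sm <- stats::lowess(p, as.numeric(y), f = span, iter = 0)
  obs <- stats::approx(sm$x, sm$y, xout = grid, rule = 2, ties = "ordered")$y
  data.frame(p = grid, observed = pmin(pmax(obs, 0), 1))
}

#' Integrated Calibration Index and E95
#'
#' Absolute vertical distances between the smoothed calibration curve and the
#' diagonal of perfect calibration, evaluated at each observation's predicted
#' value. ICI is their mean; E95 their 95th percentile.
#'
#' @inheritParams smoothed_calibration
#' @return Named vector `c(ici =, e95 =)`.
#' @export
ici_e95 <- function(p, y, span = 0.75) {
  curve <- smoothed_calibration(p, y, grid = sort(unique(p)), span = span)
  sm_at_p <- stats::approx(curve$p, curve$observed, xout = p, rule = 2,
                           ties = "ordered")$y
  d <- abs(sm_at_p - p)
  c(ici = mean(d), e95 = unname(stats::quantile(d, 0.95, type = 7)))
}

#' Bootstrap standard error of a performance metric
#'
#' Resamples (p, y) pairs with replacement and returns the standard deviation
#' of the metric over the resamples. Resamples on which the metric is
#' undefined (e.g., a single-class draw for AUC) are redrawn; if more than
#' half of the attempts are degenerate the SE is abandoned with an error.
#'
#' @param p,y Predictions and outcomes.
#' @param metric Function `(p, y) -> scalar`.
#' @param n_boot Number of bootstrap iterations (>= 2).
#' @param seed Integer seed.
#' @return List with `se`, `n_boot`, and `n_degenerate` (redrawn resamples).
#' @export
bootstrap_metric_se <- function(p, y, metric, n_boot = 1000, seed = 1L) {
  if (n_boot < 2) {
    stop("bootstrap SE undefined for n_boot < 2", call. = FALSE)
  }
  set.seed(child_seed(seed, 11L))
  n <- length(p)
  vals <- numeric(n_boot)
  degen <- 0L
  max_attempts <- 2L * n_boot
  b <- 0L
  attempts <- 0L
  while (b < n_boot && attempts < max_attempts) {
    attempts <- attempts + 1L
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(metric(p[idx], y[idx]), error = function(e) NA_real_)
    if (is.na(v) || !is.finite(v)) {
      degen <- degen + 1L
      next
    }
    b <- b + 1L
    vals[b] <- v
  }
  if (b < n_boot) {
    stop("more than half of bootstrap resamples were degenerate",
         call. = FALSE)
  }
  list(se = stats::sd(vals), n_boot = n_boot, n_degenerate = degen)
}

#' All eight held-out performance metrics for one hospital
#'
#' @param p,y Predictions and outcomes at the held-out hospital.
#' @param span Calibration smoother span.
#' @return Named numeric vector over `auc`, `brier_skill`,
#'   `calibration_slope`, `calibration_intercept`, `nagelkerke_r2`,
#'   `discrimination_slope`, `ici`, `e95`. Metrics undefined on the data
#'   (single-class outcome) are `NA`.
#' @export
performance_metrics <- function(p, y, span = 0.75) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  cal <- safe(calibration_slope_intercept(p, y))
  ie <- safe(ici_e95(p, y, span = span))
  c(auc = safe(auc(p, y)),
    brier_skill = safe(brier_skill(p, y, mean(y))),
    calibration_slope = if (length(cal) == 2) cal[["slope"]] else NA_real_,
    calibration_intercept = if (length(cal) == 2) cal[["intercept"]] else NA_real_,
    nagelkerke_r2 = safe(nagelkerke_r2(p, y)),
    discrimination_slope = safe(discrimination_slope(p, y)),
    ici = if (length(ie) == 2) ie[["ici"]] else NA_real_,
    e95 = if (length(ie) == 2) ie[["e95"]] else NA_real_)
}
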