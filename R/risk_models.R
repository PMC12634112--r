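#' Feature specification for a risk-adjustment model
#'
#' Describes the design of the diagnosis-group-specific logistic models:
#' age as a 4-knot restricted cubic spline, sex, admission urgency, Charlson
#' comorbidity category (0/1/2+), mLAPS as a continuous linear term,
#' restricted two-way interactions between age, Charlson, and mLAPS (linear
#' age component only), the number of discharges in the prior 6 months
#' (readmission outcomes only), and optionally the six equity-related
#' factors: homelessness, disability, and the four continuous neighborhood
#' marginalization dimensions. Expanded (equity) specs contain all base-spec
#' columns plus exactly those six.
#'
#' @param outcome One of `"mortality"`, `"readmission_7"`, `"readmission_30"`.
#' @param include_equity Add the six equity-related columns?
#' @param knots Age spline knots (4 ascending values) or `NULL` to compute
#'   Harrell-default quantiles (0.05, 0.35, 0.65, 0.95) from training data at
#'   fit time.
#' @param interactions Which restricted interactions to include; default all
#'   of age:Charlson, age:mLAPS, Charlson:mLAPS.
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(outcome, include_equity = FALSE, knots = NULL,
                         interactions = c("age:charlson", "age:mlaps",
                                          "charlson:mlaps")) {
  outcome <- match.arg(outcome, c("mortality", "readmission_7",
                                  "readmission_30"))
  interactions <- match.arg(interactions, several.ok = TRUE,
                            choices = c("age:charlson", "age:mlaps",
                                        "charlson:mlaps"))
  structure(list(outcome = outcome,
                 include_equity = isTRUE(include_equity),
                 knots = knots,
                 interactions = interactions),
            class = "feature_spec")
}

#' @noRd
equity_feature_names <- function() {
  c("homelessness", "disability", "onmarg_housing",
    "onmarg_racialized_newcomer", "onmarg_material", "onmarg_age_labor")
}

#' Build the design matrix for a feature specification
#'
#' Columns, in deterministic order: intercept; age spline basis (linear + 2
#' nonlinear); male; urgent; Charlson 1 and 2+ dummies; mLAPS; prior
#' discharge dummies (readmission outcomes); interaction columns; equity
#' columns when requested.
#'
#' @param table Cohort data.frame.
#' @param spec A [feature_spec()]; `spec$knots` must be set (fitting
#'   functions fill them in from the training data).
#' @return Numeric matrix with named columns.
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  needed <- c("age", "sex", "admission_category", "charlson", "mlaps")
  if (spec$outcome != "mortality") needed <- c(needed, "prior_discharges_6mo")
  if (spec$include_equity) needed <- c(needed, equity_feature_names())
  stop_missing_cols(table, needed, "cohort table")
  if (is.null(spec$knots)) {
    stop("feature_spec knots are unset; fit models first or supply knots",
         call. = FALSE)
  }
  age_b <- rcs_basis(table$age, spec$knots)
  ch1 <- as.numeric(table$charlson == "1")
  ch2 <- as.numeric(table$charlson == "2+")
  mlaps <- as.numeric(table$mlaps)
  X <- cbind(
    intercept = 1,
    age_lin = age_b[, "lin"], age_nl1 = age_b[, "nl1"],
    age_nl2 = age_b[, "nl2"],
    male = as.numeric(table$sex == "male"),
    urgent = as.numeric(table$admission_category == "urgent"),
    charlson_1 = ch1, charlson_2p = ch2,
    mlaps = mlaps
  )
  if (spec$outcome != "mortality") {
    X <- cbind(X,
               prior_1 = as.numeric(table$prior_discharges_6mo == "1"),
               prior_2p = as.numeric(table$prior_discharges_6mo == "2+"))
  }
  # restricted interactions: products with the linear age component only
  if ("age:charlson" %in% spec$interactions) {
    X <- cbind(X, age_x_charlson_1 = table$age * ch1,
               age_x_charlson_2p = table$age * ch2)
  }
  if ("age:mlaps" %in% spec$interactions) {
    X <- cbind(X, age_x_mlaps = table$age * mlaps)
  }
  if ("charlson:mlaps" %in% spec$interactions) {
    X <- cbind(X, charlson_1_x_mlaps = ch1 * mlaps,
               charlson_2p_x_mlaps = ch2 * mlaps)
  }
  if (spec$include_equity) {
    X <- cbind(X,
               homelessness = as.numeric(table$homelessness),
               disability = as.numeric(table$disability),
               onmarg_housing = as.numeric(table$onmarg_housing),
               onmarg_racialized_newcomer =
                 as.numeric(table$onmarg_racialized_newcomer),
               onmarg_material = as.numeric(table$onmarg_material),
               onmarg_age_labor = as.numeric(table$onmarg_age_labor))
  }
  rownames(X) <- NULL
  X
}

#' Pool small diagnosis groups by observed event rate
#'
#' Diagnosis groups with fewer than `min_events` outcome events map to one of
#' three "other" pools assigned by tertile of the group's observed event rate
#' in the training data; groups with at least `min_events` events (the bound
#' is strict: exactly `min_events` stays unpooled) map to themselves.
#'
#' @param table Training cohort with columns `dx_group` and `y`.
#' @param min_events Minimum event count for a group to stand alone.
#' @return data.frame `group_map` with columns `dx_group`, `model_group`,
#'   `events`, `event_rate`.
#' @export
pool_small_groups <- function(table, min_events = 200) {
  stop_missing_cols(table, c("dx_group", "y"), "training table")
  ev <- tapply(table$y, table$dx_group, sum)
  n <- tapply(rep(1L, nrow(table)), table$dx_group, sum)
  gm <- data.frame(dx_group = names(ev),
                   events = as.integer(ev),
                   event_rate = as.numeric(ev / n),
                   stringsAsFactors = FALSE)
  gm$model_group <- gm$dx_group
  small <- gm$events < min_events
  if (any(small)) {
    rates <- gm$event_rate[small]
    # tertiles of the small groups' observed event rates
    r <- rank(rates, ties.method = "first")
    tert <- ceiling(3 * r / length(r))
    gm$model_group[small] <- c("other_low", "other_mid", "other_high")[tert]
  }
  gm[, c("dx_group", "model_group", "events", "event_rate")]
}

#' Fit an L2-penalized logistic regression by IRLS
#'
#' Maximizes the Bernoulli log-likelihood minus `lambda/2` times the sum of
#' squared standardized non-intercept coefficients. Non-intercept columns are
#' centered and scaled to unit variance internally so the penalty is
#' scale-free; returned coefficients are on the original scale. The intercept
#' is never penalized. Iteratively reweighted least squares with the ridge
#' term in the normal equations; step-halving guards the penalized
#' log-likelihood.
#'
#' @param X Design matrix whose first column is the intercept.
#' @param y Binary 0/1 response.
#' @param lambda Penalty, `>= 0`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   gradient max-norm.
#' @return List with `coefficients` (original scale), `lambda`,
#'   `loglik` (unpenalized, at the penalized estimate), `df` (effective
#'   degrees of freedom, trace of the ridge hat-type matrix), `iter`,
#'   `converged`.
#' @export
fit_penalized_logistic <- function(X, y, lambda = 0, max_iter = 50,
                                   tol = 1e-9) {
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  # standardize non-intercept columns (constant columns left untouched)
  ctr <- c(0, colMeans(X[, -1L, drop = FALSE]))
  scl <- c(1, apply(X[, -1L, drop = FALSE], 2, stats::sd))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  pen <- c(0, rep(lambda, p - 1L))

  beta <- numeric(p)
  beta[1L] <- logit(clip_prob(mean(y), 1e-6))
  pll <- function(b) {
    eta <- drop(Z %*% b)
    bernoulli_loglik(expit(eta), y) - sum(pen * b^2) / 2
  }
  obj <- pll(beta)
  converged <- FALSE
  grad_norm <- Inf
  it <- 0L
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Z, y - mu)) - pen * beta
    grad_norm <- max(abs(grad))
    if (grad_norm < tol) {
      converged <- TRUE
      break
    }
    XtWX <- crossprod(Z * sqrt(w))
    H <- XtWX
    diag(H) <- diag(H) + pen
    delta <- tryCatch(solve(H, grad), error = function(e) {
      solve(H + diag(1e-8, p), grad)
    })
    step <- 1
    repeat {
      cand <- beta + step * delta
      val <- pll(cand)
      if (is.finite(val) && val >= obj - 1e-12) {
        beta <- cand
        obj <- val
        break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  if (!converged && grad_norm >= sqrt(tol)) {
    cond <- simpleError(sprintf(
      "penalized IRLS did not converge in %d iterations (gradient max-norm %.3e)",
      max_iter, grad_norm))
    cond$last_coefficients <- beta / scl
    cond$gradient_norm <- grad_norm
    stop(cond)
  }
  # effective df: tr[ I (I + P)^{-1} ] with I the unpenalized information
  eta <- drop(Z %*% beta)
  mu <- expit(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(Z * sqrt(w))
  Hp <- XtWX
  diag(Hp) <- diag(Hp) + pen
  df_eff <- sum(diag(solve(Hp, XtWX)))
  # back-transform to the original covariate scale
  coef_orig <- beta / scl
  coef_orig[1L] <- beta[1L] - sum((beta[-1L] / scl[-1L]) * ctr[-1L])
  names(coef_orig) <- colnames(X)
  list(coefficients = coef_orig, lambda = lambda,
       loglik = bernoulli_loglik(mu, y), df = df_eff,
       iter = it, converged = TRUE)
}

#' Select the L2 penalty by corrected AIC
#'
#' Fits the penalized model over a grid of penalties and picks the one
#' maximizing the corrected AIC criterion
#' \eqn{2\ell(\hat\beta_\lambda) - 2\,df(\lambda) -
#'      2\,df(df+1)/(n - df - 1)},
#' where \eqn{\ell} is the unpenalized log-likelihood at the penalized
#' estimate and \eqn{df(\lambda)} the effective degrees of freedom (trace of
#' the unpenalized information times the inverse penalized information).
#' Ties go to the smallest penalty; grid values with \eqn{n \le df + 1} are
#' skipped with a warning.
#'
#' @param X,y Design matrix and binary response.
#' @param lambda_grid Non-empty vector of non-negative penalties.
#' @return List with `lambda` (the selected value), `trace` (data.frame of
#'   lambda, df, loglik, aicc), and `fit` (the winning
#'   [fit_penalized_logistic()] result).
#' @export
select_penalty_aicc <- function(X, y, lambda_grid = default_lambda_grid()) {
  if (!length(lambda_grid) || any(lambda_grid < 0)) {
    stop("lambda_grid must be non-empty and non-negative", call. = FALSE)
  }
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  n <- nrow(X)
  rows <- vector("list", length(lambda_grid))
  fits <- vector("list", length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    lam <- lambda_grid[i]
    fit <- tryCatch(fit_penalized_logistic(X, y, lam),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (n <= fit$df + 1) {
      warning(sprintf("lambda = %g skipped: n <= df + 1", lam))
      next
    }
    aicc <- 2 * fit$loglik - 2 * fit$df -
      2 * fit$df * (fit$df + 1) / (n - fit$df - 1)
    rows[[i]] <- data.frame(lambda = lam, df = fit$df, loglik = fit$loglik,
                            aicc = aicc)
    fits[[i]] <- fit
  }
  trace <- do.call(rbind, rows)
  if (is.null(trace) || nrow(trace) == 0) {
    stop("no penalty in the grid produced a valid fit", call. = FALSE)
  }
  best <- which(trace$aicc == max(trace$aicc))[1L]  # ties -> smallest lambda
  keep <- which(!vapply(fits, is.null, logical(1)))
  list(lambda = trace$lambda[best], trace = trace,
       fit = fits[keep][[best]])
}

#' @noRd
default_lambda_grid <- function() c(0, 2^(0:10))

#' Fit the per-diagnosis-group risk-adjustment model set
#'
#' Pools small diagnosis groups ([pool_small_groups()]), places age spline
#' knots at the Harrell-default quantiles within each model group, selects
#' each group's L2 penalty by corrected AIC ([select_penalty_aicc()]), and
#' fits the penalized logistic model ([fit_penalized_logistic()]).
#'
#' @param table Training cohort with outcome column `y`, `dx_group`, and the
#'   covariates required by the spec.
#' @param spec A [feature_spec()].
#' @param lambda_grid Penalty grid.
#' @param min_events Pooling threshold, see [pool_small_groups()].
#' @return Object of class `risk_model_set`: `group_map`, per-model-group
#'   fits (coefficients, knots, lambda, event counts), the spec, and the
#'   global training event rate.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(n_hospitals = 6,
#'   admissions_per_hospital = c(300, 400), n_dx_groups = 3, seed = 2))
#' mort <- build_outcome_cohort(coh$admissions, "mortality")
#' ms <- fit_risk_models(mort$cohort, feature_spec("mortality"),
#'                       lambda_grid = c(0, 4, 64))
#' summary(predict(ms, mort$cohort))
#' }
#' @export
fit_risk_models <- function(table, spec, lambda_grid = default_lambda_grid(),
                            min_events = 200) {
  stopifnot(inherits(spec, "feature_spec"))
  stop_missing_cols(table, c("dx_group", "y"), "training table")
  gmap <- pool_small_groups(table, min_events = min_events)
  mg <- gmap$model_group[match(table$dx_group, gmap$dx_group)]
  models <- list()
  for (g in unique(gmap$model_group)) {
    rows <- which(mg == g)
    sub <- table[rows, , drop = FALSE]
    g_spec <- spec
    g_spec$knots <- rcs_default_knots(sub$age)
    X <- build_design(sub, g_spec)
    sel <- select_penalty_aicc(X, sub$y, lambda_grid)
    models[[g]] <- list(coefficients = sel$fit$coefficients,
                        knots = g_spec$knots,
                        lambda = sel$lambda,
                        df = sel$fit$df,
                        n = nrow(sub),
                        events = sum(sub$y),
                        event_rate = mean(sub$y),
                        aicc_trace = sel$trace)
  }
  structure(list(group_map = gmap, models = models, spec = spec,
                 global_event_rate = mean(table$y)),
            class = "risk_model_set")
}

#' @export
print.risk_model_set <- function(x, ...) {
  cat(sprintf("Risk model set: %s%s\n", x$spec$outcome,
              if (x$spec$include_equity) " (equity-expanded)" else " (base)"))
  cat(sprintf("  %d diagnosis groups -> %d model groups; training event rate %.3f\n",
              nrow(x$group_map), length(x$models), x$global_event_rate))
  lams <- vapply(x$models, `[[`, numeric(1), "lambda")
  cat("  selected penalties: ",
      paste(sprintf("%s=%g", names(lams), lams), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.risk_model_set <- function(object, ...) {
  lapply(object$models, `[[`, "coefficients")
}

#' Predict event probabilities from a risk model set
#'
#' Each record is scored by the model of its diagnosis group's model group.
#' A diagnosis group unseen in training is assigned to the "other" pool whose
#' training event rate is nearest the global training event rate (with a
#' message); if no pool exists, prediction fails.
#'
#' @param object A `risk_model_set`.
#' @param newdata Cohort data.frame.
#' @param ... Unused.
#' @return Probability vector in (0, 1), in row order of `newdata`.
#' @export
predict.risk_model_set <- function(object, newdata, ...) {
  stop_missing_cols(newdata, "dx_group", "newdata")
  mg <- object$group_map$model_group[
    match(newdata$dx_group, object$group_map$dx_group)]
  if (anyNA(mg)) {
    pools <- grep("^other_", unique(object$group_map$model_group),
                  value = TRUE)
    if (!length(pools)) {
      stop("records from diagnosis groups unseen in training and no 'other' pool to fall back on",
           call. = FALSE)
    }
    rates <- vapply(object$models[pools], `[[`, numeric(1), "event_rate")
    fallback <- pools[which.min(abs(rates - object$global_event_rate))]
    message(sprintf(
      "%d records from unseen diagnosis groups assigned to '%s'",
      sum(is.na(mg)), fallback))
    mg[is.na(mg)] <- fallback
  }
  p <- numeric(nrow(newdata))
  for (g in unique(mg)) {
    m <- object$models[[g]]
    if (is.null(m)) {
      stop(sprintf("no fitted model for model group '%s'", g), call. = FALSE)
    }
    rows <- which(mg == g)
    g_spec <- object$spec
    g_spec$knots <- m$knots
    X <- build_design(newdata[rows, , drop = FALSE], g_spec)
    p[rows] <- expit(drop(X %*% m$coefficients))
  }
  clip_prob(p)
}
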