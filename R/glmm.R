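# Gauss-Hermite nodes/weights (weight function exp(-z^2)) via Golub-Welsch.
#' @noRd
gauss_hermite <- function(q) {
  if (q == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(q - 1L)
  J <- matrix(0, q, q)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# log(1 + exp(x)) without overflow
#' @noRd
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Random-intercept logistic regression via adaptive Gauss-Hermite quadrature
#'
#' Fits the mixed-effects logistic model
#' \deqn{\mathrm{logit}\,P(y_i = 1) = a + b\,x_i + u_{h(i)},\qquad
#'       u_h \sim N(0, \sigma^2),}
#' the model used to risk-standardize hospital outcome rates: `x` is the
#' logit of the risk-adjustment probability (a single fixed-effect
#' covariate) and `u` the hospital random intercept. The marginal likelihood
#' is maximized with adaptive Gauss-Hermite quadrature (posterior mode and
#' curvature found per hospital by vectorized Newton steps; `quad_points = 1`
#' is the Laplace approximation). Empirical Bayes intercepts are the
#' posterior modes at the optimum.
#'
#' @param x Fixed-effect covariate (finite; typically `logit(p_risk)`).
#' @param y Binary 0/1 outcome.
#' @param hospital Cluster labels.
#' @param quad_points Number of quadrature nodes (>= 1; default 10).
#' @param start Optional starting values `c(intercept, slope, sigma)`.
#' @param control List: `sigma_min` (lower box bound, default 1e-6),
#'   `rel_tol` (default 1e-10), `max_iter` (default 200).
#' @return Object of class `ri_glmm`: `coefficients` (intercept, slope),
#'   `sigma_u`, `hospital_intercepts` (empirical Bayes, named),
#'   `loglik`, `boundary` (TRUE when the variance estimate collapsed to the
#'   lower bound), `convergence`, `quad_points`, `n`, `k`.
#' @export
fit_random_intercept_glmm <- function(x, y, hospital, quad_points = 10L,
                                      start = NULL, control = list()) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  hosp <- factor(hospital)
  k <- nlevels(hosp)
  if (k < 2) stop("at least 2 hospitals are required", call. = FALSE)
  hidx <- as.integer(hosp)
  n <- length(y)
  ctrl <- utils::modifyList(list(sigma_min = 1e-6, rel_tol = 1e-8,
                                 max_iter = 200L), control)
  gh <- gauss_hermite(as.integer(quad_points))

  # dense cluster indicator: per-hospital sums via BLAS crossprod
  M <- matrix(0, n, k)
  M[cbind(seq_len(n), hidx)] <- 1
  agg <- function(v) drop(crossprod(M, v))
  ones <- rep(1, n)

  # posterior modes of u given theta, by vectorized Newton iterations
  find_modes <- function(a, b, sigma, u0) {
    u <- u0
    fixed <- a + b * x
    for (it in 1:30) {
      eta <- fixed + u[hidx]
      mu <- expit(eta)
      g <- agg(y - mu) - u / sigma^2
      h <- agg(mu * (1 - mu)) + 1 / sigma^2
      delta <- g / h
      # dampen huge first steps
      delta <- pmin(pmax(delta, -4), 4)
      u <- u + delta
      if (max(abs(delta)) < 1e-10) break
    }
    eta <- fixed + u[hidx]
    mu <- expit(eta)
    list(u = u, curv = agg(mu * (1 - mu)) + 1 / sigma^2)
  }

  u_env <- new.env(parent = emptyenv())
  u_env$u <- numeric(k)

  nq <- length(gh$nodes)
  marginal_loglik <- function(par) {
    a <- par[1L]; b <- par[2L]; sigma <- par[3L]
    md <- find_modes(a, b, sigma, u_env$u)
    u_env$u <- md$u
    tau <- 1 / sqrt(md$curv)
    fixed <- a + b * x
    # adaptive nodes per hospital (k x Q), evaluated in one pass
    uq <- md$u + sqrt(2) * outer(tau, gh$nodes)
    eta <- fixed + uq[hidx, , drop = FALSE]
    ll_h <- crossprod(M, y * eta - softplus(eta))
    terms <- log(sqrt(2) * outer(tau, gh$weights)) +
      rep(gh$nodes^2, each = k) + ll_h - uq^2 / (2 * sigma^2) -
      log(sigma * sqrt(2 * pi))
    m <- terms[cbind(seq_len(k), max.col(terms, ties.method = "first"))]
    sum(m + log(rowSums(exp(terms - m))))
  }

  if (is.null(start)) {
    g0 <- stats::glm.fit(cbind(ones, x), y, family = stats::binomial())
    start <- c(g0$coefficients, 0.2)
  }
  start[3L] <- max(start[3L], ctrl$sigma_min * 2)
  opt <- stats::nlminb(start, function(par) -marginal_loglik(par),
                       lower = c(-Inf, -Inf, ctrl$sigma_min),
                       control = list(iter.max = ctrl$max_iter,
                                      rel.tol = ctrl$rel_tol))
  if (!opt$convergence %in% c(0L, 1L)) {
    stop(sprintf("GLMM optimizer failed (code %d): %s", opt$convergence,
                 opt$message), call. = FALSE)
  }
  a <- unname(opt$par[1L]); b <- unname(opt$par[2L])
  sigma <- unname(opt$par[3L])
  md <- find_modes(a, b, sigma, u_env$u)
  boundary <- sigma <= ctrl$sigma_min * 1.0001
  u_hat <- md$u
  if (boundary) u_hat[] <- 0  # sigma = 0: all intercepts are exactly 0
  names(u_hat) <- levels(hosp)
  structure(list(coefficients = c(intercept = a, slope = b),
                 sigma_u = if (boundary) 0 else sigma,
                 hospital_intercepts = u_hat,
                 loglik = -opt$objective,
                 boundary = boundary,
                 convergence = opt$convergence,
                 message = opt$message,
                 quad_points = as.integer(quad_points),
                 n = n, k = k),
            class = "ri_glmm")
}

#' @export
print.ri_glmm <- function(x, ...) {
  cat(sprintf(
    "Random-intercept logistic model (adaptive GHQ, %d nodes)\n", x$quad_points))
  cat(sprintf("  n = %d admissions, k = %d hospitals\n", x$n, x$k))
  cat(sprintf("  intercept %.4f, slope %.4f, sigma_u %.4f%s\n",
              x$coefficients[["intercept"]], x$coefficients[["slope"]],
              x$sigma_u, if (x$boundary) " (boundary)" else ""))
  cat(sprintf("  log-likelihood %.3f\n", x$loglik))
  invisible(x)
}

#' @export
coef.ri_glmm <- function(object, ...) {
  c(object$coefficients, sigma_u = object$sigma_u)
}

#' Predicted probabilities from a fitted random-intercept model
#'
#' @param object An `ri_glmm` fit.
#' @param x Covariate values (logit of risk-model probability).
#' @param hospital Hospital labels (used for `type = "conditional"`).
#' @param type `"conditional"` includes the empirical Bayes hospital
#'   intercept; `"typical"` sets it to zero.
#' @param ... Unused.
#' @return Probability vector.
#' @export
predict.ri_glmm <- function(object, x, hospital = NULL,
                            type = c("conditional", "typical"), ...) {
  type <- match.arg(type)
  eta <- object$coefficients[["intercept"]] +
    object$coefficients[["slope"]] * as.numeric(x)
  if (type == "conditional") {
    if (is.null(hospital)) stop("hospital labels required", call. = FALSE)
    u <- object$hospital_intercepts[as.character(hospital)]
    u[is.na(u)] <- 0
    eta <- eta + u
  }
  unname(expit(eta))
}

#' Risk-standardized outcome rates per hospital
#'
#' For each hospital, the predicted event count is the sum of model
#' probabilities including the hospital's own random intercept; the expected
#' count is the sum for a "typical" hospital (random intercept zero) over the
#' same admissions. The risk-standardized rate is their ratio times the crude
#' event rate of the cohort.
#'
#' @param fit An `ri_glmm` fit.
#' @param x Logit of the risk-model probability, per admission.
#' @param hospital Hospital label per admission.
#' @param crude_rate Cohort-wide crude event rate.
#' @return data.frame: `hospital_id`, `n`, `predicted`, `expected`, `rsr`.
#' @export
risk_standardized_rates <- function(fit, x, hospital, crude_rate) {
  stopifnot(inherits(fit, "ri_glmm"))
  hosp <- factor(hospital)
  p_cond <- predict(fit, x, hospital, type = "conditional")
  p_typ <- predict(fit, x, type = "typical")
  predicted <- drop(rowsum(p_cond, hosp))
  expected <- drop(rowsum(p_typ, hosp))
  if (any(expected == 0)) {
    stop("expected event count is zero for some hospital", call. = FALSE)
  }
  data.frame(hospital_id = levels(hosp),
             n = as.integer(table(hosp)),
             predicted = predicted,
             expected = expected,
             rsr = predicted / expected * crude_rate,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cluster-bootstrap intervals for risk-standardized rates
#'
#' Hospitals are fixed entities; admissions are resampled with replacement
#' within each hospital, holding every hospital's sample size at its
#' observed value. The mixed model is refit and the risk-standardized rates
#' recomputed on each replicate (the risk-model probabilities are fixed
#' inputs; risk models are not refit); the interval is the 2.5th/97.5th
#' percentile across replicates. Replicates on which the model fails to
#' converge are dropped and redrawn; more than 5% failures is an error.
#'
#' @param x,y,hospital Logit risk probabilities, outcomes, hospital labels.
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed.
#' @param quad_points Quadrature nodes for the replicate fits.
#' @param start Optional warm-start parameters (defaults to the full-data
#'   fit's estimates).
#' @return List: `ci` (data.frame hospital_id, ci_low, ci_high), `n_failed`,
#'   `replicates` (matrix of per-replicate rates, hospitals in columns).
#' @export
cluster_bootstrap_ci <- function(x, y, hospital, n_boot = 1000, seed = 1L,
                                 quad_points = 10L, start = NULL) {
  hosp <- factor(hospital)
  idx_by_h <- split(seq_along(y), hosp)
  if (any(lengths(idx_by_h) < 2)) {
    stop("each hospital needs at least 2 admissions", call. = FALSE)
  }
  k <- nlevels(hosp)
  set.seed(child_seed(seed, 211L))
  reps <- matrix(NA_real_, n_boot, k, dimnames = list(NULL, levels(hosp)))
  failed <- 0L
  max_failed <- ceiling(0.05 * n_boot)
  b <- 1L
  while (b <= n_boot) {
    idx <- unlist(lapply(idx_by_h, function(i) {
      i[sample.int(length(i), length(i), replace = TRUE)]
    }), use.names = FALSE)
    res <- tryCatch({
      fit_b <- fit_random_intercept_glmm(x[idx], y[idx], hosp[idx],
                                         quad_points = quad_points,
                                         start = start)
      rr <- risk_standardized_rates(fit_b, x[idx], hosp[idx],
                                    crude_rate = mean(y[idx]))
      rr$rsr[match(levels(hosp), rr$hospital_id)]
    }, error = function(e) NULL)
    if (is.null(res)) {
      failed <- failed + 1L
      if (failed > max_failed) {
        stop("more than 5% of bootstrap replicates failed to converge",
             call. = FALSE)
      }
      next
    }
    reps[b, ] <- res
    b <- b + 1L
  }
  ci <- data.frame(
    hospital_id = levels(hosp),
    ci_low = apply(reps, 2L, stats::quantile, probs = 0.025, type = 7),
    ci_high = apply(reps, 2L, stats::quantile, probs = 0.975, type = 7),
    stringsAsFactors = FALSE, row.names = NULL)
  list(ci = ci, n_failed = failed, replicates = reps)
}

#' Classify hospitals against the crude rate
#'
#' A hospital is below average when the upper bound of its 95% interval lies
#' strictly below the crude event rate, above average when the lower bound
#' lies strictly above it, and average otherwise (an endpoint exactly equal
#' to the crude rate counts as crossing).
#'
#' @param rates data.frame with `ci_low` and `ci_high` columns.
#' @param crude_rate Crude event rate.
#' @return Character vector over `below_average`, `average`, `above_average`.
#' @export
classify_hospitals <- function(rates, crude_rate) {
  stop_missing_cols(rates, c("ci_low", "ci_high"), "rates table")
  ifelse(rates$ci_high < crude_rate, "below_average",
         ifelse(rates$ci_low > crude_rate, "above_average", "average"))
}

#' Profile hospitals by risk-standardized outcome rates
#'
#' The package's central fitting function. Takes risk-adjusted event
#' probabilities for a reporting-period cohort, fits the random-intercept
#' logistic model ([fit_random_intercept_glmm()]), computes each hospital's
#' risk-standardized rate ([risk_standardized_rates()]), attaches
#' cluster-bootstrap 95% intervals ([cluster_bootstrap_ci()]), and classifies
#' hospitals as below-average, average, or above-average relative to the
#' crude rate.
#'
#' @param p Risk-model event probabilities (one per admission).
#' @param y Binary observed outcomes.
#' @param hospital Hospital labels.
#' @param n_boot Bootstrap iterations (0 skips the bootstrap; classifications
#'   are then `NA`).
#' @param seed Integer seed.
#' @param quad_points Quadrature nodes.
#' @return Object of class `hospital_profile`: `rates` (per-hospital table
#'   with intervals and classification), `glmm`, `crude_rate`, `n_boot`,
#'   `bootstrap_failures`.
#' @examples
#' \donttest{
#' set.seed(1)
#' n <- 4000; hosp <- rep(sprintf("H%02d", 1:8), each = n / 8)
#' p <- expit(rnorm(n, -2.5, 1))
#' y <- rbinom(n, 1, p)
#' prof <- hospital_profile(p, y, hosp, n_boot = 50, seed = 1)
#' print(prof)
#' }
#' @export
hospital_profile <- function(p, y, hospital, n_boot = 1000, seed = 1L,
                             quad_points = 10L) {
  x <- logit(clip_prob(as.numeric(p)))
  y <- as.numeric(y)
  crude <- mean(y)
  fit <- fit_random_intercept_glmm(x, y, hospital, quad_points = quad_points)
  rates <- risk_standardized_rates(fit, x, hospital, crude)
  failures <- 0L
  if (n_boot > 0) {
    bs <- cluster_bootstrap_ci(x, y, hospital, n_boot = n_boot, seed = seed,
                               quad_points = quad_points,
                               start = c(fit$coefficients,
                                         max(fit$sigma_u, 0.05)))
    rates <- merge(rates, bs$ci, by = "hospital_id", sort = TRUE)
    rates$classification <- classify_hospitals(rates, crude)
    failures <- bs$n_failed
  } else {
    rates$ci_low <- rates$ci_high <- NA_real_
    rates$classification <- NA_character_
  }
  structure(list(rates = rates, glmm = fit, crude_rate = crude,
                 n_boot = n_boot, seed = seed,
                 bootstrap_failures = failures),
            class = "hospital_profile")
}

#' @export
print.hospital_profile <- function(x, ...) {
  cat(sprintf(
    "Hospital profile: %d hospitals, crude rate %.4f, sigma_u %.3f\n",
    nrow(x$rates), x$crude_rate, x$glmm$sigma_u))
  if (x$n_boot > 0) {
    cat(sprintf("  bootstrap n = %d; classification: %s\n", x$n_boot,
                paste(sprintf("%s %d", names(table(x$rates$classification)),
                              table(x$rates$classification)),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.hospital_profile <- function(object, ...) {
  out <- object$rates
  out$rsr_ratio <- out$rsr / object$crude_rate
  out <- out[order(out$rsr), ]
  rownames(out) <- NULL
  structure(list(rates = out, crude_rate = object$crude_rate,
                 sigma_u = object$glmm$sigma_u, n_boot = object$n_boot),
            class = "summary.hospital_profile")
}

#' @export
print.summary.hospital_profile <- function(x, ...) {
  cat(sprintf("Risk-standardized rates (crude rate %.4f, sigma_u %.3f)\n",
              x$crude_rate, x$sigma_u))
  print(x$rates, digits = 4)
  invisible(x)
}

#' @export
coef.hospital_profile <- function(object, ...) coef(object$glmm)

#' Caterpillar plot of risk-standardized rates
#'
#' Hospitals ordered by point estimate with 95% interval bars and a
#' horizontal line at the crude rate.
#'
#' @param x A `hospital_profile`.
#' @param ... Passed to `plot()`.
#' @export
plot.hospital_profile <- function(x, ...) {
  r <- x$rates[order(x$rates$rsr), ]
  k <- nrow(r)
  ylim <- range(c(r$ci_low, r$ci_high, r$rsr, x$crude_rate), na.rm = TRUE)
  graphics::plot(seq_len(k), r$rsr, pch = 19, ylim = ylim,
                 xlab = "Hospital (ordered)",
                 ylab = "Risk-standardized rate", xaxt = "n", ...)
  graphics::axis(1, at = seq_len(k), labels = r$hospital_id, las = 2,
                 cex.axis = 0.7)
  if (!all(is.na(r$ci_low))) {
    graphics::segments(seq_len(k), r$ci_low, seq_len(k), r$ci_high)
  }
  graphics::abline(h = x$crude_rate, lty = 2)
  invisible(x)
}

#' Compare hospital classifications between two adjustment models
#'
#' Builds the 3x3 transition matrix between base and expanded (equity)
#' classifications, lists reclassified hospitals with direction, and reports
#' each hospital's relative change in risk-standardized rate,
#' `(rsr_expanded - rsr_base) / rsr_base`.
#'
#' @param base,expanded `hospital_profile` objects (or their `rates` tables
#'   with `hospital_id`, `rsr`, `classification`) over the same hospitals.
#' @return List of class `reclassification`: `transition` (3x3 matrix),
#'   `movers` (data.frame), `relative_change` (data.frame).
#' @export
compare_classifications <- function(base, expanded) {
  rb <- if (inherits(base, "hospital_profile")) base$rates else base
  re <- if (inherits(expanded, "hospital_profile")) expanded$rates else expanded
  if (!setequal(rb$hospital_id, re$hospital_id)) {
    stop("base and expanded profiles cover different hospitals",
         call. = FALSE)
  }
  re <- re[match(rb$hospital_id, re$hospital_id), ]
  lev <- c("below_average", "average", "above_average")
  trans <- table(factor(rb$classification, lev),
                 factor(re$classification, lev))
  names(dimnames(trans)) <- c("base", "expanded")
  moved <- which(rb$classification != re$classification)
  movers <- data.frame(hospital_id = rb$hospital_id[moved],
                       from = rb$classification[moved],
                       to = re$classification[moved],
                       stringsAsFactors = FALSE)
  rel <- data.frame(hospital_id = rb$hospital_id,
                    rsr_base = rb$rsr, rsr_expanded = re$rsr,
                    relative_change = (re$rsr - rb$rsr) / rb$rsr,
                    stringsAsFactors = FALSE)
  structure(list(transition = trans, movers = movers,
                 relative_change = rel,
                 n_reclassified = nrow(movers)),
            class = "reclassification")
}

#' @export
print.reclassification <- function(x, ...) {
  cat(sprintf("Reclassification after equity-related adjustment: %d hospital(s) moved\n",
              x$n_reclassified))
  print(x$transition)
  if (nrow(x$movers)) print(x$movers)
  invisible(x)
}
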