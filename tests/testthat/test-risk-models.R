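test_that("small diagnosis groups pool into event-rate tertiles", {
  mk_group <- function(g, n, events) {
    data.frame(dx_group = g, y = rep(c(1L, 0L), c(events, n - events)))
  }
  tab <- rbind(mk_group("A", 3000, 300),   # rate .10, stands alone
               mk_group("B", 7500, 150),   # rate .02
               mk_group("C", 500, 50),     # rate .10
               mk_group("D", 50, 10))      # rate .20
  gm <- pool_small_groups(tab, min_events = 200)
  expect_equal(gm$model_group[gm$dx_group == "A"], "A")
  expect_equal(gm$model_group[gm$dx_group == "B"], "other_low")
  expect_equal(gm$model_group[gm$dx_group == "C"], "other_mid")
  expect_equal(gm$model_group[gm$dx_group == "D"], "other_high")
})

test_that("groups at or above the event threshold are never pooled", {
  tab <- rbind(data.frame(dx_group = "A", y = rep(c(1L, 0L), c(200, 300))),
               data.frame(dx_group = "B", y = rep(c(1L, 0L), c(500, 500))))
  gm <- pool_small_groups(tab, min_events = 200)
  expect_equal(gm$model_group, gm$dx_group)  # exactly 200 stays unpooled
})

test_that("design matrix has the documented deterministic shape", {
  coh <- generate_cohort(cohort_config(n_hospitals = 3,
                                       admissions_per_hospital = c(80, 100),
                                       seed = 2))
  tab <- build_outcome_cohort(coh$admissions, "mortality")$cohort
  spec <- feature_spec("mortality", knots = c(40, 60, 75, 90))
  X <- build_design(tab, spec)
  # 1 intercept + 3 spline + sex + urgency + 2 charlson + mlaps + 5 interactions
  expect_equal(ncol(X), 14)
  expect_equal(colnames(X)[1:4], c("intercept", "age_lin", "age_nl1",
                                   "age_nl2"))
  spec_eq <- feature_spec("mortality", include_equity = TRUE,
                          knots = c(40, 60, 75, 90))
  X_eq <- build_design(tab, spec_eq)
  expect_equal(ncol(X_eq), 14 + 6)
  expect_identical(X, build_design(tab, spec))
  # readmission specs add the prior-discharge dummies
  tab30 <- build_outcome_cohort(coh$admissions, "readmission_30")$cohort
  X30 <- build_design(tab30, feature_spec("readmission_30",
                                          knots = c(40, 60, 75, 90)))
  expect_equal(ncol(X30), 16)
  expect_true(all(c("prior_1", "prior_2p") %in% colnames(X30)))
})

test_that("missing features raise a schema error", {
  tab <- data.frame(age = 50, sex = "male")
  expect_error(build_design(tab, feature_spec("mortality",
                                              knots = c(40, 60, 75, 90))),
               "missing required columns")
})

test_that("unpenalized fit matches a generic-optimizer MLE", {
  d <- sim_logistic_design(1500, seed = 5)
  fit <- fit_penalized_logistic(d$X, d$y, lambda = 0)
  opt <- optim(rep(0, ncol(d$X)), neg_loglik, neg_loglik_grad,
               X = d$X, y = d$y, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  expect_lt(max(abs(fit$coefficients - opt$par)), 1e-6)
})

test_that("an extreme penalty shrinks everything but the intercept", {
  d <- sim_logistic_design(800, seed = 6)
  fit <- fit_penalized_logistic(d$X, d$y, lambda = 1e8)
  expect_lt(max(abs(fit$coefficients[-1])), 1e-4)
  expect_lt(abs(fit$coefficients[1] - logit(mean(d$y))), 1e-3)
})

test_that("ridge penalty keeps separable data finite", {
  X <- cbind(intercept = 1, x = c(-3, -2, -1, 1, 2, 3))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_penalized_logistic(X, y, lambda = 2)
  expect_true(all(is.finite(fit$coefficients)))
  expect_lt(max(abs(fit$coefficients)), 20)
})

test_that("penalty selection reports full df at zero penalty and a monotone df path", {
  d <- sim_logistic_design(600, seed = 7, p_extra = 4)
  sel0 <- select_penalty_aicc(d$X, d$y, lambda_grid = 0)
  expect_equal(sel0$lambda, 0)
  expect_equal(sel0$trace$df, ncol(d$X), tolerance = 1e-6)
  sel <- select_penalty_aicc(d$X, d$y, lambda_grid = c(0, 1, 4, 16, 64, 256))
  expect_true(all(diff(sel$trace$df) < 1e-8))
})

test_that("pure-noise covariates usually trigger a positive penalty", {
  hits <- 0L
  n_rep <- 30L
  for (r in seq_len(n_rep)) {
    set.seed(100 + r)
    n <- 250
    X <- cbind(intercept = 1, matrix(rnorm(n * 12), n,
                                     dimnames = list(NULL, paste0("z", 1:12))))
    y <- rbinom(n, 1, 0.3)
    sel <- select_penalty_aicc(X, y, lambda_grid = c(0, 2^(0:8)))
    if (sel$lambda > 0) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("risk model predictions are calibrated in the large", {
  coh <- generate_cohort(cohort_config(n_hospitals = 6,
                                       admissions_per_hospital = c(900, 1100),
                                       n_dx_groups = 2, seed = 12))
  tab <- build_outcome_cohort(coh$admissions, "mortality")$cohort
  ms <- fit_risk_models(tab, feature_spec("mortality"),
                        lambda_grid = c(0), min_events = 200)
  p <- predict(ms, tab)
  expect_true(all(p > 0 & p < 1))
  expect_lt(abs(mean(p) - mean(tab$y)), 0.01)
})

test_that("predictions are invariant to affine covariate rescaling at zero penalty", {
  d <- sim_logistic_design(800, seed = 9)
  fit1 <- fit_penalized_logistic(d$X, d$y, 0)
  X2 <- d$X
  X2[, "x1"] <- 100 * X2[, "x1"] + 7
  fit2 <- fit_penalized_logistic(X2, d$y, 0)
  p1 <- 1 / (1 + exp(-drop(d$X %*% fit1$coefficients)))
  p2 <- 1 / (1 + exp(-drop(X2 %*% fit2$coefficients)))
  expect_lt(max(abs(p1 - p2)), 1e-6)
})

test_that("zeroing equity coefficients reproduces non-equity predictions", {
  coh <- generate_cohort(cohort_config(n_hospitals = 4,
                                       admissions_per_hospital = c(300, 350),
                                       n_dx_groups = 2, seed = 14))
  tab <- build_outcome_cohort(coh$admissions, "mortality")$cohort
  ms <- fit_risk_models(tab, feature_spec("mortality", include_equity = TRUE),
                        lambda_grid = 0, min_events = 100)
  ms0 <- ms
  eq_cols <- c("homelessness", "disability", "onmarg_housing",
               "onmarg_racialized_newcomer", "onmarg_material",
               "onmarg_age_labor")
  for (g in names(ms0$models)) {
    ms0$models[[g]]$coefficients[eq_cols] <- 0
  }
  p0 <- predict(ms0, tab)
  # manual base-column prediction with the same remaining coefficients
  manual <- numeric(nrow(tab))
  gmap <- ms$group_map
  mg <- gmap$model_group[match(tab$dx_group, gmap$dx_group)]
  for (g in unique(mg)) {
    rows <- which(mg == g)
    sp <- ms$spec
    sp$include_equity <- FALSE
    sp$knots <- ms$models[[g]]$knots
    Xb <- build_design(tab[rows, ], sp)
    cf <- ms$models[[g]]$coefficients[colnames(Xb)]
    manual[rows] <- 1 / (1 + exp(-drop(Xb %*% cf)))
  }
  expect_equal(unname(p0), manual, tolerance = 1e-12)
})

test_that("unseen diagnosis groups fall back to the nearest other pool", {
  coh <- generate_cohort(cohort_config(n_hospitals = 5,
                                       admissions_per_hospital = c(400, 500),
                                       n_dx_groups = 6, seed = 15))
  tab <- build_outcome_cohort(coh$admissions, "mortality")$cohort
  ms <- fit_risk_models(tab, feature_spec("mortality"), lambda_grid = 0,
                        min_events = 200)
  new <- tab[1:10, ]
  new$dx_group <- "DX_NEW"
  if (any(grepl("^other_", ms$group_map$model_group))) {
    expect_message(p <- predict(ms, new), "unseen")
    expect_true(all(p > 0 & p < 1))
  } else {
    expect_error(predict(ms, new), "unseen|fall back")
  }
})
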