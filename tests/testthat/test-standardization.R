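make_fit <- function(intercepts, a = -2, b = 1, sigma = 0.3) {
  structure(list(coefficients = c(intercept = a, slope = b),
                 sigma_u = sigma,
                 hospital_intercepts = intercepts,
                 loglik = NA_real_, boundary = sigma == 0,
                 convergence = 0L, quad_points = 10L,
                 n = NA_integer_, k = length(intercepts)),
            class = "ri_glmm")
}

test_that("a zero random intercept reproduces the crude rate exactly", {
  set.seed(51)
  x <- rnorm(300)
  hosp <- rep(c("A", "B", "C"), each = 100)
  fit <- make_fit(c(A = 0, B = 0.4, C = -0.4))
  rr <- risk_standardized_rates(fit, x, hosp, crude_rate = 0.1)
  expect_equal(rr$rsr[rr$hospital_id == "A"], 0.1, tolerance = 1e-12)
  # monotone in the intercept
  expect_gt(rr$rsr[rr$hospital_id == "B"], 0.1)
  expect_lt(rr$rsr[rr$hospital_id == "C"], 0.1)
})

test_that("predicted events track observed events on a converged fit", {
  set.seed(52)
  k <- 12; n_per <- 500
  hosp <- rep(sprintf("H%02d", 1:k), each = n_per)
  u <- rnorm(k, 0, 0.3)
  x <- rnorm(k * n_per, -2, 1)
  y <- rbinom(k * n_per, 1, expit(0.1 + 0.9 * x + u[as.integer(factor(hosp))]))
  fit <- fit_random_intercept_glmm(x, y, hosp)
  rr <- risk_standardized_rates(fit, x, hosp, mean(y))
  expect_lt(abs(sum(rr$predicted) - sum(y)) / sum(y), 0.05)
})

test_that("risk standardization ignores hospital labels and admission order", {
  set.seed(53)
  x <- rnorm(400, -1.5, 1)
  hosp <- rep(c("A", "B", "C", "D"), each = 100)
  y <- rbinom(400, 1, expit(x + 0.3 * (hosp %in% c("A", "B"))))
  fit <- fit_random_intercept_glmm(x, y, hosp)
  rr <- risk_standardized_rates(fit, x, hosp, mean(y))
  perm <- sample(400)
  rr2 <- risk_standardized_rates(fit, x[perm], hosp[perm], mean(y))
  expect_equal(rr$rsr, rr2$rsr[match(rr$hospital_id, rr2$hospital_id)],
               tolerance = 1e-12)
})

test_that("classification follows the CI-crossing rule with non-strict boundary", {
  rates <- data.frame(ci_low = c(0.10, 0.12, 0.14, 0.11, 0.13),
                      ci_high = c(0.12, 0.14, 0.16, 0.13, 0.15))
  got <- classify_hospitals(rates, 0.13)
  expect_equal(got, c("below_average", "average", "above_average",
                      "average", "average"))
})

test_that("cluster bootstrap is seed-deterministic and holds sizes fixed", {
  set.seed(54)
  k <- 6; n_per <- 120
  hosp <- rep(sprintf("H%02d", 1:k), each = n_per)
  x <- rnorm(k * n_per, -2, 1)
  y <- rbinom(k * n_per, 1, expit(x))
  bs1 <- cluster_bootstrap_ci(x, y, hosp, n_boot = 30, seed = 9)
  bs2 <- cluster_bootstrap_ci(x, y, hosp, n_boot = 30, seed = 9)
  expect_identical(bs1$ci, bs2$ci)
  expect_equal(dim(bs1$replicates), c(30L, k))
  expect_true(all(is.finite(bs1$replicates)))
  expect_true(all(bs1$ci$ci_low <= bs1$ci$ci_high))
})

test_that("standardized rates shrink relative to crude per-hospital rates", {
  set.seed(55)
  k <- 15; n_per <- 250
  hosp <- rep(sprintf("H%02d", 1:k), each = n_per)
  u <- rnorm(k, 0, 0.35)
  x <- rnorm(k * n_per, -2, 1)
  y <- rbinom(k * n_per, 1, expit(x + u[as.integer(factor(hosp))]))
  fit <- fit_random_intercept_glmm(x, y, hosp)
  rr <- risk_standardized_rates(fit, x, hosp, mean(y))
  crude_h <- tapply(y, hosp, mean)
  expect_lte(var(rr$rsr), var(as.numeric(crude_h)))
})

test_that("hospital_profile assembles rates, intervals, and classes", {
  set.seed(56)
  k <- 5; n_per <- 150
  hosp <- rep(sprintf("H%02d", 1:k), each = n_per)
  p <- expit(rnorm(k * n_per, -2, 1))
  y <- rbinom(k * n_per, 1, p)
  prof <- hospital_profile(p, y, hosp, n_boot = 25, seed = 2)
  expect_s3_class(prof, "hospital_profile")
  expect_equal(nrow(prof$rates), k)
  expect_true(all(prof$rates$classification %in%
                    c("below_average", "average", "above_average")))
  expect_equal(prof$crude_rate, mean(y))
  cf <- coef(prof)
  expect_named(cf, c("intercept", "slope", "sigma_u"))
  s <- summary(prof)
  expect_s3_class(s, "summary.hospital_profile")
  plot_file <- tempfile(fileext = ".png")
  grDevices::png(plot_file)
  plot(prof)
  grDevices::dev.off()
  expect_true(file.exists(plot_file))
  unlink(plot_file)
})

test_that("classification comparison reports transitions and movers", {
  rates_a <- data.frame(hospital_id = c("A", "B", "C"),
                        rsr = c(0.10, 0.13, 0.16),
                        classification = c("below_average", "average",
                                           "above_average"),
                        stringsAsFactors = FALSE)
  rates_b <- rates_a
  cmp0 <- compare_classifications(rates_a, rates_b)
  expect_equal(cmp0$n_reclassified, 0)
  expect_equal(sum(diag(cmp0$transition)), 3)
  rates_b$classification <- c("average", "average", "average")
  rates_b$rsr <- c(0.11, 0.13, 0.15)
  cmp <- compare_classifications(rates_a, rates_b)
  expect_equal(cmp$n_reclassified, 2)
  expect_setequal(cmp$movers$hospital_id, c("A", "C"))
  expect_equal(cmp$relative_change$relative_change,
               (rates_b$rsr - rates_a$rsr) / rates_a$rsr)
  # all movers have a nonzero relative change
  expect_true(all(abs(cmp$relative_change$relative_change[
    cmp$relative_change$hospital_id %in% cmp$movers$hospital_id]) > 0))
  rates_b$hospital_id <- c("A", "B", "Z")
  expect_error(compare_classifications(rates_a, rates_b), "different")
})
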