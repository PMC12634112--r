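# Independent oracles and small fixture builders used across the suite.

# brute-force pairwise concordance (ties count 1/2)
brute_auc <- function(p, y) {
  pos <- p[y == 1]
  neg <- p[y == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# textbook restricted cubic spline: truncated cubics with the tail
# restriction written out directly, normalized by the squared knot range
rcs_textbook <- function(x, knots) {
  tp <- function(u) ifelse(u > 0, u^3, 0)
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]; t4 <- knots[4]
  tau2 <- (t4 - t1)^2
  term <- function(tj) {
    (tp(x - tj) - tp(x - t3) * (t4 - tj) / (t4 - t3) +
       tp(x - t4) * (t3 - tj) / (t4 - t3)) / tau2
  }
  cbind(x, term(t1), term(t2))
}

# Bernoulli log-likelihood written out longhand
loglik_oracle <- function(p, y) {
  s <- 0
  for (i in seq_along(y)) {
    s <- s + if (y[i] == 1) log(p[i]) else log(1 - p[i])
  }
  s
}

# negative penalized log-likelihood and gradient for the generic-optimizer
# oracle (standardized internally exactly like the implementation when
# lambda = 0 the scaling is irrelevant)
neg_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}
neg_loglik_grad <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  -drop(crossprod(X, y - mu))
}

# small admission table built by hand for cohort-builder unit tests
make_admissions <- function(...) {
  rows <- list(...)
  base <- list(
    admission_id = NA_character_, patient_id = "P1", hospital_id = "H1",
    admit_dt = as.POSIXct("2020-01-01 10:00:00", tz = "UTC"),
    discharge_dt = as.POSIXct("2020-01-03 10:00:00", tz = "UTC"),
    age = 70, sex = "female", admission_category = "urgent",
    charlson = "0", mlaps = 10, prior_discharges_6mo = "0",
    dx_group = "DX01", mrdx_palliative = FALSE, mrdx_maid = FALSE,
    mrdx_mental_health = FALSE, mrdx_chemo = FALSE, mrdx_obstetric = FALSE,
    disposition = "home", transfer_in = FALSE, homelessness = FALSE,
    cognitive_disability = FALSE, physical_disability = FALSE,
    sensory_disability = FALSE, disability = FALSE,
    onmarg_housing = 0, onmarg_racialized_newcomer = 0,
    onmarg_material = 0, onmarg_age_labor = 0,
    dissemination_area_present = TRUE)
  out <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- utils::modifyList(base, rows[[i]])
    if (is.na(r$admission_id)) r$admission_id <- sprintf("A%03d", i)
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  out$admit_dt <- as.POSIXct(out$admit_dt, tz = "UTC", origin = "1970-01-01")
  out$discharge_dt <- as.POSIXct(out$discharge_dt, tz = "UTC",
                                 origin = "1970-01-01")
  out
}

ts <- function(x) as.POSIXct(x, tz = "UTC")

# small well-behaved design for penalized-regression tests
sim_logistic_design <- function(n, seed, p_extra = 0) {
  set.seed(seed)
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rnorm(n),
             x3 = rbinom(n, 1, 0.4))
  if (p_extra > 0) {
    noise <- matrix(rnorm(n * p_extra), n)
    colnames(noise) <- paste0("z", seq_len(p_extra))
    X <- cbind(X, noise)
  }
  beta <- c(-1, 0.6, -0.4, 0.5, rep(0, p_extra))
  y <- rbinom(n, 1, 1 / (1 + exp(-drop(X %*% beta))))
  list(X = X, y = y, beta = beta)
}
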