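#' Inverse-logit and logit
#'
#' Numerically safe logistic link helpers used throughout the package.
#'
#' @param x Numeric vector of log-odds.
#' @param p Numeric vector of probabilities.
#' @return Numeric vector.
#' @export
expit <- function(x) {
  # stable in both tails
  out <- numeric(length(x))
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out[is.na(x)] <- NA_real_
  out
}

#' @rdname expit
#' @export
logit <- function(p) log(p) - log1p(-p)

# Clip probabilities away from 0/1 for likelihood-based quantities.
#' @noRd
clip_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# Bernoulli log-likelihood of probabilities p for outcomes y.
#' @noRd
bernoulli_loglik <- function(p, y) {
  p <- clip_prob(p)
  sum(y * log(p) + (1 - y) * log1p(-p))
}

#' @noRd
stop_missing_cols <- function(tab, cols, what = "table") {
  miss <- setdiff(cols, names(tab))
  if (length(miss)) {
    stop(sprintf("%s is missing required columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Derive a child seed below 2^31 from a base seed and an index.
#' @noRd
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483629)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
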