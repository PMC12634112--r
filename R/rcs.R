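#' Restricted cubic spline basis (4 knots)
#'
#' Builds the restricted (natural) cubic spline basis in Harrell's
#' parameterization, normalized by the knot range. With 4 knots the basis has
#' 3 columns: the identity (linear) term plus two nonlinear terms. The spline
#' is linear beyond the outer knots and has continuous second derivatives
#' everywhere, which is the standard way to let age enter a clinical
#' risk-adjustment model flexibly without wild tail behaviour.
#'
#' For knots \eqn{t_1 < t_2 < t_3 < t_4} and scale \eqn{\tau = t_4 - t_1},
#' nonlinear term \eqn{j \in \{1, 2\}} is
#' \deqn{(x - t_j)_+^3 - (x - t_3)_+^3 \frac{t_4 - t_j}{t_4 - t_3}
#'       + (x - t_4)_+^3 \frac{t_3 - t_j}{t_4 - t_3},}
#' divided by \eqn{\tau^2} so the columns are on roughly the scale of \eqn{x}.
#'
#' @param x Numeric vector.
#' @param knots Numeric vector of 4 strictly increasing knot locations.
#' @return A numeric matrix with `length(x)` rows and 3 columns named
#'   `"lin"`, `"nl1"`, `"nl2"`.
#' @examples
#' b <- rcs_basis(20:90, knots = c(30, 55, 70, 88))
#' matplot(20:90, b, type = "l")
#' @export
rcs_basis <- function(x, knots) {
  if (length(knots) != 4L) {
    stop("rcs_basis() requires exactly 4 knots", call. = FALSE)
  }
  knots <- as.numeric(knots)
  if (any(diff(knots) <= 0)) {
    stop("knots must be strictly increasing", call. = FALSE)
  }
  tau <- knots[4L] - knots[1L]
  cube <- function(u) pmax(u, 0)^3
  k3 <- knots[3L]
  k4 <- knots[4L]
  nl <- function(tj) {
    (cube(x - tj) -
       cube(x - k3) * (k4 - tj) / (k4 - k3) +
       cube(x - k4) * (k3 - tj) / (k4 - k3)) / tau^2
  }
  out <- cbind(lin = as.numeric(x), nl1 = nl(knots[1L]), nl2 = nl(knots[2L]))
  rownames(out) <- NULL
  out
}

# Default knot quantiles (Harrell's recommendation for 4 knots).
#' @noRd
rcs_default_knots <- function(x) {
  k <- unname(stats::quantile(x, probs = c(0.05, 0.35, 0.65, 0.95),
                              names = FALSE, type = 7, na.rm = TRUE))
  # degenerate training samples: nudge ties apart so the basis stays defined
  if (any(diff(k) <= 0)) {
    k <- k + seq(0, 3) * max(1e-6, stats::sd(x, na.rm = TRUE) * 1e-3)
  }
  k
}
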