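#' Choose the reference hospital for an equity-related variable
#'
#' Hospitals are ranked by the hospital-level median of the variable
#' (proportion for binary variables) and the hospital at the middle rank
#' (`ceiling(k / 2)`, e.g. rank 12 of 23) is the reference. Ties are broken
#' by hospital id order, so the choice does not depend on input row order.
#'
#' @param cohort data.frame with `hospital_id` and the variable.
#' @param variable Column name of the equity-related variable.
#' @return Hospital id of the reference.
#' @export
reference_hospital <- function(cohort, variable) {
  stop_missing_cols(cohort, c("hospital_id", variable), "cohort")
  hospitals <- sort(unique(cohort$hospital_id))
  if (length(hospitals) < 2) {
    stop("at least 2 hospitals are required", call. = FALSE)
  }
  v <- cohort[[variable]]
  if (is.logical(v)) v <- as.numeric(v)
  loc <- vapply(hospitals, function(h) {
    x <- v[cohort$hospital_id == h]
    if (all(x %in% c(0, 1))) mean(x) else stats::median(x)
  }, numeric(1))
  if (length(unique(loc)) == 1L) {
    warning(sprintf("variable '%s' is constant across hospitals; using first hospital as reference",
                    variable))
    return(hospitals[1L])
  }
  ord <- order(loc, hospitals)  # tie-break by hospital id
  hospitals[ord][ceiling(length(hospitals) / 2)]
}

#' Between-hospital log odds ratios for one equity-related variable
#'
#' Fits a univariable regression with hospital as the categorical exposure
#' and the equity-related variable as the outcome: logistic regression for
#' binary variables; proportional-odds (cumulative logit) regression for
#' continuous variables after binning into cohort-wide quintiles. Returns the
#' log odds ratio of each hospital against the reference (0 for the reference
#' itself). Estimates that are infinite or near-separated are truncated at
#' +/- 10 and flagged.
#'
#' @param cohort data.frame with `hospital_id` and the variable.
#' @param variable Variable name; one of the two binary factors
#'   (`homelessness`, `disability`) or the four `onmarg_*` dimensions (any
#'   numeric column works).
#' @param reference Reference hospital id; default [reference_hospital()].
#' @param n_bins Number of ordinal bins for continuous variables.
#' @return data.frame of class `equity_effects`: `hospital_id`, `variable`,
#'   `log_or`, `truncated`, `reference` (attribute `reference_hospital`).
#' @export
hospital_equity_effects <- function(cohort, variable, reference = NULL,
                                    n_bins = 5L) {
  stop_missing_cols(cohort, c("hospital_id", variable), "cohort")
  v <- cohort[[variable]]
  if (is.logical(v)) v <- as.numeric(v)
  hospitals <- sort(unique(cohort$hospital_id))
  if (is.null(reference)) reference <- reference_hospital(cohort, variable)
  if (!reference %in% hospitals) {
    stop("reference hospital not present in cohort", call. = FALSE)
  }
  hosp <- stats::relevel(factor(cohort$hospital_id, levels = hospitals),
                         ref = as.character(reference))
  binary <- all(v %in% c(0, 1))
  cap <- 10
  if (binary) {
    fit <- stats::glm(v ~ hosp, family = stats::binomial())
    beta <- stats::coef(fit)[-1L]
    names(beta) <- sub("^hosp", "", names(beta))
  } else {
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1),
                                 type = 7))
    if (length(br) < 3) {
      stop(sprintf("variable '%s' has too few distinct values to bin",
                   variable), call. = FALSE)
    }
    vb <- cut(v, breaks = br, include.lowest = TRUE, ordered_result = TRUE)
    fit <- MASS::polr(vb ~ hosp, Hess = FALSE)
    beta <- stats::coef(fit)
    names(beta) <- sub("^hosp", "", names(beta))
  }
  truncated <- !is.finite(beta) | abs(beta) > cap
  beta[!is.finite(beta)] <- sign(beta[!is.finite(beta)]) * cap
  beta <- pmin(pmax(beta, -cap), cap)
  out <- data.frame(
    hospital_id = hospitals,
    variable = variable,
    log_or = ifelse(hospitals == reference, 0, beta[hospitals]),
    truncated = ifelse(hospitals == reference, FALSE, truncated[hospitals]),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "reference_hospital") <- reference
  class(out) <- c("equity_effects", class(out))
  out
}

#' Equity heat-map table ordered by relative change in standardized rate
#'
#' Assembles the hospital-by-variable matrix of log odds ratios, with rows
#' ordered by each hospital's relative change in risk-standardized rate after
#' equity-related adjustment (largest increase first), the display used to
#' inspect which equity gradients track reclassification.
#'
#' @param effects List of [hospital_equity_effects()] tables (one per
#'   variable), or a single long data.frame binding them.
#' @param rsr_changes data.frame with `hospital_id` and `relative_change`
#'   (e.g. `compare_classifications(...)$relative_change`).
#' @return List of class `equity_heatmap`: `matrix` (hospitals x variables,
#'   ordered), `relative_change` (aligned vector), `references` (per
#'   variable).
#' @export
heatmap_table <- function(effects, rsr_changes) {
  if (is.data.frame(effects)) effects <- split(effects, effects$variable)
  stop_missing_cols(rsr_changes, c("hospital_id", "relative_change"),
                    "rsr_changes")
  vars <- vapply(effects, function(e) e$variable[1L], character(1))
  hosp <- sort(unique(effects[[1L]]$hospital_id))
  for (e in effects) {
    if (!setequal(e$hospital_id, hosp)) {
      stop("effects tables cover different hospitals", call. = FALSE)
    }
  }
  if (!all(hosp %in% rsr_changes$hospital_id)) {
    stop("rsr_changes is missing hospitals present in effects",
         call. = FALSE)
  }
  m <- sapply(effects, function(e) {
    e$log_or[match(hosp, e$hospital_id)]
  })
  colnames(m) <- vars
  rownames(m) <- hosp
  rel <- rsr_changes$relative_change[match(hosp, rsr_changes$hospital_id)]
  ord <- order(-rel)
  refs <- vapply(effects, function(e) {
    attr(e, "reference_hospital") %||% NA_character_
  }, character(1))
  names(refs) <- vars
  structure(list(matrix = m[ord, , drop = FALSE],
                 relative_change = rel[ord],
                 references = refs),
            class = "equity_heatmap")
}

#' @export
print.equity_heatmap <- function(x, ...) {
  cat("Equity-gradient heat map (rows ordered by relative RSR change, descending)\n")
  print(round(x$matrix, 3))
  invisible(x)
}

#' Equity effects for all six standard equity-related variables
#'
#' @param cohort Reporting-period cohort.
#' @param variables Variable names; default the six standard factors.
#' @param n_bins Bins for continuous variables.
#' @return Named list of [hospital_equity_effects()] tables.
#' @export
equity_profile_all <- function(cohort, variables = equity_feature_names(),
                               n_bins = 5L) {
  out <- lapply(variables, function(v) {
    hospital_equity_effects(cohort, v, n_bins = n_bins)
  })
  names(out) <- variables
  out
}
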