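#' Area-level predictor profile
#'
#' The area-level "parallel set of predictors": for one area, the
#' design-weighted proportion of each non-reference categorical level and the
#' design-weighted mean of each continuous term of the model spec, computed
#' as weighted column means of the fixed-effect design matrix (so dummy
#' coding, interactions and reference levels match the individual-level model
#' exactly).
#'
#' @param data a [survey_dataset()].
#' @param spec a [model_spec()] (or the `spec` of a fitted `mh_model`).
#' @param area area id to profile; `NULL` profiles all rows of `data`.
#' @param by column holding the area id (default `"area"`; use `"province"`
#'   for provincial profiles).
#' @param weights optional replicate-weight column/vector overriding the
#'   design weights.
#' @return an object of class `area_profile`: list with `area`,
#'   `term_values` (named numeric, one entry per fixed-effect column),
#'   `n_respondents`, `weight_total`.
#' @export
area_profile <- function(data, spec, area = NULL, by = "area", weights = NULL) {
  rows <- if (is.null(area)) as.data.frame(data) else {
    if (!by %in% names(data)) stop_synthprev(sprintf("no column '%s'", by), "schema_error")
    as.data.frame(data)[data[[by]] == area, , drop = FALSE]
  }
  if (!nrow(rows)) {
    stop_synthprev(sprintf("area '%s' has no respondents", area %||% "<all>"),
                   "estimation_error")
  }
  sp <- spec
  sp$group <- NULL
  if (!is.null(weights)) {
    if (!is.character(weights) || !weights %in% names(rows)) {
      stop_synthprev("weights override must name a column of the dataset", "argument_error")
    }
    rows[[attr(data, "weight_col") %||% "weight"]] <- rows[[weights]]
  }
  attr(rows, "weight_col") <- attr(data, "weight_col") %||% "weight"
  attr(rows, "dictionary") <- dataset_dictionary(data)
  mf <- prepare_model_frame(rows, sp, require_outcome = FALSE)
  X <- stats::model.matrix(spec_formula_rhs(sp), mf)
  w <- mf$.design_w
  tv <- drop(crossprod(X, w)) / sum(w)
  tv <- tv[setdiff(names(tv), "(Intercept)")]
  structure(list(area = area %||% "<all>", term_values = tv,
                 n_respondents = nrow(mf), weight_total = sum(w)),
            class = "area_profile")
}

# RHS-only formula so profiles can be built without the outcome column.
spec_formula_rhs <- function(spec) {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  stats::as.formula(paste("~", rhs), env = globalenv())
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("area profile '%s' (n = %d, total weight %.1f)\n",
              x$area, x$n_respondents, x$weight_total))
  print(round(x$term_values, 4))
  invisible(x)
}

#' Synthetic (area-level) estimate from a fitted model
#'
#' The regression synthetic estimator: the fitted coefficients are applied to
#' the area-level term values,
#' `eta_a = beta0 + sum_j beta_j * term_value_j` (random intercept set to 0),
#' and `synthetic_estimate()` converts the logit to a predicted prevalence
#' `100 * expit(eta_a)` on the percent scale. Because the expit is applied to
#' aggregated predictors rather than averaged over respondents, this differs
#' from [individual_aggregation_estimate()] whenever covariates vary within
#' the area (Jensen gap).
#'
#' @param model an `mh_model`.
#' @param profile an [area_profile()] covering every model term.
#' @return `synthetic_logit()` the area logit; `synthetic_estimate()` the
#'   predicted prevalence in percent.
#' @export
synthetic_logit <- function(model, profile) {
  beta <- model$beta
  terms <- setdiff(names(beta), "(Intercept)")
  missing <- setdiff(terms, names(profile$term_values))
  if (length(missing)) {
    stop_synthprev(paste("profile lacks model term(s):", paste(missing, collapse = ", ")),
                   "schema_error")
  }
  unname(beta[["(Intercept)"]] + sum(beta[terms] * profile$term_values[terms]))
}

#' @rdname synthetic_logit
#' @export
synthetic_estimate <- function(model, profile) {
  100 * stats::plogis(synthetic_logit(model, profile))
}

#' Individual-aggregation (oracle) estimate
#'
#' The design-weighted mean of respondent-level predicted risks,
#' `100 * sum(w_i expit(eta_i)) / sum(w_i)` with the random intercept at 0.
#' On an area whose respondents all share one covariate pattern it equals
#' [synthetic_estimate()] exactly; under within-area heterogeneity it is the
#' estimator that tracks the observed proportion, and the difference to the
#' synthetic estimate quantifies the aggregation (Jensen) gap.
#'
#' @param model an `mh_model`.
#' @param data a [survey_dataset()].
#' @param area area id; `NULL` for all rows.
#' @param by area id column.
#' @return predicted prevalence in percent.
#' @export
individual_aggregation_estimate <- function(model, data, area = NULL, by = "area") {
  rows <- if (is.null(area)) data else {
    out <- as.data.frame(data)[data[[by]] == area, , drop = FALSE]
    attr(out, "weight_col") <- attr(data, "weight_col") %||% "weight"
    attr(out, "dictionary") <- dataset_dictionary(data)
    out
  }
  if (!nrow(rows)) {
    stop_synthprev(sprintf("area '%s' has no respondents", area), "estimation_error")
  }
  risk <- predict(model, rows, mode = "population_average")
  wc <- attr(rows, "weight_col") %||% "weight"
  w <- rows[[wc]]
  100 * sum(w * risk) / sum(w)
}

#' Signed difference between predicted and observed proportions
#'
#' `predicted - observed` on the percent scale — the validation metric used
#' in observed-versus-predicted tables (conventionally labelled "absolute
#' difference" in synthetic-estimation reporting, but kept signed; rounding
#' to 2 decimals happens only at serialization).
#'
#' @param predicted,observed proportions in percent.
#' @return signed difference in percentage points (vectorized).
#' @export
absolute_difference <- function(predicted, observed) predicted - observed

#' Observed-versus-predicted validation by area
#'
#' For every area in `data` (by province or health region), computes the
#' observed design-weighted outcome proportion, the synthetic predicted
#' proportion (area profile computed from *this* dataset), and their signed
#' difference. Areas without respondents are skipped with a warning.
#' Optionally adds bootstrap standard errors (replicate weights re-enter both
#' the observed proportion and the area profile).
#'
#' @param model an `mh_model`.
#' @param data a [survey_dataset()] containing the outcome, model terms and
#'   area ids.
#' @param by `"province"` or `"area"` (health region).
#' @param label dataset label recorded in the output (e.g. `"val2019"`).
#' @param bootstrap logical; add bootstrap SEs (requires replicate weights).
#' @param use_blup add the area's empirical-Bayes intercept to the synthetic
#'   logit for areas known to the model (only meaningful when `by` is the
#'   model's grouping variable on development data).
#' @param estimator `"synthetic"` (default) or `"individual"` (the
#'   aggregation oracle).
#' @return data.frame of class `mh_validation` with columns `area`, `label`,
#'   `n`, `observed_pct`, `predicted_pct`, `difference_pct`, `observed_se`,
#'   `predicted_se`.
#' @export
validate_model <- function(model, data, by = c("province", "area"), label = "",
                           bootstrap = FALSE, use_blup = FALSE,
                           estimator = c("synthetic", "individual")) {
  by <- match.arg(by)
  estimator <- match.arg(estimator)
  areas <- unique(as.character(data[[by]]))
  rows <- list()
  for (a in areas) {
    sub_n <- sum(data[[by]] == a)
    if (!sub_n) {
      warning(sprintf("area '%s' has no respondents; skipped", a))
      next
    }
    obs <- weighted_proportion(as.data.frame(data)[data[[by]] == a, , drop = FALSE],
                               model$spec$outcome,
                               weights = design_weights(data)[data[[by]] == a])
    pred <- area_prediction(model, data, a, by, estimator, use_blup)
    obs_se <- pred_se <- NA_real_
    if (bootstrap) {
      bsw <- bsw_columns(data)
      if (!length(bsw)) stop_synthprev("bootstrap = TRUE but no replicate weights", "config_error")
      sel <- data[[by]] == a
      obs_b <- vapply(bsw, function(cl) {
        100 * wsum_ratio(data[[model$spec$outcome]][sel], data[[cl]][sel])
      }, numeric(1))
      obs_se <- sqrt(mean((obs_b - obs$value)^2))
      pred_b <- vapply(bsw, function(cl) {
        area_prediction(model, data, a, by, estimator, use_blup, weights = cl)
      }, numeric(1))
      pred_se <- sqrt(mean((pred_b - pred)^2))
    }
    rows[[a]] <- data.frame(
      area = a, label = label, n = sub_n,
      observed_pct = obs$value, predicted_pct = pred,
      difference_pct = absolute_difference(pred, obs$value),
      observed_se = obs_se, predicted_se = pred_se,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mh_validation", class(out))
  out
}

area_prediction <- function(model, data, a, by, estimator, use_blup, weights = NULL) {
  if (estimator == "individual") {
    return(individual_aggregation_estimate(model, data, a, by))
  }
  prof <- area_profile(data, model$spec, area = a, by = by, weights = weights)
  eta <- synthetic_logit(model, prof)
  if (use_blup && !is.null(model$blups) && a %in% names(model$blups)) {
    eta <- eta + model$blups[[a]]
  }
  100 * stats::plogis(eta)
}

#' Round and serialize validation records
#'
#' Writes an observed-versus-predicted table as CSV with the conventional
#' 2-decimal display rounding; the difference column is recomputed after
#' rounding so that the printed columns stay self-consistent.
#'
#' @param records an `mh_validation` data.frame.
#' @param path output CSV path.
#' @return the rounded data.frame, invisibly.
#' @export
write_validation <- function(records, path) {
  out <- as.data.frame(records)
  out$observed_pct <- round(out$observed_pct, 2)
  out$predicted_pct <- round(out$predicted_pct, 2)
  out$difference_pct <- round(out$predicted_pct - out$observed_pct, 2)
  out$observed_se <- round(out$observed_se, 3)
  out$predicted_se <- round(out$predicted_se, 3)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
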