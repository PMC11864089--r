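#' Survey-weighted proportion and mean
#'
#' `weighted_proportion()` returns `100 * sum(w * y) / sum(w)` for a binary
#' indicator (percent scale, matching how area prevalences are tabulated);
#' `weighted_mean()` returns `sum(w * x) / sum(w)` for a numeric column. Both
#' attach the Kish effective sample size `(sum w)^2 / sum(w^2)`.
#'
#' @param data a [survey_dataset()] or data.frame.
#' @param column name of the indicator / numeric column.
#' @param weights weight column name, numeric vector, or `NULL` for the
#'   dataset's design weights.
#' @param se optional precomputed standard error to attach.
#' @return a `weighted_estimate`: list with `value`, `se`, `n_effective`.
#' @export
weighted_proportion <- function(data, column, weights = NULL, se = NA_real_) {
  y <- resolve_column(data, column)
  if (!all(y %in% c(0, 1))) stop_synthprev(sprintf("'%s' is not a 0/1 indicator", column),
                                           "schema_error")
  w <- resolve_weight_arg(data, weights)
  new_weighted_estimate(100 * wsum_ratio(y, w), se, kish_n(w))
}

#' @rdname weighted_proportion
#' @export
weighted_mean <- function(data, column, weights = NULL, se = NA_real_) {
  x <- resolve_column(data, column)
  w <- resolve_weight_arg(data, weights)
  new_weighted_estimate(wsum_ratio(x, w), se, kish_n(w))
}

new_weighted_estimate <- function(value, se = NA_real_, n_effective = NA_real_) {
  structure(list(value = value, se = se, n_effective = n_effective),
            class = "weighted_estimate")
}

#' @export
print.weighted_estimate <- function(x, ...) {
  cat(format(x$value, digits = 6))
  if (!is.na(x$se)) cat(" (se", format(x$se, digits = 4), ")")
  cat("\n")
  invisible(x)
}

wsum_ratio <- function(x, w) {
  if (!length(x)) stop_synthprev("empty dataset", "estimation_error")
  keep <- !is.na(x)
  x <- x[keep]; w <- w[keep]
  tot <- sum(w)
  if (!length(x) || tot <= 0) stop_synthprev("total weight is zero", "estimation_error")
  sum(w * x) / tot
}

kish_n <- function(w) sum(w)^2 / sum(w^2)

resolve_column <- function(data, column) {
  if (is.character(column) && length(column) == 1L) {
    if (!column %in% names(data)) stop_synthprev(sprintf("no column '%s'", column), "schema_error")
    data[[column]]
  } else as.numeric(column)
}

resolve_weight_arg <- function(data, weights) {
  w <- if (is.null(weights)) design_weights(data)
  else if (is.character(weights) && length(weights) == 1L) resolve_column(data, weights)
  else as.numeric(weights)
  if (any(!is.finite(w)) || any(w < 0)) stop_synthprev("weights must be nonnegative", "schema_error")
  w
}

#' Bootstrap standard error from replicate weights
#'
#' Recomputes a weighted statistic under every replicate-weight column and
#' returns `sqrt(mean((theta_b - theta_hat)^2))`, where `theta_hat` is the
#' full-sample estimate under the design weights — the mean-bootstrap
#' convention used with survey-agency replicate weights (deviations are taken
#' from the full-sample estimate, not from the replicate mean).
#'
#' @param statistic `function(data, weights)` returning a scalar (a
#'   `weighted_estimate` is also accepted and its `value` is used).
#' @param data a [survey_dataset()] with at least one `BSW*` column.
#' @return nonnegative scalar standard error.
#' @examples
#' cfg <- default_sim_config(n_per_area = 60, n_bootstrap = 50, seed = 7)
#' ds <- generate_population(cfg)
#' bootstrap_se(function(d, w) weighted_proportion(d, "perceived_need", w), ds)
#' @export
bootstrap_se <- function(statistic, data) {
  bsw <- bsw_columns(data)
  if (length(bsw) < 1L) stop_synthprev("dataset has no replicate-weight columns", "config_error")
  eval1 <- function(w) {
    out <- statistic(data, w)
    if (inherits(out, "weighted_estimate")) out <- out$value
    as.numeric(out)
  }
  theta_hat <- eval1(design_weights(data))
  theta_b <- vapply(bsw, function(cl) eval1(data[[cl]]), numeric(1))
  sqrt(mean((theta_b - theta_hat)^2))
}
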