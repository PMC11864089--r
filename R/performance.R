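#' Weighted concordance (C) statistic
#'
#' Probability-weighted concordance over all case-control pairs:
#' `sum(w_i w_j (1(p_i > p_j) + 0.5 * 1(p_i = p_j))) / sum(w_i w_j)` over
#' cases `i` and controls `j`, equal to the area under the weighted ROC
#' curve. Computed by a single sort with tie-group accumulation (O(n log n));
#' the result is exactly the pair-enumeration value.
#'
#' @param risk numeric vector of predicted risks (any monotone score works:
#'   the statistic is rank-based).
#' @param outcome 0/1 vector.
#' @param weights nonnegative weights; equal weights when `NULL`.
#' @return scalar in `[0, 1]`.
#' @export
c_statistic <- function(risk, outcome, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(risk))
  stopifnot(length(risk) == length(outcome), length(risk) == length(weights))
  keep <- !is.na(risk) & !is.na(outcome)
  risk <- risk[keep]; outcome <- outcome[keep]; weights <- weights[keep]
  if (!all(outcome %in% c(0, 1))) stop_synthprev("outcome must be 0/1", "schema_error")
  w1 <- sum(weights[outcome == 1]); w0 <- sum(weights[outcome == 0])
  if (w1 <= 0 || w0 <= 0) {
    stop_synthprev("C statistic undefined: only one outcome class present", "undefined_metric")
  }
  o <- order(risk)
  r <- risk[o]; y <- outcome[o]; w <- weights[o]
  n <- length(r)
  grp <- cumsum(c(TRUE, r[-1] != r[-n]))
  w1g <- rowsum(w * y, grp)[, 1]
  w0g <- rowsum(w * (1 - y), grp)[, 1]
  cum_w0_below <- c(0, cumsum(w0g)[-length(w0g)])
  num <- sum(w1g * (cum_w0_below + 0.5 * w0g))
  num / (w1 * w0)
}

#' Calibration slope
#'
#' Slope from a logistic regression of the outcome on the logit of the
#' predicted risk (intercept included). 1 indicates perfect calibration;
#' below 1 the risks are overconfident (too extreme), above 1 underconfident.
#'
#' @param risk predicted risks, strictly inside (0, 1), not all equal.
#' @param outcome 0/1 vector with both classes present.
#' @param weights optional weights (normalized internally).
#' @return scalar slope.
#' @export
calibration_slope <- function(risk, outcome, weights = NULL) {
  if (any(risk <= 0 | risk >= 1)) {
    stop_synthprev("risks must lie strictly inside (0, 1)", "undefined_slope")
  }
  if (stats::var(risk) == 0) {
    stop_synthprev("calibration slope undefined: all risks identical", "undefined_slope")
  }
  if (length(unique(outcome[!is.na(outcome)])) < 2L) {
    stop_synthprev("calibration slope undefined: single outcome class", "undefined_metric")
  }
  df <- data.frame(y = outcome, lp = stats::qlogis(risk))
  df$w <- if (is.null(weights)) 1 else weights / mean(weights)
  fit <- suppressWarnings(
    stats::glm(y ~ lp, family = stats::binomial(), data = df, weights = w,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  unname(stats::coef(fit)["lp"])
}

#' Decile calibration table
#'
#' Rows are assigned to 10 groups by weighted deciles of predicted risk
#' (rows sorted by risk, ties broken by row order; a row belongs to the
#' decile containing the midpoint of its weight interval). Per group the
#' table reports the weighted mean predicted risk, the weighted observed
#' event fraction, and the group's share of total weight.
#'
#' @param risk predicted risks (n >= 10).
#' @param outcome 0/1 vector.
#' @param weights optional weights.
#' @return data.frame with columns `decile`, `mean_predicted`,
#'   `observed_fraction`, `weight_share`, ordered by increasing risk.
#' @export
calibration_deciles <- function(risk, outcome, weights = NULL) {
  n <- length(risk)
  if (n < 10L) stop_synthprev("decile calibration needs n >= 10", "argument_error")
  if (is.null(weights)) weights <- rep(1, n)
  o <- order(risk)  # stable: ties keep row order
  r <- risk[o]; y <- outcome[o]; w <- weights[o]
  W <- sum(w)
  mid <- cumsum(w) - w / 2
  grp <- pmin(10L, pmax(1L, floor(10 * mid / W) + 1L))
  out <- data.frame(decile = 1:10, mean_predicted = NA_real_,
                    observed_fraction = NA_real_, weight_share = 0)
  for (g in unique(grp)) {
    idx <- grp == g
    wg <- sum(w[idx])
    out$mean_predicted[g] <- sum(w[idx] * r[idx]) / wg
    out$observed_fraction[g] <- sum(w[idx] * y[idx]) / wg
    out$weight_share[g] <- wg / W
  }
  out
}

#' Assess discrimination and calibration of a fitted model
#'
#' Computes population-average predicted risks on `data` and summarizes
#' discrimination (weighted C statistic) and calibration (calibration slope
#' and decile calibration table). Design weights are used by default; pass
#' `weighted = FALSE` for unweighted metrics.
#'
#' @param model an `mh_model`.
#' @param data evaluation dataset containing the outcome and all model terms.
#' @param weighted use design weights (default `TRUE`).
#' @param mode prediction mode, see [predict.mh_model()].
#' @return an object of class `mh_performance`: list with `c_statistic`,
#'   `calibration_slope`, `decile_table`, `n`.
#' @export
model_performance <- function(model, data, weighted = TRUE,
                              mode = "population_average") {
  risk <- predict(model, data, mode = mode)
  sp <- model$spec; sp$group <- NULL
  mf <- prepare_model_frame(data, sp)
  y <- mf[[model$spec$outcome]]
  w <- if (weighted) mf$.design_w else rep(1, nrow(mf))
  structure(list(
    c_statistic = c_statistic(risk, y, w),
    calibration_slope = calibration_slope(risk, y, w),
    decile_table = calibration_deciles(risk, y, w),
    n = length(y)
  ), class = "mh_performance")
}

#' @export
print.mh_performance <- function(x, ...) {
  cat(sprintf("C statistic        %.4f\n", x$c_statistic))
  cat(sprintf("Calibration slope  %.4f\n", x$calibration_slope))
  cat(sprintf("n = %d; decile calibration:\n", x$n))
  print(transform(x$decile_table,
                  mean_predicted = round(mean_predicted, 4),
                  observed_fraction = round(observed_fraction, 4),
                  weight_share = round(weight_share, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Decile calibration plot
#'
#' Observed event fraction against mean predicted risk per risk decile, with
#' the identity line of perfect calibration.
#'
#' @param x an `mh_performance`.
#' @param ... passed to [plot()].
#' @export
plot.mh_performance <- function(x, ...) {
  d <- x$decile_table
  lim <- range(c(d$mean_predicted, d$observed_fraction), na.rm = TRUE)
  plot(d$mean_predicted, d$observed_fraction, xlim = lim, ylim = lim,
       xlab = "Mean predicted risk (decile)", ylab = "Observed event fraction",
       pch = 19, ...)
  abline(0, 1, lty = 2)
  invisible(x)
}
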