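new_mh_model <- function(beta, sigma_u, blups, loglik, k, n_obs, cov_beta, spec,
                         boundary = FALSE, se_sigma_u = NA_real_,
                         removal_log = NULL) {
  structure(list(
    beta = beta, sigma_u = sigma_u, se_sigma_u = se_sigma_u, blups = blups,
    loglik = loglik, k = k,
    aic = -2 * loglik + 2 * k,
    bic = -2 * loglik + k * log(n_obs),
    n_obs = n_obs, cov_beta = cov_beta, spec = spec,
    boundary = boundary, removal_log = removal_log
  ), class = "mh_model")
}

#' Fit the individual-level logistic model
#'
#' `fit_logistic()` fits a plain binary logistic regression by iteratively
#' reweighted least squares (the random-intercept SD is fixed at 0 and the
#' information-criterion parameter count excludes a variance parameter).
#' `fit_random_intercept_logit()` fits the two-level model with a random
#' intercept for `spec$group`, maximizing the marginal likelihood by adaptive
#' Gauss-Hermite quadrature (`nAGQ` nodes; 1 node is the Laplace
#' approximation), and returns empirical-Bayes predicted intercepts (BLUPs)
#' per group. `fit_mh_model()` dispatches on whether the spec names a group.
#'
#' With `use_weights = TRUE` in the spec, design weights normalized to mean 1
#' enter as pseudo-likelihood weights; information criteria then refer to the
#' weighted pseudo-log-likelihood with `n_obs` the number of respondents.
#'
#' A fit where the random-intercept SD is driven to the boundary (0) is
#' returned with `boundary = TRUE`, not treated as an error. Perfect
#' separation and rank-deficient designs raise classed errors
#' (`fit_error`, `design_matrix_error`).
#'
#' @param data a [survey_dataset()] (any data.frame with a weight column).
#' @param spec a [model_spec()]; for `fit_logistic()` the group is ignored.
#' @param nAGQ number of adaptive Gauss-Hermite quadrature nodes.
#' @param se_sigma_u logical; also compute a standard error for the
#'   random-intercept SD from a numerical Hessian of the marginal deviance
#'   (slower; off by default).
#' @return an object of class `mh_model` with elements `beta` (named fixed
#'   effects), `sigma_u`, `blups`, `loglik`, `aic`, `bic`, `n_obs`,
#'   `cov_beta`, `spec`.
#' @examples
#' cfg <- default_sim_config(n_per_area = 150, seed = 1)
#' ds <- generate_population(cfg)
#' sp <- model_spec("perceived_need", c("sex", "srmh"), group = "area")
#' fit <- fit_mh_model(ds, sp)
#' coef(fit)
#' @export
fit_logistic <- function(data, spec) {
  spec$group <- NULL
  mf <- prepare_model_frame(data, spec)
  spec$dictionary <- attr(mf, "dictionary")
  f <- spec_formula(spec)
  warned_sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = mf, weights = .w,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        warned_sep <<- TRUE
      }
      if (grepl("numerically 0 or 1|non-integer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop_synthprev(paste("rank-deficient design; collinear term(s):",
                         paste(names(cf)[is.na(cf)], collapse = ", ")),
                   "design_matrix_error")
  }
  if (warned_sep && max(abs(cf)) > 10) {
    stop_synthprev(sprintf("separation detected (max |coef| = %.1f after %d IRLS iterations)",
                           max(abs(cf)), fit$iter), "fit_error")
  }
  if (!fit$converged) {
    stop_synthprev(sprintf("IRLS did not converge in %d iterations", fit$iter), "fit_error")
  }
  ll <- as.numeric(stats::logLik(fit))
  new_mh_model(beta = cf, sigma_u = 0, blups = NULL, loglik = ll,
               k = length(cf), n_obs = nrow(mf), cov_beta = stats::vcov(fit),
               spec = spec)
}

#' @rdname fit_logistic
#' @export
fit_random_intercept_logit <- function(data, spec, nAGQ = 9, se_sigma_u = FALSE) {
  if (is.null(spec$group)) stop_synthprev("spec has no grouping variable", "spec_error")
  mf <- prepare_model_frame(data, spec)
  spec$dictionary <- attr(mf, "dictionary")
  n_groups <- length(unique(mf[[spec$group]]))
  if (n_groups < 2L) stop_synthprev("random-intercept fit needs >= 2 groups", "spec_error")
  # starting values: sigma_u = 0 reference fit
  start_fit <- fit_logistic(data, spec)
  f <- spec_formula(spec, random = TRUE)
  fit <- withCallingHandlers(
    lme4::glmer(f, data = mf, family = stats::binomial(), nAGQ = nAGQ, weights = .w,
                start = list(theta = 0.1, fixef = start_fit$beta),
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w))) invokeRestart("muffleWarning")
    }
  )
  theta <- lme4::getME(fit, "theta")
  sigma_u <- unname(theta)
  re <- lme4::ranef(fit)[[spec$group]]
  blups <- stats::setNames(re[, 1], rownames(re))
  beta <- lme4::fixef(fit)
  k <- length(beta) + 1L
  ll <- as.numeric(stats::logLik(fit))
  se_su <- NA_real_
  if (isTRUE(se_sigma_u) && sigma_u > 1e-4) {
    se_su <- tryCatch({
      devfun <- suppressWarnings(
        lme4::glmer(f, data = mf, family = stats::binomial(), nAGQ = nAGQ,
                    weights = .w, devFunOnly = TRUE))
      sigma_u_se_numeric(devfun, unname(c(theta, beta)))
    }, error = function(e) NA_real_)
  }
  new_mh_model(beta = beta, sigma_u = sigma_u, blups = blups, loglik = ll,
               k = k, n_obs = nrow(mf), cov_beta = as.matrix(stats::vcov(fit)),
               spec = spec, boundary = sigma_u < 1e-4, se_sigma_u = se_su)
}

# SE of sigma_u from a numerical Hessian of the marginal deviance over
# (theta, beta); the observed information is half the deviance Hessian.
sigma_u_se_numeric <- function(devfun, pars) {
  H <- pracma::hessian(function(p) devfun(p) / 2, pars)
  V <- solve(H)
  sqrt(V[1, 1])
}

#' @rdname fit_logistic
#' @export
fit_mh_model <- function(data, spec, nAGQ = 9, se_sigma_u = FALSE) {
  if (is.null(spec$group)) fit_logistic(data, spec)
  else fit_random_intercept_logit(data, spec, nAGQ = nAGQ, se_sigma_u = se_sigma_u)
}

#' @export
print.mh_model <- function(x, ...) {
  cat("Individual-level logistic model:", x$spec$outcome, "~",
      if (length(x$spec$terms)) paste(x$spec$terms, collapse = " + ") else "1", "\n")
  if (!is.null(x$spec$group)) {
    cat(sprintf("Random intercept on %s: sigma_u = %.4f%s\n", x$spec$group, x$sigma_u,
                if (x$boundary) " (boundary)" else ""))
  }
  cat(sprintf("n = %d, logLik = %.2f, AIC = %.2f, BIC = %.2f\n",
              x$n_obs, x$loglik, x$aic, x$bic))
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.mh_model <- function(object, ...) object$beta

#' @export
vcov.mh_model <- function(object, ...) object$cov_beta

#' @export
logLik.mh_model <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = object$n_obs, class = "logLik")
}

#' @export
summary.mh_model <- function(object, ...) {
  se <- sqrt(diag(object$cov_beta))
  z <- object$beta / se
  tab <- cbind(Estimate = object$beta, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, sigma_u = object$sigma_u, model = object)
  class(out) <- "summary.mh_model"
  out
}

#' @export
print.summary.mh_model <- function(x, ...) {
  print(x$model)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' Predicted outcome probabilities
#'
#' Per-respondent risks `expit(eta)` under the fitted model.
#' `"population_average"` sets the random intercept to zero;
#' `"group_specific"` adds each group's empirical-Bayes BLUP (0 for groups
#' unseen at fitting time).
#'
#' @param object an `mh_model`.
#' @param newdata dataset containing every model term (and the group column
#'   for `mode = "group_specific"`).
#' @param mode `"population_average"` or `"group_specific"`.
#' @param type `"response"` (probability) or `"link"` (logit).
#' @param ... unused.
#' @return numeric vector, one value per (complete) row of `newdata`.
#' @export
predict.mh_model <- function(object, newdata,
                             mode = c("population_average", "group_specific"),
                             type = c("response", "link"), ...) {
  mode <- match.arg(mode)
  type <- match.arg(type)
  spec <- object$spec
  if (mode == "population_average") spec$group <- NULL  # group column not required
  mf <- prepare_model_frame(newdata, spec, require_outcome = FALSE)
  X <- stats::model.matrix(spec_formula(spec), mf)
  if (!all(names(object$beta) %in% colnames(X))) {
    stop_synthprev("newdata lacks columns for some model terms", "schema_error")
  }
  eta <- drop(X[, names(object$beta), drop = FALSE] %*% object$beta)
  if (mode == "group_specific" && !is.null(object$blups)) {
    g <- as.character(mf[[object$spec$group]])
    u <- object$blups[g]
    u[is.na(u)] <- 0
    eta <- eta + unname(u)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' @rdname predict.mh_model
#' @param model an `mh_model` (alias interface returning probabilities).
#' @param data dataset to score.
#' @export
predict_prob <- function(model, data, mode = c("population_average", "group_specific")) {
  predict(model, data, mode = match.arg(mode), type = "response")
}

#' Simulate outcomes from a fitted model
#'
#' Draws Bernoulli outcomes at the model's predicted probabilities, one column
#' per replicate.
#'
#' @param object an `mh_model`.
#' @param nsim number of replicate outcome vectors.
#' @param seed optional seed.
#' @param newdata dataset to simulate for.
#' @param mode prediction mode passed to [predict.mh_model()].
#' @param ... unused.
#' @return data.frame with `nsim` 0/1 columns.
#' @export
simulate.mh_model <- function(object, nsim = 1, seed = NULL, newdata,
                              mode = "population_average", ...) {
  p <- predict(object, newdata, mode = mode)
  with_seed(seed, {
    out <- replicate(nsim, stats::rbinom(length(p), 1L, p))
    as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  })
}
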