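#' Serialize a fitted model to JSON
#'
#' Writes coefficients, random-intercept SD, BLUPs, fit statistics, the
#' fixed-effect covariance matrix, the model spec (including the variable
#' dictionary, so deserialized models can score new datasets with identical
#' dummy coding), and the backward-selection removal log.
#'
#' @param model an `mh_model`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    beta = as.list(model$beta),
    sigma_u = model$sigma_u,
    se_sigma_u = model$se_sigma_u,
    blups = as.list(model$blups %||% stats::setNames(numeric(0), character(0))),
    loglik = model$loglik, k = model$k, aic = model$aic, bic = model$bic,
    n_obs = model$n_obs,
    boundary = model$boundary,
    cov_beta = list(names = colnames(model$cov_beta),
                    values = unname(as.vector(model$cov_beta))),
    spec = list(outcome = model$spec$outcome, terms = model$spec$terms,
                group = model$spec$group, use_weights = model$spec$use_weights,
                dictionary = model$spec$dictionary),
    removal_log = model$removal_log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(p$beta)
  d <- length(p$cov_beta$names)
  cov_beta <- matrix(p$cov_beta$values, d, d,
                     dimnames = list(p$cov_beta$names, p$cov_beta$names))
  dict <- lapply(p$spec$dictionary, function(e) {
    out <- list(type = e$type)
    if (!is.null(e$levels)) out$levels <- as.character(e$levels)
    if (!is.null(e$reference)) out$reference <- as.character(e$reference)
    out
  })
  spec <- model_spec(p$spec$outcome, p$spec$terms, group = p$spec$group,
                     use_weights = isTRUE(p$spec$use_weights))
  spec$dictionary <- dict
  blups <- if (length(p$blups)) unlist(p$blups) else NULL
  m <- new_mh_model(beta = beta, sigma_u = p$sigma_u, blups = blups,
                    loglik = p$loglik, k = p$k, n_obs = p$n_obs,
                    cov_beta = cov_beta, spec = spec,
                    boundary = isTRUE(p$boundary),
                    se_sigma_u = p$se_sigma_u %||% NA_real_)
  if (!is.null(p$removal_log) && length(p$removal_log)) {
    m$removal_log <- as.data.frame(p$removal_log)
  }
  m
}
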