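#' Backward elimination on an information criterion
#'
#' Starting from the full model, repeatedly refits the model with each single
#' term removed (categorical variables leave as whole blocks of dummies),
#' removes the term whose removal most decreases the chosen criterion, and
#' stops when no removal decreases it. When two removals are tied within
#' 1e-9, the term occurring later in `spec$terms` is removed. The returned
#' model carries an ordered `removal_log` (term, criterion before/after per
#' step).
#'
#' @param data a [survey_dataset()].
#' @param spec the full [model_spec()]; must fit successfully.
#' @param criterion `"aic"` or `"bic"`.
#' @param nAGQ quadrature nodes for random-intercept fits.
#' @return the final refitted `mh_model` with a `removal_log` data.frame.
#' @export
backward_select <- function(data, spec, criterion = c("aic", "bic"), nAGQ = 9) {
  criterion <- match.arg(criterion)
  current <- fit_mh_model(data, spec, nAGQ = nAGQ)
  log_rows <- list()
  repeat {
    terms <- current$spec$terms
    if (!length(terms)) break
    crit_now <- current[[criterion]]
    cand <- vector("list", length(terms))
    crit_vals <- rep(NA_real_, length(terms))
    for (i in seq_along(terms)) {
      sp_i <- current$spec
      sp_i$terms <- terms[-i]
      fit_i <- tryCatch(fit_mh_model(data, sp_i, nAGQ = nAGQ), error = function(e) NULL)
      if (!is.null(fit_i)) {
        cand[[i]] <- fit_i
        crit_vals[i] <- fit_i[[criterion]]
      }
    }
    if (all(is.na(crit_vals))) break
    best <- min(crit_vals, na.rm = TRUE)
    if (!(best < crit_now)) break
    pick <- max(which(!is.na(crit_vals) & crit_vals <= best + 1e-9))  # later term wins ties
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = length(log_rows) + 1L, removed = terms[pick],
      criterion = criterion, before = crit_now, after = crit_vals[pick],
      stringsAsFactors = FALSE)
    current <- cand[[pick]]
  }
  current$removal_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(step = integer(), removed = character(), criterion = character(),
               before = numeric(), after = numeric(), stringsAsFactors = FALSE)
  current
}
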