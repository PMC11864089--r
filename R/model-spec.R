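#' Declare an individual-level prediction model
#'
#' A `model_spec` names the binary outcome, the ordered fixed-effect terms
#' (variable names; interactions as `"a:b"`), the optional grouping variable
#' for an area-level random intercept, and whether fitting should use the
#' survey design weights (normalized to mean 1) as pseudo-likelihood weights.
#' Categorical terms are dummy-coded against a reference level taken from the
#' dataset's variable dictionary (first level when the dictionary is silent).
#'
#' @param outcome name of a 0/1 outcome column.
#' @param terms character vector of fixed-effect terms, in order.
#' @param group name of the random-intercept grouping column (usually the
#'   health-region id), or `NULL` for a plain logistic model.
#' @param use_weights logical; fit with normalized design weights.
#' @return an object of class `mh_model_spec`.
#' @export
model_spec <- function(outcome, terms, group = NULL, use_weights = FALSE) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop_synthprev("duplicated model terms", "spec_error")
  structure(list(outcome = outcome, terms = terms, group = group,
                 use_weights = isTRUE(use_weights), dictionary = NULL),
            class = "mh_model_spec")
}

#' @export
print.mh_model_spec <- function(x, ...) {
  cat("model spec:", x$outcome, "~", paste(x$terms, collapse = " + "))
  if (!is.null(x$group)) cat(" + (1 |", x$group, ")")
  cat(if (x$use_weights) "  [weighted]\n" else "\n")
  invisible(x)
}

spec_variables <- function(spec) unique(unlist(strsplit(spec$terms, ":", fixed = TRUE)))

spec_formula <- function(spec, random = FALSE) {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  if (random) rhs <- paste0(rhs, " + (1 | ", spec$group, ")")
  stats::as.formula(paste(spec$outcome, "~", rhs), env = globalenv())
}

# Resolve the dictionary entries the spec needs, preferring an explicit
# dictionary already attached to the spec (a refitted or deserialized model),
# then the dataset's own dictionary, then the data itself.
resolve_dictionary <- function(data, spec) {
  if (!is.null(spec$dictionary)) return(spec$dictionary)
  dict <- dataset_dictionary(data)
  out <- list()
  for (v in spec_variables(spec)) {
    e <- dict[[v]]
    if (is.null(e) || is.null(e$type) || identical(e$type, "outcome")) {
      x <- data[[v]]
      e <- if (is.numeric(x)) list(type = "continuous") else {
        lv <- sort(unique(as.character(x[!is.na(x)])))
        list(type = "categorical", levels = lv, reference = lv[1])
      }
    }
    out[[v]] <- e
  }
  out
}

# Build the model frame: outcome, releveled factor predictors, group, weights.
# Rows with missing model variables are dropped with a message.
prepare_model_frame <- function(data, spec, require_outcome = TRUE) {
  vars <- spec_variables(spec)
  has_outcome <- spec$outcome %in% names(data)
  if (require_outcome && !has_outcome) {
    stop_synthprev(sprintf("missing outcome column '%s'", spec$outcome), "schema_error")
  }
  need <- c(if (has_outcome) spec$outcome, vars, spec$group)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop_synthprev(paste("missing model column(s):", paste(missing_cols, collapse = ", ")),
                   "schema_error")
  }
  dict <- resolve_dictionary(data, spec)
  mf <- as.data.frame(data)[need]
  for (v in vars) {
    e <- dict[[v]]
    if (identical(e$type, "categorical")) {
      lv <- c(e$reference, setdiff(e$levels, e$reference))
      mf[[v]] <- factor(as.character(mf[[v]]), levels = lv)
    }
  }
  if (has_outcome) {
    y <- mf[[spec$outcome]]
    if (!all(y %in% c(0, 1) | is.na(y))) {
      stop_synthprev(sprintf("outcome '%s' is not binary 0/1", spec$outcome), "spec_error")
    }
  }
  wc <- attr(data, "weight_col") %||% "weight"
  w <- if (wc %in% names(data)) data[[wc]] else rep(1, nrow(mf))
  keep <- stats::complete.cases(mf)
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing model variables dropped")
    mf <- mf[keep, , drop = FALSE]
    w <- w[keep]
  }
  if (!nrow(mf)) stop_synthprev("no complete rows to fit on", "estimation_error")
  mf$.w <- if (spec$use_weights) w / mean(w) else rep(1, nrow(mf))
  mf$.design_w <- w
  attr(mf, "dictionary") <- dict
  mf
}

# Fixed-effect design matrix under the spec's coding (dictionary attached to
# the spec or resolved from the data). Shared by fitting, prediction and area
# profiling so coefficient names always align.
spec_model_matrix <- function(data, spec) {
  mf <- prepare_model_frame(data, spec)
  X <- stats::model.matrix(spec_formula(spec), mf)
  attr(X, "weights") <- mf$.design_w
  attr(X, "outcome") <- mf[[spec$outcome]]
  X
}
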