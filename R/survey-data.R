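#' Survey microdata containers
#'
#' A `survey_dataset` is a plain `data.frame` of respondent records carrying a
#' few attributes: a variable dictionary (`dictionary`), the name of the
#' design-weight column (`weight_col`, default `"weight"`), and the prefix of
#' the bootstrap replicate-weight columns (`bsw_prefix`, default `"BSW"`).
#' One row is one respondent; area nesting is encoded by an `area` (health
#' region) and a `province` column, with every area belonging to exactly one
#' province.
#'
#' The dictionary is a named list, one entry per variable, each a list with
#' `type` (`"categorical"` or `"continuous"`) and, for categorical variables,
#' `levels` and `reference`. It travels with the data so that model fitting
#' and area profiling use identical dummy coding everywhere, including for
#' levels absent from a subset.
#'
#' @param data data.frame of respondent records.
#' @param dictionary variable dictionary (see Details); inferred from factor
#'   and character columns when omitted.
#' @param weight_col name of the design-weight column.
#' @param bsw_prefix prefix of replicate-weight columns (`BSW1`, `BSW2`, ...).
#' @return `data` with class `survey_dataset` prepended and the attributes set.
#' @export
survey_dataset <- function(data, dictionary = NULL, weight_col = "weight",
                           bsw_prefix = "BSW") {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(dictionary)) dictionary <- infer_dictionary(data, weight_col, bsw_prefix)
  attr(data, "dictionary") <- dictionary
  attr(data, "weight_col") <- weight_col
  attr(data, "bsw_prefix") <- bsw_prefix
  class(data) <- unique(c("survey_dataset", class(data)))
  validate_survey_dataset(data)
  data
}

infer_dictionary <- function(data, weight_col = "weight", bsw_prefix = "BSW") {
  skip <- c(weight_col, grep(paste0("^", bsw_prefix, "[0-9]+$"), names(data), value = TRUE),
            "respondent_id", "cluster")
  dict <- list()
  for (nm in setdiff(names(data), skip)) {
    x <- data[[nm]]
    if (is.numeric(x) && !all(x %in% c(0, 1, NA))) {
      dict[[nm]] <- list(type = "continuous")
    } else if (is.factor(x)) {
      dict[[nm]] <- list(type = "categorical", levels = levels(x), reference = levels(x)[1])
    } else if (is.character(x)) {
      lv <- sort(unique(x[!is.na(x)]))
      dict[[nm]] <- list(type = "categorical", levels = lv, reference = lv[1])
    } else {
      dict[[nm]] <- list(type = "continuous")  # 0/1 numeric: outcome or indicator
    }
  }
  dict
}

validate_survey_dataset <- function(x) {
  wc <- attr(x, "weight_col")
  if (!wc %in% names(x)) stop_synthprev(sprintf("missing weight column '%s'", wc), "schema_error")
  if (any(!is.finite(x[[wc]])) || any(x[[wc]] <= 0)) {
    stop_synthprev("all design weights must be positive and finite", "schema_error")
  }
  if (all(c("area", "province") %in% names(x))) {
    map <- unique(x[, c("area", "province")])
    if (anyDuplicated(map$area)) {
      stop_synthprev("an area id maps to more than one province", "schema_error")
    }
  }
  bsw <- bsw_columns(x)
  if (length(bsw)) {
    bw <- as.matrix(x[bsw])
    if (any(!is.finite(bw)) || any(bw < 0)) {
      stop_synthprev("replicate weights must be nonnegative and finite", "schema_error")
    }
  }
  invisible(x)
}

#' Replicate-weight column names of a survey dataset
#' @param x a `survey_dataset` (or any data.frame with `BSW*` columns).
#' @return character vector, ordered `BSW1`, `BSW2`, ...
#' @export
bsw_columns <- function(x) {
  prefix <- attr(x, "bsw_prefix") %||% "BSW"
  cols <- grep(paste0("^", prefix, "[0-9]+$"), names(x), value = TRUE)
  if (!length(cols)) return(character(0))
  cols[order(as.integer(sub(paste0("^", prefix), "", cols)))]
}

design_weights <- function(x) {
  wc <- attr(x, "weight_col") %||% "weight"
  if (!wc %in% names(x)) stop_synthprev(sprintf("missing weight column '%s'", wc), "schema_error")
  x[[wc]]
}

dataset_dictionary <- function(x) attr(x, "dictionary") %||% infer_dictionary(as.data.frame(x))

#' Write / read survey microdata as CSV plus a JSON variable dictionary
#'
#' `write_survey()` writes `<prefix>.csv` (one row per respondent, replicate
#' weights as `BSW1..BSWk`) and `<prefix>.dict.json` (column name to type,
#' levels, reference level). `read_survey()` reverses it. Serialization is
#' deterministic: identical datasets produce byte-identical files.
#'
#' @param x a `survey_dataset`.
#' @param prefix path prefix (without extension).
#' @return `write_survey()` the prefix, invisibly; `read_survey()` a
#'   `survey_dataset`.
#' @export
write_survey <- function(x, prefix) {
  utils::write.csv(as.data.frame(x), paste0(prefix, ".csv"), row.names = FALSE, quote = FALSE)
  meta <- list(
    dictionary = dataset_dictionary(x),
    weight_col = attr(x, "weight_col") %||% "weight",
    bsw_prefix = attr(x, "bsw_prefix") %||% "BSW"
  )
  jsonlite::write_json(meta, paste0(prefix, ".dict.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_survey
#' @export
read_survey <- function(prefix) {
  df <- utils::read.csv(paste0(prefix, ".csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(prefix, ".dict.json"), simplifyVector = TRUE)
  dict <- lapply(meta$dictionary, function(e) {
    out <- list(type = e$type)
    if (!is.null(e$levels)) out$levels <- as.character(e$levels)
    if (!is.null(e$reference)) out$reference <- as.character(e$reference)
    out
  })
  survey_dataset(df, dictionary = dict, weight_col = meta$weight_col,
                 bsw_prefix = meta$bsw_prefix)
}
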