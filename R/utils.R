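#' Inverse logit
#'
#' `expit(x) = 1 / (1 + exp(-x))`, the inverse of [logit()]. Thin wrappers
#' around [stats::plogis()] / [stats::qlogis()], exported because the
#' logit/expit pair is the vocabulary of synthetic estimation.
#'
#' @param x numeric vector (log-odds for `expit`, probabilities for `logit`).
#' @return numeric vector of the same length.
#' @export
expit <- function(x) stats::plogis(x)

#' @rdname expit
#' @export
logit <- function(x) stats::qlogis(x)

# Derive a sub-seed from a master seed and an offset label/number, keeping the
# result a valid 32-bit integer. Used so that every stage of a run consumes an
# independent, reproducible stream.
derive_seed <- function(seed, offset) {
  if (is.character(offset)) offset <- sum(utf8ToInt(offset)) %% 100000L
  as.integer((as.double(seed) * 1009 + as.double(offset)) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_synthprev <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "synthprev_error")))
}
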