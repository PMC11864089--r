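# Small simulation configurations shared across the suite.

# A minimal two-predictor config: `k` regions in one or two provinces, shared
# covariate distributions, optional region-level overrides.
tiny_config <- function(n = c(100, 200, 300), sd = 0, beta = NULL,
                        n_bootstrap = 0, provinces = NULL) {
  k <- length(n)
  provinces <- provinces %||% rep("P1", k)
  regions <- lapply(seq_len(k), function(i) {
    list(area = paste0("A", i), province = provinces[i], n = n[i])
  })
  preds <- list(
    x = list(type = "categorical", levels = c("a", "b"), reference = "a",
             probs = c(0.6, 0.4)),
    z = list(type = "continuous", mean = 0, sd = 1)
  )
  beta <- beta %||% c("(Intercept)" = -1, xb = 0.8, z = 0.5)
  sim_config(regions = regions, predictors = preds, coefficients = beta,
             random_intercept_sd = sd, n_bootstrap = n_bootstrap,
             outcome = "y")
}

# Intercept-only config (no predictors in the linear predictor, but one dummy
# categorical so the dataset still has a predictor column).
intercept_config <- function(n, b0 = 0, sd = 0, k = 1, provinces = NULL) {
  n <- rep(n, length.out = k)
  tiny_config(n = n, sd = sd, beta = c("(Intercept)" = b0),
              provinces = provinces)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Equal-weight survey dataset from bare vectors (for metric-level tests).
metric_data <- function(y, w = rep(1, length(y))) {
  survey_dataset(data.frame(y = y, weight = w))
}

# Brute-force weighted concordance over all case-control pairs: the
# independent oracle for c_statistic().
c_statistic_bruteforce <- function(risk, outcome, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(risk))
  cases <- which(outcome == 1)
  controls <- which(outcome == 0)
  num <- 0
  den <- 0
  for (i in cases) for (j in controls) {
    ww <- weights[i] * weights[j]
    num <- num + ww * ((risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j]))
    den <- den + ww
  }
  num / den
}

# Within-area homogeneous covariates: one 10-level factor, each area fully in
# its own level, so every respondent of an area shares one covariate pattern.
homog_config <- function(n_per_area = 2000, k = 10, b0 = -1.8,
                         effects = seq(-0.6, 1.2, length.out = k - 1)) {
  levels <- paste0("L", seq_len(k))
  regions <- lapply(seq_len(k), function(i) {
    probs <- rep(0, k); probs[i] <- 1
    list(area = paste0("A", i), province = if (i <= k / 2) "P1" else "P2",
         n = n_per_area, predictors = list(ses = list(probs = probs)))
  })
  beta <- c(b0, effects)
  names(beta) <- c("(Intercept)", paste0("ses", levels[-1]))
  sim_config(
    regions = regions,
    predictors = list(ses = list(type = "categorical", levels = levels,
                                 reference = levels[1], probs = rep(1 / k, k))),
    coefficients = beta, outcome = "y")
}

# True area prevalences implied by homog_config.
homog_truth <- function(cfg) {
  beta <- cfg$coefficients[[1]]
  vapply(seq_along(cfg$regions), function(i) {
    eff <- if (i == 1) 0 else beta[[paste0("sesL", i)]]
    plogis(beta[["(Intercept)"]] + eff)
  }, numeric(1))
}
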