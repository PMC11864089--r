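#' Default national-scale simulation configuration
#'
#' A ready-made [sim_config()] emulating an annual national health survey:
#' ten provinces grouped into Atlantic (NL, PE, NS, NB), Central (ON, QC) and
#' Western (MB, SK, AB, BC) regions, 29 health regions, and the common
#' predictor block of perceived-need models — sex, age group, self-reported
#' mental health, diagnosed mood/anxiety disorder, self-reported life stress
#' and life satisfaction — as categorical variables. Two binary outcomes are
#' generated (`perceived_need`, `unmet_need`) with true log-odds coefficients
#' chosen to give national prevalences near 18% and 3.9% and good individual
#' discrimination, and with modest province-level differences in the
#' distributions of mental-health status and stress so that area prevalences
#' genuinely differ.
#'
#' @param n_per_area respondents per health region (default 1000, about
#'   29,000 nationally — a desk-scale stand-in for a 65,000-person survey).
#' @param random_intercept_sd SD of the area random intercept (log-odds);
#'   default 0.25.
#' @param n_bootstrap replicate weights to attach (default 0).
#' @param seed default seed stored in the config.
#' @return a `sim_config`.
#' @export
default_sim_config <- function(n_per_area = 1000, random_intercept_sd = 0.25,
                               n_bootstrap = 0, seed = NULL) {
  provinces <- list(
    NL = list(n_areas = 2, srmh = c(0.73, 0.20, 0.07), stress = 0.26, mood = 0.10),
    PE = list(n_areas = 1, srmh = c(0.72, 0.21, 0.07), stress = 0.27, mood = 0.11),
    NS = list(n_areas = 2, srmh = c(0.66, 0.24, 0.10), stress = 0.30, mood = 0.14),
    NB = list(n_areas = 2, srmh = c(0.68, 0.23, 0.09), stress = 0.29, mood = 0.13),
    ON = list(n_areas = 6, srmh = c(0.70, 0.22, 0.08), stress = 0.29, mood = 0.12),
    QC = list(n_areas = 5, srmh = c(0.72, 0.21, 0.07), stress = 0.26, mood = 0.11),
    MB = list(n_areas = 2, srmh = c(0.68, 0.23, 0.09), stress = 0.29, mood = 0.13),
    SK = list(n_areas = 2, srmh = c(0.66, 0.24, 0.10), stress = 0.30, mood = 0.13),
    AB = list(n_areas = 3, srmh = c(0.67, 0.24, 0.09), stress = 0.31, mood = 0.13),
    BC = list(n_areas = 4, srmh = c(0.70, 0.22, 0.08), stress = 0.28, mood = 0.12)
  )
  regions <- list()
  for (pv in names(provinces)) {
    info <- provinces[[pv]]
    for (k in seq_len(info$n_areas)) {
      regions[[length(regions) + 1L]] <- list(
        area = sprintf("%s%02d", pv, k),
        province = pv,
        n = n_per_area,
        predictors = list(
          srmh = list(probs = info$srmh),
          life_stress = list(probs = c(1 - info$stress, info$stress)),
          mood_anx = list(probs = c(1 - info$mood, info$mood))
        )
      )
    }
  }
  predictors <- list(
    sex = list(type = "categorical", levels = c("male", "female"),
               reference = "male", probs = c(0.494, 0.506)),
    age_group = list(type = "categorical",
                     levels = c("a12to29", "a30to49", "a50to64", "a65plus"),
                     reference = "a12to29", probs = c(0.25, 0.33, 0.25, 0.17)),
    srmh = list(type = "categorical", levels = c("good", "fair", "poor"),
                reference = "good", probs = c(0.70, 0.22, 0.08)),
    mood_anx = list(type = "categorical", levels = c("no", "yes"),
                    reference = "no", probs = c(0.88, 0.12)),
    life_stress = list(type = "categorical", levels = c("low", "high"),
                       reference = "low", probs = c(0.72, 0.28)),
    life_sat = list(type = "categorical", levels = c("satisfied", "dissatisfied"),
                    reference = "satisfied", probs = c(0.90, 0.10))
  )
  coefficients <- list(
    perceived_need = c(
      "(Intercept)" = -2.546, sexfemale = 0.35,
      age_groupa30to49 = 0.05, age_groupa50to64 = -0.25, age_groupa65plus = -0.60,
      srmhfair = 1.10, srmhpoor = 1.90, mood_anxyes = 1.30,
      life_stresshigh = 0.55, life_satdissatisfied = 0.70
    ),
    unmet_need = c(
      "(Intercept)" = -4.203, sexfemale = 0.40,
      age_groupa30to49 = -0.10, age_groupa50to64 = -0.50, age_groupa65plus = -1.00,
      srmhfair = 1.00, srmhpoor = 1.80, mood_anxyes = 1.00,
      life_stresshigh = 0.60, life_satdissatisfied = 0.90
    )
  )
  sim_config(regions = regions, predictors = predictors,
             coefficients = coefficients,
             random_intercept_sd = random_intercept_sd,
             n_bootstrap = n_bootstrap, seed = seed)
}
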