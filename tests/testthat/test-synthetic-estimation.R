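make_fit <- function(beta, outcome = "y", terms = "x", dict = NULL) {
  spec <- model_spec(outcome, terms)
  spec$dictionary <- dict %||% list(
    x = list(type = "categorical", levels = c("a", "b"), reference = "a"))
  new_mh_model <- getFromNamespace("new_mh_model", "synthprev")
  new_mh_model(beta = beta, sigma_u = 0, blups = NULL, loglik = 0,
               k = length(beta), n_obs = 1,
               cov_beta = diag(length(beta)), spec = spec)
}

test_that("area profiles are weighted level proportions that partition to one", {
  d <- survey_dataset(data.frame(
    area = "A1", province = "P1",
    x = c("b", "b", "a", "a"), y = c(1, 0, 1, 0), weight = rep(1, 4)),
    dictionary = list(x = list(type = "categorical", levels = c("a", "b"),
                               reference = "a"),
                      y = list(type = "outcome")))
  prof <- area_profile(d, model_spec("y", "x"), area = "A1")
  expect_equal(unname(prof$term_values[["xb"]]), 0.5)
  expect_equal(prof$n_respondents, 4)

  # all respondents in the reference level -> all categorical term values 0
  d0 <- survey_dataset(data.frame(area = "A1", province = "P1",
                                  x = rep("a", 5), y = rbinom(5, 1, 0.5),
                                  weight = 1),
                       dictionary = attr(d, "dictionary"))
  prof0 <- area_profile(d0, model_spec("y", "x"), area = "A1")
  expect_equal(unname(prof0$term_values[["xb"]]), 0)

  # level proportions plus the implicit reference share sum to 1
  cfg <- tiny_config(n = 500)
  ds <- generate_population(cfg, seed = 51)
  prof2 <- area_profile(ds, model_spec("y", "x"), area = "A1")
  ref_share <- sum(ds$weight[ds$x == "a"]) / sum(ds$weight)
  expect_equal(unname(prof2$term_values[["xb"]]) + ref_share, 1, tolerance = 1e-9)

  expect_error(area_profile(ds, model_spec("y", "x"), area = "NOPE"),
               class = "estimation_error")
})

test_that("synthetic logit and estimate follow the closed-form chain", {
  fit <- make_fit(c("(Intercept)" = -2, xb = 1))
  prof <- structure(list(area = "A", term_values = c(xb = 0.5),
                         n_respondents = 10, weight_total = 10),
                    class = "area_profile")
  expect_equal(synthetic_logit(fit, prof), -1.5)
  expect_equal(synthetic_estimate(fit, prof), 100 * plogis(-1.5))
  expect_equal(synthetic_estimate(fit, prof), 18.2426, tolerance = 1e-4)

  io <- make_fit(c("(Intercept)" = logit(0.18)), terms = character(0),
                 dict = list())
  prof0 <- structure(list(area = "A", term_values = numeric(0)),
                     class = "area_profile")
  expect_equal(synthetic_logit(io, prof0), logit(0.18))
  expect_equal(synthetic_estimate(io, prof0), 18)

  # zero profile returns the intercept
  profz <- structure(list(area = "A", term_values = c(xb = 0)),
                     class = "area_profile")
  expect_equal(synthetic_logit(fit, profz), -2)

  # missing term -> schema error
  prof_bad <- structure(list(area = "A", term_values = c(other = 1)),
                        class = "area_profile")
  expect_error(synthetic_logit(fit, prof_bad), class = "schema_error")
})

test_that("synthetic estimates are bounded and monotone in positive terms", {
  fit <- make_fit(c("(Intercept)" = -2, xb = 1))
  prof <- function(v) structure(list(area = "A", term_values = c(xb = v)),
                                class = "area_profile")
  vals <- vapply(seq(0, 1, by = 0.1), function(v) synthetic_estimate(fit, prof(v)),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals > 0 & vals < 100))
})

test_that("individual aggregation equals the synthetic estimate only under homogeneity", {
  # two-pattern area: eta in {-2, 0} with equal weight
  d <- survey_dataset(data.frame(
    area = "A1", province = "P1",
    x = c("a", "b"), y = c(0, 1), weight = c(1, 1)),
    dictionary = list(x = list(type = "categorical", levels = c("a", "b"),
                               reference = "a"),
                      y = list(type = "outcome")))
  fit <- make_fit(c("(Intercept)" = -2, xb = 2))
  ia <- individual_aggregation_estimate(fit, d, area = "A1")
  expect_equal(ia, 100 * (plogis(-2) + plogis(0)) / 2, tolerance = 1e-9)
  expect_equal(ia, 30.96, tolerance = 0.005)
  synth <- synthetic_estimate(fit, area_profile(d, fit$spec, area = "A1"))
  expect_equal(synth, 100 * plogis(-1), tolerance = 1e-9)
  expect_equal(synth, 26.89, tolerance = 0.005)

  # homogeneous covariate pattern: the two estimators agree to 1e-9
  dh <- survey_dataset(data.frame(
    area = "A1", province = "P1",
    x = rep("b", 6), y = rbinom(6, 1, 0.5), weight = runif(6, 0.5, 2)),
    dictionary = attr(d, "dictionary"))
  expect_equal(individual_aggregation_estimate(fit, dh, area = "A1"),
               synthetic_estimate(fit, area_profile(dh, fit$spec, area = "A1")),
               tolerance = 1e-9)

  # zero slopes: both collapse to the intercept prevalence
  fit0 <- make_fit(c("(Intercept)" = -1, xb = 0))
  expect_equal(individual_aggregation_estimate(fit0, d, area = "A1"),
               100 * plogis(-1), tolerance = 1e-12)
})

test_that("the signed difference reproduces published worked examples", {
  ref <- province_reference_table()
  pick <- function(pv, oc, yr) ref[ref$province == pv & ref$outcome == oc &
                                     ref$year == yr, ]
  sk <- pick("SK", "perceived_need", 2018)
  expect_equal(absolute_difference(sk$predicted_pct, sk$observed_pct), 3.37,
               tolerance = 1e-9)
  nl <- pick("NL", "perceived_need", 2020)
  expect_equal(absolute_difference(nl$predicted_pct, nl$observed_pct), -4.16,
               tolerance = 1e-9)
  expect_equal(absolute_difference(14.57, 14.9), -0.33, tolerance = 1e-9)
  expect_equal(absolute_difference(5, 5), 0)
})

test_that("intercept-only weighted fit validates to zero difference on its own area", {
  cfg <- intercept_config(n = 1500, b0 = -1.2)
  ds <- generate_population(cfg, seed = 52)
  fit <- fit_logistic(ds, model_spec("y", character(0), use_weights = TRUE))
  val <- validate_model(fit, ds, by = "province", label = "dev")
  expect_equal(val$difference_pct, 0, tolerance = 1e-6)
  expect_equal(val$observed_pct, weighted_proportion(ds, "y")$value,
               tolerance = 1e-9)
})

test_that("synthetic estimation recovers area prevalences under within-area homogeneity", {
  cfg <- homog_config(n_per_area = 2000)
  ds <- generate_population(cfg, seed = 53)
  fit <- fit_logistic(ds, model_spec("y", "ses", use_weights = TRUE))
  val <- validate_model(fit, ds, by = "area", label = "dev")
  expect_equal(nrow(val), 10)
  # observed vs synthetic predicted: both reproduce the weighted cell mean
  expect_lt(max(abs(val$difference_pct)), 1)
  # and the synthetic estimates recover the true prevalences
  truth <- 100 * homog_truth(cfg)
  mc_se <- 100 * sqrt(truth / 100 * (1 - truth / 100) / 2000)
  val <- val[order(as.integer(sub("A", "", val$area))), ]
  hits <- sum(abs(val$predicted_pct - truth) <= 3 * mc_se)
  expect_gte(hits, 9)
})

test_that("under heterogeneity the aggregation oracle beats the marginal estimator", {
  cfg <- tiny_config(n = c(10000, 10000), provinces = c("P1", "P1"),
                     beta = c("(Intercept)" = -2.5, xb = 2.2, z = 0.9))
  ds <- generate_population(cfg, seed = 54)
  fit <- fit_logistic(ds, model_spec("y", c("x", "z"), use_weights = TRUE))
  synth <- validate_model(fit, ds, by = "province", label = "dev")
  ia <- validate_model(fit, ds, by = "province", label = "dev",
                       estimator = "individual")
  # the two estimators genuinely differ...
  expect_gt(abs(synth$predicted_pct - ia$predicted_pct), 0.5)
  # ...the oracle tracks the observed proportion within Monte-Carlo error...
  p <- ia$observed_pct / 100
  mc <- 100 * sqrt(p * (1 - p) / nrow(ds))
  expect_lt(abs(ia$difference_pct), 3 * mc)
  # ...and the marginal synthetic estimator carries the Jensen gap
  expect_gt(abs(synth$difference_pct), abs(ia$difference_pct))
})

test_that("validation rounding keeps printed columns self-consistent", {
  cfg <- tiny_config(n = c(400, 400), provinces = c("P1", "P2"))
  ds <- generate_population(cfg, seed = 55)
  fit <- fit_logistic(ds, model_spec("y", c("x", "z")))
  val <- validate_model(fit, ds, by = "province", label = "dev")
  path <- file.path(tempdir(), "val.csv")
  out <- write_validation(val, path)
  re <- utils::read.csv(path)
  expect_equal(re$difference_pct, round(re$predicted_pct - re$observed_pct, 2),
               tolerance = 1e-9)
  expect_equal(out$difference_pct, re$difference_pct, tolerance = 1e-9)
})

test_that("bootstrap SEs attach to observed and predicted proportions", {
  cfg <- tiny_config(n = c(600, 600), provinces = c("P1", "P2"),
                     n_bootstrap = 60, sd = 0)
  ds <- generate_population(cfg, seed = 56)
  fit <- fit_logistic(ds, model_spec("y", c("x", "z")))
  val <- validate_model(fit, ds, by = "province", label = "dev", bootstrap = TRUE)
  expect_true(all(is.finite(val$observed_se)))
  expect_true(all(is.finite(val$predicted_se)))
  expect_true(all(val$observed_se > 0))
  # the synthetic estimate averages over the area, so it is the stabler one
  expect_true(all(val$predicted_se < val$observed_se))
})
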