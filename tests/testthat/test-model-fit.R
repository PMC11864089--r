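test_that("intercept-only logistic recovers logit of the outcome mean", {
  cfg <- intercept_config(n = 800, b0 = -0.7)
  ds <- generate_population(cfg, seed = 21)
  fit <- fit_logistic(ds, model_spec("y", character(0)))
  expect_equal(unname(fit$beta[["(Intercept)"]]), logit(mean(ds$y)),
               tolerance = 1e-6)
  expect_equal(fit$sigma_u, 0)
})

test_that("separation and rank deficiency raise classed fit errors", {
  sep <- survey_dataset(data.frame(
    y = c(rep(0, 10), rep(1, 10)),
    x = c(rnorm(10, -3), rnorm(10, 3)),
    weight = rep(1, 20)))
  expect_error(fit_logistic(sep, model_spec("y", "x")), class = "fit_error")

  dup <- data.frame(y = rbinom(50, 1, 0.5), a = rnorm(50), weight = 1)
  dup$b <- dup$a  # exact copy -> aliased column
  d <- survey_dataset(dup)
  expect_error(fit_logistic(d, model_spec("y", c("a", "b"))),
               class = "design_matrix_error")
})

test_that("plain logistic recovers generating coefficients at n = 20000", {
  cfg <- tiny_config(n = 20000, sd = 0, beta = c("(Intercept)" = -2, xb = 0.8))
  ds <- generate_population(cfg, seed = 30)
  fit <- fit_logistic(ds, model_spec("y", "x"))
  se <- sqrt(diag(fit$cov_beta))
  expect_lt(abs(fit$beta[["(Intercept)"]] - (-2)), 3 * se[["(Intercept)"]])
  expect_lt(abs(fit$beta[["xb"]] - 0.8), 3 * se[["xb"]])
})

test_that("random-intercept fit degenerates to plain logistic when sigma_u = 0", {
  cfg <- tiny_config(n = rep(800, 10), sd = 0)
  ds <- generate_population(cfg, seed = 31)
  plain <- fit_logistic(ds, model_spec("y", c("x", "z")))
  mixed <- fit_random_intercept_logit(ds, model_spec("y", c("x", "z"), group = "area"))
  expect_lte(mixed$sigma_u, 0.05)
  expect_equal(unname(mixed$beta), unname(plain$beta[names(mixed$beta)]),
               tolerance = 1e-3)
  # marginal likelihood of the wider model is never below the nested sigma=0 fit
  expect_gte(mixed$loglik, plain$loglik - 1e-6)
})

test_that("information criteria identities hold and quadrature is converged", {
  cfg <- tiny_config(n = rep(300, 10), sd = 0.4)
  ds <- generate_population(cfg, seed = 32)
  sp <- model_spec("y", c("x", "z"), group = "area")
  fit9 <- fit_random_intercept_logit(ds, sp, nAGQ = 9)
  expect_equal(fit9$aic, -2 * fit9$loglik + 2 * fit9$k)
  expect_equal(fit9$bic, -2 * fit9$loglik + fit9$k * log(fit9$n_obs))
  expect_equal(fit9$k, length(fit9$beta) + 1L)

  fit25 <- fit_random_intercept_logit(ds, sp, nAGQ = 25)
  expect_lt(abs(fit9$loglik - fit25$loglik), 1e-3)

  # AIC()/BIC() generics agree with the stored values
  expect_equal(AIC(fit9), fit9$aic)
  expect_equal(BIC(fit9), fit9$bic)
})

test_that("fewer than two groups is a specification error", {
  cfg <- tiny_config(n = 200)
  ds <- generate_population(cfg, seed = 33)
  expect_error(fit_random_intercept_logit(ds, model_spec("y", "x", group = "area")),
               class = "spec_error")
})

test_that("coefficients are invariant to category level order given the reference", {
  cfg <- sim_config(
    regions = list(list(area = "A1", province = "P", n = 2000)),
    predictors = list(g = list(type = "categorical",
                               levels = c("low", "mid", "high"),
                               reference = "low", probs = c(0.4, 0.35, 0.25))),
    coefficients = c("(Intercept)" = -1, gmid = 0.5, ghigh = 1.2),
    outcome = "y")
  ds <- generate_population(cfg, seed = 34)
  fit1 <- fit_logistic(ds, model_spec("y", "g"))
  ds2 <- ds
  dict <- attr(ds2, "dictionary")
  dict$g$levels <- c("high", "low", "mid")  # relabeled order, same reference
  attr(ds2, "dictionary") <- dict
  fit2 <- fit_logistic(ds2, model_spec("y", "g"))
  expect_equal(fit1$beta[sort(names(fit1$beta))],
               fit2$beta[sort(names(fit2$beta))], tolerance = 1e-6)
})

test_that("backward selection behaves as a fixed point and breaks ties later-first", {
  # strong predictors only: no removal improves BIC
  cfg <- tiny_config(n = 8000, sd = 0,
                     beta = c("(Intercept)" = -1, xb = 1.0, z = 0.8))
  ds <- generate_population(cfg, seed = 35)
  sel <- backward_select(ds, model_spec("y", c("x", "z")), criterion = "bic")
  expect_setequal(sel$spec$terms, c("x", "z"))
  expect_equal(nrow(sel$removal_log), 0)

  # a dataset exactly symmetric under swapping u and v makes the two
  # candidate removals tie to machine precision: the later term (v) goes
  cells <- expand.grid(u = 0:1, v = 0:1)
  ones <- c(10, 12, 12, 15)  # symmetric: cell (1,0) and (0,1) match
  rows <- do.call(rbind, lapply(seq_len(4), function(i) {
    data.frame(u = rep(cells$u[i], 25), v = rep(cells$v[i], 25),
               y = rep(c(1, 0), c(ones[i], 25 - ones[i])))
  }))
  rows$weight <- 1
  dd <- survey_dataset(rows)
  sel2 <- backward_select(dd, model_spec("y", c("u", "v")), criterion = "bic")
  expect_gte(nrow(sel2$removal_log), 1)
  expect_identical(sel2$removal_log$removed[1], "v")
})

test_that("selection drops null predictors and keeps a strong one", {
  cfg <- sim_config(
    regions = list(list(area = "A1", province = "P", n = 10000)),
    predictors = list(
      x = list(type = "categorical", levels = c("a", "b"), reference = "a",
               probs = c(0.5, 0.5)),
      n1 = list(type = "continuous", mean = 0, sd = 1),
      n2 = list(type = "continuous", mean = 0, sd = 1),
      n3 = list(type = "continuous", mean = 0, sd = 1)),
    coefficients = c("(Intercept)" = -1, xb = 1.0),
    outcome = "y")
  ds <- generate_population(cfg, seed = 36)
  sel <- backward_select(ds, model_spec("y", c("x", "n1", "n2", "n3")),
                         criterion = "bic")
  expect_true("x" %in% sel$spec$terms)
  expect_lte(length(intersect(c("n1", "n2", "n3"), sel$spec$terms)), 1)
  expect_gte(nrow(sel$removal_log), 2)
  # criterion decreases monotonically along the removal log
  expect_true(all(sel$removal_log$after < sel$removal_log$before))
})

test_that("models survive a JSON round trip and still predict", {
  cfg <- tiny_config(n = rep(300, 4), sd = 0.3)
  ds <- generate_population(cfg, seed = 37)
  fit <- fit_random_intercept_logit(ds, model_spec("y", c("x", "z"), group = "area"))
  path <- file.path(tempdir(), "fit.json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$beta, fit$beta, tolerance = 1e-12)
  expect_equal(back$sigma_u, fit$sigma_u, tolerance = 1e-12)
  expect_equal(back$aic, fit$aic, tolerance = 1e-10)
  expect_equal(predict(back, ds), predict(fit, ds), tolerance = 1e-12)
  expect_equal(predict(back, ds, mode = "group_specific"),
               predict(fit, ds, mode = "group_specific"), tolerance = 1e-12)
})
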