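#' Simulation configuration for survey microdata
#'
#' Describes a two-level population (respondents nested in health regions
#' nested in provinces) together with a generating logistic model, so that
#' model fitting, performance metrics and synthetic estimation can all be
#' exercised against known ground truth.
#'
#' @param regions list of region descriptors, each a list with `area` (health
#'   region id), `province` (parent province id), `n` (number of respondents,
#'   >= 1), optional `predictors` (per-region overrides of the shared
#'   predictor descriptors) and optional `weight_scale` (inverse
#'   inclusion-probability proxy, default 1).
#' @param predictors named list of predictor descriptors shared by all
#'   regions. Categorical: `list(type = "categorical", levels, reference,
#'   probs)` with `probs` summing to 1 over `levels`. Continuous:
#'   `list(type = "continuous", mean, sd)`; continuous draws use the stated
#'   mean/sd directly (defaults 0/1), so coefficients are per standard unit.
#' @param coefficients true log-odds coefficients. Either a single named
#'   numeric vector (one outcome, named by `outcome`) or a named list of such
#'   vectors, one per outcome. Names follow dummy coding: `"(Intercept)"`,
#'   `"<var><level>"` for a non-reference level of a categorical predictor,
#'   `"<var>"` for a continuous predictor.
#' @param random_intercept_sd nonnegative SD (log-odds scale) of the area
#'   random intercept; one intercept is drawn per area (and outcome).
#' @param weight_model list with `sdlog` (lognormal SD of the weight noise,
#'   default 0.4) and `cluster_size` (respondents per synthetic dwelling
#'   cluster, default 10).
#' @param n_bootstrap number of bootstrap replicate weights to attach (0 for
#'   none).
#' @param outcome outcome column name used when `coefficients` is a plain
#'   vector.
#' @param seed default RNG seed for [generate_population()].
#' @return an object of class `sim_config`.
#' @seealso [default_sim_config()] for the ready-made national configuration.
#' @export
sim_config <- function(regions, predictors, coefficients,
                       random_intercept_sd = 0, weight_model = list(),
                       n_bootstrap = 0, outcome = "outcome", seed = NULL) {
  if (is.numeric(coefficients)) {
    coefficients <- stats::setNames(list(coefficients), outcome)
  }
  cfg <- structure(list(
    regions = regions,
    predictors = predictors,
    coefficients = coefficients,
    random_intercept_sd = random_intercept_sd,
    weight_model = utils::modifyList(list(sdlog = 0.4, cluster_size = 10), weight_model),
    n_bootstrap = n_bootstrap,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$random_intercept_sd < 0) {
    stop_synthprev("random_intercept_sd must be nonnegative", "config_error")
  }
  if (cfg$n_bootstrap < 0) stop_synthprev("n_bootstrap must be >= 0", "config_error")
  for (r in cfg$regions) {
    if (is.null(r$area) || is.null(r$province) || is.null(r$n)) {
      stop_synthprev("each region needs area, province and n", "config_error")
    }
    if (r$n < 1) stop_synthprev(sprintf("region %s has size < 1", r$area), "config_error")
  }
  areas <- vapply(cfg$regions, `[[`, "", "area")
  if (anyDuplicated(areas)) stop_synthprev("duplicated area ids in regions", "config_error")
  check_pred_block <- function(preds, where) {
    for (nm in names(preds)) {
      p <- preds[[nm]]
      if (identical(p$type, "categorical")) {
        if (length(p$probs) != length(p$levels)) {
          stop_synthprev(sprintf("%s: probs/levels length mismatch for '%s'", where, nm),
                         "config_error")
        }
        if (abs(sum(p$probs) - 1) > 1e-12) {
          stop_synthprev(sprintf("%s: level probabilities of '%s' must sum to 1", where, nm),
                         "config_error")
        }
        if (!p$reference %in% p$levels) {
          stop_synthprev(sprintf("%s: reference level of '%s' not in levels", where, nm),
                         "config_error")
        }
      }
    }
  }
  check_pred_block(cfg$predictors, "predictors")
  for (r in cfg$regions) if (!is.null(r$predictors)) {
    merged <- merge_predictors(cfg$predictors, r$predictors)
    check_pred_block(merged, sprintf("region %s", r$area))
  }
  valid <- valid_coefficient_terms(cfg$predictors)
  for (oc in names(cfg$coefficients)) {
    beta <- cfg$coefficients[[oc]]
    if (!"(Intercept)" %in% names(beta)) {
      stop_synthprev(sprintf("coefficients for '%s' lack an (Intercept) term", oc), "config_error")
    }
    bad <- setdiff(names(beta), c("(Intercept)", valid))
    if (length(bad)) {
      stop_synthprev(sprintf("unknown coefficient term(s) for '%s': %s",
                             oc, paste(bad, collapse = ", ")), "config_error")
    }
  }
  invisible(cfg)
}

valid_coefficient_terms <- function(predictors) {
  unlist(lapply(names(predictors), function(nm) {
    p <- predictors[[nm]]
    if (identical(p$type, "categorical")) {
      paste0(nm, setdiff(p$levels, p$reference))
    } else nm
  }), use.names = FALSE)
}

merge_predictors <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- utils::modifyList(base[[nm]] %||% list(), override[[nm]])
  }
  base
}

#' Generate a synthetic survey population
#'
#' Draws respondent-level microdata from a [sim_config()]: one Normal(0,
#' `random_intercept_sd`^2) random intercept per area (and outcome), predictor
#' values from the region's distributions, binary outcomes from
#' `Bernoulli(expit(beta0 + sum beta_j x_j + u_area))`, lognormal design
#' weights normalized to mean 1 within each province, dwelling-cluster ids,
#' and (if `n_bootstrap > 0`) Rao-Wu-Yue rescaled bootstrap replicate weights.
#' The same `(config, seed)` always yields a bit-identical dataset.
#'
#' @param config a `sim_config`.
#' @param seed integer seed; defaults to `config$seed`.
#' @return a [survey_dataset()] with columns `respondent_id`, `province`,
#'   `area`, `cluster`, the predictors, one 0/1 column per outcome, `weight`,
#'   and `BSW1..BSWk` when replicate weights were requested.
#' @export
generate_population <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (is.null(seed)) stop_synthprev("a seed is required (argument or config$seed)", "config_error")
  with_seed(seed, {
    outcomes <- names(config$coefficients)
    blocks <- vector("list", length(config$regions))
    for (i in seq_along(config$regions)) {
      r <- config$regions[[i]]
      preds <- merge_predictors(config$predictors, r$predictors %||% list())
      n <- r$n
      u <- stats::rnorm(length(outcomes), 0, config$random_intercept_sd)
      names(u) <- outcomes
      df <- data.frame(province = rep(r$province, n), area = rep(r$area, n),
                       stringsAsFactors = FALSE)
      for (nm in names(preds)) {
        p <- preds[[nm]]
        df[[nm]] <- if (identical(p$type, "categorical")) {
          sample(p$levels, n, replace = TRUE, prob = p$probs)
        } else {
          stats::rnorm(n, p$mean %||% 0, p$sd %||% 1)
        }
      }
      for (oc in outcomes) {
        beta <- config$coefficients[[oc]]
        eta <- linear_predictor(df, preds, beta) + u[[oc]]
        df[[oc]] <- stats::rbinom(n, 1L, stats::plogis(eta))
      }
      base <- (r$weight_scale %||% 1) * stats::rlnorm(n, 0, config$weight_model$sdlog)
      df$weight <- base
      csize <- config$weight_model$cluster_size
      df$cluster <- paste0(r$area, "_c", ceiling(seq_len(n) / csize))
      blocks[[i]] <- df
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out$respondent_id <- seq_len(nrow(out))
    # normalize weights to mean 1 per province: weighted and unweighted scales comparable
    for (pv in unique(out$province)) {
      idx <- out$province == pv
      out$weight[idx] <- out$weight[idx] / mean(out$weight[idx])
    }
    front <- c("respondent_id", "province", "area", "cluster")
    out <- out[, c(front, setdiff(names(out), front))]
    dict <- list()
    for (nm in names(config$predictors)) {
      p <- config$predictors[[nm]]
      dict[[nm]] <- if (identical(p$type, "categorical")) {
        list(type = "categorical", levels = p$levels, reference = p$reference)
      } else list(type = "continuous")
    }
    for (oc in outcomes) dict[[oc]] <- list(type = "outcome")
    ds <- survey_dataset(out, dictionary = dict)
    if (config$n_bootstrap > 0) {
      ds <- make_replicate_weights(ds, config$n_bootstrap, seed = derive_seed(seed, 9781L))
    }
    ds
  })
}

linear_predictor <- function(df, preds, beta) {
  eta <- rep(beta[["(Intercept)"]], nrow(df))
  for (term in setdiff(names(beta), "(Intercept)")) {
    hit <- FALSE
    for (nm in names(preds)) {
      p <- preds[[nm]]
      if (identical(p$type, "categorical") && startsWith(term, nm) &&
          substring(term, nchar(nm) + 1) %in% p$levels) {
        eta <- eta + beta[[term]] * (df[[nm]] == substring(term, nchar(nm) + 1))
        hit <- TRUE; break
      } else if (!identical(p$type, "categorical") && term == nm) {
        eta <- eta + beta[[term]] * df[[nm]]
        hit <- TRUE; break
      }
    }
    if (!hit) stop_synthprev(sprintf("unknown coefficient term: %s", term), "config_error")
  }
  eta
}

#' Attach Rao-Wu-Yue rescaled bootstrap replicate weights
#'
#' Within each province stratum with `n_h` dwelling clusters, each replicate
#' resamples `n_h - 1` clusters with replacement; the replicate weight of a
#' respondent in cluster `i` is `weight * m_i * n_h / (n_h - 1)` where `m_i`
#' counts how often the cluster was drawn. The replicate weighted total equals
#' the full-sample total in expectation. A single-cluster stratum keeps its
#' design weights unchanged (resampling a singleton is the identity).
#'
#' @param dataset a [survey_dataset()] with a `cluster` and `province` column.
#' @param n_bootstrap number of replicates (>= 1).
#' @param seed integer seed.
#' @return the dataset with columns `BSW1..BSWn_bootstrap` replaced/added.
#' @export
make_replicate_weights <- function(dataset, n_bootstrap, seed) {
  if (n_bootstrap < 1) stop_synthprev("n_bootstrap must be >= 1", "argument_error")
  if (!all(c("cluster", "province") %in% names(dataset))) {
    stop_synthprev("dataset needs 'cluster' and 'province' columns", "schema_error")
  }
  w <- design_weights(dataset)
  old <- bsw_columns(dataset)
  df <- as.data.frame(dataset)
  df[old] <- NULL
  strata <- split(seq_len(nrow(df)), df$province)
  bsw <- matrix(NA_real_, nrow(df), n_bootstrap)
  with_seed(seed, {
    for (idx in strata) {
      cl <- factor(df$cluster[idx])
      n_h <- nlevels(cl)
      if (n_h == 1L) {
        bsw[idx, ] <- w[idx]
        next
      }
      for (b in seq_len(n_bootstrap)) {
        m <- tabulate(sample.int(n_h, n_h - 1L, replace = TRUE), nbins = n_h)
        bsw[idx, b] <- w[idx] * m[as.integer(cl)] * n_h / (n_h - 1L)
      }
    }
  })
  colnames(bsw) <- paste0(attr(dataset, "bsw_prefix") %||% "BSW", seq_len(n_bootstrap))
  out <- cbind(df, as.data.frame(bsw))
  survey_dataset(out, dictionary = dataset_dictionary(dataset),
                 weight_col = attr(dataset, "weight_col") %||% "weight",
                 bsw_prefix = attr(dataset, "bsw_prefix") %||% "BSW")
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the arguments of [sim_config()]; `coefficients` may be a
#' map outcome -> {term: value}.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- lapply(raw$coefficients, function(x) unlist(x))
  preds <- lapply(raw$predictors, function(p) {
    if (!is.null(p$probs)) p$probs <- as.numeric(unlist(p$probs))
    if (!is.null(p$levels)) p$levels <- as.character(unlist(p$levels))
    p
  })
  sim_config(regions = raw$regions, predictors = preds, coefficients = coefs,
             random_intercept_sd = raw$random_intercept_sd %||% 0,
             weight_model = raw$weight_model %||% list(),
             n_bootstrap = raw$n_bootstrap %||% 0,
             seed = raw$seed)
}
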