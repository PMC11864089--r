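#' Configuration for a full synthetic-estimation run
#'
#' Bundles everything one study cycle needs: a development dataset and any
#' number of validation datasets (each either a path prefix readable by
#' [read_survey()] or a [sim_config()] to simulate), the grouping of
#' provinces into modelling regions, the outcomes, a model-term template, the
#' selection criterion, and a master seed from which every stage derives its
#' own stream.
#'
#' @param datasets named list; each element is a list with either `path`
#'   (prefix for [read_survey()]) or `simulate` (a `sim_config`). Names are
#'   the dataset labels (e.g. `dev2018`, `val2019`).
#' @param development label of the development dataset.
#' @param regions named list mapping region name to a character vector of
#'   province ids; every province must belong to exactly one region.
#' @param outcomes character vector of outcome columns to model.
#' @param terms model-term template (fixed effects of the full model).
#' @param group grouping column for the random intercept (default `"area"`).
#' @param criterion `"aic"` or `"bic"`.
#' @param seed master integer seed.
#' @param nAGQ quadrature nodes.
#' @return an object of class `run_config`.
#' @export
run_config <- function(datasets, development, regions, outcomes, terms,
                       group = "area", criterion = "bic", seed = 1, nAGQ = 9) {
  if (!development %in% names(datasets)) {
    stop_synthprev("development label not among datasets", "config_error")
  }
  provs <- unlist(regions, use.names = FALSE)
  if (anyDuplicated(provs)) {
    stop_synthprev("a province belongs to more than one region", "config_error")
  }
  structure(list(datasets = datasets, development = development,
                 regions = regions, outcomes = outcomes, terms = terms,
                 group = group, criterion = match.arg(criterion, c("aic", "bic")),
                 seed = seed, nAGQ = nAGQ),
            class = "run_config")
}

#' Default desk-scale run configuration
#'
#' Three simulated survey years (a development year and two validation
#' years), the Atlantic/Central/Western province grouping, both outcomes and
#' the common predictor template, at about 14,500 respondents per year.
#'
#' @param seed master seed.
#' @param n_per_area respondents per health region and year.
#' @return a `run_config`.
#' @export
default_run_config <- function(seed = 1, n_per_area = 500) {
  simcfg <- function() default_sim_config(n_per_area = n_per_area)
  run_config(
    datasets = list(dev2018 = list(simulate = simcfg()),
                    val2019 = list(simulate = simcfg()),
                    val2020 = list(simulate = simcfg())),
    development = "dev2018",
    regions = list(Atlantic = c("NL", "PE", "NS", "NB"),
                   Central = c("ON", "QC"),
                   Western = c("MB", "SK", "AB", "BC")),
    outcomes = c("perceived_need", "unmet_need"),
    terms = c("sex", "age_group", "srmh", "mood_anx", "life_stress", "life_sat"),
    criterion = "bic", seed = seed)
}

#' Read a run configuration from YAML or JSON
#'
#' Mirrors [run_config()]; dataset entries may give `path` prefixes or
#' `simulate: default` (the [default_sim_config()]) or an inline simulation
#' config.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  datasets <- lapply(raw$datasets, function(d) {
    if (!is.null(d$simulate)) {
      d$simulate <- if (identical(d$simulate, "default")) default_sim_config() else {
        sim_config(regions = d$simulate$regions, predictors = d$simulate$predictors,
                   coefficients = lapply(d$simulate$coefficients, unlist),
                   random_intercept_sd = d$simulate$random_intercept_sd %||% 0,
                   weight_model = d$simulate$weight_model %||% list(),
                   n_bootstrap = d$simulate$n_bootstrap %||% 0)
      }
    }
    d
  })
  run_config(datasets = datasets, development = raw$development,
             regions = lapply(raw$regions, unlist), outcomes = unlist(raw$outcomes),
             terms = unlist(raw$terms), group = raw$group %||% "area",
             criterion = raw$criterion %||% "bic", seed = raw$seed %||% 1,
             nAGQ = raw$nAGQ %||% 9)
}

#' Run the full synthetic-estimation study pipeline
#'
#' For each modelling region and outcome: fits the full random-intercept
#' logistic model on the development dataset restricted to that region's
#' provinces, reduces it by backward selection, assesses discrimination and
#' calibration, validates internally (development data) and externally (every
#' other dataset) at both province and health-region level, and writes all
#' artifacts under `out_dir`: fitted-model JSONs (`fits/`), performance
#' JSONs and decile CSVs (`performance/`), per-dataset estimate CSVs
#' (`estimates/`), a consolidated `report.csv`/`report.md`, and a
#' reproducibility `manifest.json` (config hash, seed, package and R
#' versions). A failing region-outcome cell is logged and skipped; the other
#' cells proceed. Reruns with an identical config are byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `report` (the consolidated data.frame),
#'   `fits`, `performance`, and `datasets`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  for (d in c("", "fits", "performance", "estimates")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  datasets <- list()
  for (lab in names(config$datasets)) {
    d <- config$datasets[[lab]]
    datasets[[lab]] <- if (!is.null(d$path)) read_survey(d$path) else {
      generate_population(d$simulate, seed = derive_seed(config$seed, lab))
    }
    say("dataset %s: %d respondents [%.1fs]", lab, nrow(datasets[[lab]]),
        proc.time()[["elapsed"]] - t0)
  }
  dev <- datasets[[config$development]]

  fits <- list()
  perfs <- list()
  report <- list()
  for (region in names(config$regions)) {
    provs <- config$regions[[region]]
    dev_r <- subset_provinces(dev, provs)
    for (oc in config$outcomes) {
      cell <- paste(region, oc, sep = "_")
      res <- tryCatch({
        spec <- model_spec(oc, config$terms, group = config$group)
        fit <- backward_select(dev_r, spec, criterion = config$criterion,
                               nAGQ = config$nAGQ)
        write_model(fit, file.path(out_dir, "fits", paste0(cell, ".json")))
        perf <- model_performance(fit, dev_r)
        jsonlite::write_json(list(c_statistic = perf$c_statistic,
                                  calibration_slope = perf$calibration_slope,
                                  n = perf$n),
                             file.path(out_dir, "performance", paste0(cell, ".json")),
                             auto_unbox = TRUE, digits = NA)
        utils::write.csv(perf$decile_table,
                         file.path(out_dir, "performance", paste0(cell, "_deciles.csv")),
                         row.names = FALSE)
        list(fit = fit, perf = perf)
      }, error = function(e) {
        say("cell %s failed: %s", cell, conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      fits[[cell]] <- res$fit
      perfs[[cell]] <- res$perf
      say("fitted %s: kept %s; C = %.3f [%.1fs]", cell,
          paste(res$fit$spec$terms, collapse = "+"), res$perf$c_statistic,
          proc.time()[["elapsed"]] - t0)
      for (lab in names(datasets)) {
        ds_r <- subset_provinces(datasets[[lab]], provs)
        for (by in c("province", "area")) {
          est <- validate_model(res$fit, ds_r, by = by, label = lab)
          est$region <- region
          est$outcome <- oc
          est$level <- by
          report[[paste(cell, lab, by, sep = "_")]] <- est
          write_validation(est, file.path(out_dir, "estimates",
                                          paste0(cell, "_", lab, "_", by, ".csv")))
        }
      }
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  utils::write.csv(
    report[, c("region", "outcome", "level", "label", "area", "n",
               "observed_pct", "predicted_pct", "difference_pct")],
    file.path(out_dir, "report.csv"), row.names = FALSE, quote = FALSE)
  write_report_md(report, file.path(out_dir, "report.md"))
  manifest <- list(seed = config$seed, criterion = config$criterion,
                   config_hash = config_hash(config),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   package_version = as.character(utils::packageVersion("synthprev")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("pipeline done [%.1fs]", proc.time()[["elapsed"]] - t0)
  invisible(list(report = report, fits = fits, performance = perfs,
                 datasets = datasets))
}

subset_provinces <- function(data, provs) {
  out <- as.data.frame(data)[data$province %in% provs, , drop = FALSE]
  survey_dataset(out, dictionary = dataset_dictionary(data),
                 weight_col = attr(data, "weight_col") %||% "weight",
                 bsw_prefix = attr(data, "bsw_prefix") %||% "BSW")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

write_report_md <- function(report, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# Observed and predicted proportions by area", con)
  fmt <- function(x) formatC(round(x, 2), format = "f", digits = 2)
  for (oc in unique(report$outcome)) {
    writeLines(c("", paste("##", oc), ""), con)
    writeLines("| Level | Area | Dataset | Observed (%) | Predicted (%) | Difference (%) |", con)
    writeLines("|---|---|---|---|---|---|", con)
    sub <- report[report$outcome == oc, ]
    sub <- sub[order(sub$level, sub$area, sub$label), ]
    writeLines(sprintf("| %s | %s | %s | %s | %s | %s |",
                       sub$level, sub$area, sub$label, fmt(sub$observed_pct),
                       fmt(sub$predicted_pct),
                       fmt(round(sub$predicted_pct, 2) - round(sub$observed_pct, 2))),
               con)
  }
  invisible(path)
}
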