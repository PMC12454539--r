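#' Run the full referral-simulation pipeline
#'
#' End-to-end convenience wrapper: synthesize (or accept) a cohort, apply
#' the exclusion cascade, split 80/20 into training and test cohorts,
#' estimate facility quality with Wilson score intervals on the training
#' cohort, fit the risk-adjustment models with facility fixed effects,
#' counterfactually reassign test-cohort patients under the reassignment
#' rule, and summarize the paired predicted outcomes.
#'
#' @param config A [sim_config()]; ignored when \code{data} is supplied.
#' @param data Optional list with \code{facilities} and \code{encounters}
#'   (e.g. a [simulate_cohort()] result) to analyse instead of generating
#'   one.
#' @param min_annual_volume Facility volume exclusion threshold
#'   (cases/year).
#' @param system_mode Restrict the cohort to multi-facility health systems
#'   (usually paired with \code{rule = reassignment_rule("system")}).
#' @param train_fraction Training share of the split.
#' @param split_seed Seed of the train/test split; defaults to the config
#'   seed.
#' @param confidence Confidence level of the Wilson intervals.
#' @param rule A [reassignment_rule()].
#' @param covariate_update Counterfactual prediction mode; see
#'   [predict_outcome()].
#' @param outcomes Which outcome models to fit; see [fit_outcome_models()].
#' @return List of class \code{referral_pipeline} with every intermediate
#'   artifact: cohort, exclusion log, split, quality table, models,
#'   simulation results and report.
#' @export
run_pipeline <- function(config = sim_config(),
                         data = NULL,
                         min_annual_volume = 10,
                         system_mode = FALSE,
                         train_fraction = 0.8,
                         split_seed = NULL,
                         confidence = 0.95,
                         rule = reassignment_rule(),
                         covariate_update = "fixed_effect_only",
                         outcomes = c("sae", "readmit_30d", "los_days",
                                      "cost")) {
  if (is.null(data)) data <- simulate_cohort(config)
  split_seed <- split_seed %||% (config$seed + 1L)
  facilities <- data$facilities
  excl <- apply_exclusions(data$encounters, facilities,
                           min_annual_volume = min_annual_volume,
                           system_mode = system_mode)
  split <- split_train_test(excl$cohort, train_fraction, split_seed)

  quality <- facility_quality(split$train, confidence = confidence)
  tertiles <- compute_volume_tertiles(split$train)
  train_frame <- prepare_model_frame(split$train, facilities, tertiles)
  test_frame <- prepare_model_frame(split$test, facilities, tertiles)
  models <- fit_outcome_models(train_frame, outcomes = outcomes)

  # facilities absent from training have no quality estimate nor fixed
  # effect: their test patients are set aside and counted, not simulated
  ranked <- test_frame$facility_id %in% quality$facility_id
  sim <- run_referral_simulation(test_frame[ranked, , drop = FALSE],
                                 models, quality, facilities,
                                 rule = rule,
                                 covariate_update = covariate_update)
  report <- summarize_simulation(sim)

  structure(list(
    config = if (is.null(data$config)) NULL else data$config,
    facilities = facilities,
    exclusion_log = excl$log,
    split = split,
    quality = quality,
    tertiles = tertiles,
    train = train_frame,
    test = test_frame,
    n_test_unranked = sum(!ranked),
    models = models,
    sim = sim,
    report = report,
    rule = rule
  ), class = "referral_pipeline")
}

#' @export
print.referral_pipeline <- function(x, ...) {
  cat("Referral simulation pipeline\n")
  print(x$exclusion_log)
  cat(sprintf("Split: %d train / %d test\n",
              nrow(x$split$train), nrow(x$split$test)))
  cat(sprintf("Quality table: %d facilities in 4 quartiles\n",
              nrow(x$quality)))
  print(x$report)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes the cohort CSVs, exclusion log, quality table, model
#' coefficients and the simulation report -- the complete file-level
#' interface of the pipeline, byte-stable for a fixed configuration.
#'
#' @param pipeline A [run_pipeline()] result.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(pipeline, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(df) {
    # round floating columns so output bytes do not depend on libm quirks
    for (nm in names(df)) if (is.double(df[[nm]]))
      df[[nm]] <- round(df[[nm]], 10)
    df
  }
  paths <- c(train = file.path(dir, "cohort_train.csv"),
             test = file.path(dir, "cohort_test.csv"),
             exclusions = file.path(dir, "exclusion_log.json"),
             quality = file.path(dir, "quality_table.csv"),
             models = file.path(dir, "models.json"))
  utils::write.csv(num(pipeline$split$train), paths["train"], row.names = FALSE)
  utils::write.csv(num(pipeline$split$test), paths["test"], row.names = FALSE)
  jsonlite::write_json(list(initial_n = attr(pipeline$exclusion_log, "initial_n"),
                            rules = as.data.frame(pipeline$exclusion_log)),
                       paths["exclusions"], auto_unbox = TRUE, digits = NA)
  utils::write.csv(num(as.data.frame(pipeline$quality)), paths["quality"],
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(pipeline$models, function(m)
      list(outcome = m$outcome, family = m$family,
           reference_facility = m$reference_facility,
           beta = as.list(round(m$beta, 12)),
           alpha = as.list(round(m$alpha, 12)),
           separated = m$separated, converged = m$converged)),
    paths["models"], auto_unbox = TRUE, digits = NA)
  sim_paths <- write_simulation_report(pipeline$sim, dir,
                                       report = pipeline$report)
  invisible(c(paths, sim_paths))
}
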