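# Synthetic facility and encounter generator emulating the structure of
# state inpatient / ambulatory surgery discharge data for parathyroidectomy.

# Fixed categorical marginals of the generator (not exposed as config): these
# mirror the typical case mix of a parathyroidectomy cohort -- mostly white,
# Medicare- or privately-insured patients, admission type frequently coded
# "other/missing" in ambulatory claims.
.race_probs <- c(white = 0.775, black = 0.08, hispanic = 0.08,
                 other = 0.02, missing = 0.045)
.insurance_probs <- c(private = 0.445, medicaid = 0.023, medicare = 0.50,
                      other_missing = 0.032)
.admission_probs <- c(elective = 0.30, emergent_urgent = 0.013,
                      other_missing = 0.687)
.elixhauser_probs <- c(0.31, 0.295, 0.22, 0.175)  # categories 0,1,2,3+

# Attribution probabilities used to split a drawn SAE into its components
# (technical event, medical event, urgent/emergent 30-day readmission,
# death); components may co-occur and at least one is always present.
.sae_component_probs <- c(technical = 0.30, medical = 0.72,
                          urgent_readmit = 0.35, death = 0.02)
.nonurgent_readmit_rate <- 0.04
.reoperation_rate <- 0.01

#' Generate the synthetic facility table
#'
#' Draws \code{n_facilities} facilities with coordinates uniform in the
#' configured region, a health-system partition, cost parameters, a
#' lognormal attractiveness weight (which induces the right-skewed volume
#' distribution through the gravity assignment), and the true facility
#' quality effect: an i.i.d. Normal(0, \code{facility_effect_sd}^2) log-odds
#' offset of SAE risk.  Deterministic given \code{config$seed}, and
#' independent of \code{n_patients}.
#'
#' @param config A [sim_config()].
#' @return A data frame with one row per facility: \code{facility_id},
#'   \code{system_id} (NA when unaffiliated), \code{zip_lat}, \code{zip_lon},
#'   \code{cost_to_charge_ratio}, \code{wage_index}, \code{attractiveness},
#'   \code{charge_offset}, \code{true_quality_effect}.
#' @export
generate_facilities <- function(config) {
  config <- validate_sim_config(config)
  if (config$n_systems >= config$n_facilities)
    stop_config("n_systems must be < n_facilities so at least one system has two facilities")
  with_seed(sub_seed(config$seed, 1L), {
    nf <- config$n_facilities
    ns <- config$n_systems
    re <- config$region_extent
    fid <- sprintf("F%03d", seq_len(nf))
    sys_ids <- sprintf("S%02d", seq_len(ns))
    # each system seeded with one facility, remaining facilities join a
    # random system (or stay unaffiliated)
    membership <- c(sys_ids, sample(sys_ids, nf - ns, replace = TRUE))
    if (config$unaffiliated_fraction > 0) {
      free <- (ns + 1):nf
      drop <- free[stats::runif(length(free)) < config$unaffiliated_fraction]
      membership[drop] <- NA_character_
    }
    data.frame(
      facility_id = fid,
      system_id = membership,
      zip_lat = stats::runif(nf, re["lat_min"], re["lat_max"]),
      zip_lon = stats::runif(nf, re["lon_min"], re["lon_max"]),
      cost_to_charge_ratio = stats::runif(nf, 0.20, 0.45),
      wage_index = exp(stats::rnorm(nf, 0, 0.08)),
      attractiveness = stats::rlnorm(nf, 0, config$attractiveness_sdlog),
      charge_offset = stats::rnorm(nf, 0, 0.15),
      true_quality_effect = stats::rnorm(nf, 0, config$facility_effect_sd),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate synthetic encounters (covariates and geography; outcomes unset)
#'
#' Each patient draws a home location uniform in the region and chooses a
#' facility by a gravity rule: choice weight proportional to
#' \code{attractiveness * exp(-distance / gravity_scale_miles)}.  A
#' non-positive scale is the deterministic nearest-facility limit.
#' Covariate marginals follow the configured fractions; a small configurable
#' share of patients is flagged out-of-state or as having recent neck
#' surgery so the exclusion rules have work to do.
#'
#' @param facilities Facility table from [generate_facilities()].
#' @param config A [sim_config()].
#' @return Data frame of encounters with outcome columns set to \code{NA};
#'   fill them with [generate_outcomes()].
#' @export
generate_encounters <- function(facilities, config) {
  config <- validate_sim_config(config)
  if (!NROW(facilities)) stop_config("facility table is empty")
  assert_columns(facilities,
                 c("facility_id", "zip_lat", "zip_lon", "attractiveness",
                   "true_quality_effect"), "facilities")
  with_seed(sub_seed(config$seed, 2L), {
    n <- config$n_patients
    re <- config$region_extent
    home_lat <- stats::runif(n, re["lat_min"], re["lat_max"])
    home_lon <- stats::runif(n, re["lon_min"], re["lon_max"])
    d <- zip_distance(rep(home_lat, times = nrow(facilities)),
                      rep(home_lon, times = nrow(facilities)),
                      rep(facilities$zip_lat, each = n),
                      rep(facilities$zip_lon, each = n))
    d <- matrix(d, nrow = n)
    if (config$gravity_scale_miles <= 0) {
      fac_idx <- max.col(-d, ties.method = "first")
    } else {
      # subtract the row minimum before exponentiating for stability
      w <- exp(-(d - apply(d, 1, min)) / config$gravity_scale_miles)
      w <- sweep(w, 2, facilities$attractiveness, `*`)
      cw <- t(apply(w, 1, cumsum))
      r <- stats::runif(n) * cw[, ncol(cw)]
      fac_idx <- rowSums(cw < r) + 1L
    }
    alpha <- facilities$true_quality_effect[fac_idx]

    sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
    age <- pmin(pmax(round(stats::rnorm(n, 64, 11)), 18), 95)
    race <- sample(names(.race_probs), n, replace = TRUE, prob = .race_probs)
    insurance <- sample(names(.insurance_probs), n, replace = TRUE,
                        prob = .insurance_probs)
    admission_type <- sample(names(.admission_probs), n, replace = TRUE,
                             prob = .admission_probs)
    setting <- ifelse(stats::runif(n) < config$ambulatory_fraction,
                      "ambulatory", "inpatient")
    discharge_year <- sample(config$study_years, n, replace = TRUE)
    # comorbidity burden via a latent normal cut at the marginal quantiles;
    # the confounding knob shifts the latent score with facility quality so
    # sicker patients can cluster at worse facilities when requested
    z <- stats::pnorm(stats::rnorm(n) + config$case_mix_confounding * alpha)
    elix_cat <- findInterval(z, cumsum(.elixhauser_probs)[-4])  # 0..3
    elixhauser_count <- elix_cat +
      ifelse(elix_cat == 3L, stats::rpois(n, 0.7), 0L)

    enc <- data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      facility_id = facilities$facility_id[fac_idx],
      age = age, sex = sex, race = race, insurance = insurance,
      admission_type = admission_type, setting = setting,
      discharge_year = discharge_year,
      elixhauser_count = as.integer(elixhauser_count),
      home_lat = home_lat, home_lon = home_lon,
      out_of_state = stats::runif(n) < config$out_of_state_fraction,
      prior_neck_surgery_6mo = stats::runif(n) < config$prior_neck_surgery_fraction,
      stringsAsFactors = FALSE
    )
    enc$total_charges <- NA_real_
    enc$los_days <- NA_integer_
    for (col in c("sae", "technical_event", "medical_event",
                  "readmit_30d_urgent", "readmit_30d", "reoperation_2y",
                  "death")) {
      enc[[col]] <- NA
    }
    enc
  })
}

# design matrix of the truth model, columns named after the covariate
# effects; shared by the generator and the parameter-recovery tests
truth_design <- function(encounters) {
  elix <- pmin(encounters$elixhauser_count, 3L)
  cbind(
    age = encounters$age - 65,
    sex_male = as.numeric(encounters$sex == "male"),
    race_black = as.numeric(encounters$race == "black"),
    race_hispanic = as.numeric(encounters$race == "hispanic"),
    race_other = as.numeric(encounters$race == "other"),
    race_missing = as.numeric(encounters$race == "missing"),
    insurance_medicaid = as.numeric(encounters$insurance == "medicaid"),
    insurance_medicare = as.numeric(encounters$insurance == "medicare"),
    insurance_other_missing = as.numeric(encounters$insurance == "other_missing"),
    setting_inpatient = as.numeric(encounters$setting == "inpatient"),
    admission_emergent_urgent = as.numeric(encounters$admission_type == "emergent_urgent"),
    admission_other_missing = as.numeric(encounters$admission_type == "other_missing"),
    elixhauser = elix
  )
}

# expected value of each truth-design column under the configured marginals,
# so the baseline logit is anchored at the average patient
truth_centering <- function(config) {
  c(age = -1,  # mean of the rounded, clamped age distribution minus 65
    sex_male = 1 - config$female_fraction,
    race_black = unname(.race_probs["black"]),
    race_hispanic = unname(.race_probs["hispanic"]),
    race_other = unname(.race_probs["other"]),
    race_missing = unname(.race_probs["missing"]),
    insurance_medicaid = unname(.insurance_probs["medicaid"]),
    insurance_medicare = unname(.insurance_probs["medicare"]),
    insurance_other_missing = unname(.insurance_probs["other_missing"]),
    setting_inpatient = 1 - config$ambulatory_fraction,
    admission_emergent_urgent = unname(.admission_probs["emergent_urgent"]),
    admission_other_missing = unname(.admission_probs["other_missing"]),
    elixhauser = sum(0:3 * .elixhauser_probs))
}

#' True SAE linear predictor of the generator
#'
#' Log-odds of a serious adverse event for each encounter under the truth
#' model: baseline + centered covariate design times the true effects + the
#' facility quality offset.  Exposed so parameter-recovery tests can compare
#' fitted models against the exact truth.
#'
#' @inheritParams generate_outcomes
#' @return Numeric vector, one log-odds per encounter.
#' @export
sae_linear_predictor <- function(encounters, facilities, config) {
  beta <- config$covariate_effects[names(truth_centering(config))]
  X <- truth_design(encounters)
  Xc <- sweep(X, 2, truth_centering(config))
  alpha <- facilities$true_quality_effect[
    match(encounters$facility_id, facilities$facility_id)]
  if (anyNA(alpha)) stop_config("encounters reference unknown facilities")
  drop(config$baseline_sae_logit + Xc %*% beta + alpha)
}

#' Fill in synthetic outcomes
#'
#' Draws the serious adverse event indicator from the logistic truth model,
#' then attributes each SAE to components (technical, medical, urgent
#' readmission, death) top-down so the composite definition
#' \code{sae == technical | medical | urgent readmission | death} holds
#' exactly.  Length of stay is Poisson with a log-link truth; total charges
#' are lognormal, shifted by facility-level charge offsets.  Deterministic
#' given \code{config$seed}.
#'
#' @param encounters Encounter table from [generate_encounters()].
#' @param facilities Matching facility table.
#' @param config The same [sim_config()].
#' @return The encounter table with outcome columns filled.
#' @export
generate_outcomes <- function(encounters, facilities, config) {
  config <- validate_sim_config(config)
  if (!all(encounters$facility_id %in% facilities$facility_id))
    stop_config("encounters reference facilities absent from the facility table")
  eta <- sae_linear_predictor(encounters, facilities, config)
  with_seed(sub_seed(config$seed, 3L), {
    n <- nrow(encounters)
    fac_row <- match(encounters$facility_id, facilities$facility_id)
    alpha <- facilities$true_quality_effect[fac_row]

    sae <- stats::runif(n) < stats::plogis(eta)
    tech <- sae & stats::runif(n) < .sae_component_probs["technical"]
    med <- sae & stats::runif(n) < .sae_component_probs["medical"]
    urg <- sae & stats::runif(n) < .sae_component_probs["urgent_readmit"]
    death <- sae & stats::runif(n) < .sae_component_probs["death"]
    none <- sae & !(tech | med | urg | death)
    med[none] <- TRUE  # guarantee at least one component per SAE

    elix <- pmin(encounters$elixhauser_count, 3L)
    inpat <- encounters$setting == "inpatient"
    emerg <- encounters$admission_type == "emergent_urgent"
    # worse facilities also run longer stays and higher charges, at half /
    # one-tenth the strength of their SAE effect
    eta_los <- log(0.08) + 2.3 * inpat + 0.18 * elix +
      0.01 * (encounters$age - 65) + 0.5 * emerg + 0.5 * alpha
    los <- stats::rpois(n, exp(eta_los))
    meanlog <- config$charge_lognormal_params[["meanlog"]] +
      0.35 * inpat + 0.06 * elix +
      facilities$charge_offset[fac_row] + 0.1 * alpha
    charges <- stats::rlnorm(n, meanlog,
                             config$charge_lognormal_params[["sdlog"]])

    encounters$sae <- sae
    encounters$technical_event <- tech
    encounters$medical_event <- med
    encounters$readmit_30d_urgent <- urg
    encounters$readmit_30d <- urg | (stats::runif(n) < .nonurgent_readmit_rate)
    encounters$death <- death
    encounters$reoperation_2y <- stats::runif(n) < .reoperation_rate
    encounters$los_days <- as.integer(los)
    encounters$total_charges <- charges
    encounters
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_facilities()],
#' [generate_encounters()] and [generate_outcomes()] under one
#' configuration.
#'
#' @param config A [sim_config()].
#' @return List with elements \code{facilities}, \code{encounters} (outcomes
#'   filled) and \code{config}.
#' @export
simulate_cohort <- function(config = sim_config()) {
  facilities <- generate_facilities(config)
  encounters <- generate_encounters(facilities, config)
  encounters <- generate_outcomes(encounters, facilities, config)
  list(facilities = facilities, encounters = encounters, config = config)
}

#' Write a synthetic cohort to disk
#'
#' Writes \code{facilities.csv}, \code{encounters.csv} and a
#' \code{sim_config.json} sidecar recording the full configuration
#' (including truth parameters) so parameter-recovery analyses can reload
#' the ground truth.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_data <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    facilities = file.path(dir, "facilities.csv"),
    encounters = file.path(dir, "encounters.csv"),
    config = file.path(dir, "sim_config.json")
  )
  utils::write.csv(sim$facilities, paths["facilities"], row.names = FALSE)
  utils::write.csv(sim$encounters, paths["encounters"], row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), paths["config"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
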