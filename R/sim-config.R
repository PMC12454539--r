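#' Configuration of the synthetic encounter generator
#'
#' Parameterizes the data-generating process behind the synthetic facility
#' and encounter tables.  The defaults emulate the marginal structure of an
#' all-payer state surgical discharge cohort of parathyroidectomy patients:
#' about 77\% female, median age near 65 years, roughly 97\% of cases in the
#' ambulatory setting, strongly right-skewed facility volumes, right-skewed
#' charges, and heterogeneous facility quality with a median facility serious
#' adverse event (SAE) rate near 7\%.
#'
#' The true SAE model is a logistic regression on patient covariates plus a
#' facility-level quality offset: each facility draws a log-odds effect from
#' Normal(0, \code{facility_effect_sd}^2).  Covariates enter centered at
#' their configured marginal means, so \code{baseline_sae_logit} is exactly
#' the log-odds of SAE for an average patient at a median-quality facility.
#'
#' @param n_facilities Number of surgical facilities (at least 8 so quality
#'   quartiles are non-degenerate).
#' @param n_patients Number of encounters (one encounter per patient).
#' @param n_systems Number of health systems facilities are partitioned into.
#' @param study_years Inclusive integer range of discharge years.
#' @param facility_effect_sd Standard deviation (logit scale) of the true
#'   facility quality offsets.  Zero gives identical-quality facilities.
#' @param baseline_sae_logit Intercept of the true SAE model (logit scale);
#'   the default corresponds to a 7\% SAE rate.
#' @param covariate_effects Named numeric vector of true log-odds effects for
#'   the SAE model; see \code{default_covariate_effects()} for the names.
#' @param charge_lognormal_params Length-2 vector \code{c(meanlog, sdlog)} of
#'   total billed charges (USD).
#' @param region_extent Named vector \code{c(lat_min, lat_max, lon_min,
#'   lon_max)} bounding box (decimal degrees) that stands in for the
#'   state's zip-code centroid cloud.
#' @param ambulatory_fraction Proportion of encounters in the ambulatory
#'   (outpatient surgery) setting.
#' @param female_fraction Proportion of female patients.
#' @param gravity_scale_miles Distance scale of the facility-choice gravity
#'   rule: choice weight is proportional to
#'   \code{attractiveness * exp(-distance / scale)}.  A non-positive scale is
#'   the deterministic nearest-facility limit.
#' @param attractiveness_sdlog Log-scale SD of facility attractiveness
#'   weights; drives the right-skew of facility volumes.
#' @param unaffiliated_fraction Fraction of facilities (beyond the one seed
#'   facility per system) left without a health-system affiliation.  Default
#'   0: every facility belongs to a system.
#' @param out_of_state_fraction Fraction of encounters flagged as residing
#'   out of state (exercises the exclusion rules).
#' @param prior_neck_surgery_fraction Fraction flagged as having endocrine
#'   neck surgery in the prior six months.
#' @param case_mix_confounding Optional confounding knob: shift (per unit of
#'   facility quality effect) applied to the comorbidity burden of patients
#'   at that facility.  Default 0 = case mix independent of quality.
#' @param seed Master seed; all sub-streams derive from it.
#' @return An object of class \code{sim_config}.
#' @seealso [generate_facilities()], [generate_encounters()],
#'   [generate_outcomes()], [simulate_cohort()]
#' @export
sim_config <- function(n_facilities = 30L,
                       n_patients = 15000L,
                       n_systems = 8L,
                       study_years = 2016:2020,
                       facility_effect_sd = 0.6,
                       baseline_sae_logit = stats::qlogis(0.07),
                       covariate_effects = default_covariate_effects(),
                       charge_lognormal_params = c(meanlog = 9.95, sdlog = 0.45),
                       region_extent = c(lat_min = 25.8, lat_max = 29.8,
                                         lon_min = -84.5, lon_max = -80.5),
                       ambulatory_fraction = 0.97,
                       female_fraction = 0.77,
                       gravity_scale_miles = 15,
                       attractiveness_sdlog = 1.5,
                       unaffiliated_fraction = 0,
                       out_of_state_fraction = 0.03,
                       prior_neck_surgery_fraction = 0.01,
                       case_mix_confounding = 0,
                       seed = 1L) {
  cfg <- list(
    n_facilities = as.integer(n_facilities),
    n_patients = as.integer(n_patients),
    n_systems = as.integer(n_systems),
    study_years = as.integer(sort(unique(study_years))),
    facility_effect_sd = facility_effect_sd,
    baseline_sae_logit = baseline_sae_logit,
    covariate_effects = covariate_effects,
    charge_lognormal_params = charge_lognormal_params,
    region_extent = region_extent,
    ambulatory_fraction = ambulatory_fraction,
    female_fraction = female_fraction,
    gravity_scale_miles = gravity_scale_miles,
    attractiveness_sdlog = attractiveness_sdlog,
    unaffiliated_fraction = unaffiliated_fraction,
    out_of_state_fraction = out_of_state_fraction,
    prior_neck_surgery_fraction = prior_neck_surgery_fraction,
    case_mix_confounding = case_mix_confounding,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_facilities < 8L)
    stop_config("n_facilities must be >= 8 so quartiles are non-degenerate")
  if (cfg$n_patients < 1L) stop_config("n_patients must be positive")
  if (cfg$n_systems < 1L || cfg$n_systems > cfg$n_facilities)
    stop_config("n_systems must be in [1, n_facilities]")
  if (cfg$facility_effect_sd < 0) stop_config("facility_effect_sd must be >= 0")
  for (f in c("ambulatory_fraction", "female_fraction", "unaffiliated_fraction",
              "out_of_state_fraction", "prior_neck_surgery_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_config("%s must lie in [0, 1]", f)
  }
  re <- cfg$region_extent
  need <- c("lat_min", "lat_max", "lon_min", "lon_max")
  if (!all(need %in% names(re)))
    stop_config("region_extent must carry lat_min, lat_max, lon_min, lon_max")
  if (re["lat_max"] <= re["lat_min"] || re["lon_max"] <= re["lon_min"])
    stop_config("region_extent must be a non-empty box")
  if (abs(re["lat_min"]) > 90 || abs(re["lat_max"]) > 90 ||
      abs(re["lon_min"]) > 180 || abs(re["lon_max"]) > 180)
    stop_config("region_extent coordinates out of range")
  bad <- setdiff(names(default_covariate_effects()), names(cfg$covariate_effects))
  if (length(bad))
    stop_config("covariate_effects missing term(s): %s", paste(bad, collapse = ", "))
  cfg
}

#' Default true covariate effects of the synthetic SAE model
#'
#' Log-odds effects on the serious-adverse-event scale for the patient
#' covariates of the truth model.  Values are modest, clinically plausible
#' effects: risk rises with age and comorbidity burden, with inpatient
#' setting, and with emergent/urgent admission.  Reference levels are
#' female sex, white race, private insurance, ambulatory setting and
#' elective admission.  \code{age} is per year (centered at 65 years);
#' \code{elixhauser} is per comorbidity category step (0, 1, 2, 3+).
#'
#' @return Named numeric vector of log-odds coefficients.
#' @export
default_covariate_effects <- function() {
  c(age = 0.02,
    sex_male = 0.15,
    race_black = 0.20,
    race_hispanic = 0.10,
    race_other = 0.00,
    race_missing = 0.00,
    insurance_medicaid = 0.30,
    insurance_medicare = 0.10,
    insurance_other_missing = 0.10,
    setting_inpatient = 1.20,
    admission_emergent_urgent = 0.80,
    admission_other_missing = 0.10,
    elixhauser = 0.40)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  facilities: %d in %d systems; patients: %d; years %d-%d\n",
              x$n_facilities, x$n_systems, x$n_patients,
              min(x$study_years), max(x$study_years)))
  cat(sprintf("  baseline SAE rate %.3f; facility effect sd %.2f (logit)\n",
              stats::plogis(x$baseline_sae_logit), x$facility_effect_sd))
  cat(sprintf("  female %.2f; ambulatory %.2f; seed %d\n",
              x$female_fraction, x$ambulatory_fraction, x$seed))
  invisible(x)
}
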