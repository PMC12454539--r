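# Counterfactual reassignment of test-cohort patients to higher-quality
# facilities under proximity or health-system constraints.

#' Reassignment rule of the referral simulation
#'
#' Method \code{"proximity"} allows any facility within
#' \code{max_distance} miles (default 30) of the patient's home zip
#' centroid; method \code{"system"} allows any facility in the original
#' facility's health system, with no distance cap.  Either way the
#' destination must sit in a strictly better (smaller-numbered) quality
#' quartile than the origin.  When several facilities qualify,
#' \code{selection_policy} picks one: \code{"best_quality"} takes the
#' lowest Wilson midpoint (ties to the nearest, then by id);
#' \code{"nearest_eligible"} takes the closest (ties to the lower
#' midpoint, then by id).
#'
#' @param method \code{"proximity"} or \code{"system"}.
#' @param max_distance Miles; only used by the proximity method.
#' @param selection_policy \code{"best_quality"} or
#'   \code{"nearest_eligible"}.
#' @return Object of class \code{reassignment_rule}.
#' @export
reassignment_rule <- function(method = c("proximity", "system"),
                              max_distance = 30,
                              selection_policy = c("best_quality",
                                                   "nearest_eligible")) {
  method <- match.arg(method)
  if (method == "proximity" && (!is.numeric(max_distance) || max_distance <= 0))
    stop_config("max_distance must be positive for the proximity method")
  structure(list(method = method, max_distance = max_distance,
                 selection_policy = match.arg(selection_policy)),
            class = "reassignment_rule")
}

#' Eligible higher-quality alternative facilities for one patient
#'
#' Returns the facilities in a strictly better quartile than the patient's
#' original facility that satisfy the rule's constraint (within
#' \code{max_distance} miles of home for proximity; same health system as
#' the origin for system).  The original facility is never eligible, nor is
#' any facility without a quality estimate.  A patient whose original
#' facility is unranked gets an empty set (flagged upstream).
#'
#' @param patient One-row encounter (needs \code{facility_id},
#'   \code{home_lat}, \code{home_lon}).
#' @param quality Quality table ([facility_quality()]).
#' @param facilities Facility table.
#' @param rule A [reassignment_rule()].
#' @return Data frame of eligible facilities with their quartile, Wilson
#'   midpoint and home distance.
#' @export
eligible_alternatives <- function(patient, quality, facilities, rule) {
  qrow <- match(quality$facility_id, facilities$facility_id)
  if (anyNA(qrow))
    stop_config("quality table references facilities absent from the facility table")
  orig <- patient$facility_id[1]
  q_orig <- quality$quartile[quality$facility_id == orig]
  cand <- data.frame(
    facility_id = quality$facility_id,
    quartile = quality$quartile,
    midpoint = quality$midpoint,
    system_id = facilities$system_id[qrow],
    distance = zip_distance(patient$home_lat[1], patient$home_lon[1],
                            facilities$zip_lat[qrow],
                            facilities$zip_lon[qrow]),
    stringsAsFactors = FALSE
  )
  if (!length(q_orig)) return(cand[0, , drop = FALSE])
  keep <- cand$quartile < q_orig & cand$facility_id != orig
  if (rule$method == "proximity") {
    keep <- keep & cand$distance <= rule$max_distance
  } else {
    orig_sys <- facilities$system_id[facilities$facility_id == orig]
    if (length(orig_sys) != 1 || is.na(orig_sys)) {
      keep <- rep(FALSE, nrow(cand))  # unaffiliated origin: nowhere to go
    } else {
      keep <- keep & !is.na(cand$system_id) & cand$system_id == orig_sys
    }
  }
  cand[keep, , drop = FALSE]
}

#' Select one alternative facility from the eligible set
#'
#' @param eligibles Result of [eligible_alternatives()].
#' @param policy \code{"best_quality"} (lowest Wilson midpoint, ties by
#'   shortest home distance then facility id) or \code{"nearest_eligible"}
#'   (shortest distance, ties by midpoint then id).
#' @return A facility id, or \code{NA} when the set is empty.
#' @export
select_alternative <- function(eligibles,
                               policy = c("best_quality",
                                          "nearest_eligible")) {
  policy <- match.arg(policy)
  if (!NROW(eligibles)) return(NA_character_)
  ord <- if (policy == "best_quality") {
    order(eligibles$midpoint, eligibles$distance, eligibles$facility_id)
  } else {
    order(eligibles$distance, eligibles$midpoint, eligibles$facility_id)
  }
  eligibles$facility_id[ord[1]]
}

#' Run the counterfactual referral simulation on the test cohort
#'
#' For every test-cohort patient, finds the eligible higher-quality
#' alternatives under the rule, selects one, and produces paired
#' original-versus-counterfactual model predictions for each outcome.
#' Patients with no eligible alternative (including everyone already at a
#' quartile-1 facility) keep identical pairs.  Counterfactual outcomes are
#' model predictions only -- no stochastic outcome is re-drawn at the new
#' facility.
#'
#' @param test Prepared test-cohort frame ([prepare_model_frame()], built
#'   with the training tertile map).
#' @param models Named list of fitted models ([fit_outcome_models()]).
#' @param quality Quality table fitted on the training cohort.
#' @param facilities Facility table.
#' @param rule A [reassignment_rule()].
#' @param covariate_update Passed to [predict_outcome()];
#'   \code{"fixed_effect_only"} (default) changes only the facility fixed
#'   effect, \code{"full_facility_swap"} also updates distance and volume
#'   tertile.
#' @return Data frame of class \code{referral_sim} with one row per test
#'   patient: ids, original/alternative facility and quartile, distances,
#'   \code{moved}, and \code{pred_orig_*} / \code{pred_alt_*} columns per
#'   outcome.  Attribute \code{summary} holds cohort-level counts and
#'   means; see [summarize_simulation()] for the paired statistics.
#' @export
run_referral_simulation <- function(test, models, quality, facilities,
                                    rule = reassignment_rule(),
                                    covariate_update = "fixed_effect_only") {
  assert_columns(test, c("patient_id", "facility_id", "home_lat", "home_lon"),
                 "test cohort")
  n <- nrow(test)
  qmap <- stats::setNames(quality$quartile, quality$facility_id)
  unranked <- !(test$facility_id %in% quality$facility_id)

  alt <- rep(NA_character_, n)
  for (i in which(!unranked)) {
    el <- eligible_alternatives(test[i, , drop = FALSE], quality,
                                facilities, rule)
    alt[i] <- select_alternative(el, rule$selection_policy)
  }
  moved <- !is.na(alt)

  fi_orig <- match(test$facility_id, facilities$facility_id)
  d_orig <- zip_distance(test$home_lat, test$home_lon,
                         facilities$zip_lat[fi_orig],
                         facilities$zip_lon[fi_orig])
  d_alt <- d_orig
  if (any(moved)) {
    fi_alt <- match(alt[moved], facilities$facility_id)
    d_alt[moved] <- zip_distance(test$home_lat[moved], test$home_lon[moved],
                                 facilities$zip_lat[fi_alt],
                                 facilities$zip_lon[fi_alt])
  }

  out <- data.frame(
    patient_id = test$patient_id,
    original_facility = test$facility_id,
    alternative_facility = alt,
    moved = moved,
    unranked_origin = unranked,
    quartile_original = unname(qmap[test$facility_id]),
    quartile_alternative = unname(qmap[alt]),
    distance_original = d_orig,
    distance_alternative = d_alt,
    stringsAsFactors = FALSE
  )

  for (nm in names(models)) {
    m <- models[[nm]]
    p_orig <- predict_outcome(m, test)
    p_alt <- p_orig
    if (any(moved)) {
      p_alt[moved] <- predict_outcome(m, test[moved, , drop = FALSE],
                                      at_facility = alt[moved],
                                      covariate_update = covariate_update,
                                      facilities = facilities)
    }
    out[[paste0("pred_orig_", nm)]] <- p_orig
    out[[paste0("pred_alt_", nm)]] <- p_alt
  }

  sae_model <- models[["sae"]]
  discordant <- NA_real_
  if (!is.null(sae_model) && any(moved)) {
    a_orig <- sae_model$alpha[test$facility_id[moved]]
    a_alt <- sae_model$alpha[alt[moved]]
    discordant <- mean(a_alt >= a_orig)
  }

  attr(out, "summary") <- list(
    n = n, n_moved = sum(moved), n_stayed = sum(!moved),
    share_moved = mean(moved),
    n_unranked_origin = sum(unranked),
    discordant_mover_share = discordant,
    rule = rule, covariate_update = covariate_update,
    outcome_means = do.call(rbind, lapply(names(models), function(nm) {
      data.frame(outcome = nm,
                 mean_original = mean(out[[paste0("pred_orig_", nm)]]),
                 mean_simulated = mean(out[[paste0("pred_alt_", nm)]]),
                 stringsAsFactors = FALSE)
    }))
  )
  class(out) <- c("referral_sim", "data.frame")
  out
}

#' @export
print.referral_sim <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Referral simulation (%s method, %s): %d patients, %d moved (%.1f%%)\n",
              s$rule$method, s$covariate_update, s$n, s$n_moved,
              100 * s$share_moved))
  print(s$outcome_means, digits = 4)
  invisible(x)
}
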