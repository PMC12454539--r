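# Risk-adjustment regressions with facility fixed effects, cost
# standardization inputs, and counterfactual prediction.

.model_covariates <- c("age", "sex", "race", "insurance", "setting",
                       "admission_type", "discharge_year", "volume_tertile",
                       "distance_miles", "elixhauser_category")

.factor_levels <- list(
  sex = c("female", "male"),
  race = c("white", "black", "hispanic", "other", "missing"),
  insurance = c("private", "medicaid", "medicare", "other_missing"),
  setting = c("ambulatory", "inpatient"),
  admission_type = c("elective", "emergent_urgent", "other_missing")
)

#' Facility volume tertiles
#'
#' Mean annual facility volumes (cases per distinct discharge year) are
#' split at the empirical 1/3 and 2/3 quantiles across facilities.
#' Facilities exactly on a boundary fall in the lower tertile.
#'
#' @param encounters Training encounters with \code{facility_id} and
#'   \code{discharge_year}.
#' @return Named integer vector mapping facility_id to tertile 1..3, with
#'   the annual volumes as attribute \code{volumes}.
#' @export
compute_volume_tertiles <- function(encounters) {
  assert_columns(encounters, c("facility_id", "discharge_year"), "encounters")
  n_years <- max(length(unique(encounters$discharge_year)), 1)
  vol <- table(encounters$facility_id) / n_years
  if (length(vol) < 3)
    stop_config("need at least 3 facilities to form volume tertiles")
  q <- stats::quantile(as.vector(vol), c(1, 2) / 3, names = FALSE)
  tert <- 1L + (as.vector(vol) > q[1]) + (as.vector(vol) > q[2])
  names(tert) <- names(vol)
  attr(tert, "volumes") <- stats::setNames(as.vector(vol), names(vol))
  tert
}

#' Prepare an encounter table for model fitting and prediction
#'
#' Joins facility attributes, computes the patient-to-facility great-circle
#' distance in miles, the facility volume tertile, the Elixhauser category
#' (0/1/2/3+), standardized cost in 2020 USD, and coerces categorical
#' covariates to factors with fixed reference levels (female, white,
#' private insurance, ambulatory, elective).
#'
#' @param encounters Encounter table.
#' @param facilities Facility table with coordinates and cost parameters.
#' @param tertiles Facility tertile map from [compute_volume_tertiles()];
#'   computed from \code{encounters} when omitted.  Pass the training map
#'   when preparing a test cohort.
#' @param cpi CPI table for cost standardization; see [cpi_factor()].
#' @return The encounter table with modelling columns added.
#' @export
prepare_model_frame <- function(encounters, facilities, tertiles = NULL,
                                cpi = cpi_medical_care) {
  assert_columns(encounters,
                 c("facility_id", "home_lat", "home_lon", "age", "sex",
                   "race", "insurance", "setting", "admission_type",
                   "discharge_year", "elixhauser_count", "total_charges"),
                 "encounters")
  assert_columns(facilities,
                 c("facility_id", "zip_lat", "zip_lon",
                   "cost_to_charge_ratio", "wage_index"), "facilities")
  i <- match(encounters$facility_id, facilities$facility_id)
  if (anyNA(i)) stop_config("encounters reference unknown facilities")
  if (is.null(tertiles)) tertiles <- compute_volume_tertiles(encounters)

  out <- encounters
  out$distance_miles <- zip_distance(encounters$home_lat, encounters$home_lon,
                                     facilities$zip_lat[i],
                                     facilities$zip_lon[i])
  out$volume_tertile <- factor(tertiles[encounters$facility_id],
                               levels = 1:3)
  out$elixhauser_category <- factor(
    ifelse(encounters$elixhauser_count >= 3, "3+",
           as.character(encounters$elixhauser_count)),
    levels = c("0", "1", "2", "3+"))
  for (nm in names(.factor_levels)) {
    out[[nm]] <- factor(as.character(encounters[[nm]]),
                        levels = .factor_levels[[nm]])
    if (anyNA(out[[nm]]))
      stop_config("column '%s' has values outside %s", nm,
                  paste(.factor_levels[[nm]], collapse = "/"))
  }
  out$discharge_year <- factor(encounters$discharge_year)
  out$cost <- standardize_cost(encounters$total_charges,
                               facilities$cost_to_charge_ratio[i],
                               facilities$wage_index[i],
                               cpi_factor(encounters$discharge_year, cpi))
  out
}

glm_family <- function(family) {
  switch(family,
         logistic = stats::binomial(),
         poisson = stats::poisson(),
         linear = stats::gaussian(),
         stop_config("unknown family '%s'", family))
}

#' Fit a risk-adjustment model with facility fixed effects
#'
#' Fits the outcome on the fixed covariate set -- age, race, sex,
#' insurance, setting, admission type, discharge year, facility volume
#' tertile, patient-facility distance, Elixhauser category -- plus one
#' indicator per facility.  Serious adverse events and other binary
#' outcomes use logistic regression, length of stay Poisson regression and
#' cost linear regression.  The reference facility (fixed effect 0)
#' defaults to the largest training volume; predictions are invariant to
#' this choice.
#'
#' Volume tertile is constant within facility and therefore collinear with
#' the facility indicators; the facility terms enter first, so aliased
#' tertile coefficients are recorded as 0 and flagged, their contribution
#' being absorbed into the fixed effects.
#'
#' For a binomial outcome, facilities with zero (or all) events separate
#' perfectly and their maximum-likelihood fixed effect diverges.  When
#' detected, the whole model is refitted with a weak ridge penalty applied
#' to the facility indicators only (unpenalized patient covariates),
#' keeping every facility's effect finite.
#'
#' @param train Prepared training frame ([prepare_model_frame()]).
#' @param outcome Name of the outcome column.
#' @param family \code{"logistic"}, \code{"poisson"} or \code{"linear"}.
#' @param reference_facility Facility id of the zero fixed effect; default
#'   the facility with most training encounters.
#' @param ridge_lambda Penalty of the separation fallback (glmnet scale).
#' @return Object of class \code{fitted_outcome_model} with elements
#'   \code{beta} (intercept and covariate coefficients), \code{alpha}
#'   (named facility fixed effects, reference = 0), \code{xlevels},
#'   \code{tertile_map}, diagnostics and the model spec.
#' @export
fit_outcome_model <- function(train, outcome,
                              family = c("logistic", "poisson", "linear"),
                              reference_facility = NULL,
                              ridge_lambda = 1e-3) {
  family <- match.arg(family)
  assert_columns(train, c(outcome, .model_covariates, "facility_id"),
                 "training frame")
  if (anyNA(train[[outcome]]))
    stop_config("outcome '%s' contains NA", outcome)
  df <- train
  df$.y <- as.numeric(df[[outcome]])
  vols <- table(df$facility_id)
  if (is.null(reference_facility)) {
    reference_facility <- names(vols)[which.max(vols)]
  } else if (!reference_facility %in% names(vols)) {
    stop_config("reference facility '%s' not in training data",
                reference_facility)
  }
  fac_levels <- c(reference_facility,
                  setdiff(sort(names(vols)), reference_facility))
  df$facility <- factor(df$facility_id, levels = fac_levels)
  df <- droplevels(df)

  # constant covariates (and a single-facility cohort) carry no information
  # and would break the contrasts; drop them and record the fact
  varies <- vapply(.model_covariates, function(nm) {
    x <- df[[nm]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else stats::sd(x) > 0
  }, logical(1))
  terms_used <- .model_covariates[varies]
  use_facility <- nlevels(df$facility) > 1
  rhs <- paste(c(if (use_facility) "facility", terms_used),
               collapse = " + ")
  if (rhs == "") rhs <- "1"
  form <- stats::as.formula(paste(".y ~", rhs))

  separated <- FALSE
  if (family == "logistic" && use_facility) {
    rate <- tapply(df$.y, df$facility, mean)
    separated <- any(rate %in% c(0, 1))
  }

  if (!separated) {
    fit <- suppressWarnings(stats::glm(form, data = df,
                                       family = glm_family(family)))
    co <- stats::coef(fit)
    aliased <- names(co)[is.na(co)]
    co[is.na(co)] <- 0
    converged <- if (family == "linear") TRUE else fit$converged
    deviance <- stats::deviance(fit)
    vcov_ok <- stats::summary.glm(fit)$coefficients
    se <- stats::setNames(rep(NA_real_, length(co)), names(co))
    se[rownames(vcov_ok)] <- vcov_ok[, "Std. Error"]
  } else {
    pen <- fit_penalized(df, terms_used, family, ridge_lambda,
                         reference_facility)
    co <- pen$coef
    aliased <- pen$aliased
    converged <- TRUE
    deviance <- pen$deviance
    se <- stats::setNames(rep(NA_real_, length(co)), names(co))
  }

  is_fac <- grepl("^facility", names(co)) &
    !grepl("^facility_id", names(co))
  alpha <- co[is_fac]
  names(alpha) <- sub("^facility", "", names(alpha))
  alpha_se <- se[is_fac]
  names(alpha_se) <- sub("^facility", "", names(alpha_se))
  alpha <- c(stats::setNames(0, reference_facility), alpha)
  alpha_se <- c(stats::setNames(0, reference_facility), alpha_se)
  alpha <- alpha[fac_levels]
  alpha_se <- alpha_se[fac_levels]
  beta <- co[!is_fac]

  structure(list(
    outcome = outcome,
    family = family,
    covariates = terms_used,
    dropped_covariates = .model_covariates[!varies],
    beta = beta,
    beta_se = se[!is_fac],
    alpha = alpha,
    alpha_se = alpha_se,
    reference_facility = reference_facility,
    xlevels = lapply(df[terms_used], function(x)
      if (is.factor(x)) levels(x) else NULL),
    tertile_map = tertile_lookup(df),
    aliased = aliased,
    separated = separated,
    converged = converged,
    deviance = deviance,
    n = nrow(df)
  ), class = "fitted_outcome_model")
}

tertile_lookup <- function(df) {
  first <- !duplicated(df$facility_id)
  stats::setNames(as.integer(as.character(df$volume_tertile[first])),
                  df$facility_id[first])
}

# weak-ridge refit used when a facility indicator separates perfectly.
# The facility part enters as a FULL dummy set (one column per facility)
# so the penalty treats every facility symmetrically: the fit, and hence
# every prediction, does not depend on which facility is later declared
# the reference.  Patient covariates and the intercept are unpenalized;
# afterwards the effects are re-centred so alpha[reference] = 0.
fit_penalized <- function(df, terms_used, family, lambda, reference) {
  Xcov <- if (length(terms_used)) {
    stats::model.matrix(stats::as.formula(
      paste("~", paste(terms_used, collapse = " + "))), data = df)
  } else {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  }
  Xcov <- Xcov[, colnames(Xcov) != "(Intercept)", drop = FALSE]
  Fd <- stats::model.matrix(~ facility - 1, data = df)
  X <- cbind(Xcov, Fd)
  pf <- c(rep(0, ncol(Xcov)), rep(1, ncol(Fd)))
  gfam <- switch(family, logistic = "binomial", poisson = "poisson",
                 linear = "gaussian")
  gfit <- glmnet::glmnet(X, df$.y, family = gfam, alpha = 0,
                         penalty.factor = pf,
                         lambda = c(0.1, 0.01, lambda),
                         standardize = FALSE, thresh = 1e-12)
  co <- as.vector(stats::coef(gfit, s = lambda))
  names(co) <- c("(Intercept)", colnames(X))
  af <- co[paste0("facility", levels(df$facility))]
  names(af) <- levels(df$facility)
  af_centred <- af - af[reference]
  out <- c(co["(Intercept)"] + af[reference],
           co[colnames(Xcov)],
           stats::setNames(af_centred[names(af_centred) != reference],
                           paste0("facility",
                                  names(af_centred)[names(af_centred) != reference])))
  names(out)[1] <- "(Intercept)"
  list(coef = out, aliased = character(),
       deviance = (1 - gfit$dev.ratio[length(gfit$lambda)]) * gfit$nulldev)
}

#' @export
print.fitted_outcome_model <- function(x, ...) {
  cat(sprintf("Risk-adjustment model: %s (%s), n = %d, %d facilities\n",
              x$outcome, x$family, x$n, length(x$alpha)))
  cat(sprintf("  reference facility %s; converged: %s%s\n",
              x$reference_facility, x$converged,
              if (x$separated) "; separation handled by ridge refit" else ""))
  invisible(x)
}

coerce_xlevels <- function(newdata, xlevels) {
  for (nm in names(xlevels)) {
    if (is.null(xlevels[[nm]])) next
    x <- as.character(newdata[[nm]])
    bad <- !x %in% xlevels[[nm]]
    if (any(bad)) {
      warning(sprintf("%d value(s) of '%s' unseen in training; mapped to reference level",
                      sum(bad), nm))
      x[bad] <- xlevels[[nm]][1]
    }
    newdata[[nm]] <- factor(x, levels = xlevels[[nm]])
  }
  newdata
}

#' Predict an outcome at an (alternative) facility
#'
#' Computes the linear predictor \eqn{\eta = X\beta + \alpha_f} for each
#' encounter at facility \eqn{f} and maps it through the inverse link
#' (probability for logistic, expected count for Poisson, USD for linear).
#' With \code{covariate_update = "fixed_effect_only"} (the default, and the
#' counterfactual rule of the referral simulation) only the facility fixed
#' effect changes between facilities; distance and volume tertile keep
#' their original values.  With \code{"full_facility_swap"} the
#' patient-facility distance and the volume tertile are recomputed for the
#' target facility, which requires the \code{facilities} table.
#'
#' @param model A [fit_outcome_model()] result.
#' @param newdata Prepared encounter frame ([prepare_model_frame()]).
#' @param at_facility Facility id(s) to predict at, recycled to
#'   \code{nrow(newdata)}; default the encounter's own facility.
#' @param covariate_update \code{"fixed_effect_only"} or
#'   \code{"full_facility_swap"}.
#' @param facilities Facility table (coordinates), needed only for
#'   \code{"full_facility_swap"}.
#' @return Numeric vector of expected outcomes on the response scale.
#' @export
predict_outcome <- function(model, newdata, at_facility = NULL,
                            covariate_update = c("fixed_effect_only",
                                                 "full_facility_swap"),
                            facilities = NULL) {
  covariate_update <- match.arg(covariate_update)
  at_facility <- rep_len(at_facility %||% newdata$facility_id,
                         nrow(newdata))
  unknown <- setdiff(unique(at_facility), names(model$alpha))
  if (length(unknown))
    stop_config("no fitted fixed effect for facility/ies: %s",
                paste(unknown, collapse = ", "))

  if (covariate_update == "full_facility_swap") {
    if (is.null(facilities))
      stop_config("full_facility_swap requires the facility table")
    j <- match(at_facility, facilities$facility_id)
    if (anyNA(j))
      stop_config("target facility missing from the facility table")
    newdata$distance_miles <- zip_distance(newdata$home_lat,
                                           newdata$home_lon,
                                           facilities$zip_lat[j],
                                           facilities$zip_lon[j])
    newdata$volume_tertile <- factor(model$tertile_map[at_facility],
                                     levels = 1:3)
  }

  newdata <- coerce_xlevels(newdata, model$xlevels)
  rhs <- paste(model$covariates, collapse = " + ")
  if (rhs == "") rhs <- "1"
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)),
                           data = newdata)
  b <- model$beta[colnames(X)]
  b[is.na(b)] <- 0
  eta <- unname(drop(X %*% b)) + unname(model$alpha[at_facility])
  switch(model$family,
         logistic = stats::plogis(eta),
         poisson = exp(eta),
         linear = eta)
}

#' Fit the full outcome model set
#'
#' Fits the standard outcome battery on one training frame: logistic models
#' for SAE, technical events, medical events and 30-day readmission, a
#' Poisson model for length of stay and a linear model for standardized
#' cost.
#'
#' @param train Prepared training frame.
#' @param outcomes Character vector naming which models to fit; any subset
#'   of \code{c("sae", "technical_event", "medical_event", "readmit_30d",
#'   "los_days", "cost")}.
#' @param ... Passed to [fit_outcome_model()].
#' @return Named list of \code{fitted_outcome_model}s.
#' @export
fit_outcome_models <- function(train,
                               outcomes = c("sae", "technical_event",
                                            "medical_event", "readmit_30d",
                                            "los_days", "cost"),
                               ...) {
  fams <- c(sae = "logistic", technical_event = "logistic",
            medical_event = "logistic", readmit_30d = "logistic",
            los_days = "poisson", cost = "linear")
  bad <- setdiff(outcomes, names(fams))
  if (length(bad))
    stop_config("unknown outcome(s): %s", paste(bad, collapse = ", "))
  stats::setNames(
    lapply(outcomes, function(o)
      fit_outcome_model(train, o, family = fams[[o]], ...)),
    outcomes)
}
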