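# Independent oracles: brute-force or closed-form routes that never touch
# the implementation they check.

# Wilson interval by numerically inverting the score statistic
# |phat - p| / sqrt(p (1 - p) / n) = z; the midpoint is the mean of the
# two roots.
wilson_oracle <- function(k, n, confidence = 0.95) {
  z <- qnorm((1 + confidence) / 2)
  phat <- k / n
  f <- function(p) (phat - p)^2 - z^2 * p * (1 - p) / n
  # bracket endpoints avoid p = phat in {0, 1}, where f has a trivial root
  lower <- if (k == 0) 0 else
    uniroot(f, c(1e-15, min(phat, 1 - 1e-9)), tol = 1e-13)$root
  upper <- if (k == n) 1 else
    uniroot(f, c(max(phat, 1e-9), 1 - 1e-15), tol = 1e-13)$root
  c(lower = lower, midpoint = (lower + upper) / 2, upper = upper)
}

# spherical law of cosines on the same 3958.8-mile sphere
law_of_cosines_miles <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  3958.8 * acos(pmin(1, sin(lat1 * r) * sin(lat2 * r) +
                        cos(lat1 * r) * cos(lat2 * r) * cos((lon2 - lon1) * r)))
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# exact two-sided rank-sum p by enumerating all C(n1+n2, n1) labelings
enum_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  w_obs <- sum(r[seq_len(n1)])
  combos <- combn(length(pooled), n1)
  w_all <- apply(combos, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# two-sided Fisher p by summing hypergeometric probabilities of all tables
# with the observed margins that are no more likely than the observed one
enum_fisher_p <- function(tab) {
  m <- rowSums(tab); k <- colSums(tab)
  xs <- max(0, k[1] - m[2]):min(m[1], k[1])
  probs <- dhyper(xs, m[1], m[2], k[1])
  p_obs <- dhyper(tab[1, 1], m[1], m[2], k[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# minimal prepared model frame with every covariate present (constant
# unless overridden) so degenerate fits are exercised directly
minimal_frame <- function(n, facility = "A", y = 0, sex = "female",
                          age = 50, distance = 5) {
  data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    facility_id = rep_len(facility, n),
    age = rep_len(age, n),
    sex = factor(rep_len(sex, n), levels = c("female", "male")),
    race = factor("white", levels = c("white", "black", "hispanic",
                                      "other", "missing")),
    insurance = factor("private", levels = c("private", "medicaid",
                                             "medicare", "other_missing")),
    setting = factor("ambulatory", levels = c("ambulatory", "inpatient")),
    admission_type = factor("elective", levels = c("elective",
                                                   "emergent_urgent",
                                                   "other_missing")),
    discharge_year = factor(2018),
    volume_tertile = factor(1, levels = 1:3),
    distance_miles = rep_len(distance, n),
    elixhauser_category = factor("0", levels = c("0", "1", "2", "3+")),
    home_lat = 27, home_lon = -81.5,
    y = rep_len(y, n),
    stringsAsFactors = FALSE
  )
}

# toy facility table at given mile offsets north of a home point
toy_facilities <- function(ids, miles_from_home, systems = NA,
                           home = c(lat = 27, lon = -81.5)) {
  data.frame(
    facility_id = ids,
    system_id = rep_len(systems, length(ids)),
    zip_lat = home["lat"] + miles_from_home / 69.1,
    zip_lon = home["lon"],
    cost_to_charge_ratio = 0.3,
    wage_index = 1,
    attractiveness = 1,
    charge_offset = 0,
    true_quality_effect = 0,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# hand-built logistic model object with known intercept and fixed effects
toy_sae_model <- function(alpha, intercept = -3) {
  structure(list(
    outcome = "sae", family = "logistic", covariates = "age",
    dropped_covariates = character(),
    beta = c("(Intercept)" = intercept, age = 0),
    beta_se = c("(Intercept)" = NA_real_, age = NA_real_),
    alpha = alpha, reference_facility = names(alpha)[1],
    xlevels = list(age = NULL),
    tertile_map = setNames(rep(1L, length(alpha)), names(alpha)),
    aliased = character(), separated = FALSE, converged = TRUE,
    deviance = 0, n = 0L
  ), class = "fitted_outcome_model")
}
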