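test_that("volume tertiles split at the one-third quantiles", {
  enc <- data.frame(
    facility_id = rep(c("A", "B", "C"), c(10, 50, 500)),
    discharge_year = 2018)
  t3 <- compute_volume_tertiles(enc)
  expect_equal(unname(t3[c("A", "B", "C")]), c(1L, 2L, 3L))
  # 9 facilities with distinct volumes: 3 per tertile
  enc9 <- data.frame(
    facility_id = rep(sprintf("F%d", 1:9), times = (1:9) * 10),
    discharge_year = 2018)
  t9 <- compute_volume_tertiles(enc9)
  expect_equal(as.vector(table(t9)), c(3L, 3L, 3L))
  # boundary tie goes to the lower tertile
  encT <- data.frame(
    facility_id = rep(c("A", "B", "C"), c(20, 20, 100)),
    discharge_year = 2018)
  tT <- compute_volume_tertiles(encT)
  expect_equal(unname(tT[c("A", "B")]), c(1L, 1L))
  expect_error(compute_volume_tertiles(
    data.frame(facility_id = c("A", "B"), discharge_year = 2018)),
    "at least 3")
})

test_that("logistic fit recovers the closed-form log odds ratio", {
  # 2x2: events 10/100 among males, 5/100 among females
  fr <- minimal_frame(200, sex = rep(c("male", "female"), each = 100),
                      y = c(rep(1, 10), rep(0, 90), rep(1, 5), rep(0, 95)))
  m <- fit_outcome_model(fr, "y", family = "logistic")
  expect_equal(unname(m$beta["sexmale"]),
               log((10 * 95) / (90 * 5)), tolerance = 1e-6)
  expect_true(m$converged)
  expect_true("race" %in% m$dropped_covariates)
})

test_that("intercept-only poisson fit is the log mean", {
  fr <- minimal_frame(4, y = c(0, 1, 2, 3))
  m <- fit_outcome_model(fr, "y", family = "poisson")
  expect_equal(unname(m$beta["(Intercept)"]), log(1.5), tolerance = 1e-8)
})

test_that("facility fixed effects are referenced to the largest facility", {
  fr <- rbind(minimal_frame(60, facility = "BIG", y = rbinom(60, 1, 0.2)),
              minimal_frame(30, facility = "SML", y = rbinom(30, 1, 0.4)))
  set.seed(5); fr$y <- rbinom(90, 1, ifelse(fr$facility_id == "BIG", .2, .4))
  m <- fit_outcome_model(fr, "y", family = "logistic")
  expect_equal(m$reference_facility, "BIG")
  expect_equal(unname(m$alpha["BIG"]), 0)
  expect_true(all(names(m$alpha) %in% c("BIG", "SML")))
})

test_that("predictions are invariant to the reference facility", {
  set.seed(9)
  sim <- simulate_cohort(sim_config(n_facilities = 8, n_systems = 4,
                                    n_patients = 1500, seed = 21))
  fr <- prepare_model_frame(sim$encounters, sim$facilities)
  m1 <- fit_outcome_model(fr, "sae", "logistic")
  other <- setdiff(names(m1$alpha), m1$reference_facility)[1]
  m2 <- fit_outcome_model(fr, "sae", "logistic", reference_facility = other)
  expect_equal(predict_outcome(m1, fr), predict_outcome(m2, fr),
               tolerance = 1e-6)
})

test_that("prediction honours the covariate-update modes", {
  fr <- minimal_frame(1)
  m <- toy_sae_model(c(A = 1, B = -1, C = -1))
  # original facility: eta = -3 + 1
  expect_equal(predict_outcome(m, fr), plogis(-2))
  # equal alphas give identical fixed-effect-only predictions
  expect_equal(predict_outcome(m, fr, at_facility = "B"),
               predict_outcome(m, fr, at_facility = "C"))
  # lower alpha gives strictly lower logistic prediction
  expect_lt(predict_outcome(m, fr, at_facility = "B"),
            predict_outcome(m, fr, at_facility = "A"))
  expect_error(predict_outcome(m, fr, at_facility = "Z"), "no fitted")
})

test_that("link ranges hold and alpha shifts are equivariant", {
  set.seed(31)
  sim <- simulate_cohort(sim_config(n_facilities = 8, n_systems = 4,
                                    n_patients = 1200, seed = 31))
  fr <- prepare_model_frame(sim$encounters, sim$facilities)
  ml <- fit_outcome_model(fr, "sae", "logistic")
  pl <- predict_outcome(ml, fr)
  expect_true(all(pl > 0 & pl < 1))
  mp <- fit_outcome_model(fr, "los_days", "poisson")
  expect_true(all(predict_outcome(mp, fr) > 0))
  # adding c to every alpha and subtracting it from the intercept is a no-op
  shifted <- ml
  shifted$alpha <- ml$alpha + 0.7
  shifted$beta["(Intercept)"] <- ml$beta["(Intercept)"] - 0.7
  expect_equal(predict_outcome(shifted, fr), pl, tolerance = 1e-12)
})

test_that("zero-event facilities trigger the ridge fallback with finite effects", {
  set.seed(13)
  fr <- rbind(minimal_frame(120, facility = "A"),
              minimal_frame(120, facility = "B"),
              minimal_frame(40, facility = "Z"))
  fr$y <- c(rbinom(120, 1, 0.25), rbinom(120, 1, 0.10), rep(0, 40))
  m <- fit_outcome_model(fr, "y", family = "logistic")
  expect_true(m$separated)
  expect_true(all(is.finite(m$alpha)))
  expect_equal(unname(m$alpha[m$reference_facility]), 0)
  # the zero-event facility still predicts lowest risk
  p <- sapply(c("A", "B", "Z"), function(f)
    predict_outcome(m, minimal_frame(1), at_facility = f))
  expect_equal(names(which.min(p)), "Z")
})

test_that("fitted coefficients recover the generator's truth", {
  # 1000 encounters/facility: enough information for tight recovery
  cfg <- sim_config(n_facilities = 12, n_patients = 12000,
                    facility_effect_sd = 0.5, attractiveness_sdlog = 0,
                    gravity_scale_miles = 1e6, seed = 33)
  sim <- simulate_cohort(cfg)
  fr <- prepare_model_frame(sim$encounters, sim$facilities)
  m <- fit_outcome_model(fr, "sae", "logistic")
  truth <- sim$facilities$true_quality_effect[
    match(names(m$alpha), sim$facilities$facility_id)]
  expect_gt(cor(m$alpha, truth), 0.9)
  # 3-SE bands: several coefficients are checked at once, so per-check
  # 2-SE bands would fail by chance in a sizeable share of healthy runs
  eff <- cfg$covariate_effects
  expect_lt(abs(m$beta[["age"]] - eff[["age"]]), 3 * m$beta_se[["age"]])
  expect_lt(abs(m$beta[["settinginpatient"]] - eff[["setting_inpatient"]]),
            3 * m$beta_se[["settinginpatient"]])
  expect_lt(abs(m$beta[["elixhauser_category2"]] - 2 * eff[["elixhauser"]]),
            3 * m$beta_se[["elixhauser_category2"]])
})

test_that("prepared frames carry standardized cost and distances", {
  sim <- simulate_cohort(sim_config(n_facilities = 8, n_systems = 4,
                                    n_patients = 300, seed = 2))
  fr <- prepare_model_frame(sim$encounters, sim$facilities)
  i <- match(fr$facility_id, sim$facilities$facility_id)
  expect_equal(fr$cost,
               fr$total_charges * sim$facilities$cost_to_charge_ratio[i] /
                 sim$facilities$wage_index[i] *
                 cpi_factor(fr$discharge_year))
  expect_true(all(fr$distance_miles >= 0))
  expect_s3_class(fr$elixhauser_category, "factor")
})
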