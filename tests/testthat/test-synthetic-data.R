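test_that("generation is deterministic given the seed", {
  cfg <- sim_config(n_facilities = 20, n_patients = 500, seed = 7)
  f1 <- generate_facilities(cfg)
  f2 <- generate_facilities(cfg)
  expect_identical(f1, f2)
  e1 <- generate_outcomes(generate_encounters(f1, cfg), f1, cfg)
  e2 <- generate_outcomes(generate_encounters(f2, cfg), f2, cfg)
  expect_identical(e1, e2)
  # facilities do not depend on the patient count
  cfg2 <- sim_config(n_facilities = 20, n_patients = 900, seed = 7)
  expect_identical(f1, generate_facilities(cfg2))
})

test_that("degenerate variance gives identical-quality facilities", {
  cfg <- sim_config(n_facilities = 10, facility_effect_sd = 0, seed = 3)
  expect_true(all(generate_facilities(cfg)$true_quality_effect == 0))
})

test_that("system assignment partitions facilities", {
  cfg <- sim_config(n_facilities = 20, n_systems = 5, n_patients = 100,
                    seed = 11)
  f <- generate_facilities(cfg)
  expect_equal(nrow(f), 20)
  expect_true(all(f$system_id %in% sprintf("S%02d", 1:5)))
  expect_equal(length(unique(f$system_id)), 5)
  expect_gte(max(table(f$system_id)), 2)
  expect_error(generate_facilities(sim_config(n_facilities = 8, n_systems = 8)),
               "n_systems")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_facilities = 4), "non-degenerate")
  expect_error(sim_config(facility_effect_sd = -1), ">= 0")
  expect_error(sim_config(female_fraction = 1.3), "\\[0, 1\\]")
  expect_error(sim_config(region_extent = c(lat_min = 2, lat_max = 1,
                                            lon_min = 0, lon_max = 1)),
               "non-empty box")
})

test_that("covariate marginals hit their configured targets", {
  cfg <- sim_config(n_facilities = 10, n_patients = 5000,
                    female_fraction = 1, seed = 5)
  f <- generate_facilities(cfg)
  expect_true(all(generate_encounters(f, cfg)$sex == "female"))

  cfg <- sim_config(n_facilities = 10, n_patients = 5000,
                    female_fraction = 0.77, seed = 5)
  enc <- generate_encounters(generate_facilities(cfg), cfg)
  se <- sqrt(0.77 * 0.23 / 5000)
  expect_lt(abs(mean(enc$sex == "female") - 0.77), 3 * se)

  # marginal calibration at n = 10,000: configured fractions within 4 SE
  cfg <- sim_config(n_facilities = 10, n_patients = 10000, seed = 9)
  enc <- generate_encounters(generate_facilities(cfg), cfg)
  for (chk in list(c(mean(enc$setting == "ambulatory"), 0.97),
                   c(mean(enc$sex == "female"), 0.77),
                   c(mean(enc$out_of_state), 0.03))) {
    se <- sqrt(chk[2] * (1 - chk[2]) / 10000)
    expect_lt(abs(chk[1] - chk[2]), 4 * se)
  }
})

test_that("zero gravity scale sends every patient to the nearest facility", {
  cfg <- sim_config(n_facilities = 12, n_patients = 400,
                    gravity_scale_miles = 0, seed = 2)
  f <- generate_facilities(cfg)
  enc <- generate_encounters(f, cfg)
  d <- outer(seq_len(nrow(enc)), seq_len(nrow(f)), function(i, j)
    zip_distance(enc$home_lat[i], enc$home_lon[i], f$zip_lat[j], f$zip_lon[j]))
  nearest <- f$facility_id[max.col(-d, ties.method = "first")]
  expect_identical(enc$facility_id, nearest)
})

test_that("outcome truth model is calibrated", {
  # extreme negative intercept: no events
  cfg <- sim_config(n_facilities = 10, n_patients = 10000,
                    baseline_sae_logit = -30, facility_effect_sd = 0,
                    covariate_effects = 0 * default_covariate_effects(),
                    seed = 4)
  sim <- simulate_cohort(cfg)
  expect_equal(sum(sim$encounters$sae), 0)

  # flat model at logit(0.07): pooled rate within 3 SE
  cfg <- sim_config(n_facilities = 10, n_patients = 20000,
                    baseline_sae_logit = qlogis(0.07),
                    facility_effect_sd = 0,
                    covariate_effects = 0 * default_covariate_effects(),
                    seed = 4)
  sim <- simulate_cohort(cfg)
  se <- sqrt(0.07 * 0.93 / 20000)
  expect_lt(abs(mean(sim$encounters$sae) - 0.07), 3 * se)
})

test_that("facility quality effects separate empirical SAE rates", {
  cfg <- sim_config(n_facilities = 8, n_systems = 4, n_patients = 10000,
                    covariate_effects = 0 * default_covariate_effects(),
                    seed = 6)
  f <- generate_facilities(cfg)[1:2, ]
  f$true_quality_effect <- c(-1, 1)
  enc <- generate_encounters(f, cfg)
  enc$facility_id <- rep(f$facility_id, length.out = nrow(enc))  # 5000 each
  enc <- generate_outcomes(enc, f, cfg)
  rates <- tapply(enc$sae, enc$facility_id, mean)
  expect_gt(rates[[f$facility_id[2]]], rates[[f$facility_id[1]]])
})

test_that("the composite SAE definition holds exactly", {
  sim <- simulate_cohort(sim_config(n_facilities = 10, n_patients = 4000,
                                    seed = 8))
  enc <- sim$encounters
  expect_identical(enc$sae,
                   enc$technical_event | enc$medical_event |
                     enc$readmit_30d_urgent | enc$death)
  expect_true(all(enc$readmit_30d[enc$readmit_30d_urgent]))
  expect_true(all(enc$los_days >= 0))
  expect_true(all(enc$total_charges > 0))
  expect_true(all(enc$age >= 18))
})

test_that("written tables round-trip with the config sidecar", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(sim_config(n_facilities = 9, n_patients = 200,
                                    seed = 12))
  paths <- write_synthetic_data(sim, dir)
  expect_true(all(file.exists(paths)))
  fac <- read.csv(paths["facilities"])
  expect_equal(nrow(fac), 9)
  cfg <- jsonlite::read_json(paths["config"])
  expect_equal(cfg$seed, 12)
  expect_equal(cfg$n_patients, 200)
})
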