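test_that("paired t matches the textbook formula", {
  r <- paired_t(c(1, 2, 3, 4, 5))
  expect_equal(r$statistic, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-10)
  expect_equal(r$statistic, 4.2426, tolerance = 1e-4)
  expect_equal(r$df, 4)
  # sign symmetry
  r2 <- paired_t(-c(1, 2, 3, 4, 5))
  expect_equal(abs(r2$statistic), abs(r$statistic))
  expect_equal(r2$p, r$p)
  # degenerate: all differences identical
  rz <- paired_t(rep(0, 10))
  expect_true(rz$degenerate)
  expect_true(is.na(rz$p))
  expect_error(paired_t(1), "at least 2")
})

test_that("signed-rank p agrees with exact enumeration", {
  r <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r$statistic, 6)
  expect_equal(r$p, 0.25)
  expect_equal(r$p, enum_signed_rank_p(c(1, 2, 3)))
  set.seed(23)
  for (i in 1:5) {
    d <- round(rnorm(8), 3)
    expect_equal(wilcoxon_signed_rank(d)$p, enum_signed_rank_p(d),
                 tolerance = 1e-10)
  }
  # scale invariance
  d <- c(-0.3, 1.2, 2.5, -0.1, 0.7)
  expect_equal(wilcoxon_signed_rank(d)$p, wilcoxon_signed_rank(10 * d)$p)
  # zeros dropped and reported
  rz <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_match(rz$note, "2 zero")
  expect_equal(rz$p, 0.25)
  expect_true(wilcoxon_signed_rank(c(0, 0, 0))$degenerate)
})

test_that("rank-sum p agrees with exact enumeration", {
  r <- rank_sum(c(1, 2), c(10, 20))
  expect_equal(r$statistic, 0)  # Mann-Whitney U
  expect_equal(r$p, 1 / 3, tolerance = 1e-10)
  expect_equal(r$p, enum_rank_sum_p(c(1, 2), c(10, 20)))
  set.seed(29)
  a <- round(rnorm(5), 3); b <- round(rnorm(6, 0.5), 3)
  expect_equal(rank_sum(a, b)$p, enum_rank_sum_p(a, b), tolerance = 1e-10)
  # monotone-transform invariance for positive data
  x <- rexp(5) + 0.1; y <- rexp(7) + 0.1
  expect_equal(rank_sum(x, y)$p, rank_sum(log(x), log(y))$p)
  # identical samples are exactly indistinguishable
  expect_equal(rank_sum(1:5, 1:5)$p, 1, tolerance = 1e-10)
  expect_error(rank_sum(numeric(), 1:3), "non-empty")
})

test_that("exact and approximate signed-rank agree at the crossover size", {
  set.seed(37)
  for (i in 1:5) {
    d <- round(rnorm(12), 3)
    exact <- wilcoxon_signed_rank(d)$p  # n = 12: exact branch
    approx <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("chi-square and Fisher behave as documented", {
  flat <- matrix(10, 2, 2)
  r <- chi_square(flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # Fisher two-sided matches hypergeometric enumeration
  tab <- matrix(c(1, 8, 9, 2), 2)  # [[1,9],[8,2]] row-major
  rf <- fisher_exact(tab)
  expect_equal(rf$p, enum_fisher_p(tab), tolerance = 1e-10)
  expect_equal(rf$p, 0.005477, tolerance = 1e-4)
  # automatic escalation at low expected counts
  r2 <- chi_square(tab)
  expect_equal(r2$test, "Fisher exact")
  # scaling cells x10 keeps the odds ratio but shrinks the p
  big <- tab * 10
  expect_lt(chi_square(big, escalate = FALSE)$p, rf$p)
  # degenerate margins flagged
  expect_true(chi_square(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))$degenerate)
  expect_error(fisher_exact(matrix(1, 3, 3)), "2x2")
})

test_that("small categorical cells are masked in displays", {
  cells <- mask_small_cells(c(0, 7, 11, 300), 400)
  expect_equal(cells[1], "0 (0.0)")
  expect_equal(cells[2], "-")
  expect_match(cells[3], "^11 ")
  expect_match(cells[4], "^300 ")
})

test_that("baseline tables compare, route and mask correctly", {
  set.seed(41)
  g <- data.frame(age = rnorm(200, 65, 10),
                  sex = sample(c("female", "male"), 200, TRUE, c(.8, .2)),
                  volume = rpois(200, 150))
  tab_same <- build_baseline_table(g, g, c("age", "sex"))
  p <- tab_same$p[!is.na(tab_same$p)]
  expect_true(all(p == 1 | is.na(p)))
  # a rare category is masked in the export
  g2 <- g; g2$sex[1:7] <- "other"; g2$sex[8:200] <- "female"
  # 2x3 table with a sparse level: documented low-expected-count warning
  expect_warning(
    tab <- build_baseline_table(g2, g, "sex", group_labels = c("A", "B")),
    "expected cell count")
  expect_true("-" %in% tab$A)
  expect_false(any(grepl("^7 ", tab$A)))
  # paired facility-dependent variables use the signed-rank test
  tp <- build_baseline_table(g, transform(g, volume = volume + 1), "volume",
                             paired = TRUE, paired_vars = "volume")
  expect_equal(tp$test[1], "Wilcoxon signed-rank")
  tu <- build_baseline_table(g, g, "volume")
  expect_equal(tu$test[1], "Wilcoxon rank-sum")
  expect_error(build_baseline_table(g, g, "nope"), "schema")
})

test_that("simulation summaries propagate signs and conserve counts", {
  fac <- toy_facilities(c("A", "B"), c(2, 10))
  q <- data.frame(facility_id = c("A", "B"), quartile = c(4, 1),
                  midpoint = c(0.3, 0.05), n = 100)
  m <- toy_sae_model(c(A = 1, B = -1))
  test_fr <- minimal_frame(20, facility = rep(c("A", "B"), 10))
  sim <- run_referral_simulation(test_fr, list(sae = m), q, fac,
                                 reassignment_rule("proximity"))
  rep_ <- summarize_simulation(sim)
  all_row <- rep_[rep_$scope == "all", ]
  mov_row <- rep_[rep_$scope == "movers", ]
  cnt <- attr(rep_, "counts")
  expect_equal(cnt$n_moved + cnt$n_stayed, cnt$n)
  expect_equal(mov_row$n, cnt$n_moved)
  # all differences <= 0 with some < 0: negative mean shift
  expect_lt(all_row$mean_simulated, all_row$mean_original)
  expect_lt(all_row$mean_diff, 0)
  # zero movers: degenerate tests flagged rather than computed
  q1 <- data.frame(facility_id = c("A", "B"), quartile = c(1, 2),
                   midpoint = c(0.02, 0.3), n = 100)
  sim0 <- run_referral_simulation(minimal_frame(6, facility = "A"),
                                  list(sae = m), q1, fac,
                                  reassignment_rule("proximity"))
  rep0 <- summarize_simulation(sim0)
  expect_true(all(rep0$degenerate[rep0$scope == "all"]))
  expect_true(all(is.na(rep0$p_paired_t)))
})

test_that("report files are written with masked-only exports", {
  dir <- withr::local_tempdir()
  fac <- toy_facilities(c("A", "B"), c(2, 10))
  q <- data.frame(facility_id = c("A", "B"), quartile = c(4, 1),
                  midpoint = c(0.3, 0.05), n = 100)
  sim <- run_referral_simulation(minimal_frame(8, facility = "A"),
                                 list(sae = toy_sae_model(c(A = 1, B = -1))),
                                 q, fac, reassignment_rule("proximity"))
  paths <- write_simulation_report(sim, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["summary_json"]])
  expect_equal(js$counts$n, 8)
  md <- readLines(paths[["summary_md"]])
  expect_match(md[1], "^\\| outcome")
})
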