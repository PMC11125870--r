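test_that("r_squared matches its definition and conventions", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), c(2, 2, 2)), 0)
  obs <- c(6.71, 9.0, 11.2, 13.39)
  pred <- c(7, 9, 11, 13)
  expect_equal(r_squared(obs, pred), oracle_r2(obs, pred))
  expect_equal(round(r_squared(obs, pred), 4), 0.9888)
  # degenerate constant-data convention
  expect_equal(r_squared(c(5, 5, 5), c(5, 5, 5)), 1)
  expect_equal(r_squared(c(5, 5, 5), c(5, 5, 5 + 1e-10)), 1)
  expect_equal(r_squared(c(5, 5, 5), c(5, 5, 6)), 0)
  # errors
  expect_error(r_squared(1:3, 1:2), "equal length")
  expect_error(r_squared(numeric(0), numeric(0)), "at least one")
})

test_that("r_squared agrees with the two-pass oracle on random inputs", {
  withr::with_seed(17, {
    for (i in 1:200) {
      n <- sample(2:20, 1)
      obs <- rnorm(n, sd = runif(1, 0.1, 50))
      pred <- obs + rnorm(n, sd = runif(1, 0, 10))
      expect_equal(r_squared(obs, pred), oracle_r2(obs, pred),
                   tolerance = 1e-12)
    }
  })
})

test_that("exact Mann-Whitney reproduces hand-enumerated cases", {
  cmp <- mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$u_statistic, 0)
  expect_equal(cmp$p_two_sided, 0.1)
  expect_equal(cmp$method, "exact_enumeration")

  cmp <- mann_whitney_exact(5, 3)
  expect_equal(cmp$p_two_sided, 1)

  x <- c(1.2, 3.4, 3.4)
  cmp <- mann_whitney_exact(x, x)
  expect_equal(cmp$u_statistic, length(x)^2 / 2)
  expect_equal(cmp$p_two_sided, 1)

  expect_error(mann_whitney_exact(numeric(0), 1), "nonempty")
})

test_that("exact Mann-Whitney agrees with wilcox.test on untied inputs", {
  withr::with_seed(23, {
    for (i in 1:40) {
      n_a <- sample(2:6, 1)
      n_b <- sample(2:6, 1)
      a <- rnorm(n_a)
      b <- rnorm(n_b, mean = runif(1, -1, 1))
      ours <- mann_whitney_exact(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(ours$u_statistic, unname(ref$statistic))
      expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
    }
  })
})

test_that("exact Mann-Whitney matches pairwise-counting enumeration with ties", {
  withr::with_seed(29, {
    for (i in 1:60) {
      n_a <- sample(1:6, 1)
      n_b <- sample(1:6, 1)
      # draw from a tiny support to force heavy ties
      a <- sample(1:4, n_a, replace = TRUE)
      b <- sample(1:4, n_b, replace = TRUE)
      ours <- mann_whitney_exact(a, b)
      expect_equal(ours$u_statistic, oracle_u(a, b))
      expect_equal(ours$p_two_sided, oracle_mw_p(a, b), tolerance = 1e-12)
    }
  })
})

test_that("large samples switch to the tie-corrected normal approximation", {
  withr::with_seed(31, {
    a <- rnorm(8)
    b <- rnorm(7, 1)
  })
  ours <- mann_whitney_exact(a, b)
  expect_equal(ours$method, "normal_approximation")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-10)
  # heavily tied large case
  a <- rep(1:3, 4)
  b <- rep(2:4, 4)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mann_whitney_exact(a, b)$p_two_sided, ref$p.value,
               tolerance = 1e-10)
})

test_that("compare_arms tests every timepoint and enforces alignment", {
  spec <- generator_spec("A", "m", "monotone_increase", 6.13, 26.8,
                         fold_change_at_52h = 2.5, noise_sd = 0)
  arms <- generate_timecourse(spec, 1)
  tab <- compare_arms(arms$treated, arms$control)
  expect_equal(nrow(tab), 5)
  # complete separation at 52 h for a noiseless 2.5-fold difference
  expect_true(tab$u_statistic[tab$time_h == 52] %in% c(0, 9))
  # identical arms: all p = 1
  same <- compare_arms(arms$treated, arms$treated)
  expect_true(all(same$p_two_sided == 1))
  # exact-test floor: two-sided p with 3 vs 3 replicates is never below 0.1
  withr::with_seed(41, {
    for (i in 1:25) {
      t2 <- arms$treated
      c2 <- arms$control
      t2$percent <- runif(nrow(t2), 0, 100)
      c2$percent <- runif(nrow(c2), 0, 100)
      expect_true(all(compare_arms(t2, c2)$p_two_sided >= 0.1))
    }
  })
  missing <- arms$control[arms$control$time_h != 43, ]
  expect_error(compare_arms(arms$treated, missing), "different timepoints")
})

test_that("the fit protocol isolates the blind point and is reproducible", {
  cfg <- ga_config(population_size = 80, max_generations = 6, seed = 101)
  base <- timecourse_from_function(function(h) 2 * (h / 24) + 1)
  f1 <- fit_predict_protocol(base, cfg)
  f2 <- fit_predict_protocol(base, cfg)
  expect_identical(f1$best_expression, f2$best_expression)
  expect_equal(f1$r2_overall, f2$r2_overall)

  # perturbing the 76 h blind value must not change any training output
  shifted <- base
  shifted$percent[shifted$time_h == 76] <-
    shifted$percent[shifted$time_h == 76] + 3.7
  f3 <- fit_predict_protocol(shifted, cfg)
  expect_identical(f3$best_expression, f1$best_expression)
  expect_equal(f3$r2_train, f1$r2_train)
  expect_false(f3$r2_overall == f1$r2_overall)

  # blind point equal to the model's own prediction: zero blind error
  exact <- base
  exact$percent[exact$time_h == 76] <- f1$predicted_raw$blind
  f4 <- fit_predict_protocol(exact, cfg)
  expect_equal(f4$abs_error_blind, 0)

  expect_error(
    fit_predict_protocol(base[base$time_h != 76, ], cfg),
    "missing timepoint: 76 h"
  )
  expect_error(
    fit_predict_protocol(base[base$time_h != 33, ], cfg),
    "missing timepoint: 33 h"
  )
})

test_that("protocol result fields satisfy their invariants", {
  cfg <- ga_config(population_size = 80, max_generations = 6, seed = 3)
  spec <- generator_spec("A", "m", "dip_then_rise", 6.71, 13.39)
  arms <- generate_timecourse(spec, 5)
  fit <- fit_predict_protocol(arms$treated, cfg)
  expect_lte(fit$r2_train, 1)
  expect_lte(fit$r2_overall, 1)
  expect_gte(fit$abs_error_blind, 0)
  expect_true(fit$predicted$blind >= 0 && fit$predicted$blind <= 100)
  expect_true(all(fit$predicted$forecast >= 0 & fit$predicted$forecast <= 100))
  expect_equal(fit$time_scaling, "t = hours / 24")
  expect_equal(fit$seed, 3L)
})

test_that("run_suite fits all nine systems and summarizes scores", {
  suite <- default_study_suite(42)
  cfg <- ga_config(population_size = 60, max_generations = 3, seed = 42)
  res <- run_suite(suite$data, cfg)
  expect_length(res$fits, 9)
  expect_equal(nrow(res$report), 9)
  expect_equal(res$summary$min, min(res$report$r2_overall))
  expect_equal(res$summary$max, max(res$report$r2_overall))
  expect_equal(res$summary$mean, mean(res$report$r2_overall))
  expect_true(all(res$report$r2_overall <= 1))
  # per-system seeds derive from the master seed and the label
  expect_equal(res$fits[["HCT-116 ABCG2+"]]$seed,
               derive_seed(42, "HCT-116 ABCG2+"))

  dropped <- suite$data[
    !(suite$data$cell_line == "MDA-MB-231" &
        suite$data$marker_system == "CD44+"), ]
  expect_error(run_suite(dropped, cfg), "MDA-MB-231 CD44\\+")
})

test_that("noiseless searchable trends are recovered by the protocol", {
  # treated data generated exactly from add(mult(2, t), 1) in scaled time
  data <- timecourse_from_function(function(h) 2 * (h / 24) + 1)
  cfg <- ga_config(seed = 11)
  fit <- fit_predict_protocol(data, cfg)
  expect_gte(fit$r2_train, 0.999)
  expect_gte(fit$r2_overall, 0.99)
})
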