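test_that("trend families hit their range anchors", {
  inc <- generator_spec("A", "m", "monotone_increase", 6.13, 26.8)
  expect_equal(trend_value(inc, 24), 6.13)
  expect_equal(trend_value(inc, 76), 26.8)

  dec <- generator_spec("A", "m", "monotone_decrease", 2.09, 3.11)
  expect_equal(trend_value(dec, 24), 3.11)
  expect_equal(trend_value(dec, 76), 2.09)

  dip <- generator_spec("A", "m", "dip_then_rise", 6.71, 13.39)
  expect_equal(trend_value(dip, 33), 6.71)
  expect_equal(trend_value(dip, 76), 13.39)
  # minimum strictly inside (24, 52)
  grid <- seq(24, 52, by = 0.5)
  tmin <- grid[which.min(trend_value(dip, grid))]
  expect_gt(tmin, 24)
  expect_lt(tmin, 52)

  plat <- generator_spec("A", "m", "rise_then_plateau", 0.34, 2.09)
  plateau <- 0.34 + 0.95 * (2.09 - 0.34)
  expect_equal(trend_value(plat, 24), 0.34)
  expect_equal(trend_value(plat, 43), plateau)
  expect_equal(trend_value(plat, 60), plateau)

  acu <- generator_spec("A", "m", "acute_peak_then_decline", 6.56, 15.69)
  expect_equal(trend_value(acu, 24), 15.69)
  expect_equal(trend_value(acu, 76), 6.56)
  # maximum at 24 h over the sampled window
  expect_equal(which.max(trend_value(acu, c(24, 33, 43, 52, 76))), 1L)
})

test_that("monotone families are monotone over the sampled timepoints", {
  tp <- c(24, 33, 43, 52, 76)
  inc <- generator_spec("A", "m", "monotone_increase", 5, 20)
  expect_true(all(diff(trend_value(inc, tp)) > 0))
  dec <- generator_spec("A", "m", "monotone_decrease", 5, 20)
  expect_true(all(diff(trend_value(dec, tp)) < 0))
  acu <- generator_spec("A", "m", "acute_peak_then_decline", 5, 20)
  expect_true(all(diff(trend_value(acu, tp)) < 0))
})

test_that("a vanishing range gives a near-constant trend", {
  eps <- 1e-9
  for (fam in c("monotone_increase", "dip_then_rise", "monotone_decrease",
                "rise_then_plateau", "acute_peak_then_decline")) {
    spec <- generator_spec("A", "m", fam, 10, 10 + eps)
    v <- trend_value(spec, seq(24, 96, by = 4))
    expect_lt(max(v) - min(v), 1e-8)
  }
})

test_that("spec validation rejects bad inputs with named messages", {
  expect_error(generator_spec("A", "m", "zigzag", 1, 2),
               "unknown trend_family 'zigzag'")
  expect_error(generator_spec("A", "m", "monotone_increase", 5, 5),
               "range_low < range_high")
  expect_error(generator_spec("A", "m", "monotone_increase", 1, 101),
               "range_low < range_high")
  expect_error(generator_spec("A", "m", "monotone_increase", 1, 2,
                              noise_sd = -1), "noise_sd")
  expect_error(generator_spec("A", "m", "monotone_increase", 1, 2,
                              timepoints_h = c(24, 24)), "strictly increasing")
  expect_error(generator_spec("A", "m", "monotone_increase", 1, 2,
                              n_replicates = 0), "n_replicates")
})

test_that("noiseless generation reproduces the trend exactly in every replicate", {
  spec <- generator_spec("A", "m", "monotone_increase", 6.13, 26.8,
                         noise_sd = 0)
  arms <- generate_timecourse(spec, 1)
  for (tt in spec$timepoints_h) {
    reps <- arms$treated$percent[arms$treated$time_h == tt]
    expect_equal(reps, rep(trend_value(spec, tt), 3))
    expect_equal(sd(reps), 0)
  }
})

test_that("fold change at 52 h is honored by construction", {
  spec <- generator_spec("A", "m", "monotone_increase", 6.13, 26.8,
                         fold_change_at_52h = 2.5, noise_sd = 0)
  arms <- generate_timecourse(spec, 1)
  treated_52 <- arms$treated$percent[arms$treated$time_h == 52][1]
  control_52 <- arms$control$percent[arms$control$time_h == 52][1]
  expect_equal(treated_52 / control_52, 2.5)
})

test_that("generation is deterministic and clamped to [0, 100]", {
  spec <- generator_spec("A", "m", "dip_then_rise", 1, 99, noise_sd = 30)
  a1 <- generate_timecourse(spec, 7)
  a2 <- generate_timecourse(spec, 7)
  expect_identical(a1, a2)
  all_pct <- c(a1$treated$percent, a1$control$percent)
  expect_true(all(all_pct >= 0 & all_pct <= 100))
  a3 <- generate_timecourse(spec, 8)
  expect_false(identical(a1$treated$percent, a3$treated$percent))
})

test_that("the default study suite has nine systems with the printed ranges", {
  specs <- default_study_specs()
  expect_length(specs, 9)
  s <- specs[["HCT-116 CD24+ABCG2+"]]
  expect_equal(c(s$range_low, s$range_high), c(0.31, 2.94))
  s <- specs[["MDA-MB-231 CD24+ALDH1+"]]
  expect_equal(c(s$range_low, s$range_high), c(2.16, 5.71))
  s <- specs[["HCT-116 ALDH1+"]]
  expect_equal(s$fold_change_at_52h, 2.5)
  expect_true(specs[["MDA-MB-231 CD44+"]]$assumed_range)
  expect_equal(sum(vapply(specs, function(x) x$assumed_range, logical(1))), 1L)

  suite <- default_study_suite(42)
  # 9 systems x 2 arms x 5 timepoints x 3 replicates
  expect_equal(nrow(suite$data), 270)
  expect_identical(suite$data, default_study_suite(42)$data)
})

test_that("per-system substreams are stable under suite composition", {
  specs <- default_study_specs()
  full <- default_study_suite(42, specs)$data
  partial <- default_study_suite(42, specs[c(3, 7)])$data
  lab <- paste(full$cell_line, full$marker_system)
  sub <- full[lab %in% names(specs)[c(3, 7)], ]
  rownames(sub) <- NULL
  expect_equal(as.data.frame(sub), as.data.frame(partial))
})

test_that("CSV round trip preserves the table and rejects corrupt input", {
  suite <- default_study_suite(11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_timecourse_csv(suite$data, path)
  back <- read_timecourse_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(suite$data))

  bad <- readLines(path)
  bad[5] <- sub("^(([^,]*,){5})[0-9.]+$", "\\1abc", bad[5])
  bad_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, bad_path)
  expect_error(read_timecourse_csv(bad_path), "row 4")
  expect_error(read_timecourse_csv("/nonexistent/file.csv"), "not found")
})

test_that("duplicate replicate keys and bad arms are rejected", {
  suite <- default_study_suite(3)
  dup <- rbind(suite$data, suite$data[1, ])
  expect_error(validate_timecourse(dup), "duplicate")
  bad <- suite$data
  bad$arm[2] <- "placebo"
  expect_error(validate_timecourse(bad), "row 2")
})

test_that("generator YAML round-trips and validates", {
  specs <- default_study_specs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(specs, path)
  back <- read_generator_config(path)
  expect_equal(names(back), names(specs))
  expect_equal(back[["HCT-116 ABCG2+"]]$range_high, 13.39)
  expect_equal(back[["HCT-116 ALDH1+"]]$fold_change_at_52h, 2.5)

  writeLines("systems:\n- cell_line: A\n  marker_system: m\n  trend_family: monotone_increase\n  range_low: 1\n  range_high: 2\n  bogus_field: 3\n",
             path)
  expect_error(read_generator_config(path), "bogus_field")
})
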