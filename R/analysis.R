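#' Coefficient of determination
#'
#' `R^2 = 1 - SSR/SST`, with SSR the residual sum of squares of the
#' predictions and SST the total sum of squares of the observations about
#' their mean. Unbounded below, at most 1. Degenerate case: when every
#' observed value is equal (SST = 0), returns 1 if the predictions
#' interpolate the data to within 1e-9, else 0.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @return Numeric scalar.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 3))   # 1
#' r_squared(c(1, 2, 3), c(2, 2, 2))   # 0
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop_validation("observed and predicted must have equal length")
  }
  if (length(observed) < 1L) {
    stop_validation("need at least one observation")
  }
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    return(if (max(abs(observed - predicted)) < 1e-9) 1 else 0)
  }
  1 - sum((observed - predicted)^2) / sst
}

# --- Mann-Whitney -----------------------------------------------------------

#' Mann-Whitney U test with exact small-sample p-value
#'
#' The U statistic is computed from mid-rank sums (ties get mid-ranks). For
#' pooled sizes `n_a + n_b <= 12` the two-sided p-value is exact: every one
#' of the `choose(n_a + n_b, n_a)` assignments of the pooled values to group
#' A is enumerated and the fraction with `|U - n_a n_b / 2|` at least as
#' large as observed is returned, which handles ties exactly. For larger
#' samples the tie-corrected normal approximation with continuity correction
#' is used.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @return A list of class `group_comparison`: `u_statistic` (for group A),
#'   `p_two_sided`, `n_a`, `n_b`, `method`.
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mann_whitney_exact <- function(group_a, group_b) {
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop_validation("both groups must be nonempty")
  }
  n_a <- length(group_a)
  n_b <- length(group_b)
  pooled <- c(group_a, group_b)
  if (any(!is.finite(pooled))) stop_validation("values must be finite")
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  N <- n_a + n_b

  if (N <= 12L) {
    idx <- utils::combn(N, n_a)
    rank_sums <- colSums(matrix(r[idx], nrow = n_a))
    us <- rank_sums - n_a * (n_a + 1) / 2
    obs_dev <- abs(u_a - mu)
    p <- mean(abs(us - mu) >= obs_dev - 1e-9)
    method <- "exact_enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n_a * n_b / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      dev <- u_a - mu
      z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approximation"
  }
  structure(list(u_statistic = u_a, p_two_sided = p,
                 n_a = n_a, n_b = n_b, method = method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney (%s): U = %g (n = %d vs %d), two-sided p = %g\n",
              x$method, x$u_statistic, x$n_a, x$n_b, x$p_two_sided))
  invisible(x)
}

#' Treated-vs-control comparison at every shared timepoint
#'
#' Runs [mann_whitney_exact()] on the replicate values of the two arms at
#' each timepoint. Both arms must cover the same timepoints. No
#' multiple-testing correction is applied.
#'
#' @param treated,control Tidy single-arm time-course data frames (columns
#'   `time_h`, `replicate`, `percent`).
#' @return Tibble with one row per timepoint: `time_h`, `u_statistic`,
#'   `p_two_sided`, `n_a`, `n_b`, `method`.
#' @export
compare_arms <- function(treated, control) {
  t_times <- sort(unique(treated$time_h))
  c_times <- sort(unique(control$time_h))
  if (!identical(t_times, c_times)) {
    stop_validation("arms cover different timepoints (treated: %s; control: %s)",
                    paste(t_times, collapse = ","),
                    paste(c_times, collapse = ","))
  }
  rows <- lapply(t_times, function(tt) {
    cmp <- mann_whitney_exact(treated$percent[treated$time_h == tt],
                              control$percent[control$time_h == tt])
    tibble::tibble(time_h = tt, u_statistic = cmp$u_statistic,
                   p_two_sided = cmp$p_two_sided, n_a = cmp$n_a,
                   n_b = cmp$n_b, method = cmp$method)
  })
  do.call(rbind, rows)
}

# --- fit / blind-validate / forecast protocol -------------------------------

#' Time scaling applied before fitting
#'
#' Expression trees see `t = hours / 24`, keeping the inputs (1, 1.375,
#' 1.79, 2.17 for the training design) commensurate with the default
#' constant range. Recorded in every fit result so expressions stay
#' portable.
#'
#' @param hours Numeric vector of times in hours.
#' @return Scaled time.
#' @export
scale_time <- function(hours) as.numeric(hours) / 24

#' Fit, blind-validate and forecast one marker time course
#'
#' The core protocol: per-timepoint replicate means are computed; the
#' symbolic regressor is fitted by [evolve()] on the training timepoints
#' only (the blind timepoint is never passed to the optimizer); the fitted
#' expression is then scored on all training-plus-blind means
#' (`r2_overall`, the reported prediction score), the absolute error at the
#' blind timepoint is recorded, and the expression is evaluated at the
#' forecast horizon.
#'
#' @param treated Tidy single-arm time-course data frame covering all
#'   training and blind timepoints.
#' @param config A [ga_config()]; `config$seed` drives the whole fit.
#' @param train_times_h Training timepoints (hours).
#' @param blind_time_h Held-out validation timepoint (hours).
#' @param forecast_times_h Forecast horizon(s) (hours).
#' @param fit_replicates Fit all replicate points instead of per-timepoint
#'   means (scores are still computed on means).
#' @return A list of class `fit_result`: identification, `best_expression`,
#'   `time_scaling`, scores (`r2_train`, `r2_overall`, `abs_error_blind`),
#'   clamped `predicted` and raw `predicted_raw` values at the blind and
#'   forecast timepoints, `observed_means`, `generations_run`, `seed` and
#'   the config echo.
#' @export
fit_predict_protocol <- function(treated, config = ga_config(),
                                 train_times_h = c(24, 33, 43, 52),
                                 blind_time_h = 76,
                                 forecast_times_h = 96,
                                 fit_replicates = FALSE) {
  treated <- validate_timecourse(treated)
  needed <- c(train_times_h, blind_time_h)
  have <- unique(treated$time_h)
  absent <- setdiff(needed, have)
  if (length(absent) > 0L) {
    stop_validation("missing timepoint: %s h", paste(absent, collapse = ", "))
  }

  means <- vapply(needed, function(tt) {
    mean(treated$percent[treated$time_h == tt])
  }, numeric(1))
  names(means) <- as.character(needed)
  train_means <- means[as.character(train_times_h)]
  blind_mean <- means[[as.character(blind_time_h)]]

  if (fit_replicates) {
    sub <- treated[treated$time_h %in% train_times_h, ]
    fit <- evolve(scale_time(sub$time_h), sub$percent, config)
  } else {
    fit <- evolve(scale_time(train_times_h), train_means, config)
  }

  tree <- fit$best$tree
  eps <- config$protected_epsilon
  pred_train <- eval_tree(tree, scale_time(train_times_h), eps)
  pred_blind <- eval_tree(tree, scale_time(blind_time_h), eps)
  pred_forecast <- eval_tree(tree, scale_time(forecast_times_h), eps)

  r2_train <- r_squared(train_means, pred_train)
  r2_overall <- r_squared(c(train_means, blind_mean),
                          c(pred_train, pred_blind))

  structure(list(
    cell_line = unique(treated$cell_line),
    marker_system = unique(treated$marker_system),
    best_expression = fit$best_expression,
    time_scaling = "t = hours / 24",
    train_times_h = train_times_h,
    blind_time_h = blind_time_h,
    forecast_times_h = forecast_times_h,
    observed_means = as.list(means),
    r2_train = r2_train,
    r2_overall = r2_overall,
    abs_error_blind = abs(pred_blind - blind_mean),
    predicted = list(
      blind = clamp(pred_blind, 0, 100),
      forecast = clamp(pred_forecast, 0, 100)
    ),
    predicted_raw = list(blind = pred_blind, forecast = pred_forecast),
    generations_run = fit$generations_run,
    seed = config$seed,
    config = unclass(config)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit result: %s %s\n", x$cell_line, x$marker_system))
  cat("  expression:", x$best_expression, "\n")
  cat(sprintf("  r2_train = %.5f, r2_overall = %.5f, |blind error| = %.3f%%\n",
              x$r2_train, x$r2_overall, x$abs_error_blind))
  cat(sprintf("  predicted %g h: %.3f%%, %g h: %.3f%%\n",
              x$blind_time_h, x$predicted$blind,
              x$forecast_times_h[1], x$predicted$forecast[1]))
  invisible(x)
}

#' Fit all nine marker systems and summarize prediction scores
#'
#' Runs [fit_predict_protocol()] on the treated arm of each of the nine
#' study model systems. Per-system seeds are derived from `config$seed` and
#' the system label via [derive_seed()], so the suite is reproducible and
#' order-independent.
#'
#' @param dataset Tidy time-course data frame containing the treated arm of
#'   all nine systems (as produced by [default_study_suite()] or read back
#'   via [read_timecourse_csv()]).
#' @param config A [ga_config()]; `config$seed` acts as the master seed.
#' @param systems Character vector of expected "cell_line marker_system"
#'   labels; defaults to the nine default study systems.
#' @param ... Passed on to [fit_predict_protocol()].
#' @return A list of class `suite_result`: `fits` (named list of
#'   `fit_result`s), `report` (tibble: `model_system`, `cell_line`,
#'   `marker_system`, `r2_train`, `r2_overall`, `abs_error_blind`,
#'   `expression`) and `summary` (list with `min`, `mean`, `max` of
#'   `r2_overall`).
#' @export
run_suite <- function(dataset, config = ga_config(),
                      systems = names(default_study_specs()), ...) {
  dataset <- validate_timecourse(dataset)
  dataset <- dataset[dataset$arm == "treated", ]
  labels <- paste(dataset$cell_line, dataset$marker_system)
  absent <- setdiff(systems, unique(labels))
  if (length(absent) > 0L) {
    stop_validation("missing model system(s): %s",
                    paste(absent, collapse = "; "))
  }

  fits <- lapply(systems, function(lab) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, lab)
    fit_predict_protocol(dataset[labels == lab, ], cfg, ...)
  })
  names(fits) <- systems

  report <- do.call(rbind, lapply(fits, function(f) {
    tibble::tibble(
      model_system = paste(f$cell_line, f$marker_system),
      cell_line = f$cell_line,
      marker_system = f$marker_system,
      r2_train = f$r2_train,
      r2_overall = f$r2_overall,
      abs_error_blind = f$abs_error_blind,
      expression = f$best_expression
    )
  }))
  rownames(report) <- NULL

  structure(list(
    fits = fits,
    report = report,
    summary = list(min = min(report$r2_overall),
                   mean = mean(report$r2_overall),
                   max = max(report$r2_overall)),
    master_seed = config$seed
  ), class = "suite_result")
}

#' @export
print.suite_result <- function(x, ...) {
  cat("Prediction-score suite (", nrow(x$report), " model systems)\n", sep = "")
  for (i in seq_len(nrow(x$report))) {
    cat(sprintf("  %-28s r2_overall = %.5f\n",
                x$report$model_system[i], x$report$r2_overall[i]))
  }
  cat(sprintf("  summary: min %.5f / mean %.5f / max %.5f\n",
              x$summary$min, x$summary$mean, x$summary$max))
  invisible(x)
}
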