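#' Specification of one synthetic marker system
#'
#' Describes how to simulate the treated-arm expression trajectory of one
#' flow-cytometry marker system (percent of gated cells) in one cell line,
#' together with its control arm. The trajectory is a smooth deterministic
#' trend (one of five qualitative families) anchored to a printed
#' `[range_low, range_high]` percentage range over the observation window,
#' plus independent Gaussian replicate noise on the percentage scale.
#'
#' Trend families and their range anchoring over 24-76 h:
#' \describe{
#'   \item{monotone_increase}{linear; low at 24 h, high at 76 h.}
#'   \item{monotone_decrease}{linear; high at 24 h, low at 76 h.}
#'   \item{dip_then_rise}{quadratic with its minimum (low) at 33 h, reaching
#'     high at 76 h: an early decrease followed by a later increase.}
#'   \item{rise_then_plateau}{smooth quadratic rise from low at 24 h to a
#'     plateau 95% of the way up the range, held from 43 h on.}
#'   \item{acute_peak_then_decline}{quadratic decline from its maximum
#'     (high) at 24 h, flattening to low at 76 h and held beyond.}
#' }
#'
#' @param cell_line Label, e.g. `"HCT-116"`.
#' @param marker_system Label, e.g. `"CD24+ABCG2+"`.
#' @param trend_family One of the five families above.
#' @param range_low,range_high Percentage anchors, `0 <= low < high <= 100`.
#' @param control_level Flat control-arm level (percent). Default: midpoint
#'   of the range. Ignored when `fold_change_at_52h` is given.
#' @param fold_change_at_52h Optional treated/control ratio enforced (for the
#'   noiseless trends) at 52 h; sets the control level to
#'   `trend(52) / fold_change_at_52h`.
#' @param noise_sd Absolute Gaussian replicate noise, percentage points.
#' @param timepoints_h Strictly increasing sampling times in hours.
#' @param n_replicates Independent replicates per timepoint.
#' @param assumed_range Flag recorded when the range is an assumption rather
#'   than a printed value.
#' @return A validated list of class `generator_spec`.
#' @export
generator_spec <- function(cell_line,
                           marker_system,
                           trend_family,
                           range_low,
                           range_high,
                           control_level = NULL,
                           fold_change_at_52h = NULL,
                           noise_sd = 0.5,
                           timepoints_h = c(24, 33, 43, 52, 76),
                           n_replicates = 3L,
                           assumed_range = FALSE) {
  families <- c("monotone_increase", "dip_then_rise", "monotone_decrease",
                "rise_then_plateau", "acute_peak_then_decline")
  if (!trend_family %in% families) {
    stop_validation("unknown trend_family '%s' (expected one of: %s)",
                    trend_family, paste(families, collapse = ", "))
  }
  if (!(range_low >= 0 && range_low < range_high && range_high <= 100)) {
    stop_validation("need 0 <= range_low < range_high <= 100")
  }
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  if (n_replicates < 1L) stop_validation("n_replicates must be >= 1")
  if (length(timepoints_h) < 1L || any(diff(timepoints_h) <= 0)) {
    stop_validation("timepoints_h must be strictly increasing")
  }
  if (!is.null(fold_change_at_52h) && fold_change_at_52h <= 0) {
    stop_validation("fold_change_at_52h must be positive")
  }
  structure(list(
    cell_line = cell_line,
    marker_system = marker_system,
    trend_family = trend_family,
    range_low = range_low,
    range_high = range_high,
    control_level = control_level,
    fold_change_at_52h = fold_change_at_52h,
    noise_sd = noise_sd,
    timepoints_h = as.numeric(timepoints_h),
    n_replicates = as.integer(n_replicates),
    assumed_range = isTRUE(assumed_range)
  ), class = "generator_spec")
}

#' Deterministic trend value of a synthetic marker system
#'
#' The smooth noiseless treated-arm trajectory underlying a
#' [generator_spec()], clamped to `[0, 100]`. Anchoring per trend family is
#' described in [generator_spec()].
#'
#' @param spec A [generator_spec()].
#' @param t Time(s) in hours, within the observation-plus-forecast window.
#' @return Percent value(s) in `[0, 100]`.
#' @export
trend_value <- function(spec, t) {
  lo <- spec$range_low
  hi <- spec$range_high
  t <- as.numeric(t)
  v <- switch(spec$trend_family,
    monotone_increase = lo + (hi - lo) * (t - 24) / 52,
    monotone_decrease = hi - (hi - lo) * (t - 24) / 52,
    dip_then_rise = lo + (hi - lo) * ((t - 33) / 43)^2,
    rise_then_plateau = {
      plateau <- lo + 0.95 * (hi - lo)
      ifelse(t >= 43, plateau,
             lo + (plateau - lo) * (1 - ((43 - t) / 19)^2))
    },
    acute_peak_then_decline = lo + (hi - lo) * ((76 - pmin(t, 76)) / 52)^2,
    stop_validation("unknown trend_family '%s'", spec$trend_family)
  )
  clamp(v, 0, 100)
}

control_level_of <- function(spec) {
  if (!is.null(spec$fold_change_at_52h)) {
    trend_value(spec, 52) / spec$fold_change_at_52h
  } else {
    spec$control_level %||% ((spec$range_low + spec$range_high) / 2)
  }
}

#' Simulate a treated/control marker time course
#'
#' The treated arm follows [trend_value()] plus independent Gaussian noise
#' (`sd = noise_sd`) per replicate; the control arm is flat at
#' `control_level` (or at `trend(52) / fold_change_at_52h` when a fold change
#' is specified) with the same noise model. All percentages are clamped to
#' `[0, 100]`. Identical `(spec, seed)` give bit-identical output; the
#' caller's random-number state is untouched.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return A list with elements `treated` and `control`, each a tidy
#'   data frame with columns `cell_line`, `marker_system`, `arm`, `time_h`,
#'   `replicate`, `percent`.
#' @export
generate_timecourse <- function(spec, seed) {
  withr::with_seed(as.integer(seed), {
    one_arm <- function(arm, level_fun) {
      grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                          time_h = spec$timepoints_h)
      mu <- level_fun(grid$time_h)
      noise <- if (spec$noise_sd > 0) {
        stats::rnorm(nrow(grid), 0, spec$noise_sd)
      } else {
        numeric(nrow(grid))
      }
      tibble::tibble(
        cell_line = spec$cell_line,
        marker_system = spec$marker_system,
        arm = arm,
        time_h = grid$time_h,
        replicate = as.integer(grid$replicate),
        percent = clamp(mu + noise, 0, 100)
      )
    }
    treated <- one_arm("treated", function(t) trend_value(spec, t))
    ctrl_level <- control_level_of(spec)
    control <- one_arm("control", function(t) rep(ctrl_level, length(t)))
    list(treated = treated, control = control)
  })
}

#' The nine default marker systems of the study design
#'
#' One [generator_spec()] per model system: the HCT-116 colorectal and
#' MDA-MB-231 breast-cancer lines, each followed for single-marker and
#' double-positive stemness subpopulations (ABCG2, ALDH1, CD24 combinations,
#' CD44). Ranges are the printed percentage ranges of each subpopulation;
#' trend families encode the described qualitative kinetics under
#' polystyrene-nanoparticle treatment. The MDA-MB-231 CD44 range is not
#' printed anywhere and is an assumption (80-95%), flagged via
#' `assumed_range` and overridable through the YAML generator config.
#'
#' @param noise_sd Absolute replicate noise (percentage points) applied to
#'   every system.
#' @param n_replicates Replicates per timepoint for every system.
#' @return Named list of nine `generator_spec` objects.
#' @export
default_study_specs <- function(noise_sd = 0.5, n_replicates = 3L) {
  mk <- function(...) generator_spec(..., noise_sd = noise_sd,
                                     n_replicates = n_replicates)
  specs <- list(
    mk("HCT-116", "ABCG2+", "dip_then_rise", 6.71, 13.39),
    mk("HCT-116", "ALDH1+", "monotone_increase", 6.13, 26.8,
       fold_change_at_52h = 2.5),
    mk("HCT-116", "CD24+ABCG2+", "monotone_increase", 0.31, 2.94),
    mk("HCT-116", "CD24+ALDH1+", "rise_then_plateau", 0.34, 2.09),
    mk("MDA-MB-231", "CD24+ABCG2+", "acute_peak_then_decline", 6.56, 15.69),
    mk("MDA-MB-231", "CD24+ALDH1+", "acute_peak_then_decline", 2.16, 5.71),
    mk("MDA-MB-231", "ABCG2+CD24+", "monotone_decrease", 2.09, 3.11),
    mk("MDA-MB-231", "ALDH1+CD24+", "monotone_decrease", 1.59, 2.89),
    mk("MDA-MB-231", "CD44+", "rise_then_plateau", 80, 95,
       assumed_range = TRUE)
  )
  names(specs) <- vapply(specs, system_label, character(1))
  specs
}

system_label <- function(spec) paste(spec$cell_line, spec$marker_system)

#' Generate the full nine-system synthetic study dataset
#'
#' Runs [generate_timecourse()] for every default system. Each system draws
#' from its own random substream derived by [derive_seed()] from the master
#' seed and the system label, so adding systems never shifts the draws of
#' existing ones.
#'
#' @param seed Master integer seed.
#' @param specs List of `generator_spec` objects; defaults to
#'   [default_study_specs()].
#' @return A list with `specs` and `data`, the latter one tidy data frame of
#'   all systems and both arms (columns `cell_line`, `marker_system`, `arm`,
#'   `time_h`, `replicate`, `percent`).
#' @export
default_study_suite <- function(seed, specs = default_study_specs()) {
  rows <- lapply(specs, function(spec) {
    arms <- generate_timecourse(spec, derive_seed(seed, system_label(spec)))
    rbind(arms$treated, arms$control)
  })
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(specs = specs, data = tibble::as_tibble(data))
}

# --- tidy CSV interface -----------------------------------------------------

timecourse_columns <- c("cell_line", "marker_system", "arm", "time_h",
                        "replicate", "percent")

#' Validate a tidy marker time-course table
#'
#' Checks the exact column set, the arm labels, percent bounds and
#' uniqueness of (cell_line, marker_system, arm, time_h, replicate) keys.
#' Errors carry the offending row where applicable.
#'
#' @param data Data frame in the tidy time-course layout.
#' @return The validated data, as a tibble, invisibly usable downstream.
#' @export
validate_timecourse <- function(data) {
  missing_cols <- setdiff(timecourse_columns, names(data))
  if (length(missing_cols) > 0L) {
    stop_validation("missing column(s): %s",
                    paste(missing_cols, collapse = ", "))
  }
  pct <- suppressWarnings(as.numeric(data$percent))
  bad <- which(!is.finite(pct))
  if (length(bad) > 0L) {
    stop_validation("non-numeric percent value '%s' in row %d",
                    as.character(data$percent[bad[1]]), bad[1])
  }
  out_of_range <- which(pct < 0 | pct > 100)
  if (length(out_of_range) > 0L) {
    stop_validation("percent %g outside [0, 100] in row %d",
                    pct[out_of_range[1]], out_of_range[1])
  }
  bad_arm <- which(!data$arm %in% c("control", "treated"))
  if (length(bad_arm) > 0L) {
    stop_validation("invalid arm '%s' in row %d (expected control/treated)",
                    as.character(data$arm[bad_arm[1]]), bad_arm[1])
  }
  key <- do.call(paste, c(data[c("cell_line", "marker_system", "arm",
                                 "time_h", "replicate")], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop_validation("duplicate (arm, time_h, replicate) key in row %d", dup[1])
  }
  data$percent <- pct
  data$time_h <- as.numeric(data$time_h)
  data$replicate <- as.integer(data$replicate)
  tibble::as_tibble(data[timecourse_columns])
}

#' Read / write the tidy time-course CSV
#'
#' The on-disk contract: UTF-8 CSV with header and columns exactly
#' `cell_line, marker_system, arm, time_h, replicate, percent`, `.` as the
#' decimal separator. Reading validates the schema and value ranges.
#'
#' @param data Tidy time-course data frame.
#' @param path File path.
#' @return `read_timecourse_csv()` returns a validated tibble;
#'   `write_timecourse_csv()` returns `path` invisibly.
#' @export
write_timecourse_csv <- function(data, path) {
  data <- validate_timecourse(data)
  utils::write.csv(data, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", colClasses = "character")
  raw$time_h <- suppressWarnings(as.numeric(raw$time_h))
  raw$replicate <- suppressWarnings(as.integer(raw$replicate))
  validate_timecourse(raw)
}

# --- YAML generator configuration -------------------------------------------

spec_to_block <- function(spec) {
  block <- unclass(spec)
  block[!vapply(block, is.null, logical(1))]
}

#' Read / write generator configuration YAML
#'
#' One YAML block per marker system, mirroring the [generator_spec()] field
#' names under a top-level `systems:` list.
#'
#' @param specs List of `generator_spec` objects.
#' @param path YAML file path.
#' @return `read_generator_config()` returns a named list of validated
#'   `generator_spec`s; `write_generator_config()` returns `path` invisibly.
#' @export
write_generator_config <- function(specs, path) {
  yaml::write_yaml(list(systems = lapply(unname(specs), spec_to_block)), path)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop_validation("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$systems)) {
    stop_validation("generator config must contain a 'systems' list")
  }
  specs <- lapply(cfg$systems, function(block) {
    allowed <- names(formals(generator_spec))
    unknown <- setdiff(names(block), allowed)
    if (length(unknown) > 0L) {
      stop_validation("unknown generator field(s): %s",
                      paste(unknown, collapse = ", "))
    }
    do.call(generator_spec, block)
  })
  names(specs) <- vapply(specs, system_label, character(1))
  specs
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf("<generator_spec> %s %s: %s over [%g, %g]%%%s\n",
              x$cell_line, x$marker_system, x$trend_family,
              x$range_low, x$range_high,
              if (x$assumed_range) " (assumed range)" else ""))
  invisible(x)
}
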