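#' Construct an oxygen trace
#'
#' A timestamped record of % air saturation in one respirometer, with each
#' sample labelled by cycle phase (`"flush"`, `"closed"` or `"background"`;
#' background cycles are fish-free closed cycles recorded after the animal
#' is removed). Time is seconds from trial start (fish entry), 0-based;
#' phase intervals are half-open `[start, end)`.
#'
#' @param time_s Numeric vector, strictly increasing, seconds.
#' @param o2 Numeric vector, % air saturation, within [0, 110].
#' @param phase Character vector of phase labels.
#' @param fish_id Identifier (optional).
#' @param test_temperature Test temperature in degC (optional).
#' @return A data frame of class `o2_trace` with columns `time_s`, `o2`,
#'   `phase` and attributes `fish_id`, `test_temperature`.
#' @export
o2_trace <- function(time_s, o2, phase, fish_id = NA_character_,
                     test_temperature = NA_real_) {
  stopifnot(length(time_s) == length(o2), length(o2) == length(phase))
  bad <- which(diff(time_s) <= 0)
  if (length(bad))
    stop(sprintf("time_s must be strictly increasing; violated at row %d",
                 bad[1] + 1L))
  if (any(o2 < 0 | o2 > 110, na.rm = TRUE))
    stop("o2 values must lie within [0, 110] %% air saturation")
  ok <- phase %in% c("flush", "closed", "background")
  if (!all(ok))
    stop(sprintf("unknown phase label '%s'", phase[!ok][1]))
  out <- data.frame(time_s = as.numeric(time_s), o2 = as.numeric(o2),
                    phase = as.character(phase),
                    stringsAsFactors = FALSE)
  attr(out, "fish_id") <- as.character(fish_id)
  attr(out, "test_temperature") <- test_temperature
  class(out) <- c("o2_trace", "data.frame")
  out
}

#' Assign flush/closed phases from a cycle schedule
#'
#' When a trace lacks phase labels they are inferred by modular arithmetic
#' on time: trials begin with the fish sealed into the chamber, so each
#' cycle runs closed-then-flush and a sample at time `t` is `"closed"` when
#' `t mod (closed_s + flush_s) < closed_s`, `"flush"` otherwise.
#'
#' @param time_s Numeric vector of sample times (s).
#' @param schedule A [cycle_schedule()].
#' @return Character vector of phase labels.
#' @export
infer_phases <- function(time_s, schedule) {
  stopifnot(inherits(schedule, "cycle_schedule"))
  r <- time_s %% (schedule$closed_s + schedule$flush_s)
  ifelse(r < schedule$closed_s, "closed", "flush")
}

#' Read an oxygen trace from a tidy CSV
#'
#' Expects columns `time_s` and `o2_percent_sat`, plus an optional `phase`
#' column; when `phase` is absent it is inferred from `schedule` via
#' [infer_phases()]. Non-monotone time is rejected with the offending row
#' named; missing columns are rejected with a column report.
#'
#' @param path CSV file path (comma-separated, UTF-8, header row, '.'
#'   decimal separator).
#' @param schedule A [cycle_schedule()], required when the CSV has no
#'   `phase` column.
#' @param fish_id,test_temperature Metadata attached to the trace.
#' @return An [o2_trace()].
#' @export
read_o2_trace <- function(path, schedule = NULL, fish_id = NA_character_,
                          test_temperature = NA_real_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "o2_percent_sat")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("missing required column(s): %s (found: %s)",
                 paste(missing_cols, collapse = ", "),
                 paste(names(df), collapse = ", ")))
  phase <- if ("phase" %in% names(df)) {
    df$phase
  } else {
    if (is.null(schedule))
      stop("trace has no phase column; a cycle_schedule is required to infer phases")
    infer_phases(df$time_s, schedule)
  }
  o2_trace(df$time_s, df$o2_percent_sat, phase, fish_id = fish_id,
           test_temperature = test_temperature)
}

#' Write an oxygen trace to CSV
#'
#' @param trace An [o2_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_o2_trace <- function(trace, path) {
  stopifnot(inherits(trace, "o2_trace"))
  out <- data.frame(time_s = trace$time_s, o2_percent_sat = trace$o2,
                    phase = trace$phase)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a set of result tables as tidy CSVs
#'
#' One CSV per table, stable column order, into `out_dir` (created if
#' needed). Returns a manifest of the files written.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory.
#' @return Data frame manifest with columns `table`, `file`, `n_rows`.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables)))
    stop("tables must be a named list")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir))
      stop(sprintf("cannot create output directory '%s'", out_dir))
  }
  manifest <- data.frame(table = character(0), file = character(0),
                         n_rows = integer(0), stringsAsFactors = FALSE)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    file <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tab, file, row.names = FALSE)
    manifest <- rbind(manifest,
                      data.frame(table = nm, file = file, n_rows = nrow(tab),
                                 stringsAsFactors = FALSE))
  }
  manifest
}

#' Read a flat sectioned key-value configuration file
#'
#' Minimal TOML-style dialect: `[section]` headers, `key = value` lines,
#' `#` comments. Values are parsed as numbers when possible, as logical for
#' `true`/`false`, and comma-separated values become vectors. The result is
#' merged over [default_config()], so a file need only state overrides.
#'
#' @param path Config file path.
#' @return Nested named list (sections of key-value pairs).
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  section <- "global"
  parse_value <- function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    one <- function(p) {
      if (tolower(p) %in% c("true", "false")) return(as.logical(toupper(p)))
      num <- suppressWarnings(as.numeric(p))
      if (!is.na(num)) num else gsub("^\"|\"$", "", p)
    }
    vals <- lapply(parts, one)
    if (length(unique(vapply(vals, class, ""))) == 1L) unlist(vals) else vals
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      cfg[[section]][[key]] <- parse_value(paste(kv[-1], collapse = "="))
    } else {
      stop(sprintf("cannot parse config line: '%s'", ln))
    }
  }
  cfg
}

#' Default pipeline configuration
#'
#' Every analysis constant lives here with its standard value so that tests
#' and users can tighten or vary them: the 60-s MMR window searched in 30-s
#' steps over the first 15 min of closed time, the 10% SMR quantile with
#' 2-SD outlier exclusion, the SMR +/- 10% recovery band with the
#' 3-consecutive-sample rule, the 4-h fine / 45-min-spaced coarse recovery
#' sampling, and the 75-ms C-start kinematics window. The `study` section
#' holds the simulated study design used by [run_pipeline()].
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    global = list(seed = 1),
    analysis = list(
      mmr_window_s = 60, mmr_step_s = 30, mmr_search_s = 900,
      smr_quantile = 0.10, smr_outlier_sd = 2,
      recovery_band = 0.10, recovery_consecutive = 3,
      fine_window_s = 60, fine_horizon_h = 4,
      coarse_window_s = 180, coarse_spacing_s = 2700,
      align_tolerance_s = 30,
      cstart_window_ms = 75, cstart_smooth = 1
    ),
    respirometer = list(
      loop_volume = 0.160, alpha = 0.08, alpha_source = "config default"
    ),
    calibration = list(known_length_cm = 3, fps = 240),
    study = list(
      temperatures = c(14, 8, 2), treatments = c("acute", "acclimated"),
      wdtt = 8, q10_above = 2, q10_below = 5, compensation_factor = 1.733,
      cv = 0.15, n_per_group = 12,
      n_respirometry = 2, duration_h = 12, sample_hz = 0.2,
      smr_ref = 2, mmr_ref = 5, tau_h = 1,
      background_rate = 1, noise_sd = 0.05,
      mass_kg = 0.05, body_length_cm = 8.8,
      n_cstart_fish = 4, n_attempts = 5, umax_ref_cms = 50,
      uchase_ref_bls = 1.7, chase_duration_ref_s = 300,
      raceway_circumference_cm = 176
    )
  )
}

#' Validate a pipeline configuration
#'
#' Checks that every study temperature has a cycle schedule and that all
#' durations are positive, before any stage runs.
#'
#' @param config Configuration list as from [default_config()].
#' @param schedules Named schedule list, by temperature.
#' @return `config`, invisibly; errors otherwise.
#' @export
validate_config <- function(config, schedules = default_schedules()) {
  temps <- config$study$temperatures
  missing_t <- temps[!as.character(temps) %in% names(schedules)]
  if (length(missing_t))
    stop(sprintf("no cycle schedule for temperature(s): %s",
                 paste(missing_t, collapse = ", ")))
  an <- config$analysis
  durs <- c(an$mmr_window_s, an$mmr_step_s, an$mmr_search_s,
            an$fine_window_s, an$coarse_window_s, an$coarse_spacing_s,
            config$study$duration_h)
  if (any(durs <= 0)) stop("all analysis durations must be positive")
  invisible(config)
}
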