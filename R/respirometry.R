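# Slopes are stored as the magnitude of the O2 decline (% air sat h^-1):
# raw least-squares slopes on a declining trace are negative, so fitted
# values are negated once, here, and Eq.-of-state conversion to MO2 is
# always applied to magnitudes.
.fit_slope <- function(time_s, o2) {
  t_h <- time_s / 3600
  -(sum((t_h - mean(t_h)) * (o2 - mean(o2))) / sum((t_h - mean(t_h))^2))
}

# contiguous runs of a phase label: data.frame(start_idx, end_idx)
.phase_runs <- function(phase, which_phase) {
  r <- rle(phase == which_phase)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep])
}

#' Convert oxygen-decline slopes to metabolic rate
#'
#' Mass-specific oxygen consumption from a slope of O2 decline:
#' `MO2 = s * (loop_volume - fish_volume) * alpha / mass`
#' with `s` in % air saturation h^-1, volumes in litres, `alpha` in mg O2
#' L^-1 (% air sat)^-1 and mass in kg, giving mg O2 h^-1 kg^-1.
#'
#' @param slopes A data frame of slope records (columns `window_start`,
#'   `window_end`, `slope`, optionally `source`) as produced by
#'   [segment_cycles()], or a bare numeric vector of slopes.
#' @param spec A [respirometer_spec()].
#' @return For a data frame input, a data frame with `time_mid` (window
#'   midpoint, s), `mo2` (mg O2 h^-1 kg^-1) and `source`; for numeric
#'   input, a numeric vector.
#' @examples
#' spec <- respirometer_spec(0.160, 0.010, alpha = 0.08, mass = 0.050)
#' compute_mo2(10, spec)  # 2.4 mg O2 h^-1 kg^-1
#' @export
compute_mo2 <- function(slopes, spec) {
  stopifnot(inherits(spec, "respirometer_spec"))
  factor <- (spec$loop_volume - spec$fish_volume) * spec$alpha / spec$mass
  if (is.numeric(slopes)) return(slopes * factor)
  stopifnot(is.data.frame(slopes), all(c("window_start", "window_end",
                                         "slope") %in% names(slopes)))
  data.frame(time_mid = (slopes$window_start + slopes$window_end) / 2,
             mo2 = slopes$slope * factor,
             source = if ("source" %in% names(slopes)) slopes$source
                      else "whole_cycle",
             stringsAsFactors = FALSE)
}

#' Correct fish slopes for background respiration
#'
#' Subtracts the mean background (fish-free) slope of the trial from each
#' fish slope, on the slope scale (% air sat h^-1), before conversion to
#' MO2. Corrected slopes that fall below zero are clamped to 0 and flagged
#' so downstream estimators can exclude them.
#'
#' @param slopes Data frame with a `slope` column, or numeric vector.
#' @param background_slopes Numeric vector of background-cycle slopes (or a
#'   data frame with a `slope` column); at least one required.
#' @return Same shape as `slopes`, with corrected `slope`, the original in
#'   `slope_raw`, and logical `bg_clamped`.
#' @export
correct_background <- function(slopes, background_slopes) {
  if (is.data.frame(background_slopes))
    background_slopes <- background_slopes$slope
  if (length(background_slopes) < 1)
    stop("at least one background cycle is required")
  bg <- mean(background_slopes)
  vec <- if (is.data.frame(slopes)) slopes$slope else slopes
  corrected <- vec - bg
  clamped <- corrected < 0
  corrected[clamped] <- 0
  if (any(clamped))
    warning(sprintf("%d slope(s) fell below background and were clamped to 0",
                    sum(clamped)))
  if (is.data.frame(slopes)) {
    slopes$slope_raw <- vec
    slopes$slope <- corrected
    slopes$bg_clamped <- clamped
    slopes
  } else {
    structure(corrected, clamped = clamped)
  }
}

#' Fit one least-squares slope per closed cycle
#'
#' Segments the trace into contiguous runs of the requested phase and fits
#' an ordinary least-squares slope of O2 against time over each trimmed
#' window `[cycle_start + leading_trim, cycle_start + closed_s -
#' trailing_trim)`, excluding the equilibration period after the flush and
#' the samples just before the next flush. Cycles whose trimmed window
#' holds fewer than two samples are skipped with a warning.
#'
#' @param trace An [o2_trace()].
#' @param schedule A [cycle_schedule()].
#' @param phase Phase to segment: `"closed"` (default) or `"background"`.
#' @return Data frame with one row per usable cycle: `cycle`,
#'   `cycle_start`, `window_start`, `window_end`, `slope` (magnitude,
#'   % air sat h^-1), `n`, `source`.
#' @export
segment_cycles <- function(trace, schedule, phase = "closed") {
  stopifnot(inherits(trace, "o2_trace"), inherits(schedule, "cycle_schedule"))
  runs <- .phase_runs(trace$phase, phase)
  out <- vector("list", nrow(runs))
  src <- if (phase == "background") "background" else "whole_cycle"
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start_idx[i]:runs$end_idx[i]
    t0 <- trace$time_s[runs$start_idx[i]]
    w0 <- t0 + schedule$leading_trim_s
    w1 <- t0 + schedule$closed_s - schedule$trailing_trim_s
    sel <- idx[trace$time_s[idx] >= w0 & trace$time_s[idx] < w1]
    if (length(sel) < 2) {
      warning(sprintf("cycle %d (%s) skipped: <2 samples in trimmed window",
                      i, phase))
      next
    }
    out[[i]] <- data.frame(cycle = i, cycle_start = t0, window_start = w0,
                           window_end = w1,
                           slope = .fit_slope(trace$time_s[sel],
                                              trace$o2[sel]),
                           n = length(sel), source = src,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cycle = integer(0), cycle_start = numeric(0),
                      window_start = numeric(0), window_end = numeric(0),
                      slope = numeric(0), n = integer(0),
                      source = character(0), stringsAsFactors = FALSE)
  out
}

#' Locate maximum metabolic rate by iterative window search
#'
#' Scans 60-s windows, advanced in 30-s increments of accumulated
#' closed-phase time (0-60, 30-90, 60-120 s, ...), over the first 15 min of
#' closed time following the fish's entry into the respirometer. Windows
#' never span a flush. MMR is the window with the steepest
#' background-corrected O2 decline, converted by the respirometer equation;
#' ties go to the earliest window.
#'
#' @param trace An [o2_trace()].
#' @param spec A [respirometer_spec()].
#' @param schedule A [cycle_schedule()].
#' @param window_s Window length, s (default 60).
#' @param step_s Increment, s (default 30).
#' @param search_s Search horizon in accumulated closed time, s
#'   (default 900).
#' @param background_slope Mean background slope to subtract
#'   (% air sat h^-1; default 0).
#' @return List: `mo2` (mg O2 h^-1 kg^-1), `slope`, `time_mid`,
#'   `window_start`, `window_end` (absolute trace seconds),
#'   `closed_offset_s` (window start on the accumulated-closed-time clock),
#'   `cycle`, and `candidates` (all windows scanned).
#' @export
find_mmr <- function(trace, spec, schedule, window_s = 60, step_s = 30,
                     search_s = 900, background_slope = 0) {
  stopifnot(inherits(trace, "o2_trace"), inherits(spec, "respirometer_spec"))
  runs <- .phase_runs(trace$phase, "closed")
  if (nrow(runs) == 0) stop("trace has no closed phases")
  offsets <- seq(0, search_s - window_s, by = step_s)
  acc <- 0
  cand <- list()
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start_idx[i]:runs$end_idx[i]
    t0 <- trace$time_s[runs$start_idx[i]]
    dur <- schedule$closed_s
    for (g in offsets[offsets >= acc & offsets + window_s <= acc + dur]) {
      w0 <- t0 + (g - acc)
      sel <- idx[trace$time_s[idx] >= w0 & trace$time_s[idx] < w0 + window_s]
      if (length(sel) < 2) next
      cand[[length(cand) + 1L]] <- data.frame(
        closed_offset_s = g, window_start = w0, window_end = w0 + window_s,
        cycle = i, slope = .fit_slope(trace$time_s[sel], trace$o2[sel]),
        n = length(sel))
    }
    acc <- acc + dur
    if (acc >= search_s) break
  }
  if (!length(cand))
    stop("no complete 60-s closed window within the MMR search horizon")
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$closed_offset_s), , drop = FALSE]
  cand$slope_corrected <- pmax(cand$slope - background_slope, 0)
  # earliest window wins ties, up to floating-point jitter in the fits
  mx <- max(cand$slope_corrected)
  best <- which(cand$slope_corrected >= mx - 1e-9 * max(1, abs(mx)))[1]
  factor <- (spec$loop_volume - spec$fish_volume) * spec$alpha / spec$mass
  list(mo2 = cand$slope_corrected[best] * factor,
       slope = cand$slope_corrected[best],
       time_mid = (cand$window_start[best] + cand$window_end[best]) / 2,
       window_start = cand$window_start[best],
       window_end = cand$window_end[best],
       closed_offset_s = cand$closed_offset_s[best],
       cycle = cand$cycle[best],
       candidates = cand)
}

#' Estimate standard metabolic rate from whole-cycle values
#'
#' SMR is the mean of the lowest `quantile` fraction of whole-cycle MO2
#' values (count `ceiling(quantile * n)`), after a single-pass exclusion of
#' members of that low pool lying outside `n_sd` standard deviations of the
#' pool mean. With fewer than 10 values the full set is used, with a
#' warning.
#'
#' @param mo2_values Numeric vector of whole-cycle MO2 values.
#' @param quantile Low-quantile fraction (default 0.10).
#' @param n_sd Outlier exclusion width in pool SDs (default 2).
#' @return List: `smr`, `n_used`, `pool` (the low-quantile values),
#'   `excluded` (pool members dropped as outliers), `all_used` (logical,
#'   TRUE when n < 10 forced use of every value).
#' @export
estimate_smr <- function(mo2_values, quantile = 0.10, n_sd = 2) {
  mo2_values <- mo2_values[!is.na(mo2_values)]
  n <- length(mo2_values)
  if (n == 0) stop("no MO2 values supplied")
  all_used <- n < 10
  pool <- if (all_used) {
    warning("fewer than 10 whole-cycle values; using all for SMR")
    sort(mo2_values)
  } else {
    sort(mo2_values)[seq_len(ceiling(quantile * n))]
  }
  m <- mean(pool)
  s <- if (length(pool) > 1) sd(pool) else 0
  keep <- abs(pool - m) <= n_sd * s | s == 0
  list(smr = mean(pool[keep]), n_used = sum(keep), pool = pool,
       excluded = pool[!keep], all_used = all_used)
}

#' Build the post-MMR recovery MO2 series
#'
#' Fine sampling first: one MO2 per sequential 60-s sub-window inside each
#' trimmed closed period, from the end of the MMR window until 4 h
#' post-MMR. Afterwards, coarse sampling: one MO2 from a 3-min window at
#' the start of a trimmed closed period, spaced `coarse_spacing_s` apart
#' (default 45 min), until the end of the trace.
#'
#' @inheritParams find_mmr
#' @param mmr List returned by [find_mmr()] (its `window_start` /
#'   `window_end` define the recovery clock origin).
#' @param fine_window_s Fine sub-window length, s (default 60).
#' @param fine_horizon_h Fine-sampling horizon post-MMR, h (default 4).
#' @param coarse_window_s Coarse window length, s (default 180).
#' @param coarse_spacing_s Coarse spacing, s (default 2700).
#' @return Data frame: `time_mid`, `mo2`, `source` (`"fine_60s"` /
#'   `"coarse_3min"`), `window_start`, `window_end`, `bg_clamped`.
#' @export
build_recovery_series <- function(trace, spec, schedule, mmr,
                                  fine_window_s = 60, fine_horizon_h = 4,
                                  coarse_window_s = 180,
                                  coarse_spacing_s = 2700,
                                  background_slope = 0) {
  stopifnot(inherits(trace, "o2_trace"))
  runs <- .phase_runs(trace$phase, "closed")
  horizon_end <- mmr$window_start + fine_horizon_h * 3600
  factor <- (spec$loop_volume - spec$fish_volume) * spec$alpha / spec$mass

  fit_window <- function(idx, w0, w1, source) {
    sel <- idx[trace$time_s[idx] >= w0 & trace$time_s[idx] < w1]
    if (length(sel) < 2) return(NULL)
    sl <- .fit_slope(trace$time_s[sel], trace$o2[sel]) - background_slope
    clamped <- sl < 0
    if (clamped) sl <- 0
    data.frame(time_mid = (w0 + w1) / 2, mo2 = sl * factor, source = source,
               window_start = w0, window_end = w1, bg_clamped = clamped,
               stringsAsFactors = FALSE)
  }

  out <- list()
  coarse_target <- horizon_end
  for (i in seq_len(nrow(runs))) {
    idx <- runs$start_idx[i]:runs$end_idx[i]
    t0 <- trace$time_s[runs$start_idx[i]]
    trim0 <- t0 + schedule$leading_trim_s
    trim1 <- t0 + schedule$closed_s - schedule$trailing_trim_s
    # fine 60-s sub-windows up to the 4-h horizon
    w <- trim0
    while (w + fine_window_s <= trim1) {
      if (w >= mmr$window_end && w < horizon_end)
        out[[length(out) + 1L]] <-
          fit_window(idx, w, w + fine_window_s, "fine_60s")
      w <- w + fine_window_s
    }
    # one coarse 3-min window per spacing interval beyond the horizon
    if (trim0 >= coarse_target && trim0 + coarse_window_s <= trim1) {
      rec <- fit_window(idx, trim0, trim0 + coarse_window_s, "coarse_3min")
      if (!is.null(rec)) {
        out[[length(out) + 1L]] <- rec
        coarse_target <- trim0 + coarse_spacing_s
      }
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(time_mid = numeric(0), mo2 = numeric(0),
                      source = character(0), window_start = numeric(0),
                      window_end = numeric(0), bg_clamped = logical(0))
  out[order(out$time_mid), , drop = FALSE]
}

#' Detect metabolic recovery time
#'
#' Recovery is reached at the first sample of the earliest run of
#' `n_consecutive` consecutive MO2 values all within `SMR * (1 +/- band)`.
#' If no such run exists the series end is returned with `recovered =
#' FALSE`.
#'
#' @param series Recovery series data frame (`time_mid`, `mo2`),
#'   time-ordered, as from [build_recovery_series()].
#' @param smr Estimated SMR.
#' @param mmr_time_s Absolute time of the MMR window start, s (recovery
#'   clock origin).
#' @param band Half-width of the band as a fraction of SMR (default 0.10).
#' @param n_consecutive Required run length (default 3).
#' @return List: `recovery_time_h` (hours post-MMR), `recovery_time_s`
#'   (absolute), `recovered`, `index` (row of the first qualifying sample,
#'   NA when not recovered).
#' @export
find_recovery_time <- function(series, smr, mmr_time_s = 0, band = 0.10,
                               n_consecutive = 3) {
  stopifnot(is.data.frame(series))
  n <- nrow(series)
  if (n == 0) stop("empty recovery series")
  within <- series$mo2 >= (1 - band) * smr & series$mo2 <= (1 + band) * smr
  idx <- NA_integer_
  if (n >= n_consecutive) {
    for (i in seq_len(n - n_consecutive + 1L)) {
      if (all(within[i:(i + n_consecutive - 1L)])) { idx <- i; break }
    }
  }
  if (is.na(idx)) {
    list(recovery_time_h = (series$time_mid[n] - mmr_time_s) / 3600,
         recovery_time_s = series$time_mid[n], recovered = FALSE,
         index = NA_integer_)
  } else {
    list(recovery_time_h = (series$time_mid[idx] - mmr_time_s) / 3600,
         recovery_time_s = series$time_mid[idx], recovered = TRUE,
         index = idx)
  }
}

#' Integrate excess post-exercise oxygen consumption
#'
#' Trapezoidal integral of `max(MO2(t) - SMR, 0)` over the recovery window
#' `[mmr_time, recovery_time]`, on the irregular sample grid with the MMR
#' point prepended at `mmr_time`. Units mg O2 kg^-1.
#'
#' @inheritParams find_recovery_time
#' @param mmr MMR value (mg O2 h^-1 kg^-1) prepended at `mmr_time_s`.
#' @param recovery_time_s Absolute recovery time, s.
#' @return EPOC in mg O2 kg^-1.
#' @export
compute_epoc <- function(series, smr, mmr, mmr_time_s, recovery_time_s) {
  stopifnot(is.data.frame(series))
  if (recovery_time_s < mmr_time_s)
    stop("recovery_time_s must be >= mmr_time_s")
  sel <- series$time_mid > mmr_time_s & series$time_mid <= recovery_time_s
  t <- c(mmr_time_s, series$time_mid[sel]) / 3600
  y <- pmax(c(mmr, series$mo2[sel]) - smr, 0)
  if (length(t) < 2) return(0)
  pracma::trapz(t, y)
}

#' Align recovery time points across a trial cohort
#'
#' Fish enter their respirometers at staggered times within a trial, so at
#' some fine-window time points not every fish has a measured MO2 (some are
#' mid-flush). This drops, for all fish, any time point at which any cohort
#' member lacks a sample within `tolerance_s`.
#'
#' @param series_list List (one element per fish, >= 2) of recovery series
#'   data frames with a `time_mid` column.
#' @param tolerance_s Matching tolerance, s (default 30).
#' @return List of filtered data frames, same order and names.
#' @export
align_cohort_timepoints <- function(series_list, tolerance_s = 30) {
  stopifnot(is.list(series_list))
  if (length(series_list) < 2)
    stop("cohort alignment requires at least 2 fish")
  times <- lapply(series_list, function(s) s$time_mid)
  keep_time <- function(t) {
    all(vapply(times, function(tg) {
      length(tg) > 0 && min(abs(tg - t)) <= tolerance_s
    }, logical(1)))
  }
  lapply(series_list, function(s) {
    s[vapply(s$time_mid, keep_time, logical(1)), , drop = FALSE]
  })
}
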