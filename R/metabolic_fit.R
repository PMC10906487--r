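#' Fit the full metabolic profile of one respirometry trial
#'
#' The central fitting function of the respirometry side of the package:
#' converts one post-exercise oxygen trace into SMR, MMR, absolute aerobic
#' scope (AAS = MMR - SMR), EPOC and recovery time.
#'
#' Processing order: (1) background slopes from the trace's fish-free
#' `"background"` cycles (their mean corrects every fish slope, on the
#' slope scale, before conversion to MO2); (2) MMR by the iterative 60-s
#' window search over the first 15 min of closed time ([find_mmr()]);
#' (3) whole-cycle slopes over trimmed closed periods ([segment_cycles()]),
#' the cycle containing the MMR window and any background-clamped cycles
#' being excluded from the SMR pool; (4) SMR as the mean of the lowest 10%
#' of whole-cycle values with single-pass 2-SD outlier exclusion
#' ([estimate_smr()]); (5) the fine/coarse recovery series
#' ([build_recovery_series()]); (6) recovery time by the
#' first-of-three-consecutive SMR +/- 10% rule ([find_recovery_time()]);
#' (7) EPOC by trapezoidal integration of the excess above SMR from MMR to
#' recovery ([compute_epoc()]).
#'
#' @param trace An [o2_trace()] beginning at the fish's entry into the
#'   respirometer, immediately post-chase.
#' @param spec A [respirometer_spec()].
#' @param schedule A [cycle_schedule()].
#' @param mmr_window_s,mmr_step_s,mmr_search_s MMR search constants
#'   (defaults 60, 30, 900 s).
#' @param smr_quantile,smr_outlier_sd SMR estimator constants (defaults
#'   0.10, 2).
#' @param recovery_band,recovery_consecutive Recovery rule constants
#'   (defaults 0.10, 3).
#' @param fine_window_s,fine_horizon_h,coarse_window_s,coarse_spacing_s
#'   Recovery-series constants (defaults 60 s, 4 h, 180 s, 2700 s).
#' @param fish_id Identifier carried into the summary.
#' @return An object of class `metabolic_fit`; see [coef.metabolic_fit()]
#'   for the headline estimates. The object also carries the whole-cycle
#'   MO2 table (`cycles`), the recovery series (`recovery`), the background
#'   slope used, exclusion flags, and the alpha provenance from `spec`.
#' @seealso [simulate_o2_trace()] for generating traces with known truth.
#' @export
fit_metabolism <- function(trace, spec, schedule,
                           mmr_window_s = 60, mmr_step_s = 30,
                           mmr_search_s = 900,
                           smr_quantile = 0.10, smr_outlier_sd = 2,
                           recovery_band = 0.10, recovery_consecutive = 3,
                           fine_window_s = 60, fine_horizon_h = 4,
                           coarse_window_s = 180, coarse_spacing_s = 2700,
                           fish_id = attr(trace, "fish_id")) {
  stopifnot(inherits(trace, "o2_trace"), inherits(spec, "respirometer_spec"),
            inherits(schedule, "cycle_schedule"))

  bg_slopes <- segment_cycles(trace, schedule, phase = "background")
  if (nrow(bg_slopes) == 0) {
    warning("no background cycles in trace; assuming zero background respiration")
    bg_mean <- 0
  } else {
    bg_mean <- mean(bg_slopes$slope)
  }

  mmr <- find_mmr(trace, spec, schedule, window_s = mmr_window_s,
                  step_s = mmr_step_s, search_s = mmr_search_s,
                  background_slope = bg_mean)

  cycles <- segment_cycles(trace, schedule, phase = "closed")
  if (nrow(cycles) == 0) stop("no usable closed cycles in trace")
  cycles$slope_raw <- cycles$slope
  cycles$slope <- pmax(cycles$slope - bg_mean, 0)
  cycles$bg_clamped <- cycles$slope_raw - bg_mean < 0
  mo2_cycles <- compute_mo2(cycles, spec)
  mo2_cycles$cycle <- cycles$cycle
  mo2_cycles$bg_clamped <- cycles$bg_clamped

  smr_pool_ok <- mo2_cycles$cycle != mmr$cycle & !mo2_cycles$bg_clamped
  smr_est <- estimate_smr(mo2_cycles$mo2[smr_pool_ok],
                          quantile = smr_quantile, n_sd = smr_outlier_sd)

  recovery <- build_recovery_series(trace, spec, schedule, mmr,
                                    fine_window_s = fine_window_s,
                                    fine_horizon_h = fine_horizon_h,
                                    coarse_window_s = coarse_window_s,
                                    coarse_spacing_s = coarse_spacing_s,
                                    background_slope = bg_mean)
  rec <- find_recovery_time(recovery, smr_est$smr,
                            mmr_time_s = mmr$window_start,
                            band = recovery_band,
                            n_consecutive = recovery_consecutive)
  epoc <- compute_epoc(recovery, smr_est$smr, mmr$mo2,
                       mmr_time_s = mmr$window_start,
                       recovery_time_s = rec$recovery_time_s)

  structure(list(
    fish_id = if (is.null(fish_id)) NA_character_ else fish_id,
    smr = smr_est$smr, mmr = mmr$mo2, aas = mmr$mo2 - smr_est$smr,
    epoc = epoc, recovery_time_h = rec$recovery_time_h,
    recovered = rec$recovered,
    mmr_window_start = mmr$window_start,
    mmr_closed_offset_s = mmr$closed_offset_s,
    n_smr_slopes_used = smr_est$n_used,
    smr_detail = smr_est, mmr_detail = mmr,
    cycles = mo2_cycles, recovery = recovery,
    background_slope = bg_mean,
    n_background_cycles = nrow(bg_slopes),
    alpha = spec$alpha, alpha_source = spec$alpha_source,
    spec = spec, schedule = schedule, trace = trace,
    settings = list(recovery_band = recovery_band,
                    recovery_consecutive = recovery_consecutive)
  ), class = "metabolic_fit")
}

#' @export
print.metabolic_fit <- function(x, digits = 4, ...) {
  cat("Metabolic fit")
  if (!is.na(x$fish_id)) cat(" for fish", x$fish_id)
  cat("\n")
  est <- coef(x)
  print(signif(est, digits))
  if (!x$recovered)
    cat("note: fish did not recover within the trace (recovery time is trace end)\n")
  invisible(x)
}

#' Headline estimates of a metabolic fit
#'
#' @param object A `metabolic_fit`.
#' @param ... Ignored.
#' @return Named numeric vector: `smr`, `mmr` (mg O2 h^-1 kg^-1), `aas`
#'   (= mmr - smr), `epoc` (mg O2 kg^-1), `recovery_time_h` (h post-MMR).
#' @export
coef.metabolic_fit <- function(object, ...) {
  c(smr = object$smr, mmr = object$mmr, aas = object$aas,
    epoc = object$epoc, recovery_time_h = object$recovery_time_h)
}

#' @export
summary.metabolic_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.metabolic_fit")
}

#' @export
print.summary.metabolic_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat(sprintf("\nMMR window: %g-%g s (closed-time offset %g s)\n",
              f$mmr_window_start, f$mmr_detail$window_end,
              f$mmr_closed_offset_s))
  cat(sprintf("SMR pool: lowest %d whole-cycle values used (of %d cycles%s)\n",
              f$n_smr_slopes_used, nrow(f$cycles),
              if (length(f$smr_detail$excluded))
                sprintf("; %d outlier(s) excluded",
                        length(f$smr_detail$excluded)) else ""))
  cat(sprintf("Background: %.4g %%sat h^-1 from %d cycle(s); alpha = %.4g (%s)\n",
              f$background_slope, f$n_background_cycles, f$alpha,
              f$alpha_source))
  cat(sprintf("Recovery series: %d fine + %d coarse samples; %s\n",
              sum(f$recovery$source == "fine_60s"),
              sum(f$recovery$source == "coarse_3min"),
              if (f$recovered) sprintf("recovered at %.3g h post-MMR",
                                       f$recovery_time_h)
              else "not recovered"))
  invisible(x)
}

#' Plot a metabolic fit
#'
#' Two diagnostic panels: the raw O2 trace coloured by phase, and the
#' post-MMR MO2 recovery curve with the SMR +/- band and the detected
#' recovery time.
#'
#' @param x A `metabolic_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.metabolic_fit <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  tr <- x$trace
  plot(tr$time_s / 3600, tr$o2, type = "l", col = "grey40",
       xlab = "time (h)", ylab = "O2 (% air sat)", main = "oxygen trace", ...)
  rec <- x$recovery
  t_h <- (rec$time_mid - x$mmr_window_start) / 3600
  plot(t_h, rec$mo2, pch = 16, cex = 0.5,
       col = ifelse(rec$source == "fine_60s", "black", "blue"),
       xlab = "time post-MMR (h)", ylab = "MO2 (mg O2 h^-1 kg^-1)",
       main = "recovery", ...)
  band <- x$settings$recovery_band
  abline(h = x$smr * c(1 - band, 1, 1 + band),
         lty = c(3, 1, 3), col = "red")
  abline(v = x$recovery_time_h, lty = 2)
  invisible(x)
}

#' Summarise a set of metabolic fits as a tidy table
#'
#' @param fits List of `metabolic_fit` objects.
#' @return Data frame with one row per fish: `fish_id`, `smr`, `mmr`,
#'   `aas`, `epoc`, `recovery_time_h`, `recovered`, `mmr_window_start`,
#'   `n_smr_slopes_used`.
#' @export
metabolic_summary <- function(fits) {
  if (inherits(fits, "metabolic_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(fish_id = f$fish_id, smr = f$smr, mmr = f$mmr, aas = f$aas,
               epoc = f$epoc, recovery_time_h = f$recovery_time_h,
               recovered = f$recovered,
               mmr_window_start = f$mmr_window_start,
               n_smr_slopes_used = f$n_smr_slopes_used,
               stringsAsFactors = FALSE)
  }))
}
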