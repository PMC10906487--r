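#' Piecewise-Q10 thermal rate model
#'
#' Expected value of a performance rate at temperature `T` under the
#' standard two-segment thermal model used throughout this package: above
#' the winter dormancy threshold temperature (WDTT) the rate follows
#' `R_ref * q10_above^((T - T_ref)/10)`; below it,
#' `R(WDTT) * q10_below^((T - WDTT)/10)`. A steeper below-threshold Q10
#' emulates a cold constraint on performance.
#'
#' @param temperature Temperature(s), degC.
#' @param reference_rate Rate at `reference_temperature`.
#' @param q10_above,q10_below Q10 above/below the threshold (both > 0).
#' @param wdtt Winter dormancy threshold temperature, degC (default 8).
#' @param reference_temperature Reference temperature, degC (default 14).
#' @return Numeric vector of expected rates.
#' @examples
#' thermal_rate(c(14, 8, 2), 10, q10_above = 2, q10_below = 5)
#' @export
thermal_rate <- function(temperature, reference_rate, q10_above = 2,
                         q10_below = 5, wdtt = 8,
                         reference_temperature = 14) {
  stopifnot(q10_above > 0, q10_below > 0, reference_rate > 0)
  r_wdtt <- reference_rate * q10_above^((wdtt - reference_temperature) / 10)
  ifelse(temperature >= wdtt,
         reference_rate * q10_above^((temperature - reference_temperature) / 10),
         r_wdtt * q10_below^((temperature - wdtt) / 10))
}

#' Simulate an intermittent-closed respirometry oxygen trace
#'
#' Emulates one overnight post-exercise respirometry trial. The fish's true
#' oxygen consumption follows a mono-exponential recovery from MMR to SMR,
#' `MO2(t) = SMR + (MMR - SMR) * exp(-t / tau)` with `t` in hours from
#' chamber entry. During each closed phase the % air saturation declines by
#' the integral of `MO2(t) * M / (V_resp * alpha)` plus a constant
#' background (microbial) rate; each flush re-equilibrates the chamber
#' instantaneously to 100% saturation. Gaussian noise is added pointwise and
#' `n_background_cycles` trailing fish-free cycles are appended. The return
#' value carries the closed-form ground truth: the analytic recovery time
#' `tau * log((MMR - SMR) / (band * SMR))` (the crossing of `(1 + band) *
#' SMR`) and the EPOC to that time, `(MMR - SMR) * tau * (1 - exp(-t_r /
#' tau))` mg O2 kg^-1.
#'
#' @param true_smr,true_mmr True SMR and MMR, mg O2 h^-1 kg^-1
#'   (`true_mmr >= true_smr > 0`).
#' @param recovery_tau_h Recovery time constant in hours (`>= 0`; 0 means
#'   MO2 is constant at SMR).
#' @param background_rate Background respiration, % air sat h^-1.
#' @param noise_sd Pointwise Gaussian noise SD, % air sat.
#' @param schedule A [cycle_schedule()].
#' @param duration_h Fish-present recording duration, hours; must cover at
#'   least 3 closed cycles.
#' @param spec A [respirometer_spec()].
#' @param sample_hz Probe sampling rate, Hz.
#' @param n_background_cycles Fish-free cycles appended (default 3).
#' @param recovery_band Band used for the ground-truth recovery time
#'   (default 0.10 for SMR +/- 10%).
#' @param seed Optional integer seed.
#' @return List with elements `trace` (an [o2_trace()]) and `truth`
#'   (list: `smr`, `mmr`, `aas`, `tau_h`, `recovery_time_h`, `epoc`,
#'   `background_rate`, and `mo2` -- the true MO2 as a function of hours
#'   post-entry).
#' @export
simulate_o2_trace <- function(true_smr = 2, true_mmr = 5, recovery_tau_h = 1,
                              background_rate = 1, noise_sd = 0.05,
                              schedule = schedule_for(14), duration_h = 14,
                              spec = respirometer_spec(0.160, 0.050,
                                                       alpha = 0.08,
                                                       mass = 0.050),
                              sample_hz = 1, n_background_cycles = 3,
                              recovery_band = 0.10, seed = NULL) {
  stopifnot(inherits(schedule, "cycle_schedule"),
            inherits(spec, "respirometer_spec"))
  if (!(true_mmr >= true_smr && true_smr > 0))
    stop("need true_mmr >= true_smr > 0")
  if (recovery_tau_h < 0) stop("recovery_tau_h must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  cycle_s <- schedule$closed_s + schedule$flush_s
  if (floor(duration_h * 3600 / cycle_s) < 3)
    stop("schedule/duration mismatch: duration must cover at least 3 closed cycles")

  v_resp <- spec$loop_volume - spec$fish_volume
  conv <- spec$mass / (v_resp * spec$alpha)   # (mg O2 h^-1 kg^-1) -> % sat h^-1
  delta <- true_mmr - true_smr
  tau <- recovery_tau_h

  # cumulative fish O2 uptake between hours a and b, in % sat units
  uptake_pct <- function(a_h, b_h) {
    exc <- if (tau > 0) delta * tau * (exp(-a_h / tau) - exp(-b_h / tau)) else 0
    conv * (true_smr * (b_h - a_h) + exc)
  }

  step <- 1 / sample_hz
  n_fish <- floor(duration_h * 3600 * sample_hz)
  t_fish <- (seq_len(n_fish) - 1L) * step
  r <- t_fish %% cycle_s
  phase <- ifelse(r < schedule$closed_s, "closed", "flush")
  t0 <- t_fish - r                            # closed start of own cycle
  o2 <- ifelse(phase == "closed",
               100 - uptake_pct(t0 / 3600, t_fish / 3600) -
                 background_rate * (t_fish - t0) / 3600,
               100)

  bg_start <- n_fish * step
  n_bg <- floor(n_background_cycles * cycle_s * sample_hz)
  t_bg <- bg_start + (seq_len(n_bg) - 1L) * step
  rb <- (t_bg - bg_start) %% cycle_s
  phase_bg <- ifelse(rb < schedule$closed_s, "background", "flush")
  o2_bg <- ifelse(phase_bg == "background",
                  100 - background_rate * rb / 3600, 100)

  time_s <- c(t_fish, t_bg)
  o2_all <- c(o2, o2_bg)
  phase_all <- c(phase, phase_bg)
  if (noise_sd > 0)
    o2_all <- o2_all + rnorm(length(o2_all), sd = noise_sd)
  o2_all <- pmin(pmax(o2_all, 0), 110)

  t_r <- if (delta > 0 && tau > 0)
    tau * log(delta / (recovery_band * true_smr)) else 0
  epoc <- if (tau > 0) delta * tau * (1 - exp(-t_r / tau)) else 0

  list(
    trace = o2_trace(time_s, o2_all, phase_all),
    truth = list(smr = true_smr, mmr = true_mmr, aas = delta, tau_h = tau,
                 recovery_time_h = t_r, epoc = epoc,
                 background_rate = background_rate,
                 mo2 = function(t_h) true_smr +
                   if (tau > 0) delta * exp(-t_h / tau) else 0)
  )
}

#' Simulate a tracked C-start trajectory
#'
#' Straight-line constant-acceleration path sampled at `fps`, converted to
#' pixels, with optional Gaussian jitter. Ground-truth maximum velocity is
#' `v0 + 100 * accel * duration` cm s^-1 (reached at the end of the
#' trajectory) and ground-truth maximum acceleration is `accel` m s^-2.
#'
#' @param v0_cms Initial speed, cm s^-1.
#' @param accel_ms2 Constant acceleration, m s^-2.
#' @param fps Frame rate, frames s^-1 (default 240).
#' @param duration_s Trajectory duration, s (must be >= 0.075 so the
#'   standard 75-ms analysis window fits).
#' @param pixels_per_cm Calibration ratio.
#' @param noise_px Pixel jitter SD (default 0).
#' @param heading_deg Direction of travel, degrees.
#' @param origin_px Starting position, pixels (length-2).
#' @param seed Optional integer seed.
#' @return List with `frames` (data frame `time_s`, `x_px`, `y_px`), `fps`,
#'   `pixels_per_cm`, `onset_s` (0) and `truth` (`u_max_cms`, `a_max_ms2`).
#' @export
simulate_cstart_trajectory <- function(v0_cms = 0, accel_ms2 = 10, fps = 240,
                                       duration_s = 0.1, pixels_per_cm = 10,
                                       noise_px = 0, heading_deg = 0,
                                       origin_px = c(0, 0), seed = NULL) {
  stopifnot(fps > 0, pixels_per_cm > 0)
  if (duration_s < 0.075)
    stop("duration_s must be at least 0.075 s")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration_s, by = 1 / fps)
  a_cms2 <- 100 * accel_ms2
  s_cm <- v0_cms * t + 0.5 * a_cms2 * t^2
  th <- heading_deg * pi / 180
  x <- origin_px[1] + cos(th) * s_cm * pixels_per_cm
  y <- origin_px[2] + sin(th) * s_cm * pixels_per_cm
  if (noise_px > 0) {
    x <- x + rnorm(length(x), sd = noise_px)
    y <- y + rnorm(length(y), sd = noise_px)
  }
  list(frames = data.frame(time_s = t, x_px = x, y_px = y),
       fps = fps, pixels_per_cm = pixels_per_cm, onset_s = 0,
       truth = list(u_max_cms = v0_cms + a_cms2 * duration_s,
                    a_max_ms2 = accel_ms2))
}

#' Simulate a multi-temperature performance dataset
#'
#' Group means follow the piecewise-Q10 model of [thermal_rate()];
#' acclimated groups below the WDTT are multiplied by
#' `compensation_factor`, emulating compensatory thermal plasticity.
#' Individuals are drawn lognormally around the group mean with coefficient
#' of variation `cv` (rates are positive).
#'
#' @param temperatures_acute Acute test temperatures, degC (default the
#'   full 26-2 degC series in 3 degC steps).
#' @param temperatures_acclimated Acclimation temperatures, degC (default
#'   14, 11, 8, 5, 2; no acclimation above 14 degC).
#' @param wdtt,q10_above,q10_below See [thermal_rate()].
#' @param compensation_factor Multiplier (>= 1) applied to acclimated group
#'   means strictly below the WDTT; the default 1.733 = (5/2)^0.6 halves
#'   the effective below-threshold thermal sensitivity over a 6 degC
#'   interval (Q10 5 -> 2).
#' @param reference_rate Group-mean rate at 14 degC, metric units.
#' @param cv Coefficient of variation among individuals (0 <= cv < 1).
#' @param n_per_group Fish per temperature x treatment group (>= 2).
#' @param metric Metric name written into the table.
#' @param is_rate Logical; whether this metric is a rate (eligible for Q10).
#' @param seed Optional integer seed.
#' @return List with `table` (data frame `fish_id`, `metric`, `value`,
#'   `temperature`, `treatment`, `is_rate`) and `truth` (generating
#'   parameters plus the group-mean table).
#' @export
simulate_performance_dataset <- function(temperatures_acute = seq(26, 2, by = -3),
                                         temperatures_acclimated = c(14, 11, 8, 5, 2),
                                         wdtt = 8, q10_above = 2, q10_below = 5,
                                         compensation_factor = 1.733,
                                         reference_rate = 1, cv = 0.15,
                                         n_per_group = 12, metric = "performance",
                                         is_rate = TRUE, seed = NULL) {
  stopifnot(q10_above > 0, q10_below > 0, compensation_factor > 0)
  if (cv < 0 || cv >= 1) stop("cv must lie in [0, 1)")
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (!is.null(seed)) set.seed(seed)

  groups <- rbind(
    data.frame(temperature = temperatures_acute, treatment = "acute"),
    data.frame(temperature = temperatures_acclimated, treatment = "acclimated"))
  groups$mean <- thermal_rate(groups$temperature, reference_rate,
                              q10_above, q10_below, wdtt)
  comp <- groups$treatment == "acclimated" & groups$temperature < wdtt
  groups$mean[comp] <- groups$mean[comp] * compensation_factor

  sdlog <- sqrt(log(1 + cv^2))
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    mu <- groups$mean[i]
    vals <- if (sdlog > 0)
      rlnorm(n_per_group, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
    else rep(mu, n_per_group)
    data.frame(
      fish_id = sprintf("%s_%g_%02d", substr(groups$treatment[i], 1, 3),
                        groups$temperature[i], seq_len(n_per_group)),
      metric = metric, value = vals,
      temperature = groups$temperature[i], treatment = groups$treatment[i],
      is_rate = is_rate, stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       truth = list(wdtt = wdtt, q10_above = q10_above, q10_below = q10_below,
                    compensation_factor = compensation_factor,
                    reference_rate = reference_rate, cv = cv,
                    n_per_group = n_per_group, group_means = groups))
}
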