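# probability that a startle attempt elicits a pre-contact C-start;
# responsiveness collapses below the dormancy threshold, with only partial
# recovery after acclimation
.responsiveness_prob <- function(temperature, treatment) {
  if (treatment == "acclimated")
    stats::approx(c(2, 8, 14), c(0.35, 0.8, 0.9), xout = temperature,
                  rule = 2)$y
  else
    stats::approx(c(2, 8, 14, 26), c(0.2, 0.8, 0.9, 0.9),
                  xout = temperature, rule = 2)$y
}

#' Run the full simulated-study analysis pipeline
#'
#' Executes the stage graph simulate -> respirometry -> kinematics ->
#' performance -> sensitivity -> stats on a synthetic study defined by the
#' `study` section of the configuration: for each temperature x treatment
#' group it simulates respirometry trials (fitted with
#' [fit_metabolism()]), C-start attempt sets (analysed with
#' [cstart_results()]) and chase-performance datasets, assembles the tidy
#' performance table, runs the thermal-sensitivity engine and the
#' inferential layer, and optionally writes all result tables as CSVs.
#' With a fixed seed the result bundle is identical across runs.
#'
#' @param config Configuration list from [default_config()] or
#'   [read_config()].
#' @param schedules Named schedule list from [default_schedules()].
#' @param out_dir Optional output directory for [write_results()].
#' @param quiet Suppress per-stage log messages.
#' @return List of class `pipeline_result`: `metabolic` (per-fish
#'   metabolic summaries), `cstart` (per-fish C-start results),
#'   `performance_table`, `sensitivity` (a `thermal_sensitivity`),
#'   `anova` (per-metric two-way ANOVAs), `sensitivity_anova`,
#'   `effort_epoc` (table + regression), `manifest` (when written),
#'   `log` (stage records).
#' @export
run_pipeline <- function(config = default_config(),
                         schedules = default_schedules(),
                         out_dir = NULL, quiet = FALSE) {
  validate_config(config, schedules)
  st <- config$study
  an <- config$analysis
  set.seed(config$global$seed)
  log <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    if (!quiet) message(line)
    log <<- c(log, line)
  }

  groups <- expand.grid(temperature = st$temperatures,
                        treatment = st$treatments,
                        stringsAsFactors = FALSE)

  ## respirometry stage -----------------------------------------------------
  fits <- list()
  for (i in seq_len(nrow(groups))) {
    tt <- groups$temperature[i]; tr <- groups$treatment[i]
    comp <- if (tr == "acclimated" && tt < st$wdtt)
      st$compensation_factor else 1
    smr_t <- thermal_rate(tt, st$smr_ref, st$q10_above, st$q10_below, st$wdtt)
    mmr_t <- thermal_rate(tt, st$mmr_ref, st$q10_above, st$q10_below,
                          st$wdtt) * comp
    sched <- schedule_for(tt, schedules)
    spec <- respirometer_spec(config$respirometer$loop_volume,
                              st$mass_kg, alpha = config$respirometer$alpha,
                              mass = st$mass_kg,
                              alpha_source = config$respirometer$alpha_source)
    for (k in seq_len(st$n_respirometry)) {
      sim <- simulate_o2_trace(true_smr = smr_t, true_mmr = mmr_t,
                               recovery_tau_h = st$tau_h,
                               background_rate = st$background_rate,
                               noise_sd = st$noise_sd, schedule = sched,
                               duration_h = st$duration_h, spec = spec,
                               sample_hz = st$sample_hz)
      f <- suppressWarnings(
        fit_metabolism(sim$trace, spec, sched,
                       fish_id = sprintf("%s_%g_r%02d",
                                         substr(tr, 1, 3), tt, k)))
      row <- metabolic_summary(f)
      row$temperature <- tt; row$treatment <- tr
      fits[[length(fits) + 1L]] <- row
    }
  }
  metabolic <- do.call(rbind, fits)
  say("respirometry: %d trials fitted across %d groups",
      nrow(metabolic), nrow(groups))

  ## kinematics stage -------------------------------------------------------
  cs <- list()
  sdlog <- sqrt(log(1 + st$cv^2))
  for (i in seq_len(nrow(groups))) {
    tt <- groups$temperature[i]; tr <- groups$treatment[i]
    comp <- if (tr == "acclimated" && tt < st$wdtt)
      st$compensation_factor else 1
    umax_mu <- thermal_rate(tt, st$umax_ref_cms, st$q10_above, st$q10_below,
                            st$wdtt) * comp
    p_resp <- .responsiveness_prob(tt, tr)
    for (k in seq_len(st$n_cstart_fish)) {
      umax_fish <- rlnorm(1, log(umax_mu) - sdlog^2 / 2, sdlog)
      attempts <- lapply(seq_len(st$n_attempts), function(j) {
        responded <- stats::runif(1) < p_resp
        if (!responded)
          return(list(frames = NULL, onset_s = NA,
                      pre_contact_response = FALSE))
        traj <- simulate_cstart_trajectory(
          v0_cms = 0, accel_ms2 = umax_fish / 0.075 / 100,
          fps = config$calibration$fps, duration_s = 0.1,
          pixels_per_cm = 10, noise_px = 0)
        list(frames = traj$frames, onset_s = 0, pre_contact_response = TRUE)
      })
      res <- cstart_results(attempts, fps = config$calibration$fps,
                            pixels_per_cm = 10,
                            window_ms = an$cstart_window_ms,
                            body_length_cm = st$body_length_cm,
                            smooth_window = an$cstart_smooth,
                            fish_id = sprintf("%s_%g_c%02d",
                                              substr(tr, 1, 3), tt, k))
      res$temperature <- tt; res$treatment <- tr
      cs[[length(cs) + 1L]] <- res
    }
  }
  cstart <- do.call(rbind, cs)
  say("kinematics: %d fish analysed (%d with no analysable attempt)",
      nrow(cstart), sum(cstart$n_analyzable == 0))

  ## performance stage ------------------------------------------------------
  sim_metric <- function(metric, ref, is_rate, comp_applies = TRUE) {
    simulate_performance_dataset(
      temperatures_acute = st$temperatures,
      temperatures_acclimated = st$temperatures,
      wdtt = st$wdtt, q10_above = st$q10_above, q10_below = st$q10_below,
      compensation_factor = if (comp_applies) st$compensation_factor else 1,
      reference_rate = ref, cv = st$cv, n_per_group = st$n_per_group,
      metric = metric, is_rate = is_rate)$table
  }
  uchase_tab <- sim_metric("uchase", st$uchase_ref_bls, TRUE)
  chase_tab <- sim_metric("chase_duration", st$chase_duration_ref_s, FALSE)

  perf_cols <- c("fish_id", "metric", "value", "temperature", "treatment",
                 "is_rate")
  as_perf <- function(df, metric, value, is_rate) {
    data.frame(fish_id = df$fish_id, metric = metric, value = value,
               temperature = df$temperature, treatment = df$treatment,
               is_rate = is_rate, stringsAsFactors = FALSE)
  }
  performance_table <- rbind(
    uchase_tab[, perf_cols], chase_tab[, perf_cols],
    as_perf(metabolic, "smr", metabolic$smr, TRUE),
    as_perf(metabolic, "mmr", metabolic$mmr, TRUE),
    as_perf(metabolic, "aas", metabolic$aas, TRUE),
    as_perf(metabolic, "epoc", metabolic$epoc, TRUE),
    as_perf(metabolic, "recovery_time", metabolic$recovery_time_h, FALSE),
    as_perf(cstart, "umax", cstart$u_max_bls, TRUE),
    as_perf(cstart, "amax", cstart$a_max_ms2, TRUE),
    as_perf(cstart, "responsiveness", cstart$responsiveness, FALSE))
  performance_table <-
    performance_table[!is.na(performance_table$value), ]
  say("performance: table with %d rows over %d metrics",
      nrow(performance_table), length(unique(performance_table$metric)))

  ## sensitivity stage ------------------------------------------------------
  iv <- default_intervals()
  iv <- iv[iv$t_low %in% st$temperatures & iv$t_high %in% st$temperatures, ]
  sens <- suppressWarnings(thermal_sensitivity(performance_table, iv))
  say("sensitivity: %d per-metric Q10 values, %d omnibus rows",
      nrow(sens$q10), nrow(sens$omnibus))

  ## stats stage ------------------------------------------------------------
  anovas <- list()
  for (m in unique(performance_table$metric)) {
    a <- tryCatch(two_way_anova(performance_table, m,
                                temperatures = st$temperatures),
                  error = function(e) NULL)
    if (!is.null(a)) anovas[[m]] <- a
  }
  sens_aov <- tryCatch(sensitivity_anova(sens, mode = "q10"),
                       error = function(e) NULL)

  gm <- stats::aggregate(value ~ metric + treatment + temperature,
                         data = performance_table, FUN = mean)
  eff <- merge(
    setNames(gm[gm$metric == "chase_duration",
                c("treatment", "temperature", "value")],
             c("treatment", "temperature", "chase_duration")),
    setNames(gm[gm$metric == "uchase",
                c("treatment", "temperature", "value")],
             c("treatment", "temperature", "uchase")))
  eff$effort <- mapply(compute_effort, eff$chase_duration, eff$uchase)
  eff <- merge(eff, setNames(gm[gm$metric == "epoc",
                                c("treatment", "temperature", "value")],
                             c("treatment", "temperature", "epoc")))
  reg <- tryCatch(effort_epoc_regression(eff), error = function(e) NULL)
  say("stats: %d metric ANOVAs, sensitivity ANOVA %s, effort-EPOC regression %s",
      length(anovas), if (is.null(sens_aov)) "skipped" else "done",
      if (is.null(reg)) "skipped" else "done")

  bundle <- structure(list(
    metabolic = metabolic, cstart = cstart,
    performance_table = performance_table, sensitivity = sens,
    anova = anovas, sensitivity_anova = sens_aov,
    effort_epoc = list(table = eff, regression = reg),
    manifest = NULL, log = log, config = config
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    tables <- list(metabolic_summary = metabolic, cstart_results = cstart,
                   performance_table = performance_table,
                   q10_results = sens$q10,
                   sensitivity_summary = sens$omnibus,
                   effort_epoc = eff)
    bundle$manifest <- write_results(tables, out_dir)
    say("wrote %d result tables to %s", nrow(bundle$manifest), out_dir)
  }
  bundle
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}
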