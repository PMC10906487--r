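test_that("slope-to-MO2 conversion is exact and linear in its factors", {
  spec <- example_spec()
  expect_equal(compute_mo2(10, spec), 2.4, tolerance = 1e-12)
  expect_equal(compute_mo2(0, spec), 0)
  heavy <- respirometer_spec(0.160, 0.010, alpha = 0.08, mass = 0.100)
  expect_equal(compute_mo2(10, heavy), 1.2, tolerance = 1e-12)
  bigger <- respirometer_spec(0.310, 0.010, alpha = 0.08, mass = 0.050)
  expect_equal(compute_mo2(10, bigger), 4.8, tolerance = 1e-12)
  expect_error(respirometer_spec(0.010, 0.020, alpha = 0.08, mass = 0.05),
               "effective volume")
  # data-frame form carries the window midpoint
  df <- data.frame(window_start = 0, window_end = 60, slope = 10)
  out <- compute_mo2(df, spec)
  expect_equal(out$time_mid, 30)
  expect_equal(out$mo2, 2.4, tolerance = 1e-12)
})

test_that("background correction subtracts the mean and clamps at zero", {
  expect_equal(as.numeric(correct_background(10, c(1, 1, 1))), 9)
  expect_equal(as.numeric(correct_background(c(5, 7), c(0, 0, 0))), c(5, 7))
  expect_warning(res <- correct_background(1, c(2, 2)), "clamped")
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "clamped"))
  expect_error(correct_background(10, numeric(0)), "background")
})

test_that("whole-cycle slopes equal the decline rate and the regression oracle", {
  sched <- cycle_schedule(180, 540)
  tr <- make_linear_trace(c(10, 10, 10), sched)
  slopes <- segment_cycles(tr, sched)
  expect_equal(nrow(slopes), 3)
  expect_equal(slopes$slope, rep(10, 3), tolerance = 1e-9)
  expect_equal(slopes$window_start, c(120, 840, 1560))
  expect_equal(slopes$window_end, c(480, 1200, 1920))

  # two-segment cycle: least-squares fit must match an independent lm fit
  set.seed(5)
  for (rep in 1:5) {
    r1 <- runif(1, 5, 30); r2 <- runif(1, 5, 30)
    t <- 0:539
    o2 <- ifelse(t < 270, 100 - r1 * t / 3600,
                 100 - r1 * 270 / 3600 - r2 * (t - 270) / 3600)
    tr2 <- o2_trace(t, o2, rep("closed", 540))
    got <- segment_cycles(tr2, sched)$slope
    sel <- t >= 120 & t < 480
    expect_equal(got, oracle_slope(t[sel], o2[sel]), tolerance = 1e-9)
  }

  # a cycle shorter than the trims is skipped with a warning
  short <- o2_trace(0:100, rep(100, 101), rep("closed", 101))
  expect_warning(out <- segment_cycles(short, sched), "skipped")
  expect_equal(nrow(out), 0)
})

test_that("MMR window search finds the steepest 60-s window, earliest on ties", {
  sched <- cycle_schedule(180, 540)
  spec <- example_spec()
  # 20 %sat/h for the first 90 s of closed time, then 10
  t <- 0:539
  o2 <- ifelse(t < 90, 100 - 20 * t / 3600,
               100 - 20 * 90 / 3600 - 10 * (t - 90) / 3600)
  tr <- o2_trace(t, o2, rep("closed", 540))
  m <- find_mmr(tr, spec, sched)
  expect_equal(m$closed_offset_s, 0)
  expect_equal(m$slope, 20, tolerance = 1e-9)  # 0-60 s window sits on the steep segment

  # constant rate: every window ties; earliest wins and MMR = cycle MO2
  tr2 <- make_linear_trace(12, sched)
  m2 <- find_mmr(tr2, spec, sched)
  expect_equal(m2$closed_offset_s, 0)
  expect_equal(m2$mo2, compute_mo2(12, spec), tolerance = 1e-9)

  # monotone-decreasing MO2: first window always selected
  sim <- simulate_o2_trace(2, 5, 0.5, background_rate = 0, noise_sd = 0,
                           schedule = sched, duration_h = 3, spec = spec)
  expect_equal(find_mmr(sim$trace, spec, sched)$closed_offset_s, 0)

  expect_error(find_mmr(o2_trace(0:10, rep(100, 11), rep("flush", 11)),
                        spec, sched), "closed")
})

test_that("lowest-10% SMR estimator matches its enumerated definition", {
  est <- estimate_smr(20:1)   # values 1..20 in reverse order
  expect_equal(est$smr, 1.5)  # pool {1,2}, both within 2 SD
  expect_equal(est$n_used, 2)

  expect_equal(estimate_smr(rep(3.3, 15))$smr, 3.3)

  set.seed(9)
  v <- rlnorm(30, log(2), 0.3)
  expect_equal(estimate_smr(v)$smr, estimate_smr(sample(v))$smr)

  expect_warning(small <- estimate_smr(c(2, 3)), "fewer than 10")
  expect_true(small$all_used)
  expect_error(estimate_smr(numeric(0)), "no MO2")
})

test_that("recovery series has the expected sub-window layout and values", {
  sched <- cycle_schedule(180, 540)
  spec <- example_spec()
  sim <- simulate_o2_trace(2, 2, 0, background_rate = 0, noise_sd = 0,
                           schedule = sched, duration_h = 6, spec = spec)
  m <- find_mmr(sim$trace, spec, sched)
  rec <- build_recovery_series(sim$trace, spec, sched, m)
  # (540 - 180) / 60 = 6 fine sub-windows per 9-min cycle; the first cycle
  # contributes all 6 because the MMR window (0-60 s) precedes the trims
  per_cycle <- base::table(findInterval(rec$window_start[rec$source ==
                                                    "fine_60s"],
                                  seq(0, 6 * 3600, by = 720)))
  expect_true(all(per_cycle == 6))
  # constant-SMR trace: every recovery sample equals SMR
  expect_equal(rec$mo2, rep(2, nrow(rec)), tolerance = 1e-9)
  # coarse samples appear only beyond the 4-h fine horizon
  expect_true(all(rec$time_mid[rec$source == "coarse_3min"] >
                    m$window_start + 4 * 3600))
})

test_that("recovery series tracks the true exponential at window midpoints", {
  sched <- schedule_for(14)
  spec <- example_spec()
  sim <- simulate_o2_trace(2, 5, 1, background_rate = 0, noise_sd = 0,
                           schedule = sched, duration_h = 8, spec = spec)
  m <- find_mmr(sim$trace, spec, sched)
  rec <- build_recovery_series(sim$trace, spec, sched, m)
  truth <- sim$truth$mo2(rec$time_mid / 3600)
  # finite-window averaging bias only: well under 1% at 60-s windows
  expect_lt(max(abs(rec$mo2 - truth) / truth), 0.01)
})

test_that("recovery time is the first of three consecutive in-band samples", {
  ser <- data.frame(time_mid = (1:6) * 600,
                    mo2 = c(5.0, 3.0, 2.2, 2.05, 2.04, 2.02))
  r <- find_recovery_time(ser, smr = 2.0, mmr_time_s = 0)
  expect_true(r$recovered)
  expect_equal(r$index, 3)          # run starts at the 2.2 sample
  expect_equal(r$recovery_time_h, 1800 / 3600)

  allin <- data.frame(time_mid = (1:4) * 60, mo2 = rep(2, 4))
  expect_equal(find_recovery_time(allin, 2, 0)$index, 1)

  high <- data.frame(time_mid = (1:4) * 60, mo2 = rep(3, 4))
  rh <- find_recovery_time(high, 2, 0)
  expect_false(rh$recovered)
  expect_equal(rh$recovery_time_s, 240)

  expect_false(find_recovery_time(ser[1:2, ], 2, 0)$recovered)
})

test_that("EPOC integration matches the closed-form exponential excess", {
  # excess 3 mg O2 h^-1 kg^-1 decaying with tau = 1 h, integrated to 2 h
  t_h <- seq(1 / 60, 2, by = 1 / 60)
  ser <- data.frame(time_mid = t_h * 3600, mo2 = 2 + 3 * exp(-t_h))
  e <- compute_epoc(ser, smr = 2, mmr = 5, mmr_time_s = 0,
                    recovery_time_s = 2 * 3600)
  expect_equal(e, 3 * (1 - exp(-2)), tolerance = 0.01)

  # MO2 identically SMR integrates to zero
  flat <- data.frame(time_mid = (1:10) * 60, mo2 = rep(2, 10))
  expect_equal(compute_epoc(flat, 2, 2, 0, 600), 0)

  # linearity: halving the excess halves EPOC
  ser2 <- ser; ser2$mo2 <- 2 + (ser$mo2 - 2) / 2
  e2 <- compute_epoc(ser2, 2, 3.5, 0, 2 * 3600)
  expect_equal(e2, e / 2, tolerance = 1e-9)

  expect_error(compute_epoc(ser, 2, 5, 100, 0), "recovery_time_s")
})

test_that("cohort alignment keeps exactly the common time points", {
  s1 <- data.frame(time_mid = c(100, 200, 300, 400), mo2 = 1:4)
  s2 <- data.frame(time_mid = c(100, 200, 300, 400), mo2 = 5:8)
  out <- align_cohort_timepoints(list(s1, s2), tolerance_s = 5)
  expect_identical(out[[1]], s1)

  s3 <- data.frame(time_mid = c(100, 300, 400), mo2 = 1:3)
  out2 <- align_cohort_timepoints(list(s1, s3), tolerance_s = 5)
  expect_equal(out2[[1]]$time_mid, c(100, 300, 400))
  expect_equal(out2[[2]]$time_mid, c(100, 300, 400))

  expect_error(align_cohort_timepoints(list(s1)), "at least 2")
})

test_that("full metabolic fit recovers zero-noise ground truth and its invariants", {
  sched <- schedule_for(14)
  spec <- example_spec()
  sim <- simulate_o2_trace(2, 5, 1, background_rate = 1, noise_sd = 0,
                           schedule = sched, duration_h = 14, spec = spec)
  f <- fit_metabolism(sim$trace, spec, sched)
  est <- coef(f)
  expect_lt(abs(est["smr"] - 2) / 2, 0.05)
  expect_lt(abs(est["mmr"] - 5) / 5, 0.05)
  expect_identical(unname(est["aas"]), unname(est["mmr"] - est["smr"]))
  expect_lt(abs(est["epoc"] - sim$truth$epoc) / sim$truth$epoc, 0.10)
  expect_true(f$recovered)

  # MMR dominates whole-cycle means; SMR is below the overall mean
  expect_true(f$mmr >= max(f$cycles$mo2) - 1e-9)
  expect_true(f$smr <= mean(f$cycles$mo2) + 1e-9)

  # uniform time translation leaves every estimate unchanged
  sh <- sim$trace
  sh$time_s <- sh$time_s + 1234
  f2 <- fit_metabolism(o2_trace(sh$time_s, sh$o2, sh$phase), spec, sched)
  expect_equal(coef(f2), coef(f), tolerance = 1e-9)

  # tau ~ 0: EPOC vanishes and recovery is immediate (first sample in band)
  sim0 <- simulate_o2_trace(2, 2, 0, background_rate = 1, noise_sd = 0,
                            schedule = sched, duration_h = 6, spec = spec)
  f0 <- fit_metabolism(sim0$trace, spec, sched)
  expect_lt(f0$epoc, 0.05)
  expect_equal(f0$recovery_time_h,
               (f0$recovery$time_mid[1] - f0$mmr_window_start) / 3600)
})

test_that("EPOC is non-decreasing in recovery time", {
  t_h <- seq(1 / 60, 3, by = 1 / 60)
  ser <- data.frame(time_mid = t_h * 3600, mo2 = 2 + 3 * exp(-t_h))
  e <- vapply(c(0.5, 1, 2, 3) * 3600, function(rt)
    compute_epoc(ser, 2, 5, 0, rt), numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("print, summary, coef and plot methods run on a fitted object", {
  sched <- schedule_for(14)
  spec <- example_spec()
  sim <- simulate_o2_trace(2, 5, 1, noise_sd = 0, schedule = sched,
                           duration_h = 6, spec = spec)
  f <- fit_metabolism(sim$trace, spec, sched)
  expect_output(print(f), "Metabolic fit")
  expect_output(print(summary(f)), "MMR window")
  expect_named(coef(f), c("smr", "mmr", "aas", "epoc", "recovery_time_h"))
  pdf(NULL)
  expect_silent(plot(f))
  dev.off()
  expect_equal(nrow(metabolic_summary(list(f, f))), 2)
})
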