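# shared fixtures, all built in code

# respirometer matching the worked conversion example:
# slope 10 %sat/h -> 10 * 0.150 * 0.08 / 0.050 = 2.4 mg O2 h^-1 kg^-1
example_spec <- function() {
  respirometer_spec(0.160, 0.010, alpha = 0.08, mass = 0.050)
}

# noiseless trace with a fixed decline rate (%sat/h) per closed cycle,
# flush samples at 100; closed-then-flush pattern at `hz`
make_linear_trace <- function(rates, schedule, hz = 1, background = NULL) {
  cycle_s <- schedule$closed_s + schedule$flush_s
  time_s <- o2 <- numeric(0); phase <- character(0)
  t0 <- 0
  for (r in rates) {
    tc <- seq(0, schedule$closed_s - 1 / hz, by = 1 / hz)
    tf <- seq(schedule$closed_s, cycle_s - 1 / hz, by = 1 / hz)
    time_s <- c(time_s, t0 + c(tc, tf))
    o2 <- c(o2, 100 - r * tc / 3600, rep(100, length(tf)))
    phase <- c(phase, rep("closed", length(tc)), rep("flush", length(tf)))
    t0 <- t0 + cycle_s
  }
  if (!is.null(background)) {
    for (i in 1:3) {
      tc <- seq(0, schedule$closed_s - 1 / hz, by = 1 / hz)
      tf <- seq(schedule$closed_s, cycle_s - 1 / hz, by = 1 / hz)
      time_s <- c(time_s, t0 + c(tc, tf))
      o2 <- c(o2, 100 - background * tc / 3600, rep(100, length(tf)))
      phase <- c(phase, rep("background", length(tc)),
                 rep("flush", length(tf)))
      t0 <- t0 + cycle_s
    }
  }
  o2_trace(time_s, o2, phase)
}

# independent slope oracle: plain lm on the samples, magnitude per hour
oracle_slope <- function(time_s, o2) {
  -unname(coef(lm(o2 ~ I(time_s / 3600)))[2])
}

# tidy performance table for ANOVA tests
make_perf_table <- function(values_by_group, metric = "m", is_rate = TRUE) {
  # values_by_group: data.frame(temperature, treatment) + list column values
  do.call(rbind, lapply(seq_len(nrow(values_by_group)), function(i) {
    v <- values_by_group$values[[i]]
    data.frame(fish_id = paste0("f", i, "_", seq_along(v)), metric = metric,
               value = v, temperature = values_by_group$temperature[i],
               treatment = values_by_group$treatment[i], is_rate = is_rate,
               stringsAsFactors = FALSE)
  }))
}
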