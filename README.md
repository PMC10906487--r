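# thermoperf

Thermal exercise and metabolic performance analysis for fishes.

## What this package is for

Comparative physiologists quantify how temperature constrains whole-animal
performance by measuring a battery of metrics — standard and maximum
metabolic rate (SMR, MMR), absolute aerobic scope (AAS = MMR − SMR),
excess post-exercise oxygen consumption (EPOC) and its recovery time,
C-start burst escape velocity and acceleration (U_max, A_max), startle
responsiveness, exhaustive chase swim speed (U_chase) and endurance, and
muscle enzyme activities — across acute temperature exposures and
multi-week acclimations. `thermoperf` implements the full processing
chain from raw data to thermal-sensitivity inference:

- **Respirometry.** Intermittent-closed respirometry O2 traces (% air
  saturation vs time, with flush/closed cycling) are converted to
  mass-specific oxygen consumption via
  `MO2 = s · V_resp · α / M`,
  where `s` is the slope of O2 decline (% sat h⁻¹), `V_resp` the
  respirometer loop volume minus fish volume (L), `α` the oxygen
  solubility (mg O2 L⁻¹ %sat⁻¹) and `M` the fish mass (kg). MMR is found
  by an iterative search of 60-s windows advanced in 30-s steps over the
  first 15 min of closed time; SMR is the mean of the lowest 10% of
  whole-cycle values after 2-SD outlier exclusion; recovery time is the
  first of three consecutive MO2 values within SMR ± 10%; EPOC is the
  trapezoidal integral of the excess above SMR from MMR to recovery. All
  slopes are corrected by the trial's fish-free background cycles.
- **Burst kinematics.** Tracked C-start trajectories (pixels at 240
  frames s⁻¹) are calibrated, differentiated by centred finite
  differences over a 75-ms post-onset window, and summarised per fish by
  the best attempt's U_max with its associated A_max, plus pre-contact
  responsiveness.
- **Performance assays.** Chase swim speed
  `U_chase = laps · circumference / duration` (BL s⁻¹), exhaustive
  exercise effort `effort = mean chase duration × mean U_chase` (BL), and
  Beer–Lambert enzyme activity rates from plate-reader absorbance slopes.
- **Thermal sensitivity.** The temperature coefficient
  `Q10 = (R2/R1)^(10/(T2−T1))`
  computed from group means per metric over intervals bracketing the
  winter dormancy threshold temperature (WDTT, ~8 °C), percent change of
  the mean with cooling for all metrics (including non-rate ones), and
  omnibus (across-metric) summaries contrasting acute exposure with
  acclimation.
- **Inference.** One- and two-way ANOVA (type-II SS) with Tukey HSD,
  mean-centred Levene tests, omnibus-sensitivity ANOVA across interval
  levels, and the effort–EPOC regression with a slope-difference test.
- **Synthetic data.** Every input can be generated with closed-form
  ground truth (`simulate_o2_trace()`, `simulate_cstart_trajectory()`,
  `simulate_performance_dataset()`), which is how the estimators are
  validated.

## Worked example

Fit one overnight post-exercise respirometry trial simulated at 14 °C
(9-min closed / 3-min flush schedule; true SMR 2, MMR 5 mg O2 h⁻¹ kg⁻¹,
recovery time constant 1 h):

```r
library(thermoperf)
sched <- schedule_for(14)
spec  <- respirometer_spec(loop_volume = 0.160, fish_volume = 0.050,
                           alpha = 0.08, mass = 0.050)
sim <- simulate_o2_trace(true_smr = 2, true_mmr = 5, recovery_tau_h = 1,
                         schedule = sched, duration_h = 14, spec = spec,
                         seed = 42)
fit <- fit_metabolism(sim$trace, spec, sched)
summary(fit)
#> Metabolic fit
#>             smr             mmr             aas            epoc recovery_time_h
#>           1.976           5.261           3.285           2.815           2.325
#>
#> MMR window: 0-60 s (closed-time offset 0 s)
#> SMR pool: lowest 7 whole-cycle values used (of 70 cycles)
#> Background: 1.017 %sat h^-1 from 3 cycle(s); alpha = 0.08 (user-supplied)
#> Recovery series: 120 fine + 13 coarse samples; recovered at 2.33 h post-MMR
```

SMR is recovered within ~1%, MMR within ~5% (the 60-s window maximum
carries a small upward selection bias under probe noise), AAS is their
exact difference, and EPOC (2.82 mg O2 kg⁻¹) sits close to the
generator's closed-form 2.8.

Thermal sensitivity of a simulated performance metric (Q10 = 2 above the
8 °C threshold, 5 below, with acclimation compensation; CV 15%, n = 12
per group):

```r
perf <- simulate_performance_dataset(cv = 0.15, n_per_group = 12, seed = 42)
sens <- thermal_sensitivity(perf$table)
sens$q10[, c("label", "q10")]
#>             label  q10
#>       acute 20-14 1.97
#>        acute 14-8 2.01
#>         acute 8-2 5.02
#>   acclimated 14-8 1.93
#>    acclimated 8-2 2.02
```

The engine recovers the generating thermal sensitivities: acute cooling
below the threshold shows the steep Q10 ≈ 5 constraint, while the
acclimated 8–2 °C interval returns Q10 ≈ 2 — the compensatory-plasticity
contrast the omnibus analysis is designed to expose. A single Q10 call:
`q10(40, 100, 2, 8)` gives `4.605`.

The whole simulated study (respirometry, kinematics, chase performance,
sensitivity, ANOVA layer) runs with `run_pipeline(default_config())`.

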