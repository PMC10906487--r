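---
title: "Models and methods behind thermoperf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoperf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoperf)
```

`thermoperf` turns the raw observations of a thermal performance study on
fishes — oxygen traces from intermittent-closed respirometry, tracked
burst-escape trajectories, chase-trial records and plate-reader assays —
into the standard metrics of the field, and then into interval-wise
thermal-sensitivity statistics contrasting acute temperature exposure
with acclimation. This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic-data validation
does and does not establish.

## Respirometry model

Intermittent-closed respirometry alternates a flush phase, which
re-oxygenates the chamber, with a sealed closed phase during which the
fish depletes oxygen. Mass-specific oxygen consumption is obtained from
the slope *s* of the % air-saturation decline during a closed window:

$$\dot{M}_{\mathrm{O}_2} = \frac{s \cdot V_{\mathrm{resp}} \cdot \alpha}{M}$$

with $V_{\mathrm{resp}}$ the loop volume minus fish volume (L), $\alpha$
the oxygen solubility (mg O2 L$^{-1}$ %sat$^{-1}$) and $M$ the fish mass
(kg). Two conventions are fixed package-wide: time is seconds from the
fish's entry into the chamber (0-based, half-open phase intervals
`[start, end)`), and all slopes are stored as magnitudes of decline, so
the conversion always receives a non-negative number.

$\alpha$ depends on temperature, salinity and barometric pressure and is
accepted as a direct input rather than computed internally; because two
labs can legitimately use different solubility formulations, every fitted
object records the $\alpha$ used and its provenance
(`respirometer_spec(..., alpha_source = )`).

Estimator definitions, all exposed as config-style arguments of
`fit_metabolism()` with the field-standard defaults:

* **MMR** — the steepest background-corrected 60-s window, advanced in
  30-s increments of *accumulated closed time* (flushes are excluded from
  the clock and windows never span one) over the first 15 min of closed
  time. Ties go to the earliest window; the search clock starts at
  chamber entry because post-chase MO2 decays from its maximum
  immediately.
* **Whole-cycle MO2** — one least-squares slope per closed cycle over the
  trimmed window that drops the first 120 s (probe equilibration after
  flush) and last 60 s (avoid sampling the next flush).
* **SMR** — the mean of the lowest 10% of whole-cycle values (count
  `ceiling(0.10 n)`) after excluding members of that pool lying outside
  2 SD of the pool mean. The exclusion is a single pass (no
  re-iteration), and with fewer than 10 cycles the full set is used with
  a warning. The cycle containing the MMR window is excluded from the
  pool: it cannot be a resting measurement and would contaminate the
  pool's SD. Slopes that fall below the background after correction are
  clamped to zero, flagged, and excluded from the pool.
* **Recovery series** — sequential 60-s sub-windows inside each trimmed
  closed period until 4 h post-MMR, then one 3-min window per 45-min
  interval (`coarse_spacing_s`) until the trace ends.
* **Recovery time** — the time of the *first* sample of the earliest run
  of three consecutive MO2 values inside SMR ± 10%. If no run exists the
  series end is reported with a `recovered = FALSE` flag.
* **EPOC** — the trapezoidal integral of $\max(\dot{M}_{\mathrm{O}_2} -
  \mathrm{SMR}, 0)$ on the irregular sample grid from the MMR time to the
  recovery time, with the MMR point prepended at its window start. The
  quadrature choice matters little at 60-s sampling (the validation shows
  agreement with the closed form to ~1%).

Background respiration is corrected on the slope scale — the fish-free
cycles measure the chamber's own O2 drawdown in the same % sat h$^{-1}$
units — before conversion, using the mean of the trial's (typically
three) background cycles; the fish volume is still subtracted in
$V_{\mathrm{resp}}$ for the fish's own conversion.

When several fish share a trial they enter their chambers at staggered
times, so some fine-window time points lack a value for some fish;
`align_cohort_timepoints()` drops, for all fish, any time point not
present for every cohort member within a configurable tolerance.

## Burst kinematics

C-start escape responses are analysed over a fixed 75-ms window after
onset — the span of response stages 1 and 2 — at 240 frames s$^{-1}$.
Pixel coordinates are calibrated against an object of known length
(`calibrate()`, conventionally a 3-cm line). Speed is the norm of the
centred finite difference of position; tangential acceleration is the
centred difference of speed; one-sided differences are used only at
trajectory ends. Centred differences are exact on constant-acceleration
paths, which is why the validation demands <2% error there; tracking
software applies unspecified internal filtering, so an optional
moving-average smoother (`smooth_window`) is provided but off by
default, and onset is an input annotation, not auto-detected. Per fish,
the reported U_max is the best attempt's maximum speed and A_max is the
acceleration *of that same attempt*; responsiveness is the percentage of
attempts with a pre-contact C-start, with contact-triggered responses
counting as failures (it is a sensory, not locomotor, metric).

## Thermal sensitivity

Each metric's sensitivity over a temperature interval $(T_1, T_2)$ is

$$Q_{10} = \left(\frac{R_2}{R_1}\right)^{10/(T_2 - T_1)}$$

computed from the *arithmetic group means* at the endpoint temperatures,
because each fish is tested at a single temperature (no within-fish
pairs exist). Q10 is restricted to rate metrics with positive means;
percent change of the mean, signed in the cooling direction
($100 (\bar{x}_{low} - \bar{x}_{high})/\bar{x}_{high}$, negative =
performance loss), covers all metrics including the non-rate ones
(chase duration, recovery time, responsiveness) for which a per-time
coefficient is meaningless. The default intervals bracket a winter
dormancy threshold temperature (WDTT) of 8 °C with equal 6 °C spans
(14–8 and 8–2 °C) plus an acute warm interval (14–20 °C); no acclimated
14–20 °C interval exists because animals are not acclimated above 14 °C.
Omnibus summaries average the per-metric Q10s of rate metrics, or
percent changes of all metrics, per interval × treatment; SMR is carried
through the tables but excluded from omnibus summaries since it is a
maintenance cost, not a performance. Dispersion is reported as SD,
s.e.m. and quartiles, supporting the box-plot display conventional for
these contrasts.

## Inferential layer

Per-metric comparisons use `aov()`: a two-way ANOVA
(temperature × treatment over the shared 14–2 °C range, type-II sums of
squares via `car::Anova` because group sizes vary mildly) and a one-way
ANOVA over the broad acute series, both with Tukey HSD. The omnibus
sensitivities are compared across the five interval-treatment levels by
one-way ANOVA with the metrics as replicates. Variance homogeneity uses
the mean-centred Levene test (`car::leveneTest(center = mean)`). Note a
real property exposed by the package's own Monte-Carlo calibration: the
mean-centred Levene test is slightly anti-conservative in finite samples
(measured type-I error ≈ 0.055 at 3 groups × 20 normals), unlike the
ANOVA F and regression t tests, which are exact under normality.
Normality is left to diagnostic inspection; no automatic transformation
is applied, and no multiplicity layer beyond Tukey is added. The
effort–EPOC relationship is fitted by OLS per treatment on group means
(5 temperature points each), and the slope difference is tested via the
effort × treatment interaction of a pooled model; exercise *effort*
(mean chase duration × mean U_chase, in body lengths) is defined only at
the group-mean level because its two factors come from different
experimental animals.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions used throughout the tests:

* `simulate_o2_trace()` — mono-exponential recovery
  $\dot{M}_{\mathrm{O}_2}(t) = \mathrm{SMR} + (\mathrm{MMR} -
  \mathrm{SMR}) e^{-t/\tau}$ from chamber entry, integrated exactly
  within each closed phase, instantaneous re-equilibration to 100% at
  flush end, constant background rate, pointwise Gaussian noise, three
  trailing fish-free cycles. The mono-exponential is chosen because it
  gives closed forms for the ground truth: recovery time
  $t_r = \tau \ln[(\mathrm{MMR}-\mathrm{SMR})/(0.1\,\mathrm{SMR})]$ and
  EPOC $(\mathrm{MMR}-\mathrm{SMR})\,\tau\,(1 - e^{-t_r/\tau})$.
  Defaults: SMR 2 and MMR 5 mg O2 h$^{-1}$ kg$^{-1}$, $\tau$ = 1 h,
  background 1 %sat h$^{-1}$, noise SD 0.05 %sat at 1 Hz (typical
  optical-optode precision; much larger values would make 60-s window
  slopes noise-dominated, which no practical protocol tolerates).
* `simulate_cstart_trajectory()` — straight constant-acceleration paths
  in pixels at 240 fps with optional jitter; truth U_max = v0 + a·t.
* `simulate_performance_dataset()` — group means following a
  piecewise-Q10 model (`thermal_rate()`): Q10 = 2 above the WDTT
  (a typical passive thermal dependence), 5 below it (a cold
  constraint), reference at 14 °C; acclimated groups strictly below the
  WDTT are multiplied by a compensation factor, default
  $1.733 = (5/2)^{0.6}$, which over the 6 °C below-threshold interval
  converts the effective acclimated Q10 from 5 to 2.0 — i.e. full
  restoration of the above-threshold sensitivity, the magnitude of
  compensatory plasticity the acute-vs-acclimated contrast is designed
  to detect. Individuals are lognormal about the group mean (rates are
  positive) with CV 0.15 and n = 12 per group.

Real traces differ in ways the generator deliberately omits: probe drift
and calibration error, non-instantaneous flush mixing, activity bursts
during "resting" cycles (the reason the lowest-10% SMR estimator exists
at all), multi-phase recovery kinetics, and time-varying background
growth. Passing the synthetic validation therefore establishes that the
estimators implement their definitions correctly and recover parameters
under the stated noise model — not that any particular biological value
is accurate for a given species.

## Numerical choices and scale of the validation

Least-squares slopes are computed directly from the normal equations;
windows select samples by half-open intervals so adjacent windows never
share a sample; MMR ties are broken toward the earliest window with a
$10^{-9}$ relative tolerance so that exactly-linear traces behave like
the exact-arithmetic rule. Degenerate inputs (cycles shorter than the
trims, windows with fewer than two samples, empty SMR pools, series
shorter than three samples) are skipped or flagged with warnings rather
than silently propagated.

The test suite validates at deliberately chosen problem sizes: overnight
traces of 6–14 h at 1 Hz, 100 randomized instances per brute-force
estimator comparison, 200 replicate datasets for interval-Q10 recovery
(mean within ±0.15 of the generating values, compensation detected in
≥95% of replicates), and 1000 null replicates for the type-I-error
calibration of each inferential test. The pipeline demonstrator
(`run_pipeline()`) defaults to a compact study — temperatures 14, 8 and
2 °C, two respirometry trials and four C-start fish per group — sized so
the full stage graph runs in seconds while still exercising every module
and producing all five interval contrasts over the three shared
temperatures.

## Known limitations

* Closed (non-intermittent) respirometry, oxygen-probe drift correction
  and critical-oxygen analyses are out of scope.
* C-start onset detection, stage-1/stage-2 decomposition and latency are
  out of scope; onset is consumed as an annotation.
* Q10 is undefined for non-positive means; metrics that can hit zero
  (e.g. responsiveness) are handled by percent change only.
* Continuous thermal-performance-curve fitting (and hence formal
  T_opt estimation) is not attempted; the interval Q10 framework treats
  sensitivity as piecewise.
* The effort–EPOC regression operates on few (typically 5) group-mean
  points per treatment; its slope-difference test is exact under
  normality but low-powered, and weighted variants are deliberately not
  the default.
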