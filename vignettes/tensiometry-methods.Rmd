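---
title: "Estimating tendon shear-wave speed by fusing tensiometer delay measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tendon shear-wave speed by fusing tensiometer delay measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensiometry)
```

## The measurement problem

A shear wave tensiometer taps a superficial tendon impulsively (nominally at
100 Hz) and senses the traveling transverse wave with a line of skin-mounted
accelerometers at known distances $D_i$ from the tapper, sampled at 50 kHz.
Because the shear-wave speed $c$ in a tensioned tendon rises with axial load,
tracking $c$ tap by tap tracks tendon loading through movement.

The classical estimate uses a single pair of accelerometers: the wave travel
time $\tau$ between them is the lag maximizing the normalized
cross-correlation of the two signals, and $c = \Delta D / \tau$. Damping,
dispersion and sensor noise decorrelate the two signals, and every
decorrelated tap yields a noisy — occasionally wild — speed estimate. This
package implements and evaluates two remedies:

* **redundant sensors** ($n > 2$), turning speed estimation into a regression
  of position on arrival time, and
* **a Kalman filter** that fuses the spatial measurements (inter-sensor
  travel times $\tau_{ij}$) with temporal ones (the change $\Delta T_i$ in
  wave arrival at a *fixed* sensor between successive taps), which are less
  affected by propagation-induced decorrelation.

## Delay estimation

Both measurement types share one estimator: normalized (Pearson)
cross-correlation of a short template against a search window, evaluated at
every admissible integer lag, followed by a three-point cosine fit around
the integer peak,

$$\omega = \arccos\frac{r_{-} + r_{+}}{2 r_0}, \qquad
  \theta = \operatorname{atan2}\!\left(r_{-} - r_{+},\, 2 r_0 \sin\omega\right),
  \qquad \delta = -\theta / \omega,$$

which is exact when the correlation sequence is a sampled cosine and gives
sub-sample resolution otherwise (`cosine_subsample()`). Degenerate fits
($|(r_-+r_+)/2r_0| \ge 1$) fall back to the integer peak. Ties at the
integer peak resolve to the earliest lag; correlations are clipped to
$[-1, 1]$ before the $\arccos$.

Windowing choices that matter:

* **Template length** 2 ms (valid 1–3 ms). The impulse response rings for
  roughly 1 ms, so 2 ms captures it with margin while limiting the noise-only
  content of the window.
* **Travel-time windows.** Admissible lags span
  $\Delta D / c_\max \ldots \Delta D / c_\min$ with defaults
  $c_\min = 10$, $c_\max = 150$ m/s. The template is anchored at the tap
  onset by default; inside the filter it is *centred on the previous
  posterior arrival estimate*, because at swing-phase speeds the wave
  reaches a sensor 35–45 mm out only after 2–3 ms — an onset-anchored
  template would contain no signal at all there. The self-contained
  traditional estimator centres each pair's template on the proximal
  channel's absolute peak for the same reason.
* **Arrival-change windows.** The template is the previous tap's signal in a
  2 ms window centred on that tap's arrival estimate; the search spans
  $\pm 0.5$ ms around the same anchor, wide enough for the largest
  tap-to-tap arrival shifts a gait profile produces (a distal sensor during
  rapid unloading shifts by roughly 0.2–0.3 ms).
* Search-boundary peaks are flagged; downstream their variance is inflated
  100-fold rather than dropping the measurement.

## Calibrating measurement uncertainty

The filter needs variances for $\tau$ and $\Delta T$. These are calibrated
empirically (`run_calibration()`): simulated tap pairs with a known shift
are pushed through the estimator across a grid of signal-to-noise ratios
(default 100 log-spaced levels from 1 to 100 plus a noiseless sentinel,
1000 replicates each — 101,000 events), recording the mean peak correlation
$\bar r$ and the empirical variance of the estimated shift per level. A
least-squares quadratic of variance on $\bar r$ (`fit_variance_model()`)
then maps any observed $r$ to a variance at run time
(`variance_from_r()`), with three safeguards: evaluation is clipped to the
fitted $r$ range (no extrapolation), clipped at the parabola's vertex so
the map is non-increasing in $r$, and floored at the smallest positive
observed variance.

A genuine limitation, stated plainly: the calibrated variance spans about
five decades (delay SDs from ~1 ns noiseless to ~280 µs at SNR 1), and a
single quadratic fitted in linear space is dominated by the largest
variances. Its predictions resolve the low-$r$ regime well — which is what
lets the filter discount decorrelated measurements — but saturate at the
floor for $r \gtrsim 0.85$, so the filter treats all strong correlations
as equally reliable. The fit's $R^2$ on a default calibration exceeds 0.9
precisely because the big values dominate. A per-decade or log-domain model
would resolve the full range, at the cost of abandoning the simple
quadratic; the quadratic is retained as the package's documented model.

Pooling: one quadratic, calibrated on tap-to-tap ("delta") windows, serves
both measurement kinds by default; `style = "tau"` calibrates the
inter-sensor configuration separately, which yields systematically higher
variances at matched SNR (its template carries more noise-only content and
its search window admits more spurious peaks).

## The filter

The state is the arrival-time vector $T_k$ (seconds, one entry per
accelerometer) with covariance $P_k$. With identity transition and control
matrices,

$$T_k = T_{k-1} + \Delta T_{k-1} + W_k,$$

the arrival changes act as control input and their calibrated variances form
the diagonal process covariance $Q_k$. Observations stack $n-1$
consecutive-pair travel times, $\tau_{ij,k} = -T_{i,k} + T_{j,k} + v_k$,
and optional constant-speed constraint rows
$0 = D_j T_{i,k} - D_i T_{j,k} + v_k$ asserting arrival times proportional
to distance. The update is the standard linear one in Joseph form (posterior
covariance $(I-KH)P(I-KH)^\top + KRK^\top$, symmetrized), which keeps $P$
positive semidefinite; per-tap speed is the slope of a weighted
least-squares regression of position on arrival time with weights
$1/\mathrm{diag}(P)$.

Choices the source description leaves open, and what this package does:

* **Constraint-row variance.** The residual of a constraint row has units
  m·s, so a position uncertainty $\sigma_D$ maps to variance
  $(D_i^2 + D_j^2)(\sigma_D/c)^2$ under independent per-sensor offsets;
  $\sigma_D$ defaults to 0.5 mm and $c$ to the running speed estimate.
  Consecutive pairs only, enabled by default.
* **Initialization.** $T_0$ accumulates the first tap's travel times
  anchored at $T_1 = D_1/c_{\mathrm{xcorr}}$; $P_0$ is diagonal at 10× the
  calibrated variance of those measurements. The first tap's reported speed
  is the cross-correlation one, so the output series has full length.
* **Baseline coupling.** The cross-correlation-only baseline inside
  `run_filter()` consumes the same $\tau$ measurements the filter ingests,
  so method comparisons isolate the fusion step itself rather than
  differences in windowing.

## The simulator

Each tap is an underdamped second-order impulse response
$h(t) = A e^{-\zeta\omega_n t}\sin(\omega_d t)$,
$\omega_d = \omega_n\sqrt{1-\zeta^2}$, normalized so the peak equals the
amplitude parameter. Per tap, $f_n \sim N(1600, 100)$ Hz and
$\zeta \sim N(0.5, 0.05)$; the amplitude is nominally 20 m/s². All channels
share one waveform per tap (one physical wave); channel $i$ is the response
evaluated analytically at $t - D_i/c$, so sub-sample delays are exact and
ground-truth arrivals are stored analytically, never re-estimated. Sensor
noise is Gaussian white noise band-passed 100–5000 Hz by a 4th-order
Butterworth filter applied forward–backward and rescaled to its target SD
exactly. Records are 6 ms long with a 1 ms pre-trigger margin, mirroring
continuous acquisitions and letting arrival-change searches reach negative
lags for early arrivals.

**Gait profile.** The walking wave-speed trajectory is a parametric
template: a 15 m/s swing baseline, a raised-cosine stance bump peaking at
55 m/s at 48% of the cycle (half-width 30%), and a small late-swing rise;
running peaks at 95 m/s at 40%. The tap amplitude scales with
$c(t)/c_{\mathrm{peak}}$ (floored at 0.1), mimicking the collapse of
accelerometer amplitude in swing. These shapes stand in for
literature-derived Achilles trajectories whose values are not published
point-by-point; absolute CoV figures depend on this choice, relative
comparisons much less so.

**Noise scaling.** The SNR is the ratio of the tap's *local* signal
amplitude to the noise SD, so the prescribed SNR holds tap by tap across
the stride. Under the alternative reading (noise fixed relative to the
nominal amplitude while the signal envelope collapses), the swing phase
becomes catastrophically decorrelated at every tested SNR and the
high-speed stance phase — the regime practitioners actually flag as hard,
and the one the peak-speed accuracy figure highlights — becomes trivially
easy; the resulting error pattern is inconsistent with the accuracy scales
this class of simulation reports. Local scaling makes the hard regime the
physically hard one: high speeds compress $\tau$ toward the sampling
interval.

**Position perturbation.** Per-stride sensor offsets are
$N(0, \sigma_D)$, redrawn on ordering violations, constant within a stride;
estimation then assumes the nominal geometry.

## The simulation experiments

`noise_sweep()` crosses array sizes {2, 3, 4} (at 15/25/35/45 mm) with SNR
levels {∞, 16, 8, 4, 2}. Accuracy is the mean coefficient of variation:
per-time-point SD of estimated speed across the strides of a set, divided
by the prescribed speed, averaged over a common 100-point gait-cycle grid
(nearest-tap mapping) and over sets; the CoV at the peak-speed point is
reported alongside. The package default is 10 sets × 10 strides per
condition — the scale at which the suite and the acceptance script run —
with the full 20 × 20 available by argument.

`position_perturbation()` runs 100 noiseless strides per array size at
$\sigma_D = 0.5$ mm. Each stride yields a stride-mean absolute percent
error; the report carries the across-stride mean, 99th percentile and
maximum. The 99th percentile is the headline "error reached" figure: for
two sensors the error is $|\Delta D/(\Delta D + \delta) - 1|$, whose
reciprocal inflates the upper tail, making the raw maximum of 100 draws
swing by several percentage points from seed to seed while the 99th
percentile tracks the same tail stably.

Reduction summaries (`reduction_summary()`) compare matched conditions as
$100(1 - b/a)$. Reductions quoted "across noise conditions" average the
finite-SNR levels: at the noiseless sentinel both methods sit at ~0.02%
CoV (pure sub-sample interpolation jitter) and their ratio is numerically
meaningless.

What these experiments *cannot* show: the simulator has no dispersion,
spatial filtering, attenuation with distance, or guided-wave behaviour —
decorrelation between sensors arises from noise alone. Consequently the
premise that tap-to-tap windows correlate more strongly than inter-sensor
windows holds here through windowing (centred, short searches) rather than
through propagation physics, and inside the filter — where travel-time
templates are also centred — the two correlation populations are nearly
equal, with the tap-to-tap one slightly lower at poor SNR because
successive taps differ in waveform parameters. On real tissue the
inter-sensor correlations degrade further with distance, which can only
increase the value of the temporal channel; results here are therefore
conservative for the filter in that specific respect.

One behaviour worth knowing before applying the filter to hard data: at
SNR 2 the traditional estimator's correlation drops to $r \approx 0.5$ and
its peak picking fails intermittently across the admissible lag range,
producing heavy-tailed speed errors (mean CoV around 100% here). The filter
suppresses these tails almost entirely, so its measured CoV reduction at
that level (~75%) exceeds the ~55% this class of simulation typically
reports — the comparison baseline, not the filter, dominates that figure.

## Reproducibility

Every stochastic operation draws from R's global RNG; a single `set.seed()`
makes simulations, calibrations and experiments bit-reproducible. The
command-line interface (`main_cli()`; `inst/cli/tensiometry`) threads
`--seed` through every subcommand and logs package version, config hash and
seed on each run. Recordings travel as CSV with a commented YAML metadata
header; configurations and variance models as YAML.
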