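# tensiometry

Shear-wave tensiometry estimates in vivo tendon loading noninvasively: a
mechanical tapper excites a transverse (shear) wave in a superficial tendon
at ~100 Hz, skin-mounted accelerometers (sampled at 50 kHz, at known
distances `D_i` from the tapper) sense the wave's passage, and the wave's
propagation speed — which rises with tendon tension — is inferred from the
delays between those signals. Signal decorrelation from damping, dispersion
and sensor noise makes the classical two-sensor cross-correlation estimate
noisy, especially at high loads when the wave is fastest.

This package is for biomechanists and instrumentation developers working
with tensiometer data. It provides:

* a **simulator** with exact ground truth — underdamped second-order tap
  responses (natural frequency 1600 ± 100 Hz, damping ratio 0.50 ± 0.05,
  amplitude 20 m/s²), analytic sub-sample propagation delays, band-limited
  (100–5000 Hz) Gaussian sensor noise, and parametric walking/running
  wave-speed profiles;
* **delay estimators**: normalized cross-correlation with a three-point
  cosine fit for sub-sample resolution, for both inter-sensor travel times
  and tap-to-tap arrival changes;
* an empirical **calibration** mapping the peak correlation coefficient `r`
  to the variance of the delay estimate (quadratic fit, as used to populate
  the filter's noise covariances);
* a **Kalman filter** over the arrival-time state

  ```
  T_k = T_{k-1} + dT_{k-1} + W_k          (process; F = B = I, Q from calibration)
  tau_{ij,k} = -T_{i,k} + T_{j,k} + v_k   (travel-time observations)
  0 = D_j T_{i,k} - D_i T_{j,k} + v_k     (constant-speed constraint rows)
  z_k = H T_k + V_k
  ```

  with wave speed extracted per tap as the slope of a weighted
  least-squares regression of position on arrival time (weights
  `1/diag(P)`);
* the **simulation experiments** quantifying how the filter and redundant
  sensors (2/3/4 accelerometers) reduce wave-speed errors under sensor
  noise and sensor-placement uncertainty.

## Worked example

Simulate one noisy walking stride (SNR 4, three sensors at 15/25/35 mm) and
estimate the speed trajectory with both methods:

```r
library(tensiometry)
set.seed(42)

vm <- default_variance_model(reps = 200)   # calibrate r -> variance
#> <variance_model> var = 2.738e-07 -6.761e-07 r +4.053e-07 r^2 on r in [0.4104, 1.0000]
#>   floor 1.035e-18 s^2, R^2 = 0.917

arr <- sensor_array(c(0.015, 0.025, 0.035))
profile <- make_gait_profile("walking")
stride <- simulate_stride(profile, arr, tap_waveform_params(), noise_spec(4))
stride
#> <stride_simulation> 110 taps @ 100 Hz, 3 channels, profile 'walking'

res <- run_filter(stride, arr, vm)
res
#> <filter_result> 110 taps, 3 sensors; mean speed 28.04 m/s (kalman), 26.45 m/s (xcorr)

truth <- profile$speed(stride$gait_fraction)
mean(abs(res$speeds$speed_kalman - truth))   # 2.23 m/s
mean(abs(res$speeds$speed_xcorr - truth))    # 3.35 m/s
```

The variance model says delay estimates at `r = 0.41` carry ~280 µs of
uncertainty while strongly correlated ones are trusted to the floor; the
filter uses exactly this map to downweight decorrelated taps. On this
stride the fused trajectory tracks the prescribed speeds with ~33% less
mean absolute error than cross-correlation alone (2.23 vs 3.35 m/s), and at
the 55 m/s push-off peak reads 53.4 m/s versus 51.5 m/s for the baseline.

`run_filter()` returns per-tap speeds for both methods, per-tap standard
errors, posterior states, and degradation flags. `write_recording()` /
`read_recording()` move multichannel recordings through CSV (commented YAML
metadata header: sample rate, tap rate, positions, optional truth);
`inst/cli/tensiometry` exposes `simulate`, `calibrate`, `estimate` and
`experiment` subcommands over the same functions.

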