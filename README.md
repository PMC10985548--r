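# cortexwave

Quantification of cortical travelling waves in multi-channel TIRF
time-lapse microscopy.

Stimulated mast cells (and many other cell types) develop travelling waves
of actin polymerization on their ventral cortex: bands of protein
recruitment that sweep across the membrane with periods of ~10–40 s.
Quantifying them from fluorescence movies raises a recurring set of
questions — is a cell genuinely oscillating, at what period and speed, by
how many seconds does one protein lead another, is a second structure in
anti-phase, does marked material travel with the wave or stay put, how fast
does a bleached pool exchange — and this package answers each of them with
a tested, reusable estimator:

- **Oscillation calling** (`call_wave`, `detrend_normalize`, `periodogram`,
  `classify_wave`): a trace is a wave iff its FFT shows a *single, distinct*
  peak in the 0.8–40 s period band — the maximal in-band power must exceed
  `peak_ratio_min` (default 15) × the median in-band power, with no second
  local maximum above half the main peak's excess. Polarity (positive
  pulses vs negative dips) is scored by skewness; negative waves count as
  non-waves in population fractions.
- **Phase lags** (`cross_correlation`, `detect_cycles`, `average_profile`,
  `profile_lag`): signed delays with sub-frame parabolic/quadratic
  refinement, convention *negative = probe precedes reference*; both the
  cross-correlation lag and the peak-aligned average-profile lag are
  reported, plus a rise/fall `asymmetry_index` and an `anti_phase_score`.
- **Kymographs and speed** (`make_kymograph`, `estimate_wave_speed`,
  `time_projection`): reslicing along a line, shear-projection slope search
  over 180 orientations (flat or static input → `"undetermined"`), RGB
  three-frame projections.
- **Photoconversion & FRAP** (`track_punctum`, `punctum_displacement_test`,
  `frap_recovery`): stationary-vs-advected classification of a converted
  punctum (de novo nucleation vs transport), and single-exponential
  recovery fits `M (1 − e^{−kt})` for mobile fraction and exchange rate.
- **Population statistics** (`wave_fraction`, `compare_two`, `anova_sidak`,
  `frequency_histogram`): per-experiment wave fractions with SEM across
  experiments, unpaired t-tests, one-way ANOVA with Šidák-adjusted pairwise
  comparisons (`p_adj = 1 − (1 − p)^m`).
- **A synthetic-movie generator** (`simulate_wave_movie`,
  `simulate_traces`, `simulate_track`, `simulate_frap_trace`) renders
  planar or circular waves `B + A·w((t − δ − d(x)/v)/T)` with an asymmetric
  piecewise-linear waveform, anti-phase channels, photoconversion/FRAP
  events and Gaussian/Poisson noise, and returns the full ground truth —
  the oracle every estimator is validated against.

I/O is deliberately plain: TIFF stacks with a JSON calibration sidecar,
CSV traces and tracks, JSON ROIs/lines/ground truth
(`read_stack`/`write_stack`, `read_traces`/`write_traces`, ...). Readers
reject malformed input rather than repairing it. A thin command-line
wrapper lives at `inst/scripts/cortexwave.R` (subcommands `simulate`,
`analyze`, `report`).

## Worked example

Simulate a three-channel movie — a reference wave marker, a probe that
peaks 3.9 s earlier with a slower rise, and an anti-phased tubulin-like
channel — then run the full per-cell analysis:

```r
library(cortexwave)

cfg <- sim_config(
  grid_shape = c(48L, 200L), n_frames = 600L, seed = 11,
  channels = list(
    channel_spec("FBP17"),
    channel_spec("FHDC1", phase_offset = -3.9, rise_fraction = 0.75),
    channel_spec("tubulin", anti_phase = TRUE)),
  noise_sigma = 20)
sim <- simulate_wave_movie(cfg)

report <- analyze_movie(sim$stack, roi(14L, 90L, 20L, 20L),
                        reference = "FBP17", tubulin = "tubulin")
report
#> cell_report: 3/3 channels wave-positive (reference 'FBP17')
#>   channel lag_ccf_s lag_profile_s peak_correlation asymmetry_index
#> 1   FHDC1 -4.399417     -4.222967        0.9966543       1.4634146
#> 2 tubulin 10.043262      8.670067        0.9497403       0.7413793
#>   anti-phase: r0 = -1.00, lag fraction 0.50 -> anti-phased

report$calls$FBP17
#> wave_call: WAVE (polarity positive), period 20 s, peak/median 1.21e+05
```

All three channels pass the FFT wave criterion at the injected 20 s period
(the reference's main peak is ~10^5 × the median in-band power). The FHDC1
lag is negative — it precedes the reference — and close to the injected
−3.9 s; the small extra shift is expected and characterised: the profile
lag gains `2h(r_ref − r_probe)` = −0.32 s from ROI averaging over the
travelling wave (boxcar half-width h = 3.2 s here), and the
cross-correlation lag sits `(r_ref − r_probe)T/2` = −0.5 s from the peak
lag because it aligns waveform bulk rather than peaks (see the methods
vignette). Its asymmetry index > 1 reports the slow-rise/fast-fall
waveform. The tubulin channel correlates at −1.00 with the reference at
zero lag, half a period out of step: anti-phased.

Wave speed from a kymograph along the propagation direction (the line
should span at least two wavelengths):

```r
km <- make_kymograph(sim$stack, line_spec(c(24, 2), c(24, 197), 3L), "FBP17")
estimate_wave_speed(km)[c("status", "speed", "confidence")]
#> $status
#> [1] "ok"
#> $speed
#> [1] 0.4824326
#> $confidence
#> [1] 209.1589
```

which recovers the injected 0.5 µm/s within ~4%.

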