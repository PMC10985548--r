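---
title: "Quantifying cortical travelling waves: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical travelling waves: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexwave)
```

## The problem

Mast-cell-like (RBL) cells stimulated through their antigen receptor develop
cortical travelling waves: bands of actin polymerization and of the proteins
that nucleate it sweep across the ventral cortex with a temporal period of
roughly 10–40 s, visible by TIRF microscopy as propagating intensity fronts.
The scientific questions this package serves are quantitative: *is* a given
cell oscillating (and not just fluctuating), at what period, how fast do the
waves travel, by how many seconds does one protein's recruitment lead or lag
another's, is a second structure (microtubules) in anti-phase with the wave,
does photoconverted material move with the wave or stay put, and how fast
does a bleached protein pool exchange. Each question maps to one module of
the package, and every estimator is validated against a synthetic-movie
generator whose ground truth is known exactly.

## The synthetic wave model

The generator is phenomenological — it reproduces the statistical structure
of the recordings, not the reaction–diffusion mechanism that creates waves.
Each channel $c$ of a movie is rendered as

$$I_c(x, t) = B_c + A_c\, w\!\left(\frac{t - \delta_c - d(x)/v}{T}\right)
  + \varepsilon(x,t),$$

where $d(x)$ is the distance from a point source (circular waves) or the
signed coordinate along a propagation direction (planar waves), $T$ the
period, $v$ the speed, and $\delta_c$ a per-channel time offset (negative =
earlier). The waveform $w$ is a periodic piecewise-linear pulse in $[0,1]$:
a linear rise over a fraction $r$ (`rise_fraction`) of the cycle into the
peak, then a linear fall over $1-r$. With $r > 0.5$ this gives the
gentle-rise/sharp-fall shape characteristic of slow cortical assembly and
fast disassembly. The pulse is anchored so its **peak sits at phase zero**;
this makes `phase_offset` the peak-time lag of a channel regardless of its
`rise_fraction`, so channels of different waveform shape remain directly
comparable. Anti-phase ("tubulin-like") channels render $B + A(1-w)$:
intensity dips where the wave passes. Noise is Gaussian read noise of
standard deviation `noise_sigma`, optionally preceded by Poisson shot noise
on the noiseless signal.

Defaults are anchored to the acquisition regime of the recordings the
package targets: 5 Hz frame rate (0.2 s interval), 0.16 µm pixels (a 16 µm
camera pixel behind a 100× objective), $T = 20$ s, 128×128 px, 600 frames,
baseline 200 AU, amplitude 100 AU, noise 20 AU (ROI-level amplitude/noise
of 5 before spatial averaging). The propagation speed is **not** a measured
quantity — published kymographs show sloped stripes but no number — so the
default $v = 0.5$ µm/s is a plausible choice (wavelength $vT = 10$ µm,
a few waves per cell) and is treated as a free parameter everywhere.
Period jitter across cells is likewise not calibrated against any published
frequency distribution; the generator holds $T$ fixed within a movie.

Two event types are rendered on top of the wave field. A *photoconversion*
event adds a separate `"converted"` channel containing a Gaussian spot
(σ = 2 px) whose centre either stays fixed (`"stationary"`, the de novo
nucleation scenario) or moves along the local propagation direction at the
wave speed (`"advected"`). The spot's brightness is modulated by
$(1 + w)/2$ rather than $w$ itself so the punctum never vanishes within a
cycle — converted fluorophores remain visible — which keeps centroid
tracking well-posed. A *FRAP* event multiplies a box region by
$(1-\beta) + \beta M (1 - e^{-k(t-t_b)})$ after the bleach time $t_b$:
a fraction $\beta$ (`bleach_depth`) of the signal is removed and the
*bleached population* recovers toward its mobile fraction $M$ at rate $k$.
Defining recovery on the bleached population (rather than on the total
pre-bleach envelope) makes the fitted $M$ equal the injected $M$ for any
bleach depth.

## Trace preprocessing and the wave criterion

Intensity traces are means over a 20×20 px region of interest, the
conventional ROI size for this kind of data. `detrend_normalize()` removes
a centred moving average (default window 80 s, twice the longest period of
interest; partial windows at the trace edges) and divides by the robust
scale MAD × 1.4826 of the residual. Calling is therefore invariant to
affine gain/offset changes of the raw signal. A zero-variance trace returns
zeros with a flag, not an error.

`periodogram()` computes the one-sided FFT power of the mean-removed,
Hann-tapered trace; with the identity taper the scaling satisfies Parseval
exactly, which the tests verify against a brute-force $O(N^2)$ DFT.
`classify_wave()` then applies the single-distinct-peak criterion inside
the period band (0.8–40 s at 5 Hz; the lower edge is $4\times$ the frame
interval, since a literal 0 s period has no physical meaning):

* **distinct** — the maximal in-band power exceeds `peak_ratio_min` × the
  median in-band power;
* **single** — no other in-band local maximum rises above half the main
  peak's excess over the median.

The criterion is deliberately conjunctive (single *and* distinct); a
harmonically rich but genuine oscillation with a strong second harmonic can
therefore be rejected, which is the intended strictness of the published
wording it implements. `peak_ratio_min` defaults to 15. The value was
calibrated on the null model this package states for "no wave": across 400
white-noise traces of 600 samples at 5 Hz, a threshold of 15 leaves a
false-positive rate near 1%, while genuine waves at amplitude/noise ≥ 5
show peak ratios of order $10^5$, so detection is insensitive to the exact
value over a wide range. (A threshold as low as 5× sits *below* the typical
in-band maximum of pure noise — about 7× the median for ~150 in-band bins —
and would leave the single-peak clause as the only filter, at a ~5–6% null
false-positive rate.)

Polarity separates positive waves (pulses above baseline) from negative
waves (dips below baseline); by the reporting convention implemented in
`wave_fraction()`, negative waves are counted with the non-waves, since
dips can reflect membrane detachment rather than travelling waves. Polarity
is scored by the skewness of the detrended trace — a proxy, documented as
such: pulse-up waveforms skew positive, dip-down waveforms negative. The
piecewise-linear waveform itself has a *uniform* amplitude distribution and
hence zero skewness, so the sign would be decided by noise; for that reason
`"negative"` requires skewness below −0.1 and borderline traces default to
`"positive"`.

## Lags, profiles, and what each method measures

`cross_correlation()` scans integer frame shifts within
±`search_halfwidth` (default 0.6 × the dominant period, preventing
period-aliased picks), computes the overlap-restricted Pearson correlation
at each shift — no zero padding, so edges contribute no bias — and refines
the maximum below frame resolution with a three-point parabola. The
convention is probe(t) ≈ reference(t − lag): **negative lag = probe peaks
earlier**.

`detect_cycles()` finds reference peaks by topographic prominence with a
minimum separation of half the dominant period, then refines each peak time
by an iterated local least-squares quadratic (window ±T/8, re-centred on
the current vertex). The refinement matters: ROI averaging across a
travelling wave flattens peaks, and on a flat peak the discrete argmax
wanders by several frames under even mild noise. `average_profile()`
aligns probe windows on these (fractional) peak times by linear
interpolation and reports the mean ± SD across cycles; `profile_lag()`
takes the profile maximum, again via a local quadratic fit rather than a
3-point parabola, because the averaged peak is broad.

The two lag estimators agree to within one frame when probe and reference
share a waveform — the regime in which lag recovery is validated
(mean absolute error ≤ 0.2 s, bias ≤ 0.1 s over offsets −4…+1 s at 5 Hz).
When waveform shapes differ they measure *different things*, and both
behaviours are characterised in the tests by closed forms:

* spatial ROI averaging acts on the trace as a temporal boxcar of
  half-width $h = \ell/(2v)$ ($\ell$ = ROI extent along propagation;
  3.2 s at defaults), which shifts the apparent peak of an asymmetric
  waveform by $h(1 - 2r)$ — so profile lags between channels of different
  rise fraction gain $2h(r_\mathrm{ref} - r_\mathrm{probe})$;
* cross-correlation aligns waveform *bulk*, and between two pulses of rise
  fractions $r_1, r_2$ its maximum sits at
  $(r_\mathrm{ref} - r_\mathrm{probe})\,T/2$ from the peak lag.

Neither method is privileged; the package reports both per cell, and
population summaries are means ± SEM across cells, matching the
"(mean ± SEM, n cells)" convention of the field.

`asymmetry_index()` reports rise/fall duration of the average cycle. The
profile window is treated as one full period *cyclically* — rise =
(peak time − trough time) mod window — because with a window of at most one
period the preceding trough of a strongly asymmetric waveform (e.g. rising
over 75% of the cycle) lies outside the window on the linear time axis.
A sawtooth with $r = 0.75$ scores 3; symmetric waveforms score 1.

`anti_phase_score()` reports the zero-lag Pearson correlation between two
wave-positive traces of matching period (within 20%) and the
cross-correlation |lag| as a fraction of the period, folded into 0–0.5.
The pair is flagged anti-phase when the correlation is below −0.5 and the
fraction exceeds 0.35 — the signature of microtubule density dipping half a
period out of step with the actin wave.

## Kymographs and wave speed

`make_kymograph()` reslices the movie along a straight line at unit-pixel
steps with bilinear interpolation, averaging over symmetric perpendicular
offsets when `averaging_width > 1`. Only straight lines are supported;
curved wavefront paths are future work, not approximated.

`estimate_wave_speed()` finds the dominant stripe slope by shear
projection: for each of 180 candidate orientations the kymograph is
averaged along lines of that slope and the variance of the projected
profile computed; the true slope maximizes this variance. Projection
variances are normalized by the noise scaling of their unequal averaging
counts, so incoherent noise yields a flat orientation response, and the
maximum is refined by a quadratic vertex fitted in *slope* space (the
orientation grid is uniform in angle, hence non-uniform in slope). A flat
response (sharpness below 1) or a best slope indistinguishable from zero
(a static pattern) returns `"undetermined"` rather than a number. Accurate
estimates need the line to span at least two spatial wavelengths
($2vT$; 40 µm at defaults) — with that geometry, recovered speeds are
within ~7% of truth across 0.2–1.0 µm/s, versus a systematic low bias once
less than one wavelength fits on the line.

`time_projection()` is display-only: three frames at equal spacing become
the R, G and B planes, each stretched between its 1st and 99th intensity
percentiles (fixed so that regression hashes are stable); a static scene
is gray, a travelling wave shows spatially shifted coloured bands.

## Photoconversion, FRAP, and tracks

`track_punctum()` follows the converted spot with an intensity-weighted
centroid in a window of radius 4 px re-centred each frame, after
subtracting the window median. `punctum_displacement_test()` then
classifies: *stationary* if total displacement < max(2 px, 10% of
$v \cdot$ duration), *advected* if the displacement projected on the wave
direction exceeds 50% of $v \cdot$ duration, otherwise *ambiguous*. The
classifier is exact on noiseless renders and ≥95% correct at spot
amplitude/noise 3.

`frap_recovery()` maps the pre-bleach mean to 1 and the first post-bleach
frame to 0, then fits $M(1 - e^{-kt})$ by Levenberg–Marquardt least squares
with $M \in [0, 1.5]$ and $k$ bounded above at 5 per frame interval
(faster recoveries are unresolvable and flagged `rate_at_bound`). If the
exponential fit fails — essentially flat recoveries — the plateau estimate
is reported as the mobile fraction with flag `no_fit`. No reference-region
photofading correction is applied (none is available for the single-ROI
curves this targets); over ~2 minute FRAP windows that is a documented
limitation rather than a correction done silently. The source recordings
report recovery curves without fitted parameters; the exponential fit here
is an added quantification and is labelled as such in outputs.

`track_velocity()` is the mean step speed in µm/min (net displacement over
total time is attached as an attribute); mean step speed is the primary
statistic because manual-tracking conventions differ and the mean-step
reading is the more common one. `simulate_track()` provides a
persistent-random-walk oracle: exact step length, heading random walk with
standard deviation $(1-p)\pi$ per step.

## Population statistics

`wave_fraction()` computes per-experiment fractions of wave-positive cells
(positive polarity only, per the grouping convention above) and reports
mean ± SEM **across experiments**. Published percentages of this kind are
inconsistent with a binomial per-cell error but consistent with
across-replicate SD, so the binomial SEM is only a secondary field; a
single experiment reports SEM as undefined, never 0. `compare_two()` is
the classical equal-variance two-sided t-test; `anova_sidak()` runs a
one-way ANOVA followed by pairwise t-tests for the *requested* comparisons
only, Šidák-adjusted over those $m$ comparisons:
$p_\mathrm{adj} = 1 - (1-p)^m$. The pairwise statistic family inside the
post hoc step is not dictated by the conventions this mirrors; the plain
unpaired t is used and documented. Whether published group comparisons
were run on per-cell or per-experiment units is ambiguous;
`summarize_wave_fractions()` uses per-experiment fractions as the default
unit and exposes the per-cell values for anyone who prefers otherwise.

## Validation strategy and problem sizes

Every estimator is tested three ways: against hand-computable constructions
(constant fields, exact shifts, closed-form chord lengths, Šidák algebra),
against independent brute-force oracles (an $O(N^2)$ DFT, an explicit
shift-sum correlation), and against simulator ground truth under the study
conditions — $T = 20$ s, 5 Hz, 20×20 px ROI, amplitude/noise 5 for traces
and 3 for puncta. The test and acceptance runs use 600-frame traces on
24×24 px grids for lag work (spatial rendering is only needed under the
ROI), 64×64 px × 60-frame movies for punctum classification, and
16×260 px × 150-frame movies for kymograph speed (260 px ≈ two wavelengths
at $v = 1$ µm/s); these sizes give each estimator several cycles,
wavelengths, or recovery half-times to work with while keeping a full run
in tens of seconds.

What passing does *not* show: the generator has no point-spread function or
optical blur beyond the punctum's Gaussian, no photobleaching drift, no
curved or colliding wavefronts, no cell boundary, and no period jitter
within a movie. Real recordings have all of these, so simulator-validated
precision (e.g. sub-frame lag recovery) is an upper bound on what the same
pipeline achieves on microscope data, not a guarantee.
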