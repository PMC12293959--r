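---
title: "Nonlinear dynamics of beta-band MEG/EMG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear dynamics of beta-band MEG/EMG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Sensorimotor beta oscillations (13–30 Hz) are not a steady rhythm: during
sustained isometric contraction they come in transient bursts of a few
cycles separated by quieter periods, in both cortical (MEG) and muscular
(EMG) recordings. Burstiness of this kind is characteristic of complex,
possibly nonlinear dynamics, yet brain–muscle coupling is almost always
quantified with linear tools (coherence, envelope correlation). `betadyn`
implements a complete windowed nonlinear-dynamics pipeline for paired
single-channel beta-band MEG/EMG recordings:

1. zero-phase band-pass filtering and segmentation into fixed windows;
2. per-window phase-space reconstruction and three nonlinear features —
   largest Lyapunov exponent (LE), Higuchi fractal dimension (FD), and
   Grassberger–Procaccia correlation dimension (CD);
3. envelope burstiness (CV of the slow-normalized Hilbert envelope) and
   cross-modal envelope correlation;
4. phase-randomized surrogate testing of nonlinearity;
5. the group statistics layer (paired and one-sample *t* tests, Cohen's
   *d*, exact noncentral-*t* post hoc power, across-subject Pearson
   correlations, per-subject stability summaries).

Because suitable MEG/EMG recordings are not freely downloadable, the
package ships a first-class synthetic-data module that generates (a)
canonical dynamical systems whose invariants are known independently and
(b) paired pseudo-MEG/EMG beta-band cohorts with planted burstiness and a
controllable shared envelope component. Every estimator is validated
against those ground truths in the test suite.

# Preprocessing

**Band-pass filter.** A zero-phase FFT-based cosine filter: the spectrum
is multiplied by a real gain that is 1 inside 13–30 Hz and rolls off with
raised-cosine flanks of width 2 Hz centred on each edge (gain exactly 0.5
at 13 and 30 Hz). A purely real, symmetric gain leaves phases untouched,
so there is no group delay by construction. Before the FFT the record is
reflection-padded by 1 s at each end and zero-padded to the next 5-smooth
length; this suppresses circular wrap-around at a cost that is confined to
edge regions which downstream statistics trim. The flank width default
(2 Hz) keeps the full 13–30 Hz passband intact while still reaching ~60 dB
rejection within 1 Hz outside each flank at 10 s record lengths.

**Segmentation.** Filtering is applied once to the full recording and only
then cut into contiguous, non-overlapping 10 s windows (trailing remainder
discarded). Filtering per window would re-introduce edge artifacts into
every window; filtering first makes the windows exact slices of one
stationary filtered record.

# Phase-space reconstruction

Each window is delay-embedded with parameters estimated per window:

* **Delay** τ: first strict local minimum of the average mutual
  information (AMI), computed with equal-width 16-bin histograms over lags
  0–100 samples. Fixed binning keeps the estimate fully deterministic.
  The minimum is detected on a centred 3-point moving average of the
  curve: histogram AMI carries small lag-to-lag quantization wiggles that
  otherwise fire spuriously early "minima", while genuine minima are broad
  and survive smoothing. Narrowband signals may lack a local minimum
  altogether; the fallback is the first lag where AMI drops below
  AMI(0)/e, and as a last resort the largest lag (with a warning).
* **Dimension** m: Kennel's false-nearest-neighbours test with the
  canonical tolerances (distance-ratio 15, attractor-size 2), Theiler
  exclusion τ, threshold 1%: the smallest m whose false fraction falls to
  or below 1%. For stochastic signals the fraction may never fall below
  threshold; the estimator then returns `m_max` with a warning — the
  honest answer for noise, which fills every embedding dimension.

A caveat worth knowing: for *noiseless* deterministic signals (an exactly
periodic sampled sinusoid, say) both AMI and FNN are degenerate — the
lagged dependence is deterministic at every lag, and exact sample
periodicity makes nearest-neighbour distances pure rounding noise. Real
recordings and the synthetic cohorts always carry noise, which is the
regime these estimators are defined for.

# The three features

**Lyapunov exponent (Rosenstein).** For each trajectory point (an evenly
strided subsample of up to 1000 reference points), the nearest neighbour
outside a Theiler window is found, and the mean log-distance between pairs
is tracked over forward steps. The Theiler window and the tracking span
both default to one *mean period* — the sampling rate divided by the
power-weighted mean frequency of the window, Rosenstein's own
recommendation. The exponent is the least-squares slope of the divergence
curve over its *linear region* — the contiguous span covering at least
half the curve that maximizes the fit R² — times the sampling rate
(units 1/s). The region selection matters: the first few steps of the
curve reflect the geometry of neighbour alignment rather than exponential
divergence, and a fixed full-span fit overestimates the Lorenz exponent by
~30%, while the region fit lands within 2% of the Benettin tangent-space
value. A low fit R² (reported in the diagnostics) flags the absence of a
genuine exponential-divergence regime, as happens for noise.

**Higuchi fractal dimension.** Higuchi's curve-length construction on the
scalar window: normalized curve lengths L(k) averaged over all k offsets
for k = 1..16, FD = slope of log L(k) against log(1/k). k_max = 16 sits
in the standard stability plateau for 10^4-sample windows. FD is 1 for a
smooth curve, 2 for plane-filling noise; the estimator warns outside
[1, 2]. On exact-covariance fractional Brownian motion the estimator
reproduces the theoretical FD = 2 − H to within 0.003 at n = 10^4.

**Correlation dimension (Grassberger–Procaccia).** The correlation sum
C(r) — the fraction of Theiler-admissible point pairs closer than r — is
evaluated on 24 log-spaced radii between the 0.1th and 50th percentile of
pairwise distances, using an evenly strided subsample of at most 2000
trajectory points (striding preserves attractor geometry while bounding
the O(N²) pair count; 10 s at 1 kHz would otherwise mean 5×10^7 pairs per
window). Radii in the saturation zone (C(r) > 0.2) are excluded, and CD is
the slope of log C over the contiguous span of at least a third of the
remaining radii maximizing the fit R². Both refinements are measured
necessities: on the Lorenz attractor a radius floor at the 1st percentile
never reaches the scaling regime (slope ≈ 1.85 vs. the true ≈ 2.05), and
without the saturation cutoff the max-R² rule happily picks a smooth but
bent large-radius span. With them, the embedded-scalar estimate lands
within 0.08 of a brute-force correlation-sum oracle evaluated on the full
3-D state.

LE and CD share one embedding per window; FD is defined on the scalar
series directly. Windows where an estimator fails (e.g. constant signal)
are excluded with a logged reason rather than emitting NaN.

# Envelope burstiness and cross-modal similarity

The analytic envelope (FFT Hilbert transform) of the band-passed record is
divided by a zero-phase low-passed copy of itself (cutoff 0.1 Hz, 0.05 Hz
flank — the same cosine-filter machinery), isolating relative amplitude
fluctuations: a ×2 linear gain drift over the record changes the result by
almost nothing, because the drift lives below the cutoff. Burstiness is
the coefficient of variation (SD/mean) of this normalized envelope over
the full task recording, one value per subject and modality; 0.5 s edge
regions are trimmed first (Hilbert edge artifacts). For unmodulated
narrowband Gaussian noise the envelope is Rayleigh and the CV has the
closed-form value √(4/π − 1) ≈ 0.523, which the pipeline reproduces and
the tests assert. Cross-modal similarity is the Pearson correlation of the
two normalized envelopes over the edge-trimmed record.

# Surrogates

Phase-randomized surrogates keep the discrete-Fourier amplitude spectrum
exactly (DC and Nyquist bins keep their original values; positive
frequency phases are iid uniform, negative frequencies conjugate-mirrored)
and therefore destroy only phase structure — a linear-Gaussian null.
Surrogates are generated from the raw full-length recording and pushed
through the *identical* preprocessing and feature pipeline; per subject
the reduction is mean over windows, then mean over the (default 100)
realizations. A paired *t* test across subjects compares original versus
mean-surrogate values. On AR(2) linear-Gaussian cohorts this test is
calibrated: over 200 simulated 17-subject cohorts the measured rejection
rate is 0.050 (the test suite asserts the 95% binomial band around the
nominal 0.05).

# Statistics

All tests are two-sided at α = 0.05, with no multiple-testing correction
(a Holm option exists nowhere because raw p-values are reported and
labelled as such). Cohen's *d* for paired designs is mean(Δ)/SD(Δ), so
|t| = |d|√n holds identically. Post hoc power uses the exact noncentral
*t* distribution (noncentrality |d|√n, df n − 1), not a normal
approximation: at n = 17 this reproduces power 0.32 for d = 0.39, ≥ 0.99
for d = 1.98 and 1.00 (2 d.p.) for d = 4.22. Stability over time is
summarized per subject as the SD of each feature across windows, compared
between modalities with a paired *t* test across subjects.

# The synthetic cohort

`gen_bursty_beta()` builds each channel as
e(t)·c(t) + σ_noise·w(t), where c(t) is unit-variance Gaussian noise
band-passed to 13–30 Hz (channels independent), and the envelope
e(t) = 1 + Σᵢ aᵢ g(t − tᵢ; FWHM) superposes Gaussian bursts at Poisson
times with Gamma(2, scale) amplitudes. Each channel mixes an independent
and a shared envelope: e_ch = (1 − ρ)·e_indep + ρ·e_shared, so ρ plants
the cross-modal envelope correlation. Defaults: burst rate 1/s, FWHM
150 ms (a few beta cycles, matching reported burst durations), amplitude
scale 1.5 (strong enough that planted modulation dominates the intrinsic
Rayleigh envelope fluctuation of the carrier), shared fraction 0.3 (group
mean envelope r in the 0.1–0.2 range typical of MEG–EMG pairs), noise SD
0.05. The demo cohort draws per-subject burst rates U(0.8, 1.6) and
amplitude scales U(1, 2) for realistic heterogeneity. Burst rates and
durations are literature-motivated parameters, not fitted constants.

What the generator does *not* emulate: volume conduction, sensor arrays,
motor-unit action potential shapes, 1/f background, nonstationary task
drift. Passing tests therefore demonstrate estimator correctness and
pipeline calibration, not that real MEG/EMG will show any particular
effect.

All randomness descends from one master seed through a counter-based
child-seed scheme (`child_seed()`), so paired channels, subjects and
surrogate realizations have independent streams while the entire study is
reproducible bit-for-bit — the test suite asserts byte-identical pipeline
outputs across repeated runs.

# Problem sizes and numerical choices

The validation suite runs at deliberately chosen reduced sizes: Lorenz
oracles at 20 000 samples (dt = 0.01, 10-time-unit transient); fBm at
10 000 samples; the type-I-error simulation at 200 cohorts × 17 subjects
of 8 s AR(2) records (fs 500, 4 s windows, Higuchi FD, 12 surrogates);
envelope-recovery runs at 40–60 s per record (fs 500, 20 seeds per
condition); the determinism run at 4 subjects × 60 s (fs 250). These sizes
keep every Monte-Carlo band comfortably resolvable while the full suite
stays quick; all are configuration parameters, and the full-scale study
configuration (17 subjects × 600 s at 1 kHz, 100 surrogates) is the
package default in `run_config()`.

Other numerical conventions: ties in nearest-neighbour searches resolve to
the lowest index; the CD subsample is evenly strided (deterministic);
divergence-curve points with zero distance are dropped from the log mean;
constant windows raise errors that the table builder converts into logged
exclusions; TSV outputs are written with R's default 15-significant-digit
formatting, which round-trips the doubles produced here stably enough for
byte-identical reruns.

# Known limitations

* LE/CD assume low-noise deterministic structure; on strongly stochastic
  signals FNN saturates at `m_max` and the features describe the noise
  floor rather than an attractor. Diagnostics (fit R², FNN warnings) make
  this visible, but interpretation is on the user.
* The correlation-dimension subsample cap (2000 points) limits the
  smallest resolvable radii; dimensions above ~4 will be biased low at
  these window lengths.
* Surrogate exchangeability is exact for circular Gaussian processes;
  spectral leakage for strongly non-circular records can shift the
  original-vs-surrogate comparison slightly (measured nominal at these
  settings).
* The pipeline takes one pre-selected channel per modality; sensor
  selection (e.g. by corticomuscular coherence) is upstream and out of
  scope, as are tSSS/ICA cleaning and native MEG file formats.
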