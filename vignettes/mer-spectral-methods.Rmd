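---
title: "Methods: envelope spectral features of pallidal microelectrode recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: envelope spectral features of pallidal microelectrode recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gpimer)
```

## The problem

Intraoperative microelectrode recordings (MER) along globus pallidus
internus (GPi) trajectories carry a low-frequency (4--12 Hz) signature that
is consistently elevated in dystonia and is a candidate feedback signal for
adaptive deep brain stimulation. `gpimer` implements the analysis chain
needed to ask whether that signature differs across genetic etiologies of
dystonia: per-recording stable-epoch detection, rectified-envelope spectral
features, GPi depth normalization, and a group-comparison /
correlation / mixed-model statistics battery, together with a synthetic
cohort generator so every stage is testable without patient data.

## Signal model and processing chain

A raw MER trace `x` at sampling rate `fs` (tens of kHz) is treated as
broadband multi-unit activity whose *amplitude envelope* carries the
oscillatory structure of interest. The chain per recording:

1. **Stability.** `x` is cut into non-overlapping 50 ms segments; segment
   RMS values are computed, and a segment is *stable* when its RMS lies
   within 3 standard deviations of the median RMS. The longest run of
   consecutive stable segments is kept. The SD is the sample SD of the full
   RMS sequence in a single pass (no iterative re-estimation): one labeling
   pass is what the procedure defines, and the RMS median makes the center
   robust. A consequence worth knowing: a very large artifact inflates the
   single-pass SD, so a *borderline* outlier segment elsewhere can fall
   back inside the threshold. The monotonicity property ("adding an
   artifact never lengthens the stable epoch") is therefore guaranteed only
   for bases whose mask is fully stable, and the test suite states it that
   way.
2. **Envelope.** The stable span is full-wave rectified and demeaned:
   `e = |x| - mean(|x|)`. Full-wave rectification is the standard
   multi-unit envelope estimator; the mean subtraction removes the DC term
   so the low-frequency modulation is exposed.
3. **Decimation.** The envelope is low-passed (zero-phase order-4
   Butterworth at 80% of the target Nyquist) and decimated to ~1 kHz. The
   analysis range tops out at 200 Hz, so nothing of interest is lost and
   all later filtering happens at a numerically comfortable rate.
4. **Spectrum.** Welch PSD with Hamming-windowed 3 s segments and 50%
   overlap. The 3 s window fixes the frequency spacing at exactly 1/3 Hz;
   window shape and overlap are conventional choices (they are not pinned
   down by the resolution requirement). The PSD restricted to 2--200 Hz is
   rescaled to unit integral, removing between-patient RMS differences.
5. **Features.** Band power fractions for theta (4--8), alpha (8--12),
   beta (12--30) and gamma (30--100 Hz) are computed in the *filter
   domain*: variance of the zero-phase four-pole Butterworth band-pass
   output divided by the variance of the 2--200 Hz band-pass output
   ("four-pole" is read as design order 4; zero-phase
   forward--backward filtering avoids band-dependent group delay).
   Ratios alpha/theta, beta/theta, beta/alpha are quotients of fractions.
   Baseline elevation per band is the mean normalized-PSD bin power in the
   band divided by the median bin power over 2--100 Hz.

### Numerical choices

* **Filters as second-order sections.** The theta band at a 1 kHz envelope
  rate sits at normalized frequency 0.004--0.008, where an order-8
  band-pass polynomial is numerically fragile; all filters are designed and
  applied as biquad cascades (a small C++ kernel does the filtering).
* **Edge transients.** A band-pass transient decays with time constant
  roughly `1/(pi * bandwidth)`; three time constants are trimmed from each
  end before taking variances, capped at 10% of the signal per end so a
  3 s epoch keeps support.
* **Fraction route.** Whether the original fractions came from filtered
  variance or PSD integration is ambiguous; both are implemented
  (`band_power_fraction()` and `band_fraction_psd()`), filter-domain is the
  default, and a cross-method test bounds their disagreement at 20% on
  stationary inputs.
* **Band bin conventions.** PSD band integration uses half-open bins
  `[lo, hi)` so adjacent bands stay disjoint; the 100--200 Hz remainder
  contributes to the normalization denominator only.
* **Minimum epoch.** Stable epochs shorter than one PSD window (3 s) are
  excluded (`too_short`): 1/3 Hz resolution is unattainable on less data.
* **SD denominator.** Sample SD (n-1) by default; `label_stable()` exposes
  `population_sd` because the original convention is unstated.

## Depth handling

Recording depths are mapped affinely so GPi entry is 0 and exit is 1;
recordings outside `[entry, exit]` keep their out-of-range value, stay in
group-level feature statistics, and are dropped from depth correlation and
mixed-model analyses (those concern the region between the borders).
Trajectories enter analysis only with a GPi span of at least 2 mm and at
least four distinct in-GPi depths, both bounds inclusive ("minimum" and
"at least" read inclusively); distinctness is judged after rounding to
0.01 mm.

## Statistics

* **Group comparisons.** Kruskal--Wallis per feature (tie-corrected H,
  chi-square reference), Holm--Bonferroni across the seven-feature family
  (four fractions, three ratios), Dunn's post hoc z-tests with the
  standard tie-corrected SE and Holm correction across pairs. The unit of
  analysis defaults to individual stable epochs pooled per group (the
  design that gives the large epoch counts); `pooling = "patient_median"`
  switches to per-patient medians.
* **Correlations.** Spearman rho with a two-sided permutation test:
  exhaustive enumeration when `n! <= n_perm` (p = exceedances / n!),
  otherwise seeded Monte Carlo with the add-one estimator
  `(1 + exceed) / (1 + n_perm)` so p is never zero.
  Benjamini--Hochberg FDR within each correlation family
  (feature x clinical matrix; depth x feature heatmap). Clinical
  correlations use per-patient feature medians against baseline motor
  BFMDRS and its percent change `100 (pre - post) / pre` (improvement
  positive; the sign convention was left open and is fixed here).
* **Mixed models.** Per feature, `feature ~ 1 + normalized_depth` with
  crossed random intercepts for genetic group and for patient (lme4),
  Wald z on the depth slope, Holm across the family. Random slopes are
  omitted (no slope language in the procedure being mirrored); singular
  fits are reported with `converged = FALSE` and the slope still returned.

## The synthetic cohort generator

`generate_recording_signal()` builds broadband Gaussian noise with a
gentle high-frequency roll-off (amplitude `1/sqrt(1 + f/300)`, a mild
nod to real MER spectra), multiplies it by
`1 + sum_b m_b sin(2 pi f_b t + phi_b)` with one modulation frequency per
band drawn uniformly inside the band, and optionally adds Poisson
transient bursts (100--300 ms, amplitude a programmed multiple of the
background RMS). `generate_cohort()` expands that to a cohort with the
target study's scale as defaults: 30 patients split
2/2/2/4/8/3/9 over GNAL, KMT2B, SGCE, THAP1, TOR1A, VPS16 and idiopathic
(the composition of the published demographic table), 70 trajectories,
597 recordings, 24 kHz, 10 s. Default modulation depths are
theta 0.30 / alpha 0.25 / beta 0.20 / gamma 0.15 for every group, with
the SGCE group's theta and alpha *halved* and the VPS16 group given extra
gamma (0.30) and a beta depth gradient (+0.10 per unit normalized
depth) — the qualitative contrast structure reported for the real cohort.
Clinical scores draw baseline severity uniformly over the observed range
(11.5--60.5), improvement fraction from Beta(2, 2), and couple to
features with coefficient 0 by default (no significant coupling was
observed). GPi spans draw from U(3, 6) mm; recording depths run from
0.5 mm above entry to 0.5 mm below exit, so a minority of recordings sit
outside the borders, as in surgical practice.

What the generator does *not* emulate: spike waveforms and bursting
statistics, nonstationary drift, correlated noise across depths, or any
anatomical gradient beyond the programmed linear modulation gradients. A
green end-to-end test therefore establishes that the pipeline recovers
*programmed envelope contrasts of realistic size at realistic counts* —
not that it reproduces patient data. Absolute fraction levels depend
nonlinearly on modulation depth, so the defaults reproduce the reported
*ordering and contrast* between groups rather than the printed medians;
`run_reproduce()` exists precisely to check printed medians against the
openly deposited feature tables when a local copy is supplied.

## Scale choices in the test suite

The acceptance-style tests run a reduced-scale recovery design (2 kHz,
6 s recordings, 7 patients / 14 trajectories / 84 recordings per seed,
50 seeds) instead of the full 24 kHz default cohort, to keep the suite
within its runtime budget; group structure, modulation contrast and the
analysis chain are unchanged. The artifact-exclusion check erodes each
artifact interval by one 50 ms segment per side before testing overlap:
a segment that overlaps an artifact by a few samples is legitimately
within threshold, a quantization effect of the segmentation rather than
a detection failure.

## Known limitations

* EDF support is a minimal, continuous, single-session reader/writer
  (16-bit), sufficient for exported MER segments; EDF+ annotations are
  ignored.
* `estimate_psd()` requires `window_s * fs` to be an integer; envelopes at
  awkward rates should be decimated first (the pipeline's decimation
  produces 1 kHz from typical acquisition rates).
* The reproduction mode ships a column-mapping layer because the deposit's
  exact schema is only known at run time; it never downloads anything.
* No anteroposterior/mediolateral spatial modelling: depth along the
  trajectory is the only spatial axis.
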