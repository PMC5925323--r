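---
title: "Dynamic BOLD-CBF coupling from dual-echo pCASL: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic BOLD-CBF coupling from dual-echo pCASL: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldcbf)
```

## The measurement and the question

A dual-echo pseudo-continuous arterial spin labeling (pCASL) sequence
acquires, in a single resting-state run, two images per excitation: a short
echo (TE1, ~10 ms) whose control-minus-label difference is dominated by
perfusion, and a long echo (TE2, ~28 ms) dominated by the BOLD effect.
Control and label volumes alternate at the repetition time TR, so the
perfusion information rides on a carrier at the Nyquist frequency of the
volume sampling while the BOLD-weighted signal varies slowly.

`boldcbf` quantifies the *dynamic coupling* between the spontaneous
fluctuations of the two signals: the voxelwise Pearson correlation at zero
lag (`r0`), the maximum correlation over a grid of temporal shifts
(`rmax`), and the optimizing shift (`tau_star`). A reduced `r0` combined
with a large gain `rmax - r0` indicates a temporal mismatch between BOLD
and CBF dynamics — of interest, for example, when comparing young and older
adults, where stiffer vessels and delayed venous compliance can desynchronize
the two signals without abolishing the underlying coupling.

## Signal separation

The separation follows the high-pass/demodulation recipe for interleaved
ASL timeseries:

* **CBF series** (from TE1): high-pass the interleaved series above
  `1/(4 TR)` (`separation_cutoff()`, 0.0714 Hz at TR 3.5 s, conventionally
  printed as 0.071 Hz), multiply frame *n* (1-based) by `cos(pi (n - 1))`,
  and sum non-overlapping pairs. With the control volume first the output
  approximates control minus label, positive for positive perfusion.
* **BOLD series** (from TE2): low-pass below `1/(4 TR)` and average
  non-overlapping pairs.

Both outputs have `n_volumes / 2` frames at sampling interval `2 TR` and
are then band-pass filtered (0.01–0.071 Hz by default) and optionally
smoothed (6 mm FWHM Gaussian).

Choices the recipe leaves open, and how this package resolves them:

* **Filter realization.** Filters are zero-phase frequency-domain masks
  with a one-bin raised-cosine transition (`bandpass()`): no group delay,
  cutoffs exactly where specified, stopband attenuated to numerical zero
  beyond the transition bin. The first and last separated frames carry the
  largest residual edge effects; property checks in the test suite
  therefore assess interior frames, but the frames are retained in the
  output.
* **Pair summation scale.** The pairwise "sum" is kept as the raw sum for
  the CBF series (so the output equals control − label) and as the pair
  *mean* for BOLD (so BOLD stays in signal units). Correlations are
  scale-invariant, so this choice only affects units, and it is fixed and
  documented here.
* **Demodulation indexing.** `cos(pi (n - 1))` uses 1-based frame numbers:
  frame 1 keeps sign +1, so with a control volume first the demodulated
  series is positive for positive perfusion. `separate_cbf()` flips the
  sign for label-first runs via `control_first = FALSE`.

Physiological noise is removed before separation with a RETROICOR-style
regression (`retroicor_regress()`): sine/cosine terms of the instantaneous
cardiac and respiratory phases up to order 2 (the common convention; the
order is an argument), fitted per voxel and per tag class (label and
control separately), with regressors centered so the voxel mean is
preserved. Phases are assigned per volume at the slice-mean acquisition
time — slice-timing correction is out of scope, so slice-level phase
assignment would suggest a precision the pipeline does not have. Arbitrary
caller-supplied confounds (motion parameters, tissue regressors) go through
`nuisance_regress()`, which uses an SVD pseudo-inverse so rank-deficient
designs are handled gracefully.

## Lagged coupling

`lagged_rmax()` evaluates, for each lag tau on a symmetric grid (default
±7 s in 0.35 s steps), the Pearson correlation between BOLD advanced by tau
and CBF over their truncated overlap — no zero padding and no circular
wrap-around, which would manufacture spurious edge correlation. Both series
are evaluated on a sinc-upsampled 100 ms grid, following the standard
practice of band-limited upsampling before shift estimation.

Numerical choices:

* **Interpolation.** Band-limited interpolation uses the normalized
  truncated Whittaker sum with a point-symmetric (odd) extension of the
  samples about each end. Normalization preserves constants exactly and
  original samples exactly; the odd extension suppresses the slowly
  decaying truncation ripple, keeping interior interpolation errors of an
  in-band sinusoid below 1% of its amplitude.
* **Exact lags.** A 0.35 s lag step is 3.5 samples on the 100 ms grid, so
  integer index shifting cannot realize the grid. Instead, the interpolant
  is evaluated directly at the shifted times: since sinc evaluation is
  linear in the original samples, the correlation at every lag follows
  exactly from precomputed Gram matrices of the interpolation operators.
  This makes voxelwise lag scans cheap (the kernels are cached per
  geometry) and the lags exact rather than rounded.
* **Zero lag.** At tau = 0 interpolation adds no information, so the
  native-resolution correlation `r0` is used for that grid point. This
  guarantees the invariant `rmax >= r0` at every voxel, which an upsampled
  zero-lag correlation could violate by numerical epsilon.
* **Ties.** Among tied maxima, the smallest `|tau|` wins, and the negative
  lag wins at equal magnitude — the most conservative shift correction.
* **Degenerate voxels.** Zero-variance series give `NA` correlations;
  `NA` voxels are excluded from group tests and do not count toward the
  FDR family. `fisher_z()` clamps `|r| = 1` to `1 - 1e-7` (a noise-free
  synthetic voxel can be exactly 1; infinite z-values would poison group
  means).

Group inference uses Fisher-z transformed maps: voxelwise one-sample t
against zero per group, pooled-variance unpaired two-sample t between
groups (a Welch variant is available behind `var_equal = FALSE`; the
pooled test is the default because the classic unpaired t is the
convention for these comparisons), and Benjamini–Hochberg FDR control at
`alpha = 0.05` within a caller-supplied analysis mask. The ROI-level
summary `rmax_minus_r0_contrast()` compares the lag-optimization gain
`rmax - r0` between groups and reports Cohen's d with the pooled-SD
definition.

## Baseline perfusion

`quantify_cbf()` implements the single-compartment kinetic model for
background-suppressed pCASL:

CBF = 6000 λ (SI_C − SI_L) e^(PLD/T1a) / [2 α α_inv T1a M0 (1 − e^(−τ/T1a))]

with λ = 0.9 ml/g (blood–brain partition coefficient), T1a = 1650 ms
(arterial blood at 3T), α = 0.85 (labeling efficiency), α_inv = 0.83
(background-suppression correction), τ = 1750 ms (label duration), and a
slice-dependent post-label delay. All times are carried in seconds
internally; with T1a in seconds the factor 6000 converts ml/g/s to the
conventional ml/100g/min. The denominator groups all efficiency and
relaxation factors (2 α α_inv T1a M0 (1 − e^(−τ/T1a))) — the consensus
single-compartment form.

The PLD of an ascending 2D readout grows with slice: `slice_pld()` uses a
linear ramp from 1900 ms at slice 1 to 2800 ms at slice 19, i.e. 50 ms per
slice. Only the range is conventionally quoted; the linear ramp across the
19 ascending slices is the natural reading and is configurable via
`quant_params()`. No partial-volume or transit-delay correction is
applied.

## Quality control

* `rsfa()`: per-voxel temporal SD of the band-passed series, *unnormalized*
  — the amplitude carries the input's units. Normalized variants (e.g. by
  the voxel mean) exist in the literature; since group comparisons are on
  like-for-like units the choice is neutral, and the filter band is an
  argument.
* `dvars()`: RMS over mask voxels of the frame-to-frame difference, per
  consecutive pair, plus the run average.
* `motion_exclusion()`: RMS over all six realignment parameters with
  rotations converted to displacement on a 50 mm sphere (a common
  convention; the radius is an argument). Exclusion is *strict*: a subject
  at exactly the 1.5 mm threshold is kept.

## The synthetic generator

Every stage is validated against `ground_truth()` objects carrying exactly
the quantities the pipeline estimates. The forward model
(`assemble_dual_echo_run()`) builds, per voxel and volume,

S_e(v) = M0 (1 + g_e b(t_v)) + (c_v / 2) ΔM_e (1 + f(t_v)) + physio + noise

with `c_v = ±1` the control/label alternation, `f` the band-limited
perfusion fluctuation, `b` the BOLD fluctuation coupled to `f` with the
ground-truth correlation and lag, and `g_e` the echo-dependent BOLD gain
(TE1/TE2 = 10/28 at the short echo — a linear-in-TE approximation, so the
short echo carries little but nonzero BOLD weight). ΔM is obtained by
inverting the kinetic model at each voxel's slice PLD, and is attenuated by
a factor 0.7 at the second echo (T2* decay of the label signal).

Design choices worth knowing:

* **Frequency-domain synthesis.** Band-limited processes are synthesized
  with unit magnitude and random phase on the Fourier bins inside the band
  (`generate_band_limited_process()`), not by filtering white noise: band
  containment is exact and the sample SD equals the requested amplitude
  exactly.
* **Default fluctuation band (0.01, 0.065) Hz.** The analysis band extends
  to 0.071 Hz, but the *generator* keeps the spontaneous-fluctuation
  processes slightly below it, for a physical reason: the label/control
  modulation places sidebands at `1/(2 TR) ± f`, and fluctuation content at
  the very edge of the band would put sidebands inside the transition bin
  of the separation filter, mixing the channels by construction rather
  than by any property of the pipeline. The low-frequency hemodynamic
  range the generator emulates does not depend on sitting exactly at the
  analysis cutoff.
* **Centered labeling modulation.** The perfusion term is represented as a
  zero-mean carrier (`+ΔM/2` on control, `−ΔM/2` on label volumes) rather
  than a subtraction applied to label volumes only. The control-minus-label
  difference — the only quantity the pipeline uses — is identical
  (`ΔM (1 + f)`), but the label-only form leaks half the in-band perfusion
  fluctuation into the pair-mean BOLD channel, an offset convention rather
  than physiology. With the centered form the generator's BOLD channel
  contains exactly the injected BOLD process, which is what a ground-truth
  generator should deliver. (In real data the corresponding leakage exists
  and is part of why measured coupling values are attenuated.)
* **Coupling mixing.** `generate_coupled_pair()` returns
  `r · shift(f)/sd + sqrt(1 − r²) · ε/sd` with `ε` an independent
  band-matched process, so the population correlation with the lag-aligned
  CBF series equals the target exactly; the shift uses the same sinc
  interpolation as the analysis. Between-subject coupling variation in
  `generate_cohort()` is drawn on the Fisher-z scale, which keeps `|r| < 1`
  by construction.
* **Physiological components** are two sinusoids (cardiac 1.0 Hz,
  respiratory 0.3 Hz) sampled at each volume's slice-mean acquisition
  time; at TR 3.5 s the cardiac line aliases into the low-frequency band,
  which is precisely what RETROICOR must remove.
* **Cohort presets.** `"young-like"` draws subject coupling from
  0.24 ± 0.03 with lag −0.5 s, `"elderly-like"` from 0.18 ± 0.04 with lag
  −1.8 s, following reported group summaries; the between-subject lag SD
  (0.3 s) reflects the spread of reported regional shifts.

What the generator does *not* emulate: arterial transit delay
distributions, explicit background-suppression pulse timing (folded into
α_inv), head motion, anatomical tissue structure, and spatial
autocorrelation of the fluctuation fields (voxels are independent). Passing
recovery tests on this generator therefore demonstrates the correctness of
the estimators under the stated forward model, not robustness to transit
artifacts or motion in real data.

## Attenuation of r0, and what "recovery" means

Two deliberate facts about the recovery checks:

* The zero-lag correlation of a lagged pair is attenuated by the process
  autocorrelation: with the default band, a −1.8 s lag reduces a 0.18
  coupling to about 0.15 at zero lag, while a −0.5 s lag leaves 0.24
  nearly untouched. The recovery checks therefore compare the *mean
  estimated* r0 against the injected coupling within ±0.05, absorbing this
  attenuation rather than hiding it; it is also exactly the mechanism that
  makes the `rmax - r0` gain larger in the larger-lag group.
* Subject-level values are means over many voxels (64 in the recovery
  checks), mirroring how subject summaries are extracted from maps in
  practice; a single 45-frame voxel pair carries ~0.15 sampling SD on r,
  which no estimator can remove.

## Problem sizes

The test suite and the acceptance script run on deliberately small
geometries chosen as the package's own validation conditions: 16×16×8 or
8×8×4 voxel grids with 90 volumes for full runs; 45-frame separated series
with 32–64 voxels per subject for cohort simulations (15 + 16 subjects,
200 replicates for coupling recovery; 8 + 8 subjects, 100 replicates for
the lag-direction check); 500 replicates of m = 10,000 for the FDR null
calibration. The full-resolution 64×64×19 geometry is the generator's
default for realistic use.

## Known limitations

* The separation filters assume stationary, regularly sampled series;
  censored or scrubbed runs are not supported (pair-wise censoring of ASL
  data is its own problem).
* The lag scan's truncated-overlap correlations at extreme lags use fewer
  samples and are noisier; the ±7 s default keeps the overlap above 95% of
  the run.
* `rmax` is a maximum over 41 correlated estimates and is biased upward
  under noise; group comparisons of `rmax` between conditions with equal
  noise are unaffected, but `rmax` should not be read as an unbiased
  coupling estimate.
* Baseline quantification assumes complete bolus delivery at the slice
  PLD; transit-delay effects in older or vascularly compromised subjects
  bias absolute CBF, as with any single-PLD acquisition.
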