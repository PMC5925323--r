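# boldcbf

Dynamic BOLD–CBF coupling analysis for dual-echo pCASL resting-state data.

## The problem

Dual-echo pseudo-continuous arterial spin labeling (pCASL) acquires BOLD
and cerebral blood flow (CBF) signals simultaneously: the short echo (TE1)
carries the perfusion-weighted control-minus-label difference, the long
echo (TE2) the BOLD-weighted signal. The temporal correlation between the
spontaneous fluctuations of the two signals — the *dynamic BOLD–CBF
coupling* — probes resting-state neurovascular physiology, and is of
particular interest in aging, where vascular stiffening can delay and
desynchronize the BOLD response relative to CBF without abolishing the
underlying coupling.

`boldcbf` implements the full analysis chain for researchers working with
such data, plus a synthetic generator with known ground truth so that every
stage can be validated:

1. **Signal separation** — the interleaved control/label series is split
   into a CBF fluctuation series (high-pass above 1/(4·TR) ≈ 0.071 Hz at
   TR 3.5 s, demodulation by cos[π(n−1)], pairwise summation) and a BOLD
   series (low-pass, pairwise mean), both at sampling interval 2·TR, after
   RETROICOR physiological-noise and nuisance regression
   (`separate_run()`).
2. **Coupling estimation** — voxelwise zero-lag Pearson correlation r₀ and
   lag-optimized correlation r_max with its lag τ\*, scanned over ±7 s in
   0.35 s steps on a sinc-upsampled 100 ms grid
   (`pearson_r0()`, `lagged_rmax()`).
3. **Group inference** — Fisher-z transforms, voxelwise one- and
   two-sample t maps with Benjamini–Hochberg FDR control, ROI summaries,
   and the r_max − r₀ contrast with Cohen's d
   (`one_sample_t()`, `two_sample_t()`, `fdr_bh()`,
   `rmax_minus_r0_contrast()`).
4. **Baseline perfusion** — single-compartment kinetic model

   CBF = 6000·λ·(SI_C − SI_L)·e^(PLD/T1a) / [2·α·α_inv·T1a·M0·(1 − e^(−τ/T1a))]  [ml/100g/min]

   with slice-dependent post-label delay (1900–2800 ms over 19 ascending
   slices) and consensus 3T parameters (`quantify_cbf()`, `quant_params()`).
5. **Quality control** — RSFA fluctuation amplitudes, DVARS, and the
   motion-RMS exclusion rule (> 1.5 mm) (`rsfa()`, `dvars()`,
   `motion_exclusion()`).
6. **Synthetic data** — dual-echo runs, baseline runs, physiological
   traces, and whole cohorts with known coupling, lag, perfusion, and noise
   (`ground_truth()`, `assemble_dual_echo_run()`, `generate_cohort()`).

`run_pipeline()` orchestrates all stages over a subject roster; NIfTI, TSV
and JSON I/O helpers round-trip all containers losslessly.

## Worked example

Simulate a young-like cohort (subject-mean coupling 0.24, BOLD–CBF lag
−0.5 s) and an elderly-like cohort (coupling 0.18, lag −1.8 s), estimate
per-subject coupling, and contrast the lag-optimization gain:

```r
library(boldcbf)

young   <- generate_cohort(15, "young-like",   seed = 1, n_voxels = 64)
elderly <- generate_cohort(16, "elderly-like", seed = 2, n_voxels = 64)

summarise <- function(subject) {
  maps <- lagged_rmax(subject$bold, subject$cbf, dt = subject$dt)
  c(r0 = mean(maps$r0), rmax = mean(maps$rmax))
}
ys <- t(sapply(young$subjects,   summarise))
es <- t(sapply(elderly$subjects, summarise))

cat(sprintf("young:   r0 = %.3f +/- %.3f   rmax = %.3f\n",
            mean(ys[, "r0"]), sd(ys[, "r0"]), mean(ys[, "rmax"])))
cat(sprintf("elderly: r0 = %.3f +/- %.3f   rmax = %.3f\n",
            mean(es[, "r0"]), sd(es[, "r0"]), mean(es[, "rmax"])))

ct <- rmax_minus_r0_contrast(
  list(r0 = es[, "r0"], rmax = es[, "rmax"]),
  list(r0 = ys[, "r0"], rmax = ys[, "rmax"]))
cat(sprintf("rmax - r0 gain: elderly %.3f vs young %.3f (t = %.2f, p = %.2g, d = %.2f)\n",
            ct$mean_a[["diff"]], ct$mean_b[["diff"]], ct$t, ct$p, ct$cohens_d))
```

Output:

```
young:   r0 = 0.240 +/- 0.046   rmax = 0.311
elderly: r0 = 0.161 +/- 0.035   rmax = 0.270
rmax - r0 gain: elderly 0.109 vs young 0.071 (t = 6.29, p = 7.1e-07, d = 2.26)
```

Reading the numbers: the young cohort's zero-lag coupling is recovered at
its injected value (0.24); the elderly cohort's larger BOLD–CBF lag
attenuates its zero-lag correlation below the injected 0.18 (to ~0.16), and
correspondingly the elderly group gains more from lag optimization
(r_max − r₀ of 0.109 vs 0.071) — the signature of a temporal mismatch
between the two signals rather than a loss of coupling. The methods
vignette (`vignettes/bold-cbf-coupling.Rmd`) explains the attenuation and
every modeling choice.

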