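---
title: "Quantifying nodule vascularization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nodule vascularization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, under
which assumptions, and where genuinely open design choices were
resolved.

## The two measurement chains

### SMI sonography

Monochrome SMI Doppler encodes microvascular flow strength as pixel
gray level. For one nodule the examiner supplies five frames (two
longitudinal, two cross-sectional, one whole-lobe) and six region
annotations: the nodule ROI-A and a matched parenchyma ROI-B per plane,
plus nodal and parenchymal sub-areas of the whole-lobe region. Per
region the package measures

* the **mean gray value** — the arithmetic mean of the pixel values
  whose centres fall inside the polygon, and
* the **flow-positive area fraction** — the proportion of region pixels
  at or above a threshold.

Plane-wise values average the two frames; each node value divided by
its parenchyma counterpart is a **vascularization quotient**. Ten
parameters result per nodule. Gray values are dimensionless 8-bit
levels; area fractions are proportions in [0, 1].

Assumptions: flow signal is *brighter* than background (true of
monochrome SMI; enforced by the generator spec), regions are drawn by
the examiner (the code never auto-places an ROI), and the two frames of
a plane are exchangeable acquisitions of the same anatomy.

### CD34 histology

Brightfield RGB micrographs of CD34-stained sections are converted to
optical density per channel, `od = -log10(max(I, 1) / white_level)`;
stain contributions add linearly in OD (Beer–Lambert), so per-pixel
concentrations of haematoxylin and Fast-Red are the least-squares
solution of a 3 × 2 linear system, with negative components clipped
after solving. The Fast-Red-positive pixel fraction inside a calibrated
sampling rectangle (1440 × 1443 px = 2,077,920 px; 1 mm² of tissue at
100×, 16 mm² at 25×) is the vascularization measure. Four 100× fields
are averaged into `cd34_100_fold`; `cd34_all` is the midpoint of the
100× mean and the single 25× fraction — an exact arithmetic identity
asserted in the tests.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| threshold rule (SMI) | isodata | gray levels | the classic ImageJ auto-threshold family; `threshold_fixed(k)` for deterministic analyses |
| `positive_threshold` (CD34) | 0.15 | OD-concentration | conservative positivity cut well below a typical chromogen level of ~1.0; always set explicitly in tests |
| stain vectors | haematoxylin (0.650, 0.704, 0.286); Fast-Red (0.214, 0.851, 0.478), unit-normalised | RGB OD | widely used published vectors; real slides vary, so both are config-overridable |
| `white_level` | 255 | intensity | unstained background of 8-bit brightfield |
| ROI-B mismatch warning | 25% | relative pixel area | the parenchyma region should match the nodule region in size/depth; matching is the annotator's job, the code only warns |

Threshold semantics: a pixel counts as positive when its value is
**at or above** the resolved threshold; `threshold 0` gives fraction 1,
`threshold 256` gives 0 (both asserted as properties).

## The statistics layer

The motivating cohorts are tiny (16 nodules, 13 vs 3), so exact
small-sample behaviour is the point:

* **Wilcoxon rank-sum**: mid-ranks for ties; for `n1 + n2 <= 20` the
  two-sided p is computed by full enumeration of all `choose(n, n1)`
  group assignments (560 at 13/3), `p = min(1, 2 * min(tails))` — the
  doubled-tail convention of common SAS practice. Above 20, a normal
  approximation with tie-corrected variance and continuity correction
  (cross-checked against `wilcox.test` in the tests).
* **Spearman**: Pearson correlation of mid-ranks. Exact `n!`
  enumeration for `n <= 8`; for `8 < n <= 20` a seeded Monte-Carlo
  permutation p (100,000 draws, internal seed 20210 — full 16!
  enumeration is infeasible, a fixed seed keeps it reproducible);
  t-approximation above.
* **Partial Spearman**: all variables rank-transformed, partial
  correlation via the inverse correlation matrix, p from a t with
  `n - 2 - k` df. Whether the source analyses used partial Spearman or
  partial Pearson is not stated anywhere; ranks are used here because
  the headline statistic is Spearman (documented choice).
* **Missing policy**: undefined quotients (parenchyma value 0 makes
  0/0 or x/0) are flagged `NA`, never infinities, and excluded
  *pairwise*; `n_used` and `missing_excluded` are reported per result.
  No multiple-testing adjustment is applied anywhere — the output
  carries raw p-values only, matching the study design.

## What the synthetic generators emulate — and what they do not

* **Sonograms**: Gaussian speckle truncated to [0, 255] (default sd 8)
  with vessels planted as random-walk curvilinear strokes (default
  width 3 px) until the planted count equals `round(fraction × region
  pixels)` exactly — mimicking curvilinear SMI flow signals rather than
  salt-and-pepper noise, with a one-pixel placement quantum. This is
  *not* physically realistic ultrasound speckle (no Rayleigh
  statistics, no PSF, no attenuation); it is sufficient to test
  threshold and measurement logic, which is all the tests claim.
* **Histology**: vessels as Fast-Red strokes, nuclei as haematoxylin
  disks (~8 µm at the magnification's pixel pitch, default
  1500 /mm²), composed through the exact Beer–Lambert forward model the
  unmixer inverts, plus optional OD noise. Images stay floating-point
  in memory; 8-bit quantization happens only on PNG export, so the
  noise-free unmixing round trip is exact to machine precision. No
  tissue texture, stain gradients or out-of-focus blur are modelled.
* **Cohorts**: a Gaussian copula with Pearson parameter
  `2·sin(π·ρ/6)`, so the *Spearman* correlation of the outcome pair is
  the target ρ (exact for the normal copula, invariant under the
  monotone marginal transforms). Marginals are moment-matched Gamma
  (quotient, positive support) and Beta (CD34 fraction, [0, 1]
  support), so group means/SDs converge to the specified values; the
  defaults are the study conditions (13/3 split; quotient 0.88 ± 0.89
  vs 1.13 ± 0.19; CD34 0.05 ± 0.05 vs 0.08 ± 0.06; age 39.75 ± 12.74 y;
  BMI 26.08 ± 5.18 kg/m²; lengths 27.92/35 mm with an sd of 10 mm —
  the group length SDs are not published, 10 mm is a realistic clinical
  spread). Passing tests therefore show the *machinery* recovers known
  truth; they cannot show how real speckle, staining variability or
  examiner ROI placement would behave.

## Numerical choices

* **Pixel-inclusion rule**: a pixel is inside an ROI iff its centre is
  inside the polygon (even-odd rule), rows 0-based from the top-left,
  rectangles half-open — unambiguous and verified against a brute-force
  per-pixel oracle.
* **Isodata**: integer intermeans iteration from the rounded region
  mean; a constant region returns `max + 1` with a warning (fraction 0)
  rather than dividing by zero. Per-region resolution: every analysed
  region gets its own threshold (whether the original analyses reused a
  threshold across regions is unstated).
* **Frame combination**: the measured *parameter* is averaged across
  the two frames of a plane, not the pixels — robust to frame
  misalignment; averaging duplicated frames is exactly idempotent.
* **Degenerate statistics**: rank-identical `x` and `y` in the partial
  correlation make the matrix formula singular; the closed-form limit
  ±1 is returned instead. Zero rank variance anywhere flags the result
  as undefined rather than erroring, so correlation tables degrade
  cell-wise.
* **Copula interpretation of recovery checks**: the latent-correlation
  recovery analysis uses a single-population cohort (benign only), so
  the measured Spearman is the copula's and not inflated by the
  benign/malignant mixture shift; group structure enters only the null
  calibration analysis, where group means are set equal.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
material sized for tight feedback: sonogram scenes of 130–190 px,
histology fields of 60–220 px with whole-field sampling rectangles,
oracle comparisons on 8 × 8 images, exact-test oracles up to
`n1 + n2 = 10` (Wilcoxon) and `n = 7` (Spearman), copula recovery at
n = 500 over 20 seeds, and null calibration over 400 cohorts of 16.
The end-to-end pipeline demo uses the study-sized 16-patient cohort
with five SMI frames and five histology fields per patient.

## Known limitations

* The speckle and tissue models are deliberately minimal (see above).
* The isodata threshold assumes the flow/stain signal is well separated
  from background; on unimodal regions with very weak signal the
  intermeans fixed point can sit inside the background mode — use
  `threshold_fixed()` when the contrast regime is known.
* Per-cell values of the original correlation tables cannot be
  reproduced: the underlying per-patient images are not deposited, so
  the package reproduces the *procedure* and its printed arithmetic
  identities, and validates against synthetic ground truth.
* `cd34_all` weights the 100× and 25× summaries equally by definition;
  it is an average of averages, not an area-weighted pooled fraction.
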