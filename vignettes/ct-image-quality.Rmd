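---
title: "Automated CT image quality from structure coherence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated CT image quality from structure coherence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctiq)
```

## The measurement problem

Comparing CT reconstruction algorithms (filtered back projection, vendor
iterative reconstruction, learned denoisers) on patient scans requires
quality metrics that do not depend on a human placing regions of interest.
`ctiq` computes three such metrics per slice from one input pair — the HU
image and a liver mask (segmentation itself is out of scope; masks are an
input). Everything downstream of the mask is deterministic given a seed.

## The structure coherence feature

For a pixel `p` inside the organ, take the square window `W(p)` of side
`window_px` centered on `p`, intersected with the organ mask, and compute

$$\mathrm{SCF}(p) = \frac{\sum_{(i,j)\in W(p)} I_E(i,j)}{H_G + H_T + \epsilon},
\qquad I_E = \omega_1\,|\nabla I| + \omega_2\,|\lambda_1|,$$

* $\nabla I$ is the central-difference gradient scaled by the physical pixel
  spacing per axis (HU/mm), with edge replication at the image border.
* $\lambda_1$ is the first eigenvalue of the structure tensor
  $T = \begin{pmatrix} I_x^2 & I_x I_y \\ I_x I_y & I_y^2\end{pmatrix}$,
  optionally Gaussian-smoothed (`tensor_smooth_sigma_px`). Both $\lambda_1$
  and the first eigenvector are evaluated in closed form; the eigenvector is
  $(2T_{12},\; T_{22}-T_{11}+\sqrt{(T_{22}-T_{11})^2+4T_{12}^2})$, which
  satisfies $Tv=\lambda_1 v$ (verified against a numeric eigensolver to
  1e-10 in the tests), with the axis-aligned vector taken directly in the
  degenerate case $T_{12}=0$.
* $H_G$ and $H_T$ are Shannon entropies (natural log) of the orientation
  histograms over the window: gradient directions binned on $[-\pi,\pi)$ and
  tensor eigenvector orientations on $[0,\pi)$ — an eigenvector's sign is
  arbitrary, so orientations live on the half circle. Pixels with zero
  gradient magnitude have no defined direction and are excluded; a window
  empty after exclusion contributes zero entropy.

A coherent anatomical edge produces large edginess and concentrated
orientations (small entropies): high SCF. Pure noise produces moderate
edginess and near-uniform orientations ($H \approx \ln 8$ per histogram):
low SCF. Homogeneous tissue produces low edginess: low SCF.

The window sums are computed with exact integral images, so the map equals a
per-window brute-force evaluation to machine precision (tested), and the SCF
is exactly invariant under constant intensity offsets — bit-for-bit on
integer-valued HU images, which is what CT produces.

### Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `omega1`, `omega2` | 1, 1 | — | both terms kept as defined. $|\lambda_1|$ scales with the *square* of contrast while $|\nabla I|$ is linear, so with unit weights the pointwise edginess is contrast-inhomogeneous and dominated by the tensor term at clinical contrasts; both weights are exposed. |
| `window_px` | 9 | px | ≈ 6 mm at 0.7 mm abdominal spacing: big enough for a stable 8-bin orientation histogram, small enough to stay local. All invariants hold for any odd window ≥ 5 (tested at 5 and 9). |
| `n_angle_bins` | 8 | — | 45° sectors; coarse enough that a straight edge occupies one or two bins. Histogram counts are unweighted (magnitude weighting would be a different feature). |
| `entropy_floor` | 1e-6 | nats | guards the division for perfectly coherent windows (both entropies 0); with zero edginess the SCF is 0 regardless. |
| `tensor_smooth_sigma_px` | 0 | px | the pointwise tensor is rank one, so $\lambda_1 = |\nabla I|^2$ identically and the tensor orientation equals the gradient orientation mod $\pi$; a positive sigma gives a genuinely 2-D tensor. The default keeps the pointwise definition. |

## Regions, and the mask/window wiring

The organ mask is eroded with a square element of 7 px (disc available)
before any statistics are taken. One wiring subtlety matters: the SCF map is
evaluated with windows drawn from the *full* organ mask, and the percentile
partition is then restricted to the *eroded* mask. Intersecting windows with
the eroded mask instead would depress the edginess sum in a ring along the
eroded boundary (partial windows), and the homogeneous region would collect
in that ring rather than in genuinely homogeneous tissue. The erosion
element (7) is sized to the window (9) precisely so that windows centered on
eroded-mask pixels stay essentially inside the organ.

Within the eroded mask, the 10th and 70th percentiles of the SCF (linear
interpolation between order statistics, `stats::quantile` type 7 — the
common default; percentiles are per slice, never pooled across slices) split
the pixels into R_H (SCF ≤ p10), R_S (SCF ≥ p70), and an unused middle band.
Ties at a cut are included, so regions can slightly exceed their nominal 10%
and 30% fractions. If p10 = p70 (constant SCF — no measurable structure) the
slice is flagged unpartitionable: all pixels go to R_H, R_S is emptied, and
the pipeline reports the slice as excluded. Slices with organ area ≤ 100 cm²
(strict inequality for inclusion) or fewer than 100 defined SCF pixels are
likewise excluded with a recorded reason; every input slice appears in the
report exactly once.

## The three metrics

**Noise.** Five square ROIs (requested side 21 px ≈ 15 mm at 0.7 mm spacing)
are drawn without replacement from all centers whose full ROI lies inside
R_H, using a seeded RNG; the noise level is the mean of the five sample SDs
(denominator N−1 everywhere in the package). R_H at the 10th percentile is
spatially fragmented, so full containment at 21 px is often infeasible; the
ROI side then shrinks by 2 px at a time down to 5 px before giving up
("R_H too fragmented"). ROIs may overlap — strict non-overlap can be
infeasible in a 10%-of-organ region — and overlap is logged.

**SSI.** The raw index is the mean SCF over R_S. The calibrated index maps
it to HU/mm through `coef_a * ssi_raw + coef_b`; the default coefficients
(6.1398, 4.2813) come from a phantom calibration against manual edge-slope
measurements on one scanner and are *not* transferable across scanners,
protocols or SCF parameter choices — `fit_ssi_calibration()` on a sharpness
series (synthetic or measured) is the supported recalibration path, and
`run_validation()` performs it.

**SAI.** For a co-registered pair, $\Delta I$ = reference − target, and
$\mathrm{SAI} = \sigma_{R_S}/\sigma_{R_H}$ of $\Delta I$, with both SDs taken
over the whole region (not averaged over sub-ROIs; the alternative reading
exists but whole-region SDs are deterministic and use all pixels). The
partition always comes from the reference image, so one set of regions is
interrogated in both domains. Identical images give $\sigma_{R_H}=0$ and are
flagged as a no-op pair rather than a division by zero.

## The reference edge-slope measurement

Profile origins sit at equal arc length (default 1 mm) along the edge
polyline; each profile samples bilinear-interpolated HU at `step_mm`
increments over ±`half_length_mm` (default 5 mm) along the local unit normal
(adjacent-segment normals averaged at vertices), oriented so profiles rise.
Each profile is clipped to its 10–90% intensity rise and the OLS slope
$\xi = \mathrm{cov}(s, I)/\mathrm{var}(s)$ is averaged over profiles.

Two deliberate conventions:

* **Baseline.** The 10%/90% thresholds are set at
  `baseline + fraction * (max − baseline)` with the baseline estimated as
  the mean of the first quartile of samples along the profile. Thresholds at
  raw fractions *of the maximum* fail whenever the profile floor is far from
  0 HU (always true in liver tissue); the quartile-mean baseline is robust
  to noise where a minimum is not. Profiles that are flat, cross the
  thresholds out of order, or retain fewer than 4 samples are dropped and
  counted.
* **Step size.** The default profile step is 0.25 mm in the pipeline
  configuration. The 10–90% span of a sharp edge can be ~1 mm; with
  pixel-sized steps the first-crossing clipping quantizes the span and the
  slope saturates. At 0.05 mm steps the estimator agrees with a dense
  quadrature evaluation of the same clipped regression on an analytic erf
  edge to better than 1% (tested at 2%).

`agreement_stats()` supplies the Pearson correlation and Bland–Altman mean
difference / limits of agreement used to compare automated and reference
measurements.

## The synthetic phantom

`generate_phantom()` renders a parenchyma ellipse (100 HU) on a −50 HU
background with brighter vessels (+100 HU contrast; three circular sections
and one straight tube whose boundary provides the ground-truth edge line),
blurs the noiseless render with `edge_sigma_px`, optionally applies an extra
smoothing or an unsharp mask (the sharpness-series manipulations), and only
then adds seeded Gaussian noise (optionally correlated, renormalized to the
target SD). Blur-before-noise keeps edge blur and noise level independently
controllable; real reconstruction algorithms couple them, which is what the
stand-in denoisers model:

* `ideal` — convex combination toward the stored noiseless image. Its
  difference image is a scaled copy of the exact noise field the partition
  was computed on, and because the SCF percentile selection is correlated
  with the local noise realization, its SAI sits slightly *above* 1 — a
  useful reminder that "removed exactly the noise" is not the same as
  "removed noise uniformly at random".
* `edge_preserving` — removes noise only outside the dilated true-edge set;
  SAI < 1.
* `blurring` — Gaussian smoothing of the noisy image; SAI > 1.
* An i.i.d. difference field *independent* of the reference (target =
  reference + fresh noise) gives SAI ≈ 1, and that is how the ≈ 1 contract
  is tested.

What the generator does **not** emulate: anatomical texture, streak/
stationary-correlated CT noise (a correlation knob exists but the field is
Gaussian), beam hardening, partial volume, or segmentation error. Passing
tests therefore demonstrate the estimators' correctness and orderings under
controlled conditions, not clinical performance.

Default study sizes (chosen to keep every suite in seconds-to-a-couple-of
minutes on one core): noise recovery uses 256×256 px phantoms at 0.7 mm over
σ ∈ {5, 10, 20, 40} HU; the sharpness ladder uses 8 smoothing sigmas
(0.2–1.6 px), 3 unsharp amounts (1.5–2.5) and the base, replicated over 4
phantoms (48 images); partition invariants run on 100 randomized 128×128
phantoms.

## Known limitations

* **The automated noise level reads low.** R_H is the lowest decile of a
  statistic that is, in homogeneous tissue, essentially a local noise-energy
  estimate, so it preferentially selects windows where the noise realization
  happens to be smooth; SDs measured inside those windows underestimate the
  true σ. On white-noise phantoms the package measures this selection bias
  at roughly −15 to −20% across σ ∈ {5, 10, 20, 40} (the acceptance suite
  computes it; the correlation with true σ remains > 0.99 because the bias
  is nearly multiplicative). This is a property of the method, not of the
  implementation — relative comparisons across reconstructions, the method's
  purpose, are unaffected, but absolute noise values should be interpreted
  accordingly or calibrated against a reference measurement.
* The raw SSI is contrast-dependent (through $I_E$) and its absolute scale
  depends on window size, weights and spacing; only calibrated SSIs on a
  fixed configuration are comparable across datasets.
* Metrics are per-slice and 2-D; no 3-D structure tensor, no multi-scale
  analysis, no noise-power-spectrum/texture characterization.
* The DICOM layer is a fixture-grade codec (explicit-VR little-endian,
  single-frame classic CT); enhanced/multi-frame or compressed objects are
  rejected with a clear error.
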