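# ctiq — automated CT image-quality metrics from structure coherence

Objective image-quality monitoring of patient CT scans usually requires a
reader to place regions of interest by hand: a uniform patch of tissue for a
noise measurement, a vessel edge for a sharpness measurement. `ctiq`
implements a fully automated alternative for contrast-enhanced abdominal CT.
Given a slice in Hounsfield units and an organ (liver) mask, it computes a
per-pixel **structure coherence feature (SCF)**, uses its percentiles to
split the organ into a homogeneous region R_H and a structure-edge region
R_S, and derives three per-slice metrics without any manual ROI placement:

* **Noise level** — the mean sample SD of HU values over five randomly
  placed ROIs fully contained in R_H;
* **Structure sharpness index (SSI)** — the mean SCF over R_S, optionally
  mapped to a physical edge-slope scale (HU/mm) by a linear calibration;
* **Structure alteration index (SAI)** — for a co-registered reconstruction
  pair (e.g. FBP vs an iterative or deep-learning reconstruction), the SD
  ratio of the subtraction image between R_S and R_H: ≈ 1 for uniform noise
  removal, > 1 when structure was altered, < 1 for edge-preserving
  denoising.

The SCF of a pixel is computed over a square window W centered on it:

    SCF = Σ_{(i,j) ∈ W} I_E(i,j) / (H_G + H_T),      I_E = ω₁|∇I| + ω₂|λ₁|

where λ₁ is the first eigenvalue of the structure tensor
T = [Ix² IxIy; IxIy Iy²] (closed-form eigen-analysis), and H_G, H_T are
Shannon entropies of the orientation histograms of the gradient directions
(on [−π, π)) and of the tensor first eigenvectors (on [0, π)). Coherent
anatomical edges give large edginess with concentrated orientations (high
SCF); homogeneous or pure-noise areas give small edginess and near-uniform
orientations (low SCF). R_H and R_S are the pixels at or below the 10th and
at or above the 70th SCF percentile inside the eroded organ mask; slices
with organ area ≤ 100 cm² are excluded.

The package also implements the reference measurement used to validate SSI:
perpendicular intensity profiles sampled along a drawn edge polyline, each
clipped to its 10–90% intensity rise, with the OLS slope
ξ = cov(s, I)/var(s) in HU/mm, plus Pearson/Bland–Altman agreement
statistics — and a synthetic contrast-enhanced liver phantom generator
(parenchyma ellipse, vessels with controllable edge blur, tunable Gaussian
noise, paired stand-in "denoisers") so the entire pipeline is testable
without clinical data. A minimal DICOM CT reader/writer closes the I/O loop.

## Worked example

```r
library(ctiq)

bundle <- generate_phantom(phantom_spec(noise_sigma_hu = 15, seed = 42))
report <- evaluate_quality(bundle$image, bundle$organ_mask, seed = 42)
report[, c("area_cm2", "noise_hu", "ssi_raw", "n_pixels_rh", "n_pixels_rs")]
#>   area_cm2 noise_hu ssi_raw n_pixels_rh n_pixels_rs
#> 1    181.6    12.58   15477        3449       10347

# compare against a smoothing "reconstruction" of the same slice
target <- apply_denoiser(bundle, "blurring", 1.5)
compare_reconstructions(bundle$image, target, bundle$organ_mask, seed = 42)$sai
#> [1] 1.273

# reference sharpness along the phantom's ground-truth vessel edge
edge_slope_reference(bundle$image, bundle$truth_edge_line, step_mm = 0.25)
#> [1] 29.12
```

Reading: the 182 cm² parenchyma passes the area filter; the measured noise
(12.6 HU against a true 15 HU — the automated method reads low, see the
vignette) comes from five ROIs inside R_H; the SAI of 1.27 > 1 correctly
flags the Gaussian-smoothing target as structure-altering; and the manual
style edge-slope reference is 29 HU/mm. `run_validation()` repeats the
noise-recovery and SSI-vs-slope agreement studies on synthetic series, and
`autoplot()` methods display SCF maps, partitions, profiles and
calibrations. A command-line front end lives in `inst/cli/ctiq.R`
(`evaluate`, `compare`, `validate`, `make-fixtures`).

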