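---
title: "Task-based mammography image quality: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-based mammography image quality: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Image quality in digital mammography is only meaningful relative to a
clinical task. `mammoiq` implements a task-based quality chain for the
detection of microcalcification clusters in raw ("for processing",
detector-linearized) mammograms:

1. a **ground-truth detectability score** per image, produced by a
   channelized Hotelling observer (CHO) on hybrid regions of interest
   (ROIs) — patches with a computationally inserted cluster versus patches
   without one;
2. a **prediction model** that estimates this score directly from radiomic
   features of the raw image, so that once trained, no further observer
   runs are needed.

Because no clinical archive ships with the package, a synthetic-data module
generates raw mammograms with the statistical structure the chain assumes;
every downstream stage is exercised and tested against it.

## Lesion insertion and the ROI task

A cluster is inserted by local attenuation,

$$I(x,y) = I_0(x,y)\,\bigl(1 - \lambda\,M(x,y)\bigr),$$

where $M$ is a binary stencil of five ~200 µm calcifications placed at
random in a 1 cm² window and $\lambda$ is the contrast (default 0.08, a
level at which small calcifications are difficult for human readers).
Detection is cast as a Signal-Known-Exactly / Background-Known-Statistically
(SKE/BKS) task: per image, 200 signal-present and 200 signal-absent
$10\times10$ mm ROIs are drawn from the breast interior, at least 5 mm from
the mask boundary (skin line / chest wall), without replacement and from
*distinct* centers for the two classes. Present ROIs insert the cluster at
the ROI center immediately before extraction, which is equivalent under SKE
to storing hybrid images and avoids persisting hundreds of full-size copies.

Coordinates are 1-based (row, column) with closed extraction windows — the
native convention of R matrices and of the R image-analysis packages this
code sits beside.

## The channelized Hotelling observer

Channel $j$ is a Laguerre–Gauss (LG) function
$u_j(r) \propto e^{-\pi r^2/a^2} L_j(2\pi r^2/a^2)$, five channels with
Gaussian width $a = 1.5$ px by default (matched to the calcification size;
the parameterization of "width" is configurable since conventions differ).
Two numerical facts matter:

* **Discrete orthogonality fails at small widths.** The continuous LG family
  is orthonormal, but sampling a 1.5 px Gaussian on a unit grid undersamples
  it badly: the pairwise inner products reach ~0.8. This is recorded in the
  `gram_offdiag` diagnostic rather than "fixed", because the Hotelling
  template $w = S^{-1}(\bar v_p - \bar v_a)$ whitens whatever correlation
  the channels carry. Orthogonality to $10^{-3}$ re-emerges for widths
  $\gtrsim 5$ px, which is what the orthogonality test asserts.
* **A cluster is not a point.** The stencil scatters calcifications over
  the whole 1 cm window, so channels evaluated only at the ROI center see
  almost none of the signal. `cluster_channels()` realizes the
  *convolutional* reading of the channels for an exactly known, spatially
  extended signal: each LG image is shifted to every calcification center
  and summed (a convolution of the channel with the known center layout),
  then renormalized. With a single centered blob this reduces to the plain
  centered channel set. The channel count stays five.

Each virtual reader draws a fresh training sample (1500 signal-absent, 500
signal-present ROIs) from a pooled ROI source, forms class means and the
pooled (average-of-class) covariance with a $10^{-8}\cdot\mathrm{tr}(S)$
ridge if ill-conditioned, and scores the image's 400 ROIs with
$t = w^\top v + \eta$. Detectability is the Mann–Whitney AUC, averaged over
30 readers.

**Internal noise.** The decision noise $\eta \sim N(0, (\sigma s_0)^2)$ is
expressed in units of $s_0$, the signal-absent decision-statistic SD of the
training sample. An absolute noise level would not transfer across image
scales or presets; the relative level is calibrated by
`calibrate_internal_noise()` so that the ensemble mean AUC lands in the
75–80% operating band, which is how the observer is matched to human
performance. Calibration bisects on $\sigma$ using common random numbers
(fixed reader draws, fixed standard-normal deviates rescaled by $\sigma$),
making the objective a deterministic and monotone function of $\sigma$ so
the bracket is valid.

## Degradations

Two acquisition degradations are modeled, each applied to a random 10% of
the cohort:

* **Dose reduction** to a fraction $\gamma$ (default 0.75 of the AEC
  operating point). Under the two-component detector model
  (quantum variance $g(I-\tau)$ plus electronic variance $\sigma_e^2$), the
  transform $\gamma(I-\tau) + \tau + \varepsilon$ with
  $\mathrm{Var}(\varepsilon) = \gamma(1-\gamma)g(I-\tau) +
  (1-\gamma^2)\sigma_e^2$ gives the output the first two moments of a true
  $\gamma$-dose acquisition; the tests verify this against a directly
  simulated reduced-dose flat field. Injected noise is white — no detector
  correlation kernel is modeled.
* **Motion blur** by a $5\times5$ directional kernel at 45°, a line of five
  equal weights through the center (the uniform-line reading; the weight
  profile is configurable). Convolution uses reflective padding to avoid
  dark rims inside the breast near edges.

The scoring protocol inserts the lesion *first* and degrades the patch
afterwards, so the signal itself is noisier or blurred in degraded images —
without this, a linear observer can paradoxically benefit from blur (the
background noise smooths faster than a low-frequency signal attenuates).
Feature extraction, by contrast, sees the image-level degraded raster, as a
clinical pipeline would.

## The synthetic generator and what it does not emulate

Backgrounds are isotropic $1/f^\beta$ filtered Gaussian textures
($\beta = 3$) inside an ellipse-plus-half-plane breast mask, plus
signal-dependent Gaussian quantum noise ($\mathrm{Var} = g(I-\tau)$, an
adequate approximation of Poisson statistics at mammographic signal levels)
and additive electronic noise. Two presets ship: "A" (100 µm pitch,
100 px ROI) and "B" (70 µm pitch, 144 px ROI); their noise parameters are
package configuration values, not claims about any vendor's hardware.

Cohort variability comes from per-image draws of the mean tissue signal
(uniform 300–900 digital units, emulating AEC/anatomy variation — this is
the main driver of quantum SNR and hence detectability) and of the texture
RMS (uniform 20–100, the clutter level). These ranges were chosen once so
that the zero-internal-noise ensemble AUC sits well above the calibration
band (≈0.99 mean), as the calibration procedure presumes, with a usable
spread after calibration (≈0.53–0.92).

The generator does **not** emulate anatomical parenchyma, scatter, detector
MTF, heel effect, or inter-view correlation. Consequently, a passing
pipeline demonstrates that the chain is implemented coherently — the
observer responds correctly to contrast, noise, blur and clutter, and the
regression can recover detectability from image statistics — not that the
specific feature subsets selected here would transfer to clinical images.

## Radiomic features

No radiomics backend exists for R in this environment, so the extractor is
native: a filter bank (original, single-level undecimated wavelet with four
sub-bands, Laplacian-of-Gaussian at σ = 2, 3, 4 px, square, square root,
logarithm, exponential, gradient magnitude, 8-neighbor LBP) crossed with
first-order statistics and the five gray-level texture-matrix classes
(GLCM, GLRLM, GLSZM, GLDM, NGTDM), plus 2D shape descriptors of the mask.
Conventions:

* Air is replaced by the masked mean *before* filtering, so no feature can
  depend on pixels outside the breast (a tested invariant).
* Gray levels use a fixed bin width (25 digital units) from the masked
  minimum. Filtered domains are affinely rescaled to the original masked
  intensity range before binning — otherwise compressive domains (log,
  square root) collapse into one or two bins and carry no texture
  information.
* Degenerate statistics follow fixed conventions (skewness/kurtosis of a
  constant region are 0; entropy of a single bin is 0), never NaN.
* The default grid yields 736 named features (`filter_class_statistic`);
  the documented count is configuration-derived, since per-class feature
  menus differ between radiomics implementations. Cohort-scale runs use
  `feature_config_reduced()` (7 domains × 4 classes = 259 features), which
  drops the costliest domains while keeping the signal carriers.

## Feature selection and regression

Selection is correlation-based (CFS): subset merit
$k\bar r_{cf} / \sqrt{k + k(k-1)\bar r_{ff}}$ with Pearson correlations on
the continuous features (the regression setting; the classic discretized
variant does not apply to a continuous target). The merit can exceed 1 for
anticorrelated pairs and is reported as computed. Search is best-first
forward selection from the empty set with an open list, terminating after 5
consecutive non-improving expansions, deterministic with lexicographic
tie-breaking.

Selection runs inside a 10-outer × 5-inner nested cross-validation on
inner-training rows only; the 50 inner subsets are pooled and features kept
if selected in at least a threshold fraction of them (0.5 for homogeneous
cohorts, 0.1 when degradations — affecting only 10% of images — must keep
their specific markers). Held-out outer rows never touch selection, an
invariant verified by scrambling them and checking the selections are
byte-identical.

The regressor is a 30-15-5 ReLU multilayer perceptron with a linear output,
trained by seeded mini-batch SGD (learning rate 0.05, momentum 0.05, 1200
epochs, batch 100, MSE loss, no early stopping). Weights initialize
uniformly in $[-0.5, 0.5]$; biases initialize at +0.1 because a zero-mean
random start occasionally kills the narrow 5-unit bottleneck outright (all
ReLUs inactive for every input), after which plain SGD cannot recover — a
small positive bias removes this failure mode at initialization. The same
collapse can still, rarely, happen mid-training (roughly one outer fold in
twenty on the synthetic cohorts); a fit that ends with zero prediction
spread on a non-constant target is therefore restarted from a
deterministically derived reinitialization (at most four times, recorded as
`n_restarts` on the fit). Per outer fold, min–max normalization is refit on training
rows only, and metrics (r, MAE, RMSE, RAE, RRSE — the relative errors
normalized by the predict-the-training-mean baseline) are averaged over the
10 folds.

## Problem sizes and reproducibility

The package's cohort experiments run at desk scale: 300 images of
320 × 320 px for the end-to-end study (about 8 minutes on one core,
dominated by feature extraction), 50 images for the calibration ensemble,
and a 20 px toy preset for the fast test fixtures. Every stage seed derives
deterministically from the master seed and the stage name, so a full
experiment is a pure function of its configuration: rerunning a config
reproduces byte-identical tabular outputs.

## Known limitations

* One task (calcification-cluster detection at one size and contrast); no
  masses, no search task, no LROC/FROC.
* The degradation model covers quantum/electronic noise scaling and uniform
  linear blur only; no correlated noise injection, detector lag, or
  spectrum changes with dose.
* The observer uses decision-variable internal noise; channel-domain noise
  injection is not implemented.
* DICOM input is not supported in this build (no R DICOM reader available);
  rasters enter as 16-bit TIFF or NPY with a JSON sidecar.
* Synthetic cohorts make detectability unusually predictable (mean signal
  and texture amplitude are fully visible to first-order features); clinical
  correlation coefficients should be expected to be lower.
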