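---
title: "Multiscale imaging features of oral epithelial neoplasia: methods and design"
author: "MucosalScope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale imaging features of oral epithelial neoplasia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MucosalScope)
```

# The analysis problem

Benign inflammation and early neoplasia (oral epithelial dysplasia, OED)
look alike under white light, which is why widefield autofluorescence
screening of oral mucosa has good sensitivity but poor specificity once
benign lesions are in the population. MucosalScope implements a multiscale
analysis that combines three quantitative image features with different
failure modes:

1. **Normalized RG** — the macroscopic red-to-green autofluorescence
   intensity ratio of a site, normalized by an internal-control strip on
   the sample holder. Neoplasia elevates red (porphyrin) emission and
   depresses green (collagen, redox coenzyme) emission, but so does
   inflammation, which caps the specificity of this feature alone.
2. **ECTI contour** — from depth-resolved two-channel microscopy
   (multiphoton autofluorescence + second-harmonic generation), the surface
   area of the epithelial–connective-tissue interface relative to a flat
   surface. Hyperproliferating epithelium deforms the basement-membrane
   region from a flat sheet into a corrugated surface; inflammation does
   not.
3. **Basal nuclear CoVa** — the coefficient of variance (sd/mean) of
   nuclear area in the basal epithelium, a morphometric proxy for
   anisonucleosis / nuclear pleomorphism.

Single features are compared across histology classes (one-way ANOVA with
Tukey's post hoc test) and evaluated by empirical ROC curves; feature pairs
and the full triple feed two-class binomial GLMs, the triple via forward
selection starting from the widefield feature.

# Widefield normalized RG

For a site, three 20 × 20-pixel ROIs each give a red/green mean-intensity
ratio; five ROIs on the internal-control strip give the control factor
IC-RG (mean of their five ratios). The site value is the mean of the three
site ratios each divided by IC-RG. Because every ratio is red/green at one
location and the control is acquired under the same illumination, any
global intensity scale factor cancels exactly; the suite asserts this
invariance to machine precision, together with invariance under ROI
ordering.

Tunables:

* `epsilon` (default 1 count) — a ROI or pixel whose green mean is at or
  below it is invalid rather than yielding a huge or infinite ratio.
* `threshold` (default 1.46, dimensionless) — the normalized RG level above
  which map pixels are flagged suspicious in `thresholdOverlay()`; it is
  the ROC-derived operating threshold separating normal from neoplastic
  mucosa and is overridable.
* `window` (default 0–7) — display clamp for `rgHeatmap()`.

Channel separation takes the R and G planes of the demosaiced RGB frame
directly; raw Bayer-mosaic input and spectral crosstalk between the red and
green passbands (which overlap around 560–600 nm) are out of scope — the
ratio largely mitigates crosstalk, but it is not modeled. Site and
control-ROI placement is user-supplied geometry (CSV/JSON), not automatic
lesion proposal.

# Microscopy features

## Interface extraction

The interface is recovered from the SHG channel, which is near zero inside
the epithelium and bright in the collagenous stroma. After separable
Gaussian pre-smoothing (defaults: sigma 2 px lateral, 1 plane axial,
replicate-padded), a lateral position is *detected* as carrying an
interface when its z-column exceeds `thresholdFrac` (default 0.2) of the
robust SHG maximum (99th percentile); undetected columns are masked
invalid. The height itself is *localized* at the first crossing of the
half-plateau level (0.5 × robust maximum), with sub-plane precision by
linear interpolation between the bracketing samples. These two levels
differ deliberately: a low threshold is the right detector for weak
columns, but on a smooth rising edge it sits systematically shallow —
for an erf-shaped edge of effective width sigma the f-crossing lies
`qnorm(f) * sigma` before the true edge, about 0.8 sigma at f = 0.2 —
whereas the half-height crossing of a symmetric edge is unbiased. Columns
that are detected but never reach the half-plateau level fall back to the
detection crossing. Heights are micrometers of depth from the first
acquired plane (z increases downward into tissue).

## Triangulated contour

Each valid quad of the height-map grid (lateral spacing = pixel size) is
split into two 3-D triangles whose areas come from Heron's formula in
Kahan's numerically stabilized ordering (sides sorted, factored so thin
triangles lose no precision; degenerate triangles return 0). The contour is
total triangulated area over the flat projected area of the same valid
region, so it is ≥ 1, equals 1 exactly on a constant map, equals
`sqrt(1 + s^2)` on a plane of slope `s`, and is invariant to adding a
constant height and to lateral rotations/flips. The quad diagonal choice
(`"nw-se"` default) changes smooth-surface results by well under 0.5%; both
are exposed. The full pixel grid is triangulated by default (no mesh
decimation), which means fine-scale roughness contributes to the absolute
scale of the metric — consistent with flat-looking normal tissue reading
above 1.

## Nuclear morphometry

Basal cytology is sampled on three planes 5–10 µm apart (default 5 µm)
centered on a user-supplied basal-depth hint; in vivo the basal layer is
located by operator judgment, so a hint parameter stands in. Nuclei appear
as dark elliptical lumina on brighter cytoplasm (two-photon NADH/FAD
contrast is cytoplasmic). Automatic delineation thresholds the plane
(Otsu), labels connected components, keeps components in an admissible area
range (default 8–200 µm²) that do not touch the border, and fits each with
its moment-equivalent ellipse (axis length = 4 × sqrt of the covariance
eigenvalue). Manual outlines are accepted either as fitted axes or as
polygons, whose moments are evaluated analytically (Green's theorem).
Nuclear area uses the ellipse axis *lengths*: `pi * major * minor / 4`.
CoVa pools the ~60 areas of the three planes and divides the sample
(n − 1) standard deviation by the mean — the small-sample morphometry
convention; whether the original measurements used sample or population sd
is not stated, and the choice moves CoVa by under 1% at n = 60. CoVa is
unit-free and invariant to nucleus ordering and area rescaling.

# Classification

* `rocCurve()` computes the empirical ROC over all achievable thresholds;
  AUC is the trapezoid area, identical to Mann–Whitney pair counting with
  ties worth 1/2 (the suite checks this against exhaustive pair counting on
  small tied samples). The operating point maximizes Youden's J, with ties
  broken toward the lower threshold (higher sensitivity). How the original
  operating points were chosen is not stated, so Youden's rule is adopted
  and overridable.
* `fitGLM()` is a binomial GLM with logit link fit by IRLS (weights floored
  at 1e-10, deviance-change stopping at 1e-10, cap 25 iterations). Under
  quasi-separation it stops at the cap with `converged = FALSE` and still
  reports a usable probability-0.5 boundary. Coefficients agree with the
  reference IRLS implementation in `stats::glm` to 1e-6 on fixed tables.
* `forwardSelect()` starts from the normalized-RG-only model and adds the
  single microscopy feature with the largest residual-deviance reduction,
  accepting an addition only when the reduction exceeds
  `qchisq(0.95, 1)` (a 0.05-level likelihood-ratio cutoff). A plain
  "any improvement" rule is not usable here: a nested MLE refit always
  lowers deviance a little, so noise features would always enter. The
  threshold is an argument.
* `classifySites()` calls a site neoplastic when the model probability
  exceeds 0.5 (no cutoff was specified originally; 0.5 is the natural
  choice and is an argument) and reports the misclassified sites,
  sensitivity, specificity, percent correct and the ROC of the model
  probabilities.
* Neoplastic is OED ∪ OSCC for widefield-only analyses and OED alone for
  microscopy/multimodal analyses (exophytic tumors cannot be flattened and
  imaged by the depth-resolved modality); both groupings are explicit
  options.

# The synthetic-data generators

No raw images are distributed with the package, so every stage is
validated against synthetic data with planted ground truth.

**Feature cohorts** (`genFeatureTable()`). The default calibration encodes
the class-conditional moments of the three features: normalized RG
1.23 ± 0.55 / 2.48 ± 0.96 / 3.13 ± 3.23 / 8.15 ± 4.9 for
normal/inflammation/OED/OSCC; ECTI contour 1.55 ± 0.37 / 2.43 ± 1.03 /
4.28 ± 1.88 and CoVa 0.21 ± 0.04 / 0.2 ± 0.05 / 0.4 ± 0.09 for the three
classes imaged by microscopy (no OSCC microscopy values). Families respect
each feature's support and skew without extra parameters: a lognormal,
moment-matched in closed form, for the right-skewed normalized RG;
lower-truncated Gaussians for ECTI contour (support > 1 — a triangulated
surface cannot have less area than its projection) and CoVa (support > 0).
For the truncated families the pre-truncation (mu, sigma) are solved
numerically (1-D root in the standardized bound) so that the
*post-truncation* mean and sd equal the calibrated moments; naive
truncation of N(mean, sd) would bias the normal-class contour mean upward
by about 0.05. Features are drawn independently within a site — no
within-site cross-modality correlation was reported, so independence is an
assumption (a configurable correlation structure is a possible extension,
not currently implemented). Default cohort sizes are 37/16/28/31 (widefield)
and 33/11/19 (microscopy) so small-sample behavior can be emulated.

**Widefield scenes** (`genWFImage()`). Uniform background, a uniform
internal-control strip (disjoint from all lesions by construction),
circular lesion foci with per-focus red/green multipliers, a global
illumination scale that the normalization must cancel, and additive
Gaussian noise. The planted lesion mask is returned.

**Z-stacks** (`genNLOMStack()`). Nominal geometry 512 × 512 at 0.625 µm
lateral pixels and 1 µm z-steps; a bright speckled keratin layer, a basal
layer of dark non-overlapping elliptical nuclei (area distribution solved
to the target CoVa, aspect ratios 1.05–1.8, uniform orientations), and an
SHG channel that rises across the interface as an erf edge of ~1 µm width
(emulating the axial point spread; a sub-sample-width hard step would alias
into phase-dependent interpolation error, i.e. fake roughness) plus a mild
multiplicative fiber texture. The interface corrugates sinusoidally along
x, so its true area ratio has a quadrature closed form
(`sinusoidSurfaceRatio()`); ground truth (per-plane nucleus axes, the
height map, the analytic contour) is returned alongside the stack.

What the generators do *not* emulate: optical point-spread functions,
hemoglobin absorption, spectral crosstalk, photorealistic tissue texture,
within-site feature correlation, or motion. Passing tests therefore show
that the *computations* recover known truth under controlled conditions —
not that the features are this clean in real mucosa.

# Numerical choices and degenerate inputs

* Rectangles are 1-based, inclusive, in (row, col, height, width) order —
  the idiomatic convention for R matrices; all schemas document it.
* Degenerate dispersion (sd → 0, or target CoVa 0) collapses draws onto the
  mean rather than invoking the solvers.
* Collinear triangles have area 0; constant height maps give contour
  exactly 1; invalid map cells are excluded from both the numerator and
  denominator of the contour.
* ROC threshold ties break toward higher sensitivity; AUC is invariant
  under strictly monotone score transforms.
* TIFF quantization (8/16-bit) happens once on write, within one intensity
  level; a re-written file round-trips bit-identically. 12-bit packed input
  is rejected with an explicit unsupported-format error.
* Every generator and the pipeline accept a seed; identical spec + seed
  gives bit-identical output, and the pipeline manifest records the
  config, seed, versions and the feature-file checksum.

# Validation scale

The test suite exercises: calibration recovery at 20,000 draws per class
(each class-conditional sample mean within 3 standard errors of its
calibrated value); noise-free widefield recovery exactly and noisy recovery
within 3 SE over 100 seeded replicates; interface-contour closed forms
(flat, tilted plane, sinusoid vs quadrature at pixel ≤ period/32); planted
contour recovery through the full extraction chain to 2% on noise-free
stacks and planted CoVa within 3 SE over 100 noisy stacks (160 × 160 × 30
voxels, 20 nuclei per plane — sizes chosen to keep the full suite fast
while leaving ≥ 60 nuclei per stack); and the qualitative ordering of
discriminative power (median AUC over 500 simulated microscopy cohorts,
with inflammation included: CoVa > ECTI contour > normalized RG). These
problem sizes are the package's own validation choices and are easy to
scale up by editing the specs in the tests.

# Known limitations

* All classification performance is in-sample; no cross-validation or
  external validation is provided, matching the scope of the original
  analyses.
* The interface extractor assumes SHG brightness increases across the
  interface monotonically at the scale of the smoothing kernel; deeply
  invaginated (multi-valued) interfaces would be summarized by their first
  crossing.
* Automatic nuclear delineation expects dark lumina on brighter cytoplasm
  and will not segment touching nuclei; manual outlines remain the
  fallback, as in the original workflow.
* The 1.46 widefield threshold is a property of the original cohort and
  instrument; new instruments need their own ROC calibration.
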