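---
title: "Models and numerical choices in spheromech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in spheromech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

spheromech implements the analysis chain for spheroids grown in linear
stiffness-gradient hydrogels: AFM-based gradient calibration, 3D
voxel-based morphometry, mechanomarker quantification, quantitative
micro-elastography (QME) reconstruction, and the trend/group statistics
that tie them together. This vignette records the models, the tunable
parameters that matter, and the design decisions taken where the
underlying procedures are conventionally left to instrument software or
unstated analysis settings.

## Stiffness calibration from AFM indentation

A pyramidal tip indenting an elastic half-space follows the Sneddon-type
law

$$F = C(\theta, \nu)\, E\, \delta^2, \qquad
  C = \frac{\tan\theta}{\sqrt{2}\,(1-\nu^2)},$$

with $F$ in nN, indentation $\delta$ in µm and $E$ in kPa (1 kPa =
1 nN/µm², so $C$ is numerically dimensionless). Instrument vendors differ
in the exact front factor for pyramidal tips; the package commits to this
single closed form and uses it in **both** the curve generator and the
fitter, so round-trip self-consistency — not the constant itself — is
what the tests assert. Defaults are $\nu = 0.5$ (incompressible
hydrogel) and $\theta = 35^\circ$, both exposed in
`afm_curve_config()` / `indenter_model()`.

**Contact point.** Rather than a force-threshold crossing (sensitive to
baseline offset), the contact point is found by a change-point search:
for every candidate separation the curve is fit as flat baseline +
quadratic contact law, and the residual-sum-of-squares minimiser wins. A
curve whose force range never exceeds 5 robust SDs of the baseline is
rejected as contact-free. On noiseless curves the estimate is exact
(the generator's grid contains the contact point); at 0.05 nN noise on
trigger-scale (~2 nN) curves it stays within two sample spacings
essentially always.

**Gradient map.** Replicate (triplet) indentations at each position are
averaged before the ordinary least-squares line $E(x)$ is fit. The
calibrated domain is the position range of the data and
`stiffness_at()` refuses extrapolation, because the printed gradient
end-points and the fitted line over the full span disagree slightly in
the source setting; anchors are therefore explicit configuration, not an
assumption baked into the code.

## Synthetic spheroid stacks

`generate_spheroid_stack()` voxelizes one spherical spheroid envelope
whose target volume is `n_nuclei * cell_volume`, packs `n_nuclei`
axis-aligned ellipsoids of exactly `nuclear_volume` each (semi-axis
ratios drawn in [0.9, 1.12]), and renders three channels: nuclei
(binary), F-actin (envelope minus nuclei — cytoplasmic), and a marker
channel whose mean over the envelope equals $a e^{bV}$ at the
*voxel-counted* volume $V$, with nuclear voxels at `yap_ratio_true`
times the cytoplasmic intensity.

Placement decisions:

* **Rejection sampling with restarts.** Centres are drawn uniformly in
  the admissible ball; a configuration stuck for 1500 consecutive
  rejections restarts from scratch (all under the one seed, so output is
  a pure function of config + seed).
* **Separation.** In normal mode nuclei must clear each other by 15% of
  the sum of their directional radii — "well-separated", the regime the
  watershed is expected to resolve exactly. The explicit
  `touching_pairs` mode places pairs at 95% of the contact distance so
  that they form a single foreground blob, exercising watershed
  splitting.
* **Cortical margin.** Nuclei keep ≥ 1.5 µm (capped at 0.15 R) of
  cytoplasm between themselves and the envelope surface. Without it a
  surface-touching nucleus punches a hole through the actin shell and
  the whole-spheroid gate develops craters — an artefact of the phantom,
  not of real spheroids, where a cortical cytoplasm layer always exists.

Degradation: isotropic Gaussian blur (`blur_sigma`, default 0.5 µm) as a
PSF proxy, then Poisson shot noise (`poisson_scale` photons per
intensity unit) and additive Gaussian read noise — the standard
fluorescence noise model with independently testable knobs. The default
voxel size is (0.3, 0.3, 0.5) µm: the axial step matches confocal
acquisition of these samples; the lateral value is a typical 40×
confocal sampling and is a documented assumption (the source setting
does not state it).

The truth record stores voxel-counted volumes (not nominal ones), the
noiseless masks and the placement centroids, so every downstream value
is checkable by brute-force voxel counting.

**Scale.** Phantoms are desk-scale — six to ten cells rather than the
hundreds in a mature spheroid — so that a 250-spheroid cohort segments
in well under a minute. The morphometric relationships under test
(volume ratios, count recovery, trend signs) do not depend on absolute
cell number, but readers should not take the default volumes as
biological estimates.

## 3D morphometry

* **Prefilter**: Gaussian-weighted median on the nuclei channel
  (radius 1 voxel, weight sigma 1 voxel by default — values unstated in
  the source setting and exposed as parameters). The filter is the exact
  weighted median over the clipped cubic window; tests check it against
  a brute-force oracle voxel by voxel.
* **Spheroid gate**: smooth (1 µm) → Otsu threshold → closing (1 µm ball
  via two distance transforms) → border-connected hole filling → largest
  26-connected component, warning about discarded components. Otsu is
  the committed automatic threshold; it is config-overridable.
* **Nuclei**: Otsu inside the spheroid mask, anisotropic (physical-unit)
  squared Euclidean distance transform (Felzenszwalb lower-envelope,
  exact), light Gaussian smoothing (0.5 µm), markers = local maxima
  above `h_frac` (0.3) of the distance maximum thinned to a minimum
  separation of about one nuclear radius, Meyer priority-flood watershed
  descending the distance map, then removal of labels below
  `min_volume_um3` (50 µm³ by default — debris scale; the cohort
  pipeline lowers it for its deliberately small phantom nuclei).
* **Volumes** are voxel counts × dx·dy·dz; cytoplasmic = spheroid −
  nuclear is exact by construction, and per-cell volume = spheroid
  volume / nuclei count.

Connectivity is 26 in 3D throughout; arrays are (z, y, x) with
`voxel_size` quoted (dx, dy, dz).

## Marker quantification

The background estimate is the median of a 5 µm annulus dilated outside
the spheroid mask (robust to nearby objects), with a global low
percentile as fallback when the mask touches the stack border. Two
estimator refinements address PSF mixing, both off-by-default or
documented:

* `yap_nuc_cyto_ratio(..., erode_um = 1)`: nuclear and cytoplasmic
  compartments are eroded by about one PSF sigma before averaging.
  Without erosion the nuclear mean absorbs cytoplasmic signal at the
  shared boundary and a true ratio of 0.8 reads as ≈ 0.87 at 0.5 µm
  blur; with it the ratio is recovered to < 1%.
* `mean_marker_intensity(..., erode_um = 0)`: by default the plain
  annulus-subtracted mask mean (the straightforward estimator), which
  under-reads the interior concentration by a few percent because the
  PSF dilutes the outermost shell; passing `erode_um` of about two PSF
  sigmas yields the undiluted interior mean, used when fitted law
  parameters are compared against generator truth.

Expression trends: linear by OLS; exponential $I = a e^{bx}$ by
nonlinear least squares initialised from the log-linear OLS solution.
$r^2$ is computed on the intensity scale (not the log scale) in both
cases — the source setting does not state its convention, so this one is
documented. The non-zero-slope p-value is the t-test on the linear slope
or the asymptotic test of $b = 0$. Measurements are per-spheroid means
(not pooled voxels), another committed reading of an unstated choice.

## QME reconstruction

The forward model (and therefore the generator) assumes uniaxial stress:
$\varepsilon(x,z) = \sigma_0 / E(x,z)$, axial displacement is the depth
integral of strain, and the inter-B-scan phase difference is
$\Delta\phi = 4\pi n u / \lambda_0$ wrapped to $(-\pi, \pi]$
(double-pass convention, $\lambda_0$ = 1300 nm, $n$ = 1.4). The
generator refuses configurations whose per-pixel displacement increment
reaches $\lambda_0/(4n)$, where unwrapping becomes ambiguous.

Reconstruction steps and choices:

* **Unwrapping** is 1D per A-line by nearest-2π correction of successive
  increments — matching B-scan-wise processing; no 2D unwrapping.
* **Strain** is the WLS slope of displacement versus depth over a
  centred axial window (default 25 µm), weights proportional to SNR²
  when an SNR map exists (uniform otherwise — the weight functional is a
  committed choice), followed by masked-normalised Gaussian smoothing
  sized so the effective FWHM resolution reaches ≈ 35 µm isotropically.
  Edge pixels whose window leaves the data are invalid, not guessed.
* **Layer stress**: mean valid strain in the compliant-layer band per
  lateral position, pushed through the tabulated stress-strain curve as
  a *stress increment about the preload operating point*,
  $\sigma(x) = g(\varepsilon_l(x) + \varepsilon_{pre}) -
  g(\varepsilon_{pre})$. Evaluating the curve at the offset strain
  without subtracting the preload stress would add the static preload
  stress to the micro-scale increment and break exact forward/inverse
  consistency whenever $\varepsilon_{pre} > 0$; the incremental (tangent)
  reading keeps zero-noise reconstruction exact and reduces to plain
  curve evaluation at zero preload.
* **Elastogram**: $E = \sigma(x)/\varepsilon(x,z)$, invalid where
  $|\varepsilon| < 10^{-5}$ (noise floor, exposed in config).
* **Peaks**: the summary "peak" is the mode of a Gaussian KDE with
  Silverman bandwidth over valid pixels per region — a reproducible
  definition for a quantity that is conventionally read off a histogram.

Zero-noise reconstruction recovers the phantom modulus map to better
than $10^{-3}$ relative error outside one smoothing support (axial
window plus the 3σ-truncated kernel, ~60 µm) of material interfaces; at
0.05 rad phase noise both KDE peaks stay within 10% of the phantom
moduli. Speckle is modelled only as additive phase noise: the
reconstruction consumes phase differences, so that is the minimal
sufficient abstraction, and full complex speckle statistics are out of
scope.

## Statistics

* Trend significance is the two-sided t-test of zero slope in an OLS
  fit.
* Group comparisons are gated on per-group Shapiro-Wilk normality at
  α = 0.05 (the gate level is unstated in the source setting): all
  normal → one-way ANOVA, otherwise Kruskal-Wallis. The branch taken and
  per-group normality p-values are recorded. Whether log-transformed
  data should re-enter ANOVA after a "lognormality" check is ambiguous;
  the package tests normality only and notes the gap.
* No multiple-testing correction is applied, matching per-comparison
  reporting.
* Growth is fit as $A(t) = A_0 e^{kt}$ by NLS from the log-linear start,
  $r^2$ on the area scale.

Type-I error of the slope test and of both comparison branches is
verified by simulation (rejection rate 0.05 ± 0.02 under each null), and
the parametric slope p-value is checked against a 10,000-shuffle
permutation oracle.

## Pipeline and reproducibility

`run_full_pipeline()` chains the stages with a single global seed fanned
out to per-stage sub-seeds by the counter scheme
`(seed + k·10007) mod (2³¹−1)`, so a stage can be re-run in isolation
and reruns are byte-identical (verified on the CSV outputs). The cohort
generator draws each spheroid's target volume *independently* of its
drawn cell count — volume varies through per-cell volume, which is the
quantity tied to stiffness — so nuclei count and spheroid volume are
uncorrelated across the cohort, reproducing the observed absence of a
count-volume trend. Cohort defaults (five bins at 2 mm spacing, per-cell
volume falling from 700 µm³ at the soft end by 15 µm³/kPa, constant
30 µm³ nuclei, marker rate 5·10⁻⁴ per µm³, 10% lognormal volume
scatter) are chosen once as a realistic-shaped, desk-scale world and not
revisited.

## What green tests do and do not establish

The synthetic generators share their forward models with the fitters
(AFM contact law, QME inversion) by design: those tests establish
self-consistency and numerical correctness, not the physical accuracy of
the committed constants. The phantoms lack deconvolution artefacts, real
PSF anisotropy and shading, OCT speckle, segmentation-confounding
debris, and realistic cell counts; printed experimental quantities that
depend on unavailable images (absolute spheroid volumes, protein-fit
r² values, measured elastogram peaks) are out of reach by construction,
and the suites instead verify the trends, calibrations and inversions
the analysis chain is responsible for.
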