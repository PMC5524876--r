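---
title: "Methods: dual-modality quantification of breast lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality quantification of breast lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionquant)
```

## Scope and model

`lesionquant` quantifies breast-cancer lesions from two co-registered
functional imaging modalities:

* **DWI-MR**: an apparent diffusion coefficient (ADC) map is computed from a
  two-point diffusion acquisition, and a *functional volume* `V_ADC` — the
  probable spatial extent of high-cellularity tumor tissue — is segmented on
  it by compartment exclusion.
* **FDG-PET**: the activity-concentration volume is converted to
  standardized uptake values (SUV), the metabolic tumor volume (MTV) is
  segmented by an adaptive threshold over a k-means background estimate, the
  mean SUV is corrected for the partial-volume effect, and total lesion
  glycolysis TLG = SUV_mean(PVC) × MTV is formed.

The MR analogue of TLG is the **total lesion diffusion**
TLD = ADC_mean × V_ADC (cm⁵/s), the integrated diffusion over the functional
volume. From each segmented volume a fixed vector of 22 features is
extracted (4 macroscopic, 14 first-order histogram statistics, 4 shape/size
descriptors), and a cohort-level univariate screen relates features to
histopathological labels (receptor status, molecular subtype, MiB-1
proliferation) and therapy response (pCR after neoadjuvant chemotherapy).

## ADC mapping

With signals $S_{low}, S_{high}$ at diffusion weightings $b_{low} < b_{high}$,

$$\mathrm{ADC} = \frac{\ln(S_{low}/S_{high})}{b_{high}-b_{low}},$$

computed voxelwise wherever both signals are strictly positive (above an
optional noise floor). Excluded voxels are *flagged invalid*, never clamped:
clamping would silently bias every downstream histogram feature. Negative
estimates (noise making $S_{high} > S_{low}$) are retained by default; a
`floor_zero` flag exists for users who prefer clipping.

**Unit convention.** Clinical ADC values in breast imaging are printed with
magnitudes of order 10²–10³ in units written "mm²/s"; physically these are
10⁻⁶ mm²/s. The package carries ADC on the printed scale throughout
(`adc_output_scale = 1e6` in `pipeline_config()`), so `ADC_mean ≈ 1100`
reads like the clinical literature, and TLD uses the unit factor
10⁻² (mm² · cm³ = 10⁻² cm⁵).

## Semi-automated V_ADC segmentation

The segmentation composes four steps, each auditable in the returned
`vadc_result`:

1. **Enhanced tissue (DCE).** Inside an operator-drawn 3-D box on the DCE
   subtraction volume, a 2-compartment 1-D k-means separates enhancing
   lesion from background; the upper cluster forms the enhanced mask. This
   replaces manual lesion contouring.
2. **Resampling.** The DCE mask is carried onto the DWI grid by
   nearest-neighbour resampling of voxel centres (the DCE grid is finer than
   the DWI grid, so this step is always exercised).
3. **b0 exclusion.** Within the region, a 3-compartment k-means on DWI b0
   intensity identifies (1) noise/fat/fibrous (low), (2) high-cellularity
   tumor (intermediate), (3) cyst/necrosis/fluid (high). The decision
   boundary between clusters 1 and 2 is the *lower cut-off*; voxels at or
   above it are kept.
4. **ADC exclusion.** Mirror step on the ADC map: the boundary between
   clusters 2 and 3 is the *upper cut-off*; voxels at or below it are kept.

`V_ADC` is the overlap of the two binary masks — a conservative exclusion of
probable non-carcinoma compartments rather than a direct classification of
tumor tissue.

### Numerical choices

* **1-D k-means.** For samples up to `kmeans_exact_n = 2048` the globally
  optimal minimum-within-variance partition is computed exactly by dynamic
  programming over the sorted values (optimal 1-D clusters are contiguous in
  sorted order). This is deterministic, seed-independent and a fixed point of
  Lloyd iteration; larger samples use Lloyd iterations from deterministic
  quantile seeding (centroid $i$ at quantile $(2i-1)/2k$) with seeded random
  restarts if a cluster empties. Exact small-sample optimisation was chosen
  over plain Lloyd because single-start Lloyd can stall in local optima even
  on a dozen points, which would make cut-offs irreproducible across
  implementations.
* **Cut-off definition.** Midpoint of adjacent sorted centroids — the
  nearest-centroid decision boundary. Voxels exactly at a cut-off are kept
  (≥ on b0, ≤ on ADC), making masks bit-reproducible.
* **Robust cut-off fitting.** Cut-offs are fitted on the central 98% of
  in-region intensities (`trim = 0.01` per end) and then applied to all
  voxels. Rationale: a handful of voxels at the DWI noise floor can carry
  enormous log-ratio ADC values; untrimmed, five such voxels can capture an
  entire cluster and displace the fluid cut-off far above the true fluid
  mode, so necrosis is never excluded. Trimming 1% per end removes this
  failure mode without touching well-behaved regions (the fit falls back to
  the full sample if fewer than three distinct values would remain).
* **Coordinates.** 1-based inclusive voxel indices (idiomatic R), world
  coordinates at voxel centres, spacing in mm. Boxes are inclusive index
  ranges.
* **No morphological post-processing** by default (no hole filling or
  smoothing of masks); an optional largest-connected-component flag exists
  for the DCE step and is off by default, matching the minimal published
  description of the procedure.

## PET quantification

SUV normalises concentration by injected dose per body weight,
$\mathrm{SUV} = C / (A_{net}/W)$, with $A_{net}$ the injected-minus-residual
activity decay-corrected from injection to scan with the ¹⁸F half-life
(109.77 min). Absent timestamps disable decay correction with a logged
warning.

MTV segmentation estimates the local background as the lower centroid of a
2-cluster k-means over the search box, then keeps the largest 26-connected
component above the adaptive threshold $T = bg + f\,(\max - bg)$. The
fraction `f = 0.41` is the common PET convention standing in for a
scanner-calibrated constant, and is exposed in the configuration; component
ties break toward higher mean SUV.

Partial-volume correction is a *surrogate* for scanner-calibrated
procedures whose internals are not public: the measured mean is divided by
the recovery coefficient (RC) of a uniform sphere with the lesion's
sphere-equivalent diameter under an isotropic Gaussian point-spread function
(default FWHM 6 mm). The blurred radial profile of a uniform sphere has a
closed form in `erf`; RC is its volume average by quadrature. RC ∈ (0, 1],
rises monotonically with diameter and decays toward 1 like FWHM/d — so even
a 20 cm sphere sits at RC ≈ 0.97, not 1. The correction never decreases a
value. SUV_max is reported pre-PVC (the correction model applies to the
mean).

## Features

Per modality the 22-feature schema is frozen: macroscopic
(MTV, SUV_mean(PVC), SUV_max, TLG | V_ADC, ADC_mean, ADC_min, TLD),
14 first-order statistics of the in-mask histogram (energy, entropy,
kurtosis, maximum, mean, mean absolute deviation, median, minimum, range,
RMS, skewness, standard deviation, uniformity, variance) and 4 shape/size
descriptors (surface area, spherical disproportion, sphericity,
surface-to-volume ratio).

* **Moments** are population moments (`sum()/n` accumulation, matching the
  definitions exactly); kurtosis is not excess-corrected. A constant sample
  has entropy 0, uniformity 1, dispersion 0, and undefined (NA) skewness and
  kurtosis.
* **Histogram** features use 64 fixed-width bins between the in-mask
  minimum and maximum (configurable). The bin policy used by published
  radiomics studies varies; it affects cross-study comparability, not
  internal consistency.
* **Surface area** comes from a triangulated 0.5-level isosurface extracted
  by marching tetrahedra. The binary mask is first anti-aliased with a
  Gaussian of 0.7 voxels: meshing the raw binary staircase overestimates a
  digital sphere's area by ~9% (sphericity 0.91), while the anti-aliased
  surface is within ~1–2% of the analytic value for radii ≥ 8 voxels. If
  smoothing would melt a thin structure below the iso-level (e.g. a
  one-voxel-thick shell on a coarse PET grid), the raw binary surface is
  used instead. A voxel-face-counting mode (`surface_mode = "faces"`) is
  exact for axis-aligned blocks. Sphericity and spherical disproportion are
  algebraic reciprocals; both are reported because both appear in the
  feature catalogue.

## Statistical screen

The screen is deliberately **uncorrected** for multiplicity — it mirrors an
exploratory, hypothesis-forming design; a Benjamini–Hochberg option exists
but is off by default and labelled an extension. Tests are two-sided, with
average ranks for ties:

* binary labels (ER+/ER−, PR, triple-negative vs other, pCR):
  Mann–Whitney, exact enumeration of all labelings for total n ≤ 12 (valid
  under ties), tie-corrected normal approximation with continuity
  correction otherwise;
* four-class molecular subtype: Kruskal–Wallis (tie-corrected H,
  χ² reference);
* continuous pairs (MiB-1 index, matched PET–MR features): Spearman rank
  correlation, exhaustive permutation p for n ≤ 9, t approximation
  otherwise. MiB-1 is treated as continuous because dichotomising at its
  laboratory cut-off (18%) leaves an unbalanced split.

Comparisons whose groups have fewer than two members are skipped with an
explicit warning. The subtype classifier is rule-based: hormone-receptor
positivity means expression > 0%; Luminal A/B split on c-erbB-2 status;
triple-negative and HER2+ are the hormone-negative classes.

Calibration of the implementations is checked by simulation in the test
suite: at the large-sample branches (Mann–Whitney 50 vs 48, Kruskal–Wallis
three groups of 20, Spearman n = 40) null p-values pass a
Kolmogorov–Smirnov uniformity test at 10⁴ replicates and the empirical
type-I error at α = 0.05 stays within [0.04, 0.06]. At small n the discrete
support of the rank statistics makes p-values conservative in a way no
continuity-correction choice removes; that is a property of rank tests, not
of this implementation, and the exact branches handle the very small
samples.

## The synthetic phantom

No patient data ship with the package; every stage is validated on
synthetic multimodal studies with known ground truth.

A lesion is a sphere (optionally a volume-preserving ellipsoid) embedded in
background, partitioned into three concentric compartments — fluid core,
high-cellularity tumor shell, fat/fibrous rim — with volume fractions
defaulting to 0.2 / 0.6 / 0.2. The published compartment model does not
state proportions, so these were fixed once as a plausible rim-enhancing
lesion with a necrotic core. Signal orderings follow the compartment model
and are validated at configuration time: on DWI b0 and ADC,
fibrous < tumor < fluid; on DCE subtraction, all compartments enhance above
background.

* The DWI pair satisfies the decay law
  `b900 = b0 · exp(−Δb · ADC · 10⁻⁶)` *exactly* before noise, so the ADC
  module must invert the generator to machine precision on noise-free
  phantoms.
* ADC ground truth adds per-compartment biological spread (σ = 30/60/100
  printed units) on top of the compartment means — this drives realistic
  histogram heterogeneity (entropy, uniformity) and is the dial used by
  cohort effect injection.
* Measurement noise is additive Gaussian per modality (Rician available
  behind a flag for the DWI magnitude volumes); defaults (DCE 2, DWI 3, PET
  0.15 SUV) are 2–3% of the respective compartment contrasts.
* Grids mimic the acquisition geometry: DWI 48×48×24 at 1.4×1.4×3 mm, DCE
  finer at 0.84×0.84×2.5 mm covering the same field of view (so mask
  resampling is always exercised), PET 4 mm isotropic with its own origin.
* Default PET metadata: 70 kg patient, 259 MBq injected (3.7 MBq/kg),
  2 MBq residual, 60 min uptake.

Cohorts draw lesion diameters from a log-normal (median ≈ 1.4 cm) truncated
to the admissible 0.61–3.88 cm range, and clinical labels at fixed
prevalences (Luminal A 24%, Luminal B 21%, HER2+ 13%, triple-negative 42%;
MiB-1 ≥ 18% in 81%; pCR 42%) allocated deterministically up to rounding.
ER/PR percentages are drawn so the subtype classifier reproduces the sampled
subtype exactly. `effect_spec` injects label-linked effects at the *image*
level (e.g. doubling intra-tumor ADC spread for pCR-positive lesions raises
MR entropy downstream); with no effects, feature distributions are identical
across label groups by construction.

**What the phantom does not emulate:** MR coil profiles and EPI distortion,
DCE pharmacokinetics, PET reconstruction artefacts, partial-volume mixing at
compartment boundaries (voxels take the compartment of their centre), and
anatomically realistic lesion shapes. Passing tests therefore demonstrate
the internal consistency and calibration of the pipeline under its own
generative model, not clinical performance on patient data.

## Problem sizes used in validation

The validation suite and the acceptance script run, per invocation: one
full dual-modality pipeline for the structural feature counts; noise-free
phantoms for the ADC round trip; 20 seeded default phantoms for
segmentation recovery (Dice against the true tumor compartment, plus the
mask-chain invariant `V_ADC ⊆ b0-mask ⊆ region`); 100 random samples for
the first-order oracle and 100 ≤ 12-point samples for exhaustive k-means
verification; 10⁴ null replicates per statistical test; and a 38-lesion
synthetic cohort for the cohort-level functional-volume regression. These
sizes were chosen to make Monte-Carlo error small relative to every
tolerance tested while keeping a full run in well under a minute per
component.

## Known limitations

* The PVC surrogate assumes a uniform sphere and an isotropic Gaussian PSF;
  it is a documented stand-in, not a reproduction of scanner-calibrated
  corrections.
* The MTV threshold fraction (0.41) is a convention, not a per-scanner
  calibration.
* Nearest-neighbour mask resampling is adequate for the ≤ 2× grid ratios it
  is used at, but is not a registration method.
* The screen reports uncorrected p-values by design; any confirmatory use
  requires the BH option (or stronger) and larger cohorts.
* DICOM input is not supported; volumes must be NIfTI.
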