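---
title: "Reference-tissue relative thresholds for FLT PET lesion segmentation"
author: "fltseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-tissue relative thresholds for FLT PET lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fltseg)
```

## The problem

[18F]fluorothymidine (FLT) PET/CT images cellular proliferation and is a
candidate replacement for FDG in monitoring diffuse large B-cell lymphoma
(DLBCL), where post-therapy inflammation inflates FDG's false-positive rate.
Computing the metabolic tumour volume (MTV) from FLT scans requires
segmenting lesions, and segmenting lesions requires an SUV threshold. A
fixed absolute threshold travels poorly across patients and treatment
stages; this package implements a *reference-tissue-normalized* threshold:
the cutoff for "pathologic" uptake is expressed as a percentage of each
patient's own liver or bone-marrow uptake, in the spirit of the PERCIST
convention of normalizing to the liver.

The pipeline runs in five conceptual stages, each exposed as package
functions and exercised end to end by `run_full_analysis()`:

1. **Reference VOI quantification.** Liver uptake is the mean SUV in a
   sphere (29, 41 or 48 mm diameter; 29 mm is the default because it is
   closest to the PERCIST sphere) placed in hepatic segment VIII. Bone
   marrow uptake is the mean SUV in vertebrae delineated on CT by Hounsfield
   units (T12 by default; L3 and pooled T10–T11–T12 as alternatives). Each
   VOI also yields the within-VOI voxel standard deviation, used by the
   stricter criteria below.
2. **Stability and normal ranges.** A one-way fixed-effects ANOVA of the
   per-stage means checks that the reference uptake is stable along
   treatment (baseline, interim "iPET", end-of-treatment "fPET"). The
   *normal range* of each tissue is the pooled mean ± 1 SD over every
   patient-stage measurement. A scan is *eligible* for a tissue whenever its
   uptake lies within that tissue's range (inclusive bounds); the selection
   rule prefers liver, falls back to marrow, and otherwise excludes the
   scan.
3. **Minimum relative threshold.** For each stage, with
   $\mathrm{SUV}_{\min}^{j,i}$ the minimum SUV of manually reported lesion
   $i$ of patient $j$ and $\mathrm{SUV}_{\mathrm{ref}}^{j}$ the patient's
   reference uptake,
   $$\mathrm{RT} = \frac{1}{N_{\mathrm{stage}}} \sum_{i,j}
   \frac{\mathrm{SUV}_{\min}^{j,i}}{\mathrm{SUV}_{\mathrm{ref}}^{j}},$$
   the unweighted mean of ratios over all eligible lesions of the stage.
4. **Criteria and the reformulated threshold.** The per-patient absolute
   threshold under criterion $n{+}1$ is
   $\mathrm{RT}\,(\mathrm{SUV}_{\mathrm{ref}} + n\,\mathrm{SD}_{\mathrm{ref}})$
   with $n = 0, 1, 2$. For reporting, the SD term is folded back into a
   single multiplier of the plain reference uptake,
   $$\widetilde{\mathrm{RT}} = \frac{\mathrm{RT}}{N_{\mathrm{pat}}} \sum_j
   \frac{\mathrm{SUV}_{\mathrm{ref}}^{j} + n\,\mathrm{SD}_{\mathrm{ref}}^{j}}
        {\mathrm{SUV}_{\mathrm{ref}}^{j}},$$
   which reduces to RT exactly at $n = 0$ and is strictly increasing in $n$
   whenever any SD is positive. Both identities are enforced by tests.
5. **Segmentation.** Voxels with SUV *strictly* greater than the patient's
   absolute threshold, outside a physiological-exclusion mask, are labelled
   into 26-connected components; a reported lesion counts as detected when
   at least one of its voxels is foreground, and MTV is the summed component
   volume.

## What the synthetic cohort emulates

No clinical scans ship with the package; every analysis runs on a synthetic
phantom cohort from `cohort_spec()` / `generate_scan()`. The generator's
defaults are the study conditions the methodology was developed under:

* inter-patient reference uptake: liver $5.1 \pm 1.4$ SUV, bone marrow
  $7.8 \pm 2.7$ SUV (Gaussian, truncated at 0.5 SUV since SUV is positive);
* three stages with *zero true drift* by default — the stability finding —
  switchable via `stage_drift` to verify the ANOVA actually detects drift
  (see `analysis/05_recovery_and_drift.R`);
* lesion burden falling along treatment (4 / 2 / 1 lesions per patient at
  baseline / iPET / fPET), mirroring the observed thinning of lesion counts;
* lesion minimum SUV planted as a controlled fraction of the patient's
  reference uptake, defaulting to $0.49 / 0.33 / 0.24$ of liver uptake per
  stage — the published minimum relative thresholds, so the pipeline's
  estimates should land on these values;
* within-VOI voxel noise as a multiplicative CV, defaulting to
  `c(liver = 0.13, marrow = 0.25)`. These are the within-VOI relative SDs
  *implied* by the ratio of published final to minimum thresholds
  (e.g. baseline liver $62/49 = 1 + 2\,\mathrm{SD}/\mathrm{SUV}$ gives
  $\mathrm{SD}/\mathrm{SUV} \approx 0.13$), i.e. the noise level at which
  the criterion arithmetic reproduces the published tables;
* anatomy: a liver ellipsoid large enough to contain the 48 mm sphere VOI,
  an axis-aligned vertebral column (T10–T12 high, L3 low) at 300 HU against
  40 HU soft tissue and a −1000 HU air border, and a bladder-like hot
  sphere (SUV 12) recorded in the physiological ground-truth mask.

Lesions are axis-aligned ellipsoids (diameters drawn uniformly from
8–25 mm) with a centre plateau falling linearly to the target minimum at
the rim; the rim-most rasterized voxel is pinned to the target so the
planted minimum is exact, and lesion voxels are written after the noise
field so the minimum stays controlled. Placement is rejection sampling with
a 3 mm guard margin against all organs, the air border and previously
placed lesions (≥ 2 voxel gap, so lesions never merge at 26-connectivity).

**What the phantom does not emulate** — and hence what passing tests do
*not* establish about clinical data: scanner point-spread blur and partial
volume effects (the published discussion identifies partial volume as the
likely cause of the falling threshold along treatment; our generator takes
the fractions as given rather than reproducing their cause), reconstruction
artefacts, attenuation/scatter residuals, respiratory motion, CT noise,
anatomical variability, and correlated liver/marrow physiology. Cohort
numbers computed here (thresholds, detection rates, MTV) characterize the
pipeline's correctness, not any patient population.

## Numerical and design choices

* **Two SD conventions.** The within-VOI SD uses the population divisor
  $N$ (the VOI is the complete set of voxels measured; criteria 2/3 use it
  as a spread scale), with a `sd_type = "sample"` switch. The cohort-level
  normal-range SD uses $N-1$ (a sample estimate of inter-patient spread).
* **Sphere/ellipsoid membership by voxel centre**, so masks and thresholds
  are bit-stable for a given grid; the 29 mm sphere's voxel count converges
  to $(\pi/6)d^3$ as spacing shrinks (tested at 2, 1, 0.5 mm).
* **Strict inequality** for pathologic voxels ("higher than"); threshold-equal
  voxels are background.
* **26-connectivity** for lesion labelling (6 available), with deterministic
  label order: descending size, ties by smallest linear seed-voxel index.
* **Inclusive normal-range bounds**: boundary patients stay eligible.
* **Eligibility**: lesions of out-of-range patients are dropped from RT with
  a logged count; the $N_{\mathrm{pat}}$ average in the reformulated
  threshold runs over in-range patients of the stage, including lesion-free
  ones (their scans exist and their thresholds are defined).
* **Equal lesion weights** in RT regardless of how many lesions a patient
  contributes (the sum runs over lesions, not patients).
* **Criterion selection is configuration**, defaulting to criterion 3 at
  baseline, 1 at iPET, 2 at fPET. The selection originally came from
  qualitative expert review of lesion boundaries, which no automatic score
  replaces; the package therefore treats it as an input.
* **Displayed percentages round half up** to whole per cent; all
  computation keeps full precision.
* **Vertebral delineation** takes HU in $[150, 1500]$ (configurable; the
  published method cites HU-based delineation without numbers), keeps the
  largest 26-connected component and fills interior holes, delineating the
  whole vertebral body; an interior-only variant would erode cortical bone
  first, and the HU floor is exposed precisely because this choice is open.
* **SUV conversion** assumes the scanner already decay-corrected the
  reconstruction; `to_suv()` is the plain body-weight formula
  $C\,[\mathrm{kBq/ml}] \times w\,[\mathrm{kg}] / A\,[\mathrm{MBq}]$ and the
  package neither applies nor removes decay correction.
* **Resampling direction**: statistics are always taken on native PET
  voxels; CT (trilinear) and CT-drawn masks (nearest neighbour) are brought
  to the PET grid, never the reverse. Oblique NIfTI orientations are
  rejected rather than silently reoriented.
* **Degenerate ANOVA** (every group constant) returns $p = 1$ for equal
  means and $p = 0$ otherwise instead of 0/0.
* **Reproducibility**: one master seed feeds derived sub-streams (patient
  draws, per-scan noise, summary jitter), so any scan can be regenerated
  standalone, in any order, bit-identically; rerunning the pipeline with the
  same seed reproduces its CSV tables byte for byte.

### Cross-tissue planting

A single planted lesion minimum cannot be a fixed fraction of *both* liver
and marrow uptake at once, so `lesion_reference_tissue` selects which
tissue the fraction refers to (default liver). Parameter-recovery checks
therefore run once per tissue, each on a cohort planted against that
tissue. A side effect of liver-planted defaults is that marrow-relative
thresholds are smaller (roughly by the liver/marrow uptake ratio) and, for
patients with low marrow uptake, criterion-1 marrow thresholds can approach
the soft-tissue background, producing small false-positive components —
realistic behaviour for a threshold near background, and visible in the MTV
columns of the detection table.

## Problem sizes and runtimes

The shipped default analysis simulates 16 patients × 3 stages on a
64 × 64 × 80 grid at 3 mm isotropic spacing (≈ 0.33 M voxels per volume),
streaming scans one at a time in two passes (measurement, then
segmentation) so memory stays below a few hundred MB; a full run takes
about half a minute on one core. Pipeline-level tests use a coarser
44 × 44 × 60 grid at 4 mm. Statistical calibration checks use 2000 null
ANOVA replicates (3 stages × 15 patients); parameter recovery uses 30
patients and 100 lesions. Geometry checks run at 1 mm spacing on small
grids.

## Worked example

```{r example, eval = FALSE}
library(fltseg)

cfg <- default_run_config(out_dir = "flt_run", seed = 1)
res <- run_full_analysis(cfg)

res$normal_ranges$liver
#> liver normal uptake range: 5.1 +/- 1.3 SUV -> [3.84, 6.37] (n = 48)
res$threshold_table[, c("stage", "tissue", "rt_pct", "final_pct")]
#> baseline liver 49 61; iPET liver 33 33; fPET liver 24 27; ...
```

The liver row reads: at baseline a voxel is pathologic when its SUV exceeds
61 % of the patient's liver uptake (criterion 3 folded into one multiplier);
at iPET, 33 % (criterion 1); at fPET, 27 % (criterion 2). The estimated
minimum thresholds recover the planted fractions 49/33/24 %.

## Known limitations

* The phantom's idealizations listed above; in particular, no partial-volume
  modelling, so the package cannot reproduce *why* thresholds fall along
  treatment, only the estimation machinery.
* Automatic anatomical localization (liver segment VIII, vertebra labels) is
  out of scope; sphere centres and vertebra search boxes are inputs.
* Matching of merged segmented components to reported lesions uses ≥ 1 voxel
  of mask overlap; many-to-one merges are logged, not disambiguated.
* Only body-weight SUV is implemented (no lean-body-mass or BSA variants),
  and DICOM series handling is out of scope (NIfTI only).
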