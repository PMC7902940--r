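---
title: "Methods: IHC thresholding, Jacobian volumetrics and factorial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IHC thresholding, Jacobian volumetrics and factorial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoquant)
```

# Scope

`morphoquant` implements the quantitative core of a paired
histology-plus-imaging mouse study design: brightfield immunohistochemistry
(IHC) quantified against a per-image background model, deformation-based
morphometry (DBM) on Jacobian-determinant maps, and a uniform two-way
sex × genotype ANOVA for group comparison. Registration, atlas construction
and acquisition are upstream of this package and out of its scope: it starts
from section images plus ROI masks, and from a label atlas plus per-subject
Jacobian maps.

# The IHC quantification model

Chromogenic staining on sections that spent weeks in fixative with contrast
agent shows a strong, bright, roughly unimodal background. The method
assumes exactly that:

* the **whole-image histogram mode** of the 8-bit gray values is an estimate
  of the background staining level (stained pixels are a minority, so they
  do not displace the mode);
* true signal is **darker** than background (a dark red-brown precipitate on
  a bright field);
* background spread is summarized by the **whole-image standard deviation**.

The per-picture threshold is `mode − k·SD`, with `k` fixed per antibody
across the entire series (MBP 2, GFAP 2.5, Iba1 3; `compute_threshold()`
accepts either the antibody name or a numeric override). Pixels at or below
the threshold are positive; per-ROI positive area is reported as a
percentage of ROI pixels. For markers that label discrete somata (GFAP,
Iba1), connected positive components with area strictly greater than 250 px
are counted as cells.

Statistics are always computed over the **entire picture**, never per ROI:
the threshold models the image-wide background, and one threshold is shared
by all ROIs of a picture.

Decisions the method description leaves open, fixed here and covered by
tests:

* **Polarity and inclusiveness.** Positive ⇔ `gray ≤ T`. A pixel exactly at
  the threshold is marked by it.
* **Mode tie-break.** Among equally frequent gray levels the *highest*
  (brightest) is taken, because the mode stands in for the bright
  background.
* **SD definition.** Population SD (divide by N), the convention of
  image-analysis descriptive statistics.
* **RGB → 8-bit.** Unweighted channel mean, rounded half up — the common
  default conversion, chosen over luminance weighting because no weighting
  was documented in the workflow being reproduced.
* **Connectivity.** 8-connectivity by default (diagonal pixels of a blob
  belong together); 4-connectivity is a switch on `count_objects()`.
* **"Above 250 pixels"** is read strictly (`area > 250`); a 250-px component
  does not count. The 225/256-px boundary is pinned by tests.
* **Threshold clamping** to [0, 255]: gray values are bounded, and a mode
  low enough to push `mode − k·SD` negative simply makes everything
  positive-eligible down to 0.
* Whether the size filter applies per ROI or per image is not documented;
  it is applied **per ROI** here (counts are reported per ROI).

# The DBM volumetrics model

The Jacobian determinant `J_s(v)` of the deformation carrying subject *s*
to atlas space is the local volume-change factor at voxel *v*. For a
structure *S* of the label atlas,

```
V_s(S) = sum over v in S of J_s(v) * h^3        (h = voxel edge, mm)
```

and the whole-brain volume is the same sum over all labels > 0. Because
global brain size varies with body growth, relative volumes
`V_s(S)/V_s(brain)` are the primary group-comparison quantity; they are
shares of a partition and sum to 1 per subject.

Voxel-wise inference fits, **separately within each sex**, a linear model
with an intercept and a genotype indicator at every brain voxel and reports
the genotype-contrast t on `n − 2` df. With one binary covariate this is
algebraically the pooled-variance two-sample t test, which the test suite
uses as an independent closed-form oracle (agreement to 1e-10). FDR is
controlled with Benjamini–Hochberg at `level = 0.01` across brain voxels,
within each sex stratum.

Choices made where the upstream description is silent:

* **Response scale.** Log-Jacobians by default: expansion and contraction
  are treated symmetrically and group effects become additive shifts.
  `scale = "raw"` is available.
* **Brain restriction.** Statistics run on atlas labels > 0 only; voxels
  outside the brain carry no hypothesis and would only dilute the FDR
  budget.
* **Zero-residual-variance voxels** (possible with constant synthetic
  input) get `t = NA`, are excluded from the BH pool, and are counted in
  `n_undefined` and in the pipeline run log — fabricating infinite t
  statistics would corrupt the FDR step.
* **No spatial smoothing** is applied; none was described. Voxel
  independence in the simulations is therefore the best case for BH, which
  is also valid under positive dependence.
* **Structure-level tests** use the same per-sex genotype-contrast model on
  per-subject *relative* volumes and are reported with uncorrected p plus
  BH q across structures — both conventions (corrected voxel maps,
  uncorrected structure tables) coexist in this study design, so both are
  emitted.

# The factorial analysis

`two_way_anova()` fits `response ~ sex * genotype` and reports F and p for
the two main effects and the interaction with **Type II sums of squares**
(via `car::Anova`). The cohorts are nominally balanced (n = 6 per cell), in
which case Type I, II and III coincide — a property the tests assert — and
Type II degrades most gracefully once an exclusion unbalances a cell.
Per-region analyses (`batch_anova()`) apply no across-region multiplicity
correction, matching the reporting convention of per-region p values; this
is a deliberate caveat, not an oversight. Post hoc exploration is limited to
the two within-sex genotype contrasts with Welch t
(`pairwise_genotype_welch()`).

# What the synthetic generators emulate

`simulate_ihc_image()` draws background pixels from a rounded, clamped
Gaussian and plants darker discs at a requested areal fraction, returning
the exact mask. Defaults encode the study conditions at desk scale:

| parameter | default | rationale |
|---|---|---|
| `background_level` | 200 | bright field with elevated background |
| `noise_sd` | 5 gray levels | modest unimodal background spread |
| `signal_offset` | 100 | dark chromogen; well separated (≥ 5·noise SD) |
| `signal_fraction` | 0.10 | plausible stained share of an ROI |
| `object_area_px` | U[120, 400] | blob areas straddling the 250-px filter |
| `image_shape` | 256 × 256 | desk scale; native 1920 × 2560 via params |

Blob placement is rejection sampling of non-overlapping discs, with overlap
permitted only once non-overlapping placement becomes infeasible; the
achieved fraction overshoots the target by less than one blob. The Gaussian
background is a modeling convenience — nothing is claimed about the actual
noise law of chromogen staining — and the generator reproduces **none** of:
uneven illumination, optics/PSF blur, RGB color chemistry, partial staining
gradients, or anatomically shaped ROIs. Passing recovery tests therefore
demonstrates correctness of the *method implementation* under its own
assumptions, not robustness to real-tissue artifacts.

`simulate_morphometry_cohort()` builds a deterministic atlas (spherical
brain inscribed in the grid, small cubic structures on a lattice, a
`rest_of_brain` complement so labels > 0 partition the brain) and gives
each subject `log J = planted effect + N(0, subject_noise_sd²)` i.i.d. per
voxel, exponentiated so Jacobians are strictly positive by construction.
Defaults: 32³ voxels, 20 structures, `voxel_size` 0.05 mm (the 50-µm
acquisition resolution), noise SD 0.05; the native regime (182 structures)
is reachable through the parameters. Planted log-volume shifts apply to KO
subjects; the returned truth table integrates each subject's noiseless
field, so a `log(1.1)` shift is exactly a 10% volume ratio. Real Jacobian
fields are spatially smooth and registration-biased; i.i.d. voxel noise is
deliberately the cleanest case for verifying the statistics.

The cohort layout is 2 sexes × 2 genotypes × n = 6, one section per animal
per area, with support for excluding subjects (the packaged pipeline drops
one WT male from the morphometry arm, leaving an 11-subject male stratum
and `df = 9` contrasts, as happens when a scan fails quality control).

# Numerical and reproducibility choices

* All generators consume an explicit integer seed and restore the caller's
  RNG state; identical parameters + seed give bit-identical images, maps
  and tables, which the pipeline test asserts by comparing written CSVs of
  two runs.
* Connected components are computed on the pixel-adjacency graph
  (`igraph::components`); the test suite checks equality with a literal
  flood-fill on random blob and noise masks for both connectivities.
* BH adjustment uses `stats::p.adjust(method = "BH")` behind `fdr_bh()`,
  with NA p values excluded from the pool; a literal step-up scan is the
  test oracle.
* The vectorized voxel-wise least squares marks a voxel undefined when its
  residual sum of squares is ≤ 1e-24 relative to the response scale.
* Pipeline outputs are traceable: the written `config.json` is md5-hashed
  and the hash recorded in `run_log.txt` and `run_info.json` next to the
  tables, rather than stamped into every CSV.

# Problem sizes used in the checks

The packaged analyses and tests run at desk scale, chosen once as
representative: 256×256 sections (50 for threshold-recovery scoring),
100 random 128×128 masks for the counting oracle, 200 replicate 20³-voxel
null cohorts for the FDR-control estimate, 500 replicates for ANOVA null
calibration, 100 replicates for planted-effect ranking, and a 24-section /
23-subject / 20-structure end-to-end run. At these sizes the FDR-control
estimate has binomial SD ≈ 0.7 percentage points around the 1% target.

# Known limitations

* The IHC background model is global per image; strong illumination
  gradients would bias a single mode/SD pair, and no field correction is
  provided.
* Mode estimation on very noisy, small images is discrete and can wander a
  gray level or two among near-tied bins; the generators' background checks
  treat the ±1 claim statistically (median over seeds).
* The voxel-wise model has no spatial component; neighboring voxels are
  modeled independently.
* Percent-area and count measurements are reported without µm² calibration
  beyond the documented ≈ 20 µm² equivalence of the 250-px filter.
* Structure-level and voxel-level inferences are both provided but not
  reconciled into a single hierarchical model; they answer different
  questions at different resolutions.
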