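---
title: "Methods: locus coeruleus neuromelanin quantification and permutation inference"
author: "lcnm package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: locus coeruleus neuromelanin quantification and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcnm)
```

## What the package measures

The locus coeruleus (LC) is a thin noradrenergic nucleus in the dorsal
pons whose neurons accumulate neuromelanin.  Paramagnetic
neuromelanin-iron complexes shorten T1, so the LC appears as a small
hyperintense streak on neuromelanin-sensitive fast-spin-echo MRI.  The
package quantifies LC integrity as the *neuromelanin contrast ratio*

$$\mathrm{contrast} \;=\; \frac{\bar I_{\mathrm{LC}} - \bar I_{\mathrm{bg}}}{\bar I_{\mathrm{bg}}},$$

where $\bar I_{\mathrm{LC}}$ is the mean intensity of the five brightest
connected voxels inside a search ROI and $\bar I_{\mathrm{bg}}$ is the
mean intensity of a background ROI in the central pons.  The search ROI
is divided by two axial planes into three equal rostro-caudal thirds
(rostral, middle, caudal), and left and right contrasts are averaged per
third.  Downstream, the package compares these contrasts across groups
(healthy controls, multiple system atrophy, Parkinson's disease) with a
permutation ANCOVA, correlates them with cognition (MoCA), and maps
associations between smoothed FDG-PET SUVR images and scalar regressors
with cluster-extent family-wise-error (FWE) correction.

Because the motivating study's participant images are not publicly
deposited, validation rests entirely on synthetic phantoms with known
ground truth.  Every stage is exercised end to end on those phantoms.

## The measurement chain

### Slice normalization

Multi-slice FSE acquisitions show multiplicative slice-to-slice
intensity drift.  `normalize_slices()` rescales each axial slice by
(global in-mask mean)/(slice in-mask mean), which removes any
per-slice gain exactly while preserving the global in-mask mean.  The
normalization mask should exclude the hyperintense structure being
quantified: scaling against a mask that contains the LC would make the
correction signal-dependent and bias the contrast.  The phantom
generator therefore emits a brain mask with the search-ROI territory
(plus a one-voxel margin) carved out, and uses the same in-plane mask on
every slice so that, in the noiseless limit, gain correction is exact to
machine precision.

### Tri-section

`trisect_roi()` partitions the search ROI by axial slice index into
three contiguous blocks, superior block = rostral.  When the slice count
is not divisible by three the remainder is assigned rostral-first (8
slices give 3/3/2).  The reference procedure divides an ROI whose slice
count is divisible by three, so any consistent tie-break is admissible;
the rule is fixed, documented, and tested.

### Five brightest connected voxels

The target set is defined as the connected subset of five voxels inside
the (sub-)ROI that maximizes mean intensity; connectivity defaults to
the 26-neighbourhood.  `extract_brightest_connected()` finds the exact
maximizer by branch-and-bound enumeration of connected subsets: subsets
are grown in brightness-rank order, and a partial subset is pruned when
its sum plus the largest remaining intensities cannot beat the
incumbent (initialized by greedy growth from the ten brightest seeds).
Sub-ROIs hold tens of voxels, so the exact search costs milliseconds.  A
pure `method = "greedy"` variant is provided for comparison; the exact
method is the default and is verified in the tests against brute-force
enumeration of all connected five-subsets on random ROIs.  If an ROI's
largest connected component holds fewer than five voxels the extraction
uses what is available and flags the result `undersized`.

### PET SUVR and smoothing

`compute_suvr()` divides every voxel by the median uptake of a
reference region (an occipital-like region in the phantom), making the
in-reference median exactly 1.  `smooth_gaussian()` applies a separable
Gaussian with $\sigma_{\mathrm{axis}} = \mathrm{FWHM} / \sqrt{8\ln 2} /
\mathrm{voxelsize}_{\mathrm{axis}}$ (8 mm FWHM by default,
$\sigma \approx 3.397$ mm).  Kernels are truncated at $4.5\sigma$
(relative truncation error below $10^{-5}$) and boundaries are handled
by reflection, which preserves total image intensity; both properties
are asserted in the tests.  Partial-volume-effect correction is not
implemented: the statistics in the reference procedure use
non-PVE-corrected images.

## Inference

### Permutation ANCOVA and post hocs

Group effects on each sub-regional contrast are tested with an
ANCOVA-type linear model (group factor plus age covariate) evaluated by
the Freedman-Lane permutation scheme: residuals of the reduced
(covariate-only) model are permuted, the reduced fit is re-added, and
the partial F for the group factor is recomputed.  This is the standard
scheme for GLMs with nuisance regressors and is what general-purpose
permutation GLM tools implement by default.  P-values use the add-one
estimator $(1+b)/(1+m)$, so they are never zero; when the number of
distinct relabelings (or of raw permutations, $n \le 10$, when a
covariate is present) does not exceed `n_perm`, the implementation
switches to exhaustive enumeration and reports the exact fraction.

Significant omnibus tests are followed by six one-tailed pairwise
contrasts (HC>MSA, HC<MSA, HC>PD, HC<PD, MSA>PD, MSA<PD) sharing one
permutation null.  Family-wise error is controlled with Bonferroni:
$p_{\mathrm{FWER}} = \min(1, 6p)$.  The source description of the
correction ("dividing p values by the number of tests") is interpreted
as the standard operation of dividing the *significance level* by the
number of tests — literally dividing p-values would be anti-conservative
and is inconsistent with corrected p-values being larger than
uncorrected ones.

### Correlations and descriptives

`spearman_corr()` computes rho as the Pearson correlation of mid-ranks
(tie-aware).  For $n \le 9$ by default (supported to $n = 10$) the
p-value is exact, from full enumeration of all $n!$ rank permutations;
beyond that the usual $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ approximation is
used.  Homogeneity of variance uses the Brown-Forsythe variant of
Levene's test (one-way F on absolute deviations from group medians).
Demographics use Kruskal-Wallis (age), chi-square without continuity
correction (sex), and Mann-Whitney U (two-group clinical scores), all
via the corresponding base-R tests.

### Voxel-wise mapping and cluster FWE

`voxelwise_glm()` fits, per voxel, a simple regression of SUVR on one
scalar regressor (MoCA or rostral LC contrast) and returns the slope t
map with $n-2$ degrees of freedom.  `cluster_fwe()` thresholds the map
at a one-tailed cluster-forming level (0.001 primary, 0.01 exploratory),
labels connected components (18-neighbourhood by default, the SPM
convention), and builds the permutation null of the *maximum cluster
extent* by relabeling the regressor across subjects — the Freedman-Lane
scheme with an intercept-only nuisance model reduces to exactly this.
Each observed cluster gets $p_{\mathrm{FWE}} = (1 + \#\{M^{*} \ge
s\})/(1+m)$.  Random-field theory is deliberately out of scope; the
permutation approach needs no smoothness estimation and is exact up to
Monte-Carlo error.  Peak coordinates are reported in voxel indices and
in mm relative to the first voxel; no atlas lookup is attempted.

## The phantom generator

`generate_cohort()` builds, per subject, a pontine-slab phantom
(default $32 \times 32 \times 16$ voxels at $0.5 \times 0.5 \times
2.5$ mm):

* two straight axial **LC tubes** spanning 9 slices.  The tube axis sits
  midway between two voxel columns, so the default 1-voxel radius gives
  a 2-voxel in-plane cross-section (1 mm, about the width of the LC)
  and each tri-section third holds six tube voxels.  This geometry was
  chosen deliberately: extracting the five brightest connected voxels
  from a pool of six nearly equal ones keeps the selection bias of the
  order statistics small (about $0.25\sigma$), whereas a 5-voxel
  cross-section per slice (15 per third) would bias the recovered
  contrast upward by roughly a full noise SD.  Tube intensity per third
  is `background_mean * (1 + true contrast)`.
* per-subject **true contrasts** drawn as group mean plus between-subject
  variation (`contrast_sd`, default 0.05, drawn independently per side).
  Group means default to 0.30/0.25/0.20 (rostral/middle/caudal) in
  controls with patient reductions concentrated in the middle and caudal
  thirds for MSA (-30% both) and the middle third for PD (-15%),
  consistent with the qualitative pattern of the motivating study; the
  study does not publish per-group contrast values, so these are
  configuration choices, not reference values.
* **noise and drift**: additive Gaussian noise (`noise_sd`, default 2%
  of background) scaled by $1/\sqrt{n_{\mathrm{acq}}}$ to represent
  averaging of three co-registered acquisitions (co-registration itself
  is out of scope), then multiplicative per-slice gains drawn from
  (0.9, 1.1).  Noise is Gaussian, not Rician — at contrast-to-noise
  levels of 10 and above the difference is immaterial for testing the
  pipeline.
* **ROI set**: search ROIs (tube dilated by one voxel in-plane),
  background ROI between the tubes matching the tubes' slice extent,
  the normalization brain mask described above, an occipital-like
  reference region, and a gray-matter-like analysis mask for voxel-wise
  statistics (the outer 40% annulus of the brain disc over the upper
  two-thirds of slices — a cortical-ribbon-like search volume that
  excludes the pontine structures and the reference region).
* a **cognition model**: a latent score loads on the standardized
  rostral contrast (loading 0.8 by default, chosen so the within-MSA
  rank correlation between rostral contrast and MoCA is about 0.7, the
  order of magnitude the study reports) plus independent noise; raw
  MoCA is `round(26 + 2.5 * score)` clamped to 0-30.  The education
  adjustment (+1 if 12 or fewer years, capped at 30 per standard MoCA
  instructions) is applied at analysis time.
* **PET volumes** for the MSA-like group: uniform baseline uptake with a
  planted spherical "frontal" cluster (default radius 3 voxels, i.e.
  about 9 mm at PET resolution, the scale of the study's reported
  cluster) whose amplitude is `baseline * (1 + a * score)`, plus
  Gaussian noise.  The reference region is disjoint from the cluster,
  so SUVR scaling is independent of the score.

Everything is deterministic given `seed`; volumes, masks, covariates and
the ground-truth sidecar are written as NIfTI-1 / TSV / YAML by
`run_simulation()`.

### What the phantom does *not* emulate

Scanner physics, motion, Rician noise, curved LC geometry, template
registration and inverse-warping of atlas ROIs, PET reconstruction and
partial-volume effects are all absent.  Passing tests therefore
demonstrate that the measurement and inference chain is correct *given*
well-posed inputs in a common space; they say nothing about registration
quality or acquisition artifacts in real data.

## Numerical choices and problem sizes

* Exact extraction prunes at tolerance $10^{-12}$; ties in mean
  intensity are resolved arbitrarily among equal-mean subsets (only the
  mean enters the contrast).
* Permutation p-values compare statistics at a relative tolerance of
  $10^{-8}$ so that exhaustive enumeration is robust to floating-point
  jitter.
* Degenerate outcomes (no residual variation around the reduced model)
  report F = 0, p = 1 rather than 0/0.
* Perfect voxel fits in the GLM report signed infinite t and are
  flagged; they survive any threshold, which is the intended behaviour.
* The test suite validates the statistical calibration at scalar level
  (500 null cohorts for the ANCOVA type-I error, 200 cohorts for post
  hoc power at a planted 30% middle-LC reduction with n = 15 per group)
  and the voxel-wise chain at image level (200 null and 100
  planted-cluster cohorts of n = 12 on $32^3$ grids at 3 mm with 200
  permutations each).  These sizes were chosen to keep Monte-Carlo error
  well inside the asserted calibration bands.
* For the planted-cluster recovery check, the phantom is generated with
  a peak effect size of $d = 2$ in the *generated volumes* (planted
  amplitude 5% of baseline per SD of the cognition score against 2.5%
  voxel noise).  An alternative reading — calibrating the noise so that
  the *smoothed, analyzed* field has peak $d = 2$ — was also evaluated:
  under it the joint recovery rate (FWE significant and peak within two
  voxels) plateaus near 0.70 across phantom geometries, because cluster
  extent and peak localization trade off against each other at that
  effect size with n = 12.  The generator-level reading matches the
  definition of the phantom itself and is the one implemented.

## Known limitations

* The extraction's exact search is exponential in the worst case; it is
  fast because sub-ROIs are tiny.  For pathologically large ROIs use
  `method = "greedy"`.
* Exact Spearman enumeration beyond n = 10 is not supported (memory
  grows as $n \cdot n!$).
* The voxel-wise model supports a single regressor plus intercept, as in
  the reference analyses (e.g. t with n-2 degrees of freedom for n
  subjects); additional voxel-wise covariates are out of scope.
* Cluster peaks are reported by coordinate only; anatomical labeling is
  out of scope.
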