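---
title: "Methods: 4DCT-ventilation functional avoidance virtual trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4DCT-ventilation functional avoidance virtual trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventavoid)
```

## The ventilation model

4DCT-ventilation treats the breathing-induced change in CT density as a
surrogate for regional lung function. A lung voxel is a mixture of air
(≈ −1000 HU) and tissue (≈ 0 HU), so its Hounsfield value encodes its air
fraction. If the end-inhale image is deformably registered to the
end-exhale geometry, the fractional change in the air volume of each
exhale voxel is

$$\frac{V_{in}-V_{ex}}{V_{ex}}
  \;=\; 1000\,\frac{HU_{in}-HU_{ex}}{HU_{ex}\,(1000+HU_{in})},$$

which `compute_ventilation()` evaluates per voxel inside the lung mask.
The model assumes (i) mass conservation of tissue within the registered
voxel, (ii) a correct displacement field, and (iii) calibrated HU. It is
singular at $HU_{ex}=0$ and $HU_{in}=-1000$; voxels with either
denominator factor within `eps_den = 10` HU of zero are removed from the
valid mask rather than propagated as non-finite values. 10 HU is roughly
scanner noise scale; voxels that close to pure tissue or pure air carry no
usable ventilation signal anyway. Negative raw values (possible under
noise) are kept in the raw map — clipping happens only in normalisation —
so that regional sums can treat them explicitly (they contribute zero to
percent-of-total masses).

Ventilation is defined on the exhale geometry, the common planning
reference; the displacement field maps exhale world positions to inhale
positions, and `warp_to_exhale()` samples the inhale volume there with
trilinear interpolation (masks, when resampled, use nearest neighbour —
order statistics of a binary image are preserved). Out-of-field samples
are flagged invalid, never extrapolated.

`qa_displacement_field()` plays the role of the registration review: the
Jacobian determinant of $x \mapsto x + u(x)$ is computed by central
differences (one-sided at faces); non-positive determinants mean local
folding. The trial screening rejects patients whose field folds anywhere
(`qa_max_folding = 0`).

### Normalisation

`normalize_ventilation()` clips raw values at the within-lung 1st/99th
percentiles and rescales to [0, 1]. Percentile normalisation makes the
functional-lung threshold invariant to positive affine rescalings of the
raw map (a property the tests assert), which matters because the raw ΔV/V
scale varies with breathing depth. A constant map gets 0.5 by convention,
with a warning, so downstream thresholding degrades gracefully.

## Eligibility metrics

Each lung's craniocaudal bounding extent is split into three equal-height
slabs — the thirds convention of VQ imaging, which geometrically
approximates lobes. Equal height, not equal volume, is deliberate: it
mirrors the planar-scan convention the metrics come from. Ties at slab
boundaries go to the inferior slab. The six percent-ventilation values use
mass sums (not means) of nonnegative raw ventilation, so they add to 100
exactly.

From the partition and the GTV centroid the package derives:

* `vtt` — percent ventilation in the tumor-bearing third;
* `vta` — the minimum over that third and its adjacent thirds, where
  adjacency means directly superior, directly inferior (same lung), or the
  same-level third of the contralateral lung. Diagonal neighbours are
  excluded. This is the only reading of "superior, inferior, or lateral"
  consistent with six geometric thirds;
* `ic` — ipsilateral/contralateral ventilation sum ratio;
* `cov` — coefficient of variation of raw ventilation over valid lung
  voxels.

A low `vta` means a poorly ventilated third sits at or next to the tumor —
exactly the configuration functional avoidance can exploit, since beams
must traverse that neighbourhood anyway.

`roc_analysis()` scores a metric against observer defect labels: AUC via
the Mann–Whitney identity (midranks give ties 0.5 credit; the test suite
checks equality with brute-force pair counting), a univariate logistic fit
by IRLS (`stats::glm`) with a Wald p-value, and an operating threshold
maximising the Youden index $J = \text{sens} + \text{spec} - 1$ (smallest
threshold on ties). The phrase "optimal operating point" cannot be defined
by AUC alone — AUC is threshold-free — so Youden, the standard criterion,
is used. Because a *low* %VTA flags a defect, the trial calls
`roc_analysis(direction = "<")`; thresholds are reported on the original
scale, and the trial applies the cutoff inclusively (a patient exactly at
the Youden threshold is eligible).

## The functional-avoid structure

`segment_functional_avoid()` takes normalised ventilation ≥ `threshold`
(default 0.15) inside the lungs, subtracts GTV and ITV, and applies a
morphological opening with a radius-1 (6-connected) ball to remove
speckle. Whether the literature's "15%" refers to raw ΔV/V, a percentile,
or a normalised scale is genuinely ambiguous; this package applies it on
the normalised [0, 1] scale and exposes the threshold as a parameter so
either reading can be configured. The opening radius is fixed at one voxel
— enough to remove isolated voxels that a planner could not target, small
enough not to erode real defect boundaries. Opening is a subset operation,
so the structure can never re-enter the targets; an empty result is a
warning, not an error (a uniformly ventilated patient simply has no
structure to spare).

## Dose and dose-function metrics

Cumulative DVHs are binned at 0.1 Gy; $D_x$ (dose exceeded by x% of the
structure) is linearly interpolated between bins, giving sub-bin accuracy
with bounded memory, and $V_x$ uses exact voxel counting (equivalent to
the binned value within one bin width, which is what the tests assert).
Conventions:

* HI = D90%/D5% of the PTV (1 is perfectly homogeneous);
* CI = prescription-isodose volume / PTV volume;
* MLD and lung V20 are computed on lungs minus GTV (the RTOG total-lung
  convention; configurable via `exclude_gtv_from_lung`);
* SfMLD / SfVx: mean dose and ≥x Gy percentages over the functional-avoid
  structure;
* ImfMLD / ImfVx: ventilation-weighted lung metrics from the dose-function
  histogram, with weights $w_i = \max(\text{raw}_i, 0)$. Raw (not
  normalised) weights are used because the dose-function histogram weights
  by function magnitude; normalisation would discard relative magnitude.
  All Imf metrics are invariant to positive rescaling of the weights.

`compare_plans()` pairs per-patient summaries (functional minus clinical),
reporting means, difference ranges, and two-sided paired t-tests; a
zero-variance difference vector gets p = 1 by convention (reachable with
identical plans, and degenerate for a t statistic).

## The phantom generator

The generator exists so every stage can be validated against known ground
truth; no patient data ship with the package.

**Geometry.** Two superellipsoidal lungs (quadratic in-plane, exponent 4
along z) in a soft-tissue elliptic-cylinder body. The blunt apex/base
profile matters: on a pure ellipsoid the middle third holds roughly twice
the ventilation of the outer thirds, so the %VTA baseline is dictated by
the small outer thirds and middle-third defects are geometrically
undetectable; the flatter profile — also closer to real lung shape — makes
thirds comparable. OARs (cord, heart, esophagus) are simple primitives
placed deterministically: they exist to exercise the OAR metrics, not to
be anatomical.

**Segmentation masks.** The analysis lung masks are the anatomical lung
region eroded by two voxels. Partial-volume voxels at the pleural
interface mix −850 HU parenchyma with +40 HU tissue under interpolation
and would dominate the ventilation error budget; clinical lung contours
exclude the pleural boundary for the same reason.

**Ventilation and HU.** Background ventilation is uniform (0.3) inside
the lungs; a defect multiplies it by $1 - s\,e^{-r^2/2\sigma^2}$ with
severity $s \in [0,1]$ and $\sigma$ = `extent_mm`/2. Exhale lung HU is
−1000 × air fraction (default 0.85 → −850 HU). The inhale HU that the
density-change model must see is obtained by exact closed-form inversion,
$HU_{in} = 1000\,HU_{ex}(1+v)/(1000 - v\,HU_{ex})$, clamped to
[−1000, 0]; the inhale volume is then built by pushing that field through
the deformation (dense-table inversion of the monotone craniocaudal map,
then linear resampling). Recovering the map through
`warp_to_exhale()` + `compute_ventilation()` is therefore
interpolation-limited by construction. Gaussian HU noise (default 0 for a
single phantom, 5 HU in cohorts) is added independently to both phases.

**Deformation.** $u_z(z) = -A \sin(\pi (z - z_0)/L)$ over the lung
extent, zero outside; fold-free whenever $A\pi/L < 1$, which the
constructor enforces. Default amplitude 10 mm is a typical diaphragmatic
excursion under quiet breathing.

**Dose.** Nine equispaced coplanar beams aimed at the PTV centroid, each a
Gaussian lateral profile (σ tied to the PTV radius) with mild divergence
from a 1 m source and a linear depth falloff — no heterogeneity
corrections, since plan realism is a non-goal; only the relative sparing
mechanics must be exercised. The clinical style weights beams equally. The
functional style emulates favorable-arc selection: each beam is scored by
ventilation-weighted lung dose per unit PTV dose, the three
lowest-burden directions keep full weight, and the others drop to a 0.15
floor (fully switching beams off would be an undeliverable plan). If the
ventilation map offers no directional signal — identical path-mean
ventilation for every beam, as with a uniform map — all weights stay
equal and the functional plan reproduces the clinical plan exactly; that
is the deterministic tie rule. Both styles are rescaled so the PTV mean
equals the prescription, making paired PTV doses match by construction.

**Cohorts.** `generate_cohort()` draws defect presence Bernoulli at the
requested prevalence, severity uniform on (0.6, 0.95), a uniform tumor
third, and places the defect in the tumor third (probability 0.6) or a
uniformly chosen adjacent third — defects near the tumor are the
configuration the %VTA metric is designed to detect, and severities below
0.6 with the default 70 mm extent would not constitute the "major defect"
phenotype an observer would label. Per-case seeds derive deterministically
from the cohort seed, so cases are reproducible independently of order.

**What the phantom does not emulate.** Real anatomy (lobes, airways,
vasculature), 4DCT binning artifacts, registration error (the true DVF is
supplied — a deliberate choice, so ventilation errors are not confounded
with registration errors), observer variability (labels equal generator
truth), Monte Carlo or convolution-superposition dose, and optimizer
behaviour beyond beam-direction preference. Passing tests therefore show
the analysis chain is correct and well-calibrated under the stated model,
not that the method is validated on patients.

## The virtual trial

`run_virtual_trial()` screens every patient (DVF QA → ventilation →
normalisation → thirds → metrics), fits ROC curves for IC, CoV, %VTT and
%VTA against observer labels, derives the %VTA cutoff from the Youden
point when `vta_cutoff = "auto"`, assesses eligibility (quantitative
`vta < cutoff`, qualitative observer label, either suffices), selects a
seeded simple random planning subset (`n_planning`, mirroring a trial that
plans a subset of eligibles; no stratification, since none is specified
for such designs), and aggregates paired plan comparisons. One patient's
QA failure is logged as `failed_qa` and never aborts the cohort, matching
screening flow in a real trial; the per-patient ledger conserves the
cohort (enrolled = eligible + ineligible + failed QA).

## Problem sizes and runtime choices

Single-phantom validation uses 64³ voxels at 4 mm; cohort studies use 32³
at 7.5 mm (same 24 cm field of view), which keeps a 100-patient virtual
trial in the tens of seconds while leaving every third with hundreds of
voxels. The test suite uses 24³ phantoms at 10 mm where only pipeline
mechanics are at stake. These sizes are the package's own defaults, chosen
so that interpolation error, not statistical noise, limits the phantom
round trip at the fine scale and regional metrics remain stable at the
coarse scale.

## Known limitations

* The adjacency rule excludes diagonal thirds; with real, asymmetric lungs
  "same level" contralateral adjacency is an approximation.
* Percent ventilation per third uses mass sums; a mean-based variant would
  weight small thirds differently. The sum is the VQ convention.
* The 15% functional-lung threshold is applied to the normalised map; on
  raw ΔV/V it would select different voxels.
* DICOM RTDOSE/RTSTRUCT are not read; volumes and label maps move through
  NIfTI.
* The analytic dose model has no lateral scatter, buildup, or tissue
  heterogeneity; absolute dose metrics are internally consistent but not
  clinically meaningful — only paired contrasts are.
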