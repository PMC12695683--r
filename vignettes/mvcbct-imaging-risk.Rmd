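---
title: "Modelling the radiobiological impact of daily MV-CBCT imaging dose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the radiobiological impact of daily MV-CBCT imaging dose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Megavoltage cone-beam CT (MV-CBCT) acquires a volumetric setup image with the
treatment beam itself, typically once per fraction. Each acquisition deposits
a few centigray in surrounding normal tissue, and over a 25–35-fraction course
the accumulated imaging dose reaches the 1–2 Gy range — small next to the
prescription, but not negligible for radiosensitive organs or for young
patients with long survivorship. `rtimagerisk` quantifies this burden per
organ at risk (OAR): it accumulates per-fraction imaging dose (scaled by the
monitor units, MU, of the acquisition protocol) with the treatment dose,
computes differential dose-volume histograms (DVHs) over contoured organs,
and converts them into two complementary risk summaries:

* **NTCP** — normal tissue complication probability, for deterministic
  (tissue-reaction) risk;
* **EAR** — excess absolute risk of radiation-induced secondary cancer, for
  stochastic risk, with explicit dependence on age at exposure.

The cohort layer compares two imaging protocols (e.g. 5 vs 10 MU per
fraction) with paired statistics and stratifies EAR by age, which is the
evidence base for age-tailored imaging protocols.

## Models

**Dose accumulation.** Total course dose on the planning lattice is
$D_\text{total} = D_\text{tx} + \frac{\mathrm{MU}}{\mathrm{MU}_\text{ref}}
\, D_\text{img}^{(1)} \cdot n_\text{fx}$, where $D_\text{img}^{(1)}$ is one
acquisition's dose grid exported at a reference MU setting. Imaging dose is
taken as proportional to MU — the linac delivers the same beam, only longer —
so a single per-fraction grid serves any protocol; a second measured grid can
be supplied instead if that approximation is unwanted. An *imaging-only* mode
(treatment term zero) isolates the imaging contribution, mirroring plans
whose beam doses are zeroed out in the planning system.

**DVH.** Voxels whose centers fall inside the organ's contours (even–odd
rule, nearest-slice assignment, boundary points inside) are binned into
left-closed, right-open dose bins of width 0.01 Gy by default. Each bin also
stores the exact mean dose of the voxels it holds, so DVH-based summaries are
exact for within-bin-constant distributions and carry only an
$O(\text{bin width}^2)$ curvature error otherwise. Mean dose is always
reported voxel-exactly (the arithmetic average over the contoured volume).

**NTCP.** Two dose-response families are available per organ:

* logistic on mean dose $D$: $\mathrm{NTCP} = \left[1 + e^{\gamma (D_{50} -
  D)}\right]^{-1}$, with $\gamma$ in Gy$^{-1}$ (published *normalized* slopes
  $\gamma_{50}$ convert via $\gamma = 4\gamma_{50}/D_{50}$);
* Lyman–Kutcher–Burman (LKB): $\mathrm{NTCP} = \Phi\!\left(\frac{\mathrm{gEUD}
  - D_{50}}{m\,D_{50}}\right)$ on the generalized equivalent uniform dose
  $\mathrm{gEUD} = (\sum_i v_i D_i^{1/n})^n$ with volume exponent $n$.

Both are evaluated in numerically stable forms (`plogis`, `pnorm`), so
extreme arguments underflow to 0/1 without error.

**OED and EAR.** Secondary-cancer risk uses Schneider's organ equivalent
dose with the linear-exponential (cell-sterilization) mechanism,
$\mathrm{OED} = \sum_i v_i D_i e^{-\alpha' D_i}$ with $\alpha' = 0.085$
Gy$^{-1}$ by default, and
$\mathrm{EAR} = \mathrm{EAR}_0 \cdot \mathrm{OED} \cdot \mu(e, a)$ in cases
per 10 000 person-years, where $\mathrm{EAR}_0$ is the organ's baseline risk
per Sv and the age modifier is
$\mu(e,a) = e^{\gamma_e (e - e_0)} (a/a_0)^{\gamma_a}$ with reference ages
$e_0 = 30$, $a_0 = 70$ and attained age fixed at $a = 70$. Photon Gy are
treated as Sv (weighting factor 1, configurable). For patients already older
than the attained-age reference the attained age is lifted to exposure age
plus one year so the modifier stays defined.

Note one structural property: $D e^{-\alpha' D}$ peaks at $1/\alpha' \approx
11.8$ Gy. Below that dose OED grows with dose (imaging-only doses of ~1 Gy
are safely in this regime, so more MU always means more modelled risk);
*above* it, extra dose can lower OED — so in total-dose mode a high-dose organ
such as an ipsilateral lung can show slightly *lower* EAR under the higher
imaging protocol. That is the model, not a bug, and it is why the
monotonicity and doubling properties in the test suite are asserted in
imaging-only mode.

## Parameter registry

Radiobiological coefficients live in a JSON/YAML registry
(`inst/extdata/parameter_registry.json`), one record per organ with an NTCP
block (`model`, `d50`, `gamma`/`gamma50` or `m`, `n`) and an EAR block
(`ear0`, `alpha_prime`, `gamma_e`, `gamma_a`, `e0`, `a0`), each carrying a
mandatory `source` citation. The shipped values are literature stand-ins
(QUANTEC-era NTCP fits; Schneider/BEIR VII-derived EAR coefficients) meant to
be replaced by institution-specific choices: a partial override file merged
over the defaults swaps any single coefficient without code changes. All
shipped `gamma_e` are negative, so modelled risk decreases with age at
exposure — the inverse age gradient that motivates age-stratified protocols.
With these coefficients the <40 vs >60 contrast is a factor of ~2–4; much
steeper gradients reported in some clinical analyses would require
correspondingly larger $|\gamma_e|$, which users can set in the registry.

## The synthetic phantom cohort

No patient DICOM accompanies this kind of retrospective analysis, so the
`synthdata` module generates complete, seeded DICOM-RT phantom cohorts that
make every stage testable:

* geometry: spheres/cylinders/ellipsoids for the canonical OARs of each site
  (breast: contralateral breast, both lungs, heart; pelvic: rectum, bladder,
  bowel bag; head & neck: parotids, spinal cord, brainstem, optic nerves) on
  an isotropic lattice, by default $64^3$ voxels at 4 mm (25.6 cm extent) —
  coarse enough for seconds-scale runs, with the shape and spacing exposed as
  template fields for finer phantoms;
* treatment field: an isotropic sigmoid falloff
  $D(r) = \mathrm{Rx}\,/\,(1 + e^{(r - R_0)/w})$ from a site-specific target,
  whose $(R_0, w, \mathrm{Rx})$ were calibrated once so course-total organ
  mean doses land in the magnitude ranges reported for clinical cohorts
  (ipsilateral lung ≈ 18–19 Gy, rectum ≈ 47–49 Gy, parotid ≈ 25–28 Gy); the
  intended per-ROI ranges are stored in the template and checked as a
  generator property;
* imaging field: a spatially broad per-fraction dose proportional to MU
  (default 6.5 mGy/MU at isocenter, i.e. a few cGy per acquisition) with a
  mild anterior–posterior gradient; the acquisition arc itself is not
  modelled;
* demographics: ages drawn from a three-stratum mixture (<40 / 40–60 / >60,
  default 30/40/30%), uniform within stratum; laterality for breast patients;
* determinism: every draw comes from a per-patient substream of the cohort
  seed, so regeneration is byte-identical.

What the phantoms deliberately do **not** emulate: anatomical realism, CT
image content, beam directionality, deformation or registration error, or
inter-fraction setup variation. Passing tests therefore demonstrate the
correctness of the *pipeline* — I/O, geometry, accumulation, histogramming,
model evaluation, statistics — on data with the right structure and
magnitudes, not the clinical accuracy of any specific risk estimate.

## Numerical choices

* DVH bin width 0.01 Gy by default; with exact per-bin mean doses the
  remaining quadrature error is negligible for all shipped summaries.
* Rasterization: voxel-center sampling, even–odd rule, boundary points
  (within $10^{-9}$ mm) inside; a contour attaches to the nearest grid slice
  and is rejected beyond half a slice spacing.
* Resampling: trilinear, with 0 Gy outside the source extent; constants and
  trilinear fields are reproduced to machine precision.
* Dose files quantize to 32-bit integers with an 8-significant-digit grid
  scaling chosen so the maximum dose maps near $2^{30}$; round-trip error is
  bounded by the quantization step.
* Degenerate paired comparisons: all-zero differences report $p = 1$,
  constant nonzero differences report $t = \pm\infty$, $p = 0$; both carry a
  `degenerate` flag instead of failing the run. No multiple-testing
  correction is applied (raw per-ROI p-values, noted in the report metadata).
* Age strata: boundaries 40 and 60 both belong to the middle group; empty
  strata appear with count 0.

## Scope and limitations

* DICOM support is the subset this pipeline needs (Explicit VR Little Endian
  RTDOSE/RTSTRUCT plus a CT geometry stub; axis-aligned orientations), not a
  general codec. Files written by the package are read back by pydicom, which
  the test suite uses as an independent oracle.
* Dose is consumed from RTDOSE grids; no dose calculation from machine
  parameters, no image registration or reconstruction.
* EAR is absolute risk only (no relative-risk pathway), with attained age
  fixed rather than integrated over a life table; no fractionation
  correction is applied to the DVH before OED.
* Uncertainty is addressed by one-parameter sensitivity sweeps
  (`sensitivity_sweep()`), not formal propagation; risk-coefficient
  uncertainties of a factor of a few are typical for these models, so
  absolute EAR values should be read as order-of-magnitude estimates while
  protocol *ratios* are far more robust.

## Problem sizes used in the shipped checks

The test suite and acceptance script run on phantom cohorts of 4–10 patients
per site at the default $64^3$/4 mm lattice, 100-replicate oracle-equivalence
batches ($32^3$ grids, random convex polygons), and 1000-replicate DVH
inequality sweeps — sizes chosen so a full check runs in a few minutes on one
CPU while still exercising every code path at realistic magnitudes.
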