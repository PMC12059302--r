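---
title: "Evaluating real-time kV imaging dose against lung-SBRT planning constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating real-time kV imaging dose against lung-SBRT planning constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Stereoscopic room-mounted kV systems can monitor lung tumour motion in real
time while a VMAT arc is delivered. The monitoring dose is small relative to
the prescription, but lung SBRT plans are often driven *to* their
organ-at-risk (OAR) limits, and kV photons deposit dose preferentially in
posterior tissue (the tubes sit in the floor behind the patient) and in bone
(roughly a four-fold mass-energy-absorption enhancement relative to soft
tissue). `kvimpact` asks the operational question: with the monitoring dose
added to the treatment dose, do any planning constraints change their
pass/fail state?

Two structural facts organize everything downstream. Adding a non-negative
dose can never decrease a DVH metric, so OAR constraints (all of the form
`value ≤ limit` or `< limit`) can only flip pass→fail, while PTV coverage
(`V90% > 99%`) can only flip fail→pass. The package's tests assert this
monotonicity, and the stressed-cohort acceptance check verifies that every
flip observed end-to-end respects it.

## Dose containers and numerical conventions

Dose and density live on regular grids in a fixed patient frame (x
patient-left, y patient-posterior, z patient-superior, mm), voxel-centre
convention, R array layout (x fastest). Grid harmonization is trilinear;
points outside the source grid's voxel-centre hull map to 0 Gy, which is the
right behaviour for an imaging dose computed on a sub-volume. Interpolation
is convex, so resampling never manufactures dose above the source maximum.
The treatment-dose grid is the canonical frame: the imaging dose is
resampled onto it before addition.

All DVH metrics are computed from sorted voxel doses directly, so bin width
never limits accuracy; binned cumulative DVHs (default 0.01 Gy) exist only
for export and plotting. Conventions that needed pinning:

* **Dmax** is the dose to the hottest 0.03 cc, by descending-volume
  accumulation with linear interpolation inside the voxel run that crosses
  0.03 cc. This makes the value grid-resolution-robust; a volume request at
  or below one voxel volume returns the hottest voxel's dose.
* **"Receiving a dose higher than D"** is implemented as `>=` at the voxel
  level. For continuous dose the difference is measure-zero, and `>=` keeps
  the uniform-dose edge case (V_D at exactly D) non-pathological. A strict
  mode (`dvh$strict_threshold`) is available in the configuration.
* **Voxel membership** in a structure is centre-inclusion (even-odd rule
  for contours), not partial-volume weighting: deterministic and below
  reporting precision at the default 2.5 mm grid. The crossing test is
  half-open (left/bottom edges in, right/top out), the standard choice that
  tiles adjacent polygons without double counting.
* **Margins** (5 mm for the PTV and for the trachea, esophagus and
  spinal-cord PRVs) are 3D Euclidean dilations respecting anisotropic
  spacing, not per-slice 2D expansions.
* **Pass/fail** is decided on unrounded values; report rendering rounds to
  1 decimal (2 for PTV coverage and the increment columns). A value exactly
  at a `≤` limit passes; `<` (skin) and `>` (PTV coverage) are exclusive.

## Constraint tables

The three fractionation-specific protocols — RTOG 0915 for 48 Gy/4 fr,
LUSTER for 60 Gy/8 fr, SUNSET for 60 Gy/15 fr — ship as editable CSVs under
`inst/extdata/protocols/`, one row per rule, grouped into C1 (absolute dose,
Gy), C2 (absolute volume, cc) and C3 (percent volume). Rules a protocol
marks not-applicable are simply absent (SUNSET has no skin rules and a
single spinal-cord rule). Two bone metrics (V30 Gy in cc, mirroring the
chest-wall rule, and D2%) are appended to every protocol as report-only
rows: bone is not a clinical OAR in these protocols but absorbs kV dose
disproportionately, so it is tracked for comparison and excluded from all
pass/fail denominators. One typographic discrepancy between published
versions of the SUNSET esophagus-PRV Dmax limit (55.5 vs 50.5 Gy) is
resolved in favour of the protocol table's 55.5 Gy, noted in the CSV.

Per constraint the package reports the value under Tx and Tx + Im, both
pass flags, the flip flag, and two increments: `Im/Tx (%) = 100 (v_total −
v_tx)/v_tx` (0/0 defined as 0; a zero Tx value with positive total reports
an infinite sentinel with a warning) and, for C1 rules only, `Im/Rx (%) =
100 (v_total − v_tx)/Rx`. The increments act on *constraint values*, which
for Dmax-type metrics is deliberately not the same thing as a DVH metric of
the imaging dose alone: the hottest imaging voxel and the hottest treatment
voxel are generally in different places, so the increment is usually much
smaller than the imaging dose's own maximum. Constraints whose structure is
missing from a case are recorded as not evaluated and excluded from cohort
denominators rather than counted as passes.

## The imaging model

**Schedule.** Gantry motion is assumed uniform in time over each arc.  Each
tube is blocked while the gantry head is within a configurable half-width
(default ±60°) of that tube's line of sight (defaults 240° and 120° on the
IEC scale for the two posterior-oblique floor tubes); sweeping through a
blocked range turns stereoscopic imaging into monoscopic imaging from the
other tube, and overlapping blocked ranges produce intervals with no active
tube and no dose. Interval durations partition the delivery time exactly;
each interval contributes ⌊duration × frequency⌋ images at the default
1.67 Hz. Imaging is assumed on only while the beam is on.

**Per-image dose.** The kV dose engine is an analytic primary-beam
surrogate, chosen over Monte Carlo transport to keep the model closed-form
testable: for each voxel inside a tube's divergent cone,

D = K_ref · mAs · (d_ref / r)² · exp(−μ_w · t_rad) · f_mat,

with r the source distance, t_rad the density-weighted (midpoint-rule) path
length from the body surface, and f_mat the bone factor (default 4.0) for
bone-labelled voxels. Scatter, the heel effect and spectral hardening along
the path are ignored. What the surrogate preserves — and what the tests pin
— is the behaviour the constraint analysis relies on: exponential-times-
inverse-square depth dose (verified against the closed form to 1% in a
water phantom), a surface maximum, strict linearity in mAs, image count and
fraction number, posterior weighting on a thorax, and the bone/soft ratio.
What it cannot claim: absolute accuracy of scattered dose outside the cone
(exactly zero here) and build-up within the first millimetre.

**Technique and calibration.** The imaging technique is patient-size
dependent: the water-equivalent lateral thickness through the isocenter
selects one of three (kVp, mAs, μ_w) rows (110 kVp/10 mAs to
130 kVp/25 mAs). The reference output K_ref = 2×10⁻⁵ Gy/mAs at 1 m puts the
per-image entrance dose at 0.2–0.5 mGy and the skin D2 of a four-fraction
course near 0.35 Gy — an order-of-magnitude anchor against published
course-level skin doses from comparable room-mounted monitoring systems,
not a fit to any reported value. The per-image dose is computed once per
tube on a 5 mm grid (it is gantry-independent) and resampled onto the
2.5 mm treatment grid; at these photon ranges the 5 mm computation changes
constraint increments by far less than the surrogate's own model error, at
an eight-fold cost saving.

## The synthetic cohort

There is no public lung-SBRT dataset with treatment dose, contours and
delivery information, so the package generates one with the statistical
structure the analysis needs. Each case is an elliptic-cylinder thorax
(per-patient habitus scale drawn from ±10%) with two 0.25-relative-density
lungs, a vertebral column and spinal canal, periodic rib bands, trachea and
bronchial tree with air lumens, esophagus, heart, aorta, a 4 mm skin shell
and a 2 cm chest-wall shell; a spherical tumour (radius 9–14 mm) is placed
in the requested lobe and side. The ITV is the tumour itself — breathing
motion is deliberately not modelled — and PTV/PRVs add 5 mm margins via the
package's own dilation. The default cohort is 30 patients: 26 at
48 Gy/4 fr, 3 at 60 Gy/8 fr, 1 at 60 Gy/15 fr, with upper lobes and
right-sided lesions predominating, on a 2.5 mm grid of 220×160×200 mm
(~450k voxels, desk-scale). One full 360° arc of 120 s per case.

The treatment dose is a geometric surrogate, not an optimized plan: the
prescription inside the PTV, an exponential radial falloff outside it, and
a uniform in-body bath of 1% of Rx standing in for scatter and leakage
(without the bath, far-organ metrics sit at numerical zero and the relative
increment columns lose meaning). The falloff length is tuned per case by
bisection so that the *binding* OAR constraint — whichever rule is closest
to its limit — reaches `limit × (0.9 + 0.1 × stress)` under Tx. `stress` is
the cohort's single realism dial: at 0 every rule has ≥10% headroom and the
imaging dose flips nothing; at 0.9 (the default, reflecting how close
clinical plans run to their limits) a ~1% increment can flip the binding
rule. PTV coverage is drawn near 99.5% at stress 0 and drifts marginally
below the 99% requirement as stress grows — the dose level crossing 90% of
Rx is placed at the coverage-target quantile of the digital PTV's voxel
distances, so the realized coverage tracks the target despite
voxelization — which is what makes fail→pass coverage flips possible. If a
tumour sits so close to an organ that even the steepest falloff overshoots
the stress target, the generator keeps the closest achievable dose and
warns.

What passing tests on this cohort do **not** show: agreement with any real
patient's DVH, the published per-patient constraint values (institutional
data), realistic plan heterogeneity inside the PTV, OAR overshoot patterns
of real plans (under the tuning rule the synthetic Tx dose almost never
fails an OAR constraint, whereas real cohorts do), breathing motion, or the
bone-versus-chest-wall dose ordering of real anatomy — the paired V30
comparison is exercised mechanically, but with the surrogate's falloff both
volumes are usually near zero at 48 Gy/4 fr.

## Reproducibility and problem sizes

Every stochastic step is seeded: `makePhantom(seed)` restores the caller's
RNG state, per-case seeds derive deterministically from the recipe seed,
and `runPipeline` with a fixed seed is byte-reproducible including the JSON
summary. The test suite runs the full oracle battery on 30³-voxel grids and
the end-to-end flip-direction check on the complete 30-case cohort at
stress 0.9; `scripts/acceptance.R` repeats the cohort run from scratch and
writes the summary statistics. Both complete in minutes on one CPU; these
problem sizes were chosen as the package's own desk-scale defaults.

## Known limitations

* No DICOM import/export: the exchange format is the package's native case
  bundle (JSON metadata plus raw little-endian arrays); no R DICOM reader
  dependency is used. Real-data workflows need an upstream conversion.
* Primary-beam-only kV transport; no scatter, heel effect or spectral
  hardening; pretreatment CBCT dose is out of scope.
* One frame of reference; no deformable registration.
* Physical constraints only — no EQD2/BED/NTCP.
* The Im/Tx increment is numerically fragile for near-zero Tx metrics; the
  1%-of-Rx bath bounds it but cold-organ ratios remain large, so the cohort
  mean of Im/Tx should be read with its distribution, not alone.
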