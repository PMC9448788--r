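---
title: "Validating, synthesizing and quantifying ASL-BIDS perfusion data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating, synthesizing and quantifying ASL-BIDS perfusion data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslbids)
```

## Why a typed model of the `perf` datatype

Arterial spin labeling (ASL) magnetically labels arterial blood water and
measures its delivery to tissue, giving cerebral blood flow (CBF) in absolute
units (mL/100 g/min) without contrast agents. Because the output is a
quantitative physical number, quantification stands or falls with the
acquisition metadata: the labeling scheme and its timing, the calibration
(M0) strategy, the readout geometry, and — unusually among MRI modalities —
the intensity scale factors applied between scanner and file. The BIDS
`perf` datatype standardises how all of this is stored: NIfTI images, a JSON
sidecar, and an `_aslcontext.tsv` naming the type of every volume
(`control`, `label`, `m0scan`, `deltam`, `cbf`) in acquisition order.

This package implements that standard as executable artifacts. The
organising idea is a single machine-readable *field registry*: every sidecar
field with its value kind, units (times in seconds throughout), requirement
level and an applicability condition. Requirement levels are ranked by
necessity for quantification — REQUIRED fields are exactly those without
which a CBF map cannot be computed from the sidecar; RECOMMENDED fields
improve or contextualise quantification (e.g. `AcquisitionVoxelSize` for
partial-volume handling); everything else is OPTIONAL. The validator, the
synthesizer and the quantifier all read the same registry, so "the fixture
validates cleanly", "deleting a REQUIRED field is flagged" and "the REQUIRED
set suffices to quantify" are checked against one source of truth.

## The validator

`validate_asl()` is a pure function from a dataset to a report; problems are
issues, never exceptions, and the issue list is ordered (rule id, then path)
so repeated validation is bit-identical. Rules carry stable identifiers
(ASL101 missing REQUIRED, ASL2xx context/series consistency, ASL3xx M0
declaration, ASL4xx structural lengths, ASL501 forbidden scaling metadata,
ASL6xx PEPolar linkage; the full catalogue is in `?validate_asl` and
`R/validator.R`).

Two mappings here are this package's own design where the standard is
silent:

* **Severity mapping.** Missing REQUIRED → ERROR, missing RECOMMENDED →
  WARNING, missing OPTIONAL → silent. `strict = TRUE` promotes the
  RECOMMENDED omissions to errors for curation workflows.
* **Pair-count mismatch is a warning.** `TotalAcquiredPairs` records the
  acquired control–label pairs; exports that average repetitions legitimately
  store fewer volumes than were acquired, so a mismatch warns (ASL203)
  rather than errors.

A third heuristic is the *milliseconds suspicion*: BIDS stores times in
seconds, and the single most common conversion defect is millisecond
carry-over. Any time-valued field above 10 s (50 s for
`RepetitionTimePreparation`, which can be genuinely long) draws a
plausibility WARNING (ASL104), never an ERROR.

Context rules treat a `deltam` series as first-class (vendor pipelines often
export only the averaged difference image) but reject a context that mixes
`deltam`/`cbf` with `control`/`label` rows in one series (ASL204): no
published layout does this and the pairing semantics would be ambiguous.
`TotalAcquiredPairs` is required even for `deltam`-only series — the
averaged export is precisely the case where the pair count is otherwise
lost.

## Conversion-time mandates

Two transforms must happen at conversion, and the package exposes them so
any converter front-end can comply:

* `apply_scaling()` — DICOM-style `value * slope + intercept`, applied per
  series (ASL and M0 factors often differ by orders of magnitude when
  background suppression is on). ASL-BIDS deliberately has **no** metadata
  for scaling, so the validator deny-lists scaling keys (ASL501): a stored
  slope is indistinguishable from an unapplied one.
* `sort_to_acquisition_order()` — scanners export volumes in arbitrary
  order; storage order must be acquisition order. The permutation moves
  volumes and context rows jointly, so the (volume, type) pairing is
  invariant.

## The synthetic generator and its ground truth

`synthesize_dataset()` is the package's substitute for downloaded example
data: it builds a dataset *by inverting the quantifier's closed forms*, so
the embedded CBF phantom is recoverable exactly in the noise-free case. The
five `example_plan()` configurations emulate the five public example
datasets: GE single-delay PCASL with 3D spiral readout, four
background-suppression pulses and an averaged `deltam` plus in-series
`m0scan` (asl001); Philips single-delay PCASL 2D-EPI with two pulses and a
separate `m0scan` (asl002); Siemens multi-delay PASL 3D GRASE with separate
`m0scan` (asl003); a custom multi-delay PCASL 2D-EPI with in-series `m0scan`
and a reversed phase-encoding `m0scan` in `fmap/` (asl004); and Siemens
single-delay PCASL 3D GRASE with in-series `m0scan` (asl005).

Choices made once, fixed as the generator's study conditions:

* **Timings.** The published example descriptions fix schemes, readouts,
  pulse counts and M0 placement but not numeric timings; delays and
  durations use consensus-typical product values (e.g. labeling 1.45 s /
  delay 1.525 s for the GE plan, 1.65/1.8 s for Philips, bolus cutoff 0.7 s
  for PASL). Nothing downstream depends on the specific numbers except
  through the forward–inverse round trip.
* **Phantom.** A two-compartment block phantom: inner "gray matter" at CBF
  60, outer "white matter" shell at 20 mL/100 g/min, zero background; M0
  1000/900 arbitrary units in brain. Conventional physiology used as a test
  fixture, not a claim about any dataset. Default grid 16x16x5 voxels —
  large enough for distinct GM/WM/background compartments and per-slice
  timing effects, small enough that the full suite synthesizes hundreds of
  datasets in seconds.
* **Background suppression** multiplies the static control baseline by a
  single factor 0.1 regardless of pulse count; what matters for the format
  logic is only that ASL and M0 signal levels differ grossly, which this
  reproduces.
* **Order conventions.** In-series `m0scan` volumes are stored first;
  multi-delay pairs cycle through the delay list in order; the asl001-style
  series stores one averaged `deltam` volume plus the in-series `m0scan`.
* **Noise** is additive zero-mean Gaussian, seeded per plan; default 0 (the
  deterministic phantom). It emulates thermal noise only — no motion, no
  T2* decay, no coil profiles, no physiological fluctuation. Passing
  recovery tests therefore demonstrate *metadata sufficiency and algebraic
  correctness*, not robustness to real-data artefacts.
* For `M0Type = "Estimate"` plans the phantom's in-brain M0 is flat, since a
  scalar estimate can only be exact for a spatially constant M0.

`mutate_dataset()` injects exactly one catalogued defect for
mutation-matrix testing; `violation_catalogue()` publishes the mapping to
expected rule ids. One catalogue entry needed interpretation:
`shuffle-context` cannot be a pure permutation of balanced rows (that is
undetectable without ground truth), so it relabels one `label` row as
`control`, which the balance rule (ASL202) catches.

## Quantification

`quantify_dataset()` demonstrates that the REQUIRED metadata suffice. The
single-delay closed forms are, with λ the blood–brain partition coefficient,
α the labeling efficiency, T1b arterial-blood T1, τ the labeling duration,
and PLD the (per-slice effective) post-labeling delay:

$$\mathrm{CBF}_{\mathrm{(P)CASL}} =
  \frac{6000\,\lambda\,\Delta M\,e^{\mathrm{PLD}/T_{1b}}}
       {2\,\alpha\,T_{1b}\,M_0\,(1 - e^{-\tau/T_{1b}})},
\qquad
\mathrm{CBF}_{\mathrm{PASL}} =
  \frac{6000\,\lambda\,\Delta M\,e^{\mathrm{TI}/T_{1b}}}
       {2\,\alpha\,\mathrm{TI}_1\,M_0}$$

in mL/100 g/min. Defaults keyed by `MagneticFieldStrength`: T1b 1.650 s
(3 T) / 1.350 s (1.5 T), tissue T1 — used only for the M0
saturation-recovery correction `1 - exp(-TRprep/T1t)` — 1.330 s / 1.100 s,
λ = 0.9 mL/g, α = 0.85 for (P)CASL and 0.98 for PASL, overridden by a
sidecar `LabelingEfficiency`. Unknown field strengths raise an error rather
than interpolating. For 2D readouts the effective delay of slice *z* is
`PostLabelingDelay + SliceTiming[z]`.

Decisions where the convention is genuinely open:

* **PASL delay convention.** The QUIPSS-II form needs the inversion time TI;
  this package reads `PostLabelingDelay` *as* TI (with `BolusCutOffDelayTime`
  as TI1). The alternative reading (PLD = TI − TI1) exists in the wild;
  the choice is recorded here and in the provenance JSON so downstream users
  can re-derive.
* **Multi-delay series** are quantified per delay — one CBF map per PLD,
  pairs grouped by their delay — with no kinetic-model fitting: the storage
  standard, not perfusion modelling, is the subject of this package.
* **M0 handling.** `Separate`/`Included` m0scans are averaged and
  saturation-corrected; a scalar `M0Estimate` is used uncorrected (whether
  estimates are pre-corrected is unspecified upstream; assuming uncorrected
  keeps the scalar interpretable as a calibrated blood M0). `Absent` errors
  unless the caller opts into the mean-control fallback, which is logged.
* **Masking.** Voxels with M0 below 10% (configurable) of the robust M0
  maximum (99th percentile) are masked and set to `NA` explicitly; with a
  scalar M0 no spatial mask can be derived and all voxels are reported.
* **Scalar-or-array fields.** Exactly `PostLabelingDelay`,
  `LabelingDuration` and `FlipAngle` accept either shape in the registry —
  the fields that multi-delay, Look-Locker and QUASAR-style series
  vectorise. Look-Locker series themselves are refused by the quantifier
  (`UnsupportedScheme`): their flip-angle correction is out of scope.

## Numerical choices

* **Images are stored as 64-bit float** with scl slope/intercept 1/0. The
  toolkit promises both a bit-identical write→read round trip and exact
  noise-free recovery; under background suppression the difference signal is
  ~7% of the control signal, so float32 storage would lose up to ~2e-6
  relative precision in ΔM through cancellation. float64 keeps both
  guarantees at machine precision. (NIfTI headers hold voxel sizes as
  float32; the model snaps `voxel_size_mm` accordingly so the round trip is
  exact there too.)
* Sidecar JSON is written with full numeric precision (`digits = NA`) in the
  model's own stable key order; the aslcontext TSV with the single
  `volume_type` header and LF endings.
* Pair formation is positional: the k-th control pairs with the k-th label
  in acquisition order; m0scan rows are skipped.

## Limitations

Real vendor DICOM conversion is out of scope (the transforms it must apply
are exposed, the archives are not read). One ASL run per subject; no
sessions, no derivatives tree beyond the CBF output, no non-brain ASL, no
advanced variants (time-encoded, velocity-selective, vessel-encoded,
diffusion-weighted, functional). The validator checks NIfTI dimensions, not
orientation metadata. The generator's realism ends at the signal model, so
green tests here say nothing about motion, distortion or outlier handling on
clinical data.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run on the 16x16x5 phantom: five
example fixtures plus a 20-plan random sweep for validity-by-construction,
~70 single-field deletions for the mutation matrix, and 25 seeded noisy
replicates (difference-signal SNR ≈ 5, 40 pairs) for stochastic recovery,
which lands within 0.5% of the true masked mean against a 5% acceptance
band.
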