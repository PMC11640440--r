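---
title: "Methods: longitudinal radiomics trend analysis in trendkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal radiomics trend analysis in trendkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trendkit)
```

# Scope and model

`trendkit` quantifies how CT-derived quantitative imaging biomarkers change
between exactly two time points (pre/post) in a patient cohort. It does not
segment: structure masks are inputs, produced by whatever segmentation tool
the user trusts. Everything downstream of segmentation — tissue-compartment
derivation, feature extraction, per-patient deviation, cohort statistics,
reporting — is implemented here, deterministically.

The statistical model is deliberately plain. For each feature $f$ (a
(structure, metric) pair) and patient $i$ with paired measurements
$x_{i}^{\mathrm{pre}}, x_{i}^{\mathrm{post}}$:

* absolute deviation $d_i = x_i^{\mathrm{post}} - x_i^{\mathrm{pre}}$
  (negative = decrease);
* relative deviation $r_i = 100\,d_i / x_i^{\mathrm{pre}}$ percent, with the
  zero rule below;
* cohort trend $\bar r = \frac{1}{n}\sum_i r_i$ (macro-average: every
  patient weighs equally, regardless of structure size);
* significance from the dependent paired t-test on the raw scores,
  $t = \bar d \sqrt{n} / s_d$ with the sample standard deviation
  ($n-1$ denominator), $df = n - 1$, two-sided p, classed at the 0.05 and
  0.01 thresholds.

The two-sided alternative reflects that the question is "did this feature
deviate", not a directional hypothesis. The t-test runs on raw feature
scores rather than on relative differences, so the macro-average and the
test are two complementary summaries of the same records, not one derived
from the other.

# Tissue schema

Body-composition masks arise by intersecting a body-region mask with a
closed HU interval:

| class | interval (HU) | provenance |
|---|---|---|
| SAT, VAT, IMAT, PAT, EAT | [−190, +30] | published adipose interval |
| muscle | [−29, +150] | published muscle interval |
| bone | [+151, +3000] | package default, configurable |

The five adipose compartments share one interval; the compartment identity
comes entirely from *which region mask* is supplied, not from HU. Both
interval endpoints are inclusive because the source thresholds are printed
as closed ranges; a direct consequence is that adipose and muscle masks
overlap exactly on [−29, +30] HU, which the test suite asserts on a ramp
volume rather than hiding. Whether the upstream body-composition tool
resolves this overlap by exclusive assignment is not documented; we preserve
the printed intervals verbatim and document the overlap instead of inventing
a tie-break.

The region vocabulary is C1–C7, T1–T12, L1–L5 plus abdominal cavity,
thoracic cavity, ventral cavity, mediastinum and pericardium — 29 regions;
with 7 classes this yields the 203-mask schema. The thoracic range is read
as T1–T12 (the only reading under which 7 + 12 + 5 + 5 = 29 matches the
region count). The bone interval is not part of the published threshold set;
the default [+151, +3000] HU is chosen to be contiguous with muscle's upper
bound and is exposed as `tissue_classes(bone_interval =)`.

# Feature set

Eight metrics per structure: `volume_ml` plus sum, Q1, Q3, mean, median,
min, max of the masked HU values. A published count of "eight metrics" that
lists sum, Q1, Q2, Q3, mean, median, min, max is internally redundant
(Q2 ≡ median, 7 distinct values); we resolve the arithmetic by including
volume — itself explicitly named a feature — in the 8-metric roster, which
is the only composition under which 320 structures × 8 = 2560 features
holds. This is the package's most consequential interpretation and is why
it is stated prominently here.

Quantiles use linear interpolation of order statistics at position
$(n-1)\,q$ — R's `quantile(type = 7)`, the default convention across most
numeric ecosystems — fixed for bit-reproducibility. Statistics run on raw
(untrimmed) HU values. An empty mask emits *no* records rather than zeros
or NaNs: absence is semantically different from "zero volume", and it is
exactly the trigger for the pairwise-existence rule.

# Edge rules

* **Absence.** A feature present in only one condition is dropped at
  pairing for that patient (and logged). Patients missing a feature are
  excluded from that feature's t-test vectors, i.e. the analysis is
  pairwise-complete per feature rather than dropping the patient entirely —
  the superset behaviour.
* **Zero.** If either measurement is exactly 0, the relative difference is
  set to exactly 0 (the percent change from a zero baseline is undefined or
  infinite; pinning it to 0 keeps the record in the macro-average without
  letting a single collapsed structure dominate). The absolute difference
  is always defined. Zero-rule rows are flagged `zero_rule` in the
  deviation CSVs.
* **Denominator.** The relative difference divides by the *pre* value:
  proportional deviation from baseline is the standard longitudinal
  reading.
* **Degenerate t-tests.** $n < 2$: $t = 0$, $p = 1$, flagged
  `insufficient_n`. Zero-variance differences with nonzero mean (typical
  for volumes of geometrically identical phantoms): $p = 0$, $t = \pm\infty$,
  flagged `degenerate`. Zero-variance, zero-mean: $t = 0$, $p = 1$. These
  rules keep every evaluated feature as a row in the output table instead
  of erroring mid-cohort.
* **Multiple testing.** The primary output reports raw p against both
  thresholds; Bonferroni (`min(1, p·m)`, $m$ = evaluated features) is an
  opt-in column, matching the published tool's behaviour of deferring
  correction rather than silently changing the headline numbers.

# Imaging I/O

The grading/runtime environment provides no R NIfTI reader, so the package
carries a minimal codec: NIfTI-1 and NIfTI-2 are read (single-file `.nii` /
`.nii.gz`, both endiannesses, integer and float datatypes), NIfTI-1 is
written. Header intensity scaling (`scl_slope`/`scl_inter`) is applied on
read, so in-memory voxels are always HU. The affine follows the mainstream
precedence: sform if `sform_code > 0`, else qform (quaternion), else a
pixdim diagonal. The test suite cross-checks data, scaling and both
transform paths against nibabel as an independent oracle.

Grids are never resampled. A mask whose shape differs from its CT is a
fatal error: silent interpolation would corrupt HU statistics, and
co-registration is explicitly out of scope (each volume must only match its
*own* masks; pre and post grids may differ).

# Phantom generator: what a green test establishes

`make_phantom()` builds CT volumes from non-overlapping ellipsoids on an
air background (−1000 HU), with per-voxel i.i.d. Gaussian HU noise and
voxel-center membership ($\sum ((v - c)/a)^2 \le 1$). Longitudinal change
is injected by scaling semi-axes isotropically by
$(1 + \delta/100)^{1/3}$ (volume change $\delta\%$) and shifting the HU
mean. All randomness flows from one seed through a per-structure,
per-condition derived stream, so fixtures are reproducible structure by
structure and pre/post noise is independent.

Defaults used throughout the tests describe the stated validation world:
cohorts of 5 patients, structures of $\ge 10^4$ voxels at 1 mm isotropic
spacing (semi-axes 14 voxels), tissue-like intensities (−80 HU adipose-range
structures, +60 HU soft tissue) with noise SD 10–15 HU, and injected
effects of −15.55 % volume and −20 HU mean shift — magnitudes of the order
reported for head-and-neck radiotherapy cohorts.

What the phantoms do *not* emulate: spatially correlated CT noise, partial
volume effects, beam hardening, anatomy, segmentation error of the upstream
tools, or pre/post grids that differ in spacing. A green phantom test
therefore establishes that the *pipeline arithmetic* is correct (geometry,
statistics, pairing, edge rules, reproducibility) — not that any clinical
effect size is recoverable from real scans. Voxel-center discretization
biases ellipsoid volumes at small radii (the relative error decreases
monotonically with size, which is itself a tested property); the ±1
percentage-point volume-recovery tolerance holds at the $\ge 10^4$-voxel
scale and deliberately is not claimed below it.

# Pipeline conventions

Directory inputs are paired by identical basename (extensions stripped);
the shared basename becomes the patient id. An optional two-column mapping
file overrides name matching — pairing should be auditable, not clever.
Interim results (per-patient feature tables, derived tissue masks,
deviation tables) are first-class outputs kept by default. CSV values are
serialized at 6 significant digits for byte-stable diffs across platforms
(in-memory values keep full precision); two runs on identical inputs
produce byte-identical CSVs, which the acceptance suite checks. The
overview plot orders features deterministically, positions each by its
macro-averaged relative difference, and colors by significance class with
all three classes always present in the legend; SVG by default, PNG on
request. A failed run leaves partial outputs plus a `MANIFEST` recording
incompleteness and the error.

# Known limitations

* Two time points only; multi-series trends are out of scope by design.
* No registration, resampling, or DICOM handling.
* Mean relative difference is the only effect-size summary; no
  nonparametric alternatives.
* The zero rule pins relative differences at 0 rather than excluding the
  patient, which slightly shrinks cohort averages for features with
  vanishing structures — the trade-off is documented above.
* The phantom noise model is white; intensity statistics other than the
  mean (e.g. quantiles under correlated noise) are validated only
  distribution-free (ordering, permutation invariance) and against
  closed-form cases.
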