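# trendkit

Longitudinal radiomics trend analysis for paired CT volumes.

## The problem

Treatments such as radiotherapy leave measurable traces in CT images: fat
compartments shrink, muscle density drops. Quantitative imaging biomarkers
(QIBs) — per-structure volumes and Hounsfield-unit (HU) statistics — make
those changes measurable, but turning two time points of a cohort into a
defensible statement ("subcutaneous fat at C3 decreased significantly")
requires a reproducible chain: consistent segmentation-mask handling,
tissue-compartment derivation, feature extraction, per-patient pairing with
explicit edge rules, and cohort-level statistics. `trendkit` implements that
chain for researchers who already have structure masks (e.g. from external
deep-learning segmenters) and want the downstream analysis to be auditable.

## The method

For each patient with a pre- and a post-condition CT volume:

1. **Tissue masks.** Body-region masks (vertebral levels C1–L5 and five
   body cavities, 29 regions) are intersected with closed HU intervals:
   adipose \[−190, +30\] HU (shared by the SAT/VAT/IMAT/PAT/EAT
   compartments), muscle \[−29, +150\] HU, bone \[+151, +3000\] HU
   (configurable). 7 classes × 29 regions = 203 tissue masks.
2. **Features.** Every non-empty mask yields 8 metrics: volume in mL plus
   sum, Q1, Q3, mean, median (≡ Q2), min, max of the masked HU values
   (quantiles by linear interpolation at position (n−1)·q).
3. **Pairing and deviations.** Features are inner-joined per patient on
   (structure, metric); features existing in only one condition are
   excluded. Absolute difference is `post − pre`; relative difference is
   `100·(post − pre)/pre`, set to exactly 0 when either value is 0.
4. **Cohort evaluation.** Per feature: the macro-average of per-patient
   relative differences (each patient weighs equally) and a two-sided
   dependent paired t-test on the raw feature scores,
   `t = mean(d)·√n / sd(d)`, `df = n − 1`, classed at p < 0.05 and
   p < 0.01, optionally Bonferroni-corrected (`min(1, p·m)`).

Outputs are tidy CSVs, a run log, and an overview plot with one mark per
feature, positioned by mean relative difference and colored by significance.

## Worked example

A seeded 5-patient phantom cohort with a −15.55 % volume change injected
into a ~11 500-voxel "C3" ellipsoid and a −20 HU mean shift in "liver":

```r
library(trendkit)

spec <- phantom_spec(
  grid_shape = c(48L, 48L, 48L),
  structures = list(
    list(name = "C3",    center = c(16, 16, 24), semi_axes = c(14, 14, 14),
         hu_mean = -80, hu_sd = 10),
    list(name = "liver", center = c(38, 38, 24), semi_axes = c(7, 7, 7),
         hu_mean = 60, hu_sd = 8)
  ),
  seed = 2026L
)
cohort <- tempfile("cohort")
make_phantom_cohort(cohort, 5, spec,
                    change = list(C3    = list(volume_change_pct = -15.55),
                                  liver = list(hu_shift = -20)),
                    seed = 2026L)

res <- run_pipeline(run_config(
  pre  = file.path(cohort, "pre"),   post = file.path(cohort, "post"),
  out  = tempfile("radta_out"),
  masks_pre  = file.path(cohort, "masks_pre"),
  masks_post = file.path(cohort, "masks_post")
))
subset(res$evaluation,
       metric %in% c("volume_ml", "hu_mean") &
       structure %in% c("C3", "liver", "SAT_C3"))
```

prints

```
   structure    metric n mean_rel_diff_pct           t            p significance
2         C3   hu_mean 5        -0.1182131    1.268278 2.734898e-01           ns
8         C3 volume_ml 5       -15.1307218        -Inf 0.000000e+00       p<0.01
26     liver   hu_mean 5       -33.2937817 -281.012545 9.620813e-10       p<0.01
32     liver volume_ml 5         0.0000000    0.000000 1.000000e+00           ns
42    SAT_C3   hu_mean 5        -0.1182131    1.268278 2.734898e-01           ns
48    SAT_C3 volume_ml 5       -15.1307218        -Inf 0.000000e+00       p<0.01
```

Reading the table: the injected −15.55 % volume change is recovered as
−15.13 % (the 0.4 pp gap is ellipsoid voxelization error, which shrinks with
structure size); geometry is identical across phantom patients, so the
volume t-test degenerates to zero-variance differences (`t = -Inf`,
`p = 0`, flagged). The liver HU shift appears as a −20 HU mean change
(−33 % relative to the +60 HU baseline) with a regular, highly significant
t-test, while unchanged features stay non-significant. `SAT_C3` mirrors
`C3` because the phantom's C3 ellipsoid sits entirely inside the adipose HU
interval. The output directory additionally holds `evaluation.csv`,
per-patient feature/deviation CSVs under `interim/`, derived tissue masks,
`overview.svg` and `run.log`.

## Command line

```sh
inst/exec/trendkit run --pre pre/ --post post/ --out results/ \
    --masks-pre masks_pre/ --masks-post masks_post/ [--bonferroni] \
    [--pairs pairs.tsv] [--label-table labels.txt] [--no-interim] \
    [--plot-format svg|png] [--seed 1]
```

`--pre/--post` accept either two NIfTI files or two directories whose files
are matched by basename (overridable with `--pairs`). Masks come either as
per-structure binary NIfTI directories or as integer label images plus a
two-column label table.

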