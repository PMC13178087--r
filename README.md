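# mitomorph

Quantitative morphometry of cardiomyocyte mitochondrial ultrastructure from
transmission-EM annotations.

Assessing how badly chronic heart failure (CHF) and atrial fibrillation (AF)
have damaged the mitochondria of atrial cardiomyocytes requires more than
counting organelles on a micrograph: both their packing between myofibrils
and the integrity of their inner-membrane cristae matter. `mitomorph`
implements a planar-morphometry pipeline for right-atrial-appendage biopsy
micrographs traced in ImageJ (or any tool exporting GeoJSON), built around
three quantities:

* **TAIM** — *total area of interfibrillar mitochondria*: on 5000×
  micrographs, the percentage of the traced interfibrillar space occupied by
  traced mitochondrial cross-sections,

  `TAIM = 100 · Σᵢ area(mitoᵢ ∩ region) / Σⱼ area(regionⱼ)`.

* **OIMR** — *outer-to-inner membrane length ratio*: on 15 000×
  micrographs, per mitochondrion,

  `OIMR = 100 · length(outer membrane) / Σ length(inner membrane traces)`,

  where the inner length totals the inner boundary membrane and every
  traced crista. Dense, intact cristae give low OIMR; cristae loss drives it
  towards 100 %.

* **Total index** — `TAIM / OIMR`, a single dimensionless summary of
  packing density *and* internal structure. The two components move in
  opposite directions as ultrastructure deteriorates, so the ratio amplifies
  their joint signal.

Per patient, the measurement protocol averages three micrographs at each
magnification with three mitochondria per 15 000× micrograph; the index is
formed from the patient-level means. Cohorts are summarised as median
[Q1; Q3], compared with the two-sided Mann–Whitney test, and related to a
binary outcome (e.g. AF) by rank-based ROC analysis
(AUC = U/(n₀·n₁)).

Because all three quantities are ratios of areas or lengths, the pixel scale
cancels and no nm/pixel calibration is needed.

The package is aimed at cardiovascular morphology groups processing manual
EM annotations, and ships a seeded synthetic-annotation generator with known
ground truth so the entire pipeline is testable without any micrographs.

## Worked example

Generate a 5000× scene with a known packing fraction, a membrane set with a
known length ratio, and a two-group cohort; then run the comparison:

```r
library(mitomorph)

sc <- generate_scene(scene_spec(target_packing = 0.437, seed = 1), "demo_5000_1")
sc
#> <annotation scene 'demo_5000_1' at 5000x: 1 region(s), 35 mitochondria, 0 membrane trace(s)>
taim_for_scene(sc)
#> [1] 43.7

ms <- generate_membrane_set(membrane_spec(target_oimr = 31, seed = 1))
sc15 <- scene("demo_15000_1", 15000, membranes = list(m1 = ms))
scene_oimr(sc15)
#> # A tibble: 1 × 2
#>   mitochondrion_id oimr_pct
#>   <chr>               <dbl>
#> 1 m1                     31

co <- generate_cohort(cohort_spec(seed = 1))   # 27 + 12 patients
compare_cohort(co)
#> Two-group comparison (Mann-Whitney, rank ROC)
#>   taim_pct      55.8 [44.2; 64.8] vs  43.3 [39.0; 54.6]   U=119, p=0.196, AUC=0.633 (lower_in_positive)
#>   oimr_pct      30.5 [27.4; 35.0] vs  35.9 [25.9; 41.0]   U=128, p=0.308, AUC=0.605 (higher_in_positive)
#>   total_index    1.9 [1.3; 2.2] vs   1.3 [1.1; 1.7]   U=113, p=0.140, AUC=0.651 (lower_in_positive)
```

The generator recovered its ground truth exactly (43.7 % packing, 31 %
membrane ratio). In the simulated cohort the index runs lower in the
positive (AF-like) group — the direction the index is designed to detect —
with an AUC of 0.651 for this draw; `p_value` columns, per-group
median [Q1; Q3] and ROC points (`plot_roc()`) come with it.
`tidy()` and `glance()` return the comparison as plain tibbles.

Real annotations enter through `read_imagej_rois()` (`.roi`/`.zip` plus a
role manifest) or `read_geojson_scene()`, and flow through
`compute_morphometry()` to `write_results_csv()`.

## Command line

A thin wrapper is installed under `exec/`:

```sh
mitomorph simulate --out fixtures --seed 7 --n_per_group 3,3
mitomorph compute  --manifest fixtures/manifest.csv --out results.csv
mitomorph compare  --results results.csv --out comparison/
mitomorph report   --manifest fixtures/manifest.csv --out report/
```

Exit codes: 0 success, 2 invalid input, 3 protocol/feasibility violation.
Options can also come from a flat YAML file via `--config`; flags win.

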