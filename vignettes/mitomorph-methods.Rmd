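---
title: "Morphometry of mitochondrial ultrastructure: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of mitochondrial ultrastructure: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomorph)
```

## The measurement model

Chronic heart failure remodels cardiomyocyte mitochondria in two distinct
ways visible on transmission-EM micrographs of right-atrial-appendage
biopsies: the organelles thin out between myofibrils, and their cristae —
the inner-membrane folds carrying the respiratory chain — degrade.
`mitomorph` quantifies both from manual planar annotations.

**TAIM (total area of interfibrillar mitochondria).** On a 5000×
micrograph the annotator traces the interfibrillar space as one or more
closed contours and every mitochondrion inside it. TAIM is the occupied
area fraction in percent:

$$\mathrm{TAIM} = 100\cdot\frac{\sum_i |m_i \cap R|}{\sum_j |R_j|},$$

where $R$ is the union of the traced interfibrillar regions. Two modelling
commitments are made here. First, a mitochondrion partially outside the
region contributes only its clipped intersection: "inside the region" has
to generalize deterministically to partial overlaps, and clipping is the
only rule that neither discards nor double-counts area. Second, the
denominator is the *whole* traced interfibrillar area, including the part
covered by mitochondria — observed fractions around 40–50 % are only
consistent with this reading (excluding mitochondrial area from the
denominator would push typical values above 70 %).

**OIMR (outer-to-inner membrane length ratio).** On a 15 000× micrograph
the annotator traces, per mitochondrion, the closed outer-membrane contour
and every resolvable inner-membrane segment. OIMR is

$$\mathrm{OIMR} = 100\cdot\frac{L_\text{outer}}{\sum_k L_{\text{inner},k}}.$$

The inner total deliberately pools the inner boundary membrane (when
traced) with all cristae: typical observed values near 31 % are impossible
unless cristae are counted, since the inner boundary membrane alone runs
just inside the outer membrane and would give a ratio near 100 %. Cristae
loss therefore *raises* OIMR towards 100 %.

**Total index.** The patient-level index is
$\mathrm{TAIM}/\mathrm{OIMR}$, computed from the patient means of the two
components, not per scene — the index is defined on the two patient
parameters, and the two components are measured on different micrographs
(different magnifications), so no per-scene pairing exists. Packing loss
and cristae loss move the two components in opposite directions, so the
ratio amplifies their joint signal: low index = sparse mitochondria with
degraded cristae.

**Averaging protocol.** Three micrographs per patient and magnification;
three mitochondria per 15 000× micrograph. The patient OIMR is the grand
mean over all measured mitochondria. Under the balanced 3 × 3 design this
equals the mean of per-scene means exactly; for unbalanced data the two
rules diverge and the grand mean (equal weight per mitochondrion) is used —
a mitochondrion is the measurement unit, and scenes with more measured
mitochondria carry proportionally more information. By default a deviation
from 3 × 3 warns; `strict = TRUE` turns it into an error, for workflows
that must enforce the protocol.

## Geometry and numerics

Contours are continuous pixel coordinates (no 0/1-based grid semantics);
since every reported quantity is a ratio, the pixel scale cancels and no
physical calibration is required or accepted. Areas are absolute shoelace
sums — annotators' winding direction is not controlled, so orientation must
not matter. Polygons are validated as simple (an $O(n^2)$ pairwise segment
test, ample for hand-traced contours of tens to hundreds of vertices);
degenerate or self-intersecting contours are rejected by name rather than
silently measured. Intersection areas go through Vatti polygon clipping
(\pkg{polyclip}), with the clipper's spatial resolution pinned to $10^{-12}$
of the coordinate magnitude so that clipped areas agree with shoelace areas
to ~$10^{-14}$ relative — the clipper's default integer grid would
otherwise quantize areas at the $10^{-9}$ level, which the test suite's
similarity-invariance checks (tolerance $10^{-9}$) would see.

Quartiles follow Tukey's inclusive-hinge rule (`stats::fivenum`). The rule
had to be fixed explicitly because common statistics packages default to
different quartile definitions, and median [Q1; Q3] summaries are part of
the reported output.

The Mann–Whitney test uses midranks for ties. The exact two-sided p is used
for tie-free samples up to $n_0+n_1 \le 25$ (doubling the smaller tail of
the exact U distribution); with ties, exact mode falls back to a seeded
Monte-Carlo permutation of labels (default $10^5$ draws); otherwise the
normal approximation with tie correction and continuity correction is used.
ROC analysis is computed by the rank identity $\mathrm{AUC} = U/(n_0 n_1)$
and reported oriented so AUC ≥ 0.5 with an explicit direction flag — in the
motivating application the index is *lower* in the positive (AF) class, and
silently flipping the orientation would hide that. No AUC confidence
interval is reported by default.

## The synthetic-annotation generator

No public annotation sets exist for this kind of measurement, so the
generator is a first-class module: it emulates annotation scenes whose
ground truth is known *by construction*, which is what makes every
downstream stage testable.

**Scenes (TAIM ground truth).** A rectangular interfibrillar region is
tiled into cells; each cell receives one convex, ellipse-shaped outline
with seeded size, aspect and position jitter, and all outlines are then
rescaled about their centroids by one common factor chosen analytically so
the realized area fraction equals the target exactly (shrinking convex
bodies about their centroids preserves disjointness and containment).
Grid placement rather than naive sequential rejection sampling is a
deliberate choice: random sequential placement of disjoint convex bodies
jams near an area fraction of 0.55, below fractions the generator must
reach; the grid construction reaches ~0.72 and fails with an explicit
feasibility error beyond that. Convex shapes are used because every
measured quantity depends only on areas and lengths; shape realism is a
non-goal.

**Membrane sets (OIMR ground truth).** The outer membrane is a 96-vertex
elliptical contour of perimeter $P$; cristae are near-diametral chords
drawn with a seeded RNG and contracted about their midpoints by one common
factor so the total inner length equals $100\,P/\mathrm{OIMR}_\text{target}$
exactly (contraction about a midpoint keeps a chord inside the convex
contour). Unreachable targets — too few chords for the required length —
raise a feasibility error.

**Cohorts.** Per-patient TAIM and OIMR are drawn from normal distributions
truncated to (1, 99) %, with group locations at the published group medians
(TAIM 49 vs 42 %; OIMR 31 vs 35 %) and scales set from the published
interquartile ranges via $\sigma = \mathrm{IQR}/1.349$; group sizes default
to 27 and 12. Only medians and IQRs are published, so matching normal
quantiles is the minimal distributional assumption, and TAIM and OIMR are
drawn independently within patient because no joint information is
published. This is a known limitation with a measurable consequence: the
real patient-level index separation (medians 1.75 vs 0.96) is larger than
independent marginals can produce (about 1.58 vs 1.20), implying
within-patient dependence between the two parameters in the real cohort.
Simulation-based checks that depend on the *index* effect size therefore
understate the published separation: the power of the index comparison at
n = 27/12 is ~28 % under these defaults, and the group-effect direction is
recovered in ~93 % of replicates. The defaults are nonetheless kept at the
published marginal values rather than strengthened, because they are the
only values the published record pins down.

With `materialize = TRUE` the drawn parameters are additionally realized as
full annotation scenes following the 3 × 3 protocol: per-scene packing
targets are the patient value plus a symmetric, zero-mean spread (so the
patient mean is exact), and likewise for the nine per-mitochondrion ratio
targets. Materialized TAIM is clamped to (2, 65) % and OIMR to
(6.5, 98.5) % — the feasibility windows of the geometric constructions —
and the clamped values are recorded in the returned truth table. All
generators are bit-reproducible given spec and seed.

**What passing tests do and do not show.** The generator produces convex,
disjoint, noise-free contours with exactly known ratios. Passing recovery
tests demonstrates that the measurement pipeline is correct arithmetic on
annotations; it says nothing about segmentation quality, annotator
variability, or non-convex/overlapping organelle profiles in real
micrographs — the package measures traces, it does not produce them.

## Problem sizes used in the test suite

The suite exercises: 200 random convex polygons against a $10^6$-sample
Monte-Carlo rasterization oracle; exact Mann–Whitney p against full
enumeration for every group split up to $n_0+n_1 = 12$; the AUC–U identity
on 1000 random tied instances; 2000 null-cohort replicates for type-I
calibration and 500 default-effect replicates for power; and small
materialized cohorts (5–6 patients) for end-to-end file-format roundtrips.
These sizes give Monte-Carlo standard errors comfortably below the asserted
tolerances while keeping the default run lightweight.

## Known limitations

* Planar (2-D) morphometry only: no stereological correction, no 3-D
  reconstruction, no shape descriptors.
* The ImageJ `.roi` codec covers polygon/freehand/traced/polyline/freeline
  (and rectangles); point, oval, angle and straight-line ROIs are rejected.
  Coordinates are written on the integer pixel grid, so ROI roundtrips are
  exact only to 0.5 px (sub-pixel float coordinates are read when present).
* Roles for ImageJ ROIs come from an explicit manifest, not from ROI-name
  parsing — naming conventions vary too much across annotation workflows to
  guess from.
* The cohort generator draws the two parameters independently within
  patient (see above).
* No multiple-testing correction across the three parameter comparisons is
  applied, and none is imposed — the comparisons are reported side by side.
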