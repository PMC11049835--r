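---
title: "Measuring sperm nuclear architecture from FISH images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sperm nuclear architecture from FISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In a mature human sperm nucleus the chromatin is packed an order of
magnitude more densely than in somatic cells, and this packing is spatially
organized: centromeres cluster into a central chromocenter, and the two
telomeres of each chromosome are bound to one another near the nuclear
periphery, giving every chromosome a hairpin conformation inside a distinct
chromosome territory. Departures from this architecture accompany poor
sperm quality. Two scalar summaries of the architecture of one chromosome
(here chromosome 1, the longest) can be read off a two-dimensional FISH
preparation:

* **ITD, inter-telomeric distance** — the Euclidean distance between the
  short-arm and long-arm telomere probe signals, divided by the nucleus
  length from the midpiece insertion (base) to the tip. Dimensionless; a
  tight hairpin gives a small ITD.
* **CTA, chromosomal territory area** — the area of the whole-chromosome
  painting signal divided by the whole nucleus area. Dimensionless; a
  compact territory gives a small CTA.

`spermfish` computes both per cell from three-channel images (nuclear
counterstain, telomere probes, chromosome paint), compares groups of cells
labelled by high-magnification morphology score class (score 6 = "high",
score 0 = "low"), and fits a small Gini-impurity decision tree that
classifies cells from (ITD, CTA).

Because no raw image set is publicly deposited for this assay, the package
ships a synthetic FISH-image generator with exact per-cell ground truth.
All validation is parameter *recovery*: the generator embeds known ITD/CTA
values in rendered images, and the tests require the measurement pipeline
to get them back.

## The synthetic study and its calibration

The emulated study design is five subjects — two in the high-score class,
three in the low-score class — with 50 analyzable cells each, giving 150
low-score and 100 high-score cells. The phrase "50 cells" in the source
protocol is ambiguous between per-subject and per-group; we read it
per-subject, which matches standard FISH scoring practice, and expose it as
`cells_per_subject` so either reading can be run.

Per-cell true values are drawn from class-specific beta distributions on
(0, 1). Each class preset is calibrated from three numbers per metric — the
reported group median and a 95% interval:

| metric | class | q2.5 | median | q97.5 |
|--------|-------|------|--------|-------|
| ITD | low  | 0.06 | 0.379 | 0.73 |
| ITD | high | 0.00 | 0.269 | 0.59 |
| CTA | low  | 0.17 | 0.349 | 0.54 |
| CTA | high | 0.09 | 0.20  | 0.32 |

Two interpretation points are deliberate and worth stating prominently:

1. The intervals are treated as the **2.5th–97.5th percentile range of
   per-cell values**, not as confidence intervals of the median. At
   n ≥ 100 cells per group a CI of the median would be many times narrower
   than these intervals; only the per-cell-spread reading is consistent
   with their width.
2. Calibration (`calibrate_preset()`) enforces the **median exactly** (root
   solved to 1e-3 or better) and fits the two tail quantiles in least
   squares, because the medians are the quantities the downstream analysis
   reproduces. For ITD-high the reported lower bound 0.00 is unattainable
   by any beta quantile and is approached as closely as the median
   constraint allows.

ITD and CTA are sampled independently within a cell (no dependence is
reported for them); a Gaussian-copula `correlation` knob exists for
sensitivity analyses but defaults to 0. Beta draws clip the underlying
uniform at 5e-4 from either end as a geometric guard; no quantile between
0.025 and 0.975 is measurably affected.

## What the renderer emulates — and what it does not

Each cell is rendered at 12 px/µm (the calibration of a ×100 oil-immersion
setup, stored in a JSON sidecar next to each 16-bit multi-page TIFF) on a
128 × 128 px field:

* **Nucleus** (channel 0): an ellipse with semi-axes drawn within ±10% of
  2.25 × 1.5 µm (normal human sperm-head half-dimensions), random
  orientation, filled at 3000 counts over a 500-count background, Gaussian
  blur σ = 1 px. A brighter stub (×1.5) inside the mask at one Feret
  endpoint marks the midpiece insertion, so base and tip are identifiable.
* **Telomere spots** (channel 1): two Gaussian spots of σ = 2 px and peak
  12000 counts at sub-pixel positions placed on a chord whose length is
  exactly ITD × nucleus length (nucleus length = Feret diameter of the
  nucleus mask, the same definition the measurement uses).
* **Territory** (channel 2): a connected region grown from an interior
  seed, covering exactly `round(CTA × nucleus pixels)` pixels, filled and
  blurred like the nucleus.
* **Noise**: Poisson shot noise (gain 4 counts/photon) plus Gaussian read
  noise (σ = 20 counts) on every channel; `noise_scale = 0` renders
  noiselessly for oracle tests.

Not emulated: the hooked/asymmetric outline and vacuoles of real sperm
heads, hybridization and illumination inhomogeneity, chromatic shift,
probe-failure cells, 3D structure, and touching or overlapping nuclei.
Passing round-trip tests therefore demonstrates that the *measurement
operators are correct and unbiased* under controlled imaging, not that the
pipeline is robust to every real-world artifact; on real data the
interactive checks that the automated QC replaces (see below) regain
importance.

## Measurement pipeline: numerical choices

**Segmentation.** Global Otsu threshold on the counterstain channel,
largest connected component, hole fill. The original analysis delineated
nuclei interactively in Fiji; the automated thresholding here is a
documented stand-in. Nucleus length is the maximum Feret (caliper) diameter
— pixel-center extremes plus 1 px for the half-pixel extent at each end —
which is rotation-stable (tested to ≤2%) and coincides with the anatomical
base-to-tip axis for an elliptical head. The base label goes to the Feret
endpoint whose just-inside 7×7 neighborhood is ≥5% brighter (the midpiece
stub), falling back to the endpoint nearer the mask's wider half; the
length, and hence ITD, is independent of which end is called base. Geometry
QC bounds: area 3–30 µm², length 2–8 µm.

**Spot detection.** Scale-normalized Laplacian-of-Gaussian filtering at
σ ∈ {1.5, 2, 3, 4} px, restricted to the nucleus mask. Candidate positions
are taken from local maxima of the *finest* scale: coarser scales blur a
close pair of spots into a single midpoint maximum, which would either
hide one spot or inject a spurious third candidate. Candidate strength is
the maximum response across scales; the detection threshold (default 300
counts, ≈5% of the nominal spot response and far above the noise floor) and
a 3-px non-maximum suppression radius are exposed in `spot_params()`.
Sub-pixel centers are intensity-weighted centroids of the
background-subtracted 5×5 neighborhood, making positions exactly invariant
to constant intensity offsets (the LoG kernels are zero-sum for the same
reason).

A **lone candidate** is not discarded: with both telomeres of a
hairpin-conformed chromosome near one another, the two signals overlap
optically, and the reported ITD distribution extends to 0. The single blob
is split into two sub-spots along its principal intensity axis using second
moments — for two equal spots a distance *d* apart the intensity variance
along the pair axis exceeds the perpendicular one by *d*²/4, so
*d* = 2√(λ₁ − λ₂), which degrades gracefully to a coincident pair for an
isotropic blob. Without this step, QC exclusion of merged pairs truncates
the low tail of the ITD distribution and biases group medians upward by
up to ~0.03. Conversely, when more than two comparably strong candidates
exist (a third within 80% of the second-best response) the cell is
ambiguous and is QC-failed rather than resolved by force-picking, matching
scoring practice of discarding unscorable nuclei.

**Territory.** Otsu threshold computed over the paint intensities of
nucleus-mask pixels only (the background outside the nucleus has no bearing
on the territory definition); all thresholded in-mask pixels count, in
however many components. Two degenerate regimes are detected by a contrast
guard (Otsu class means closer than 4 pooled standard deviations): if the
in-mask signal still sits clearly above the out-of-mask background the
channel is saturated and the territory is the whole nucleus; otherwise
there is no paint signal and the area is 0 with a warning flag.

**Per-cell QC** runs in a fixed order — segmentation, geometry limits, spot
count, territory signal — so the first failing reason is deterministic.
Failed cells carry no metric values and are excluded from all statistics.

## Statistics

Groups are compared with the two-sided Mann–Whitney U test (the metric
distributions are skewed; normality is not assumed), pooling cells per
class. Subject-level clustering is deliberately ignored to mirror the
emulated analysis; `subject_summary()` emits a per-subject table so the
cluster structure stays visible. U is the min-convention statistic from
midranks. For pooled n ≤ 12 without ties the p-value is exact by full
enumeration of rank assignments — with the min convention,
P(U′ ≤ U) already covers both tails. Otherwise a normal approximation with
tie correction and a 0.5 continuity correction is used; both paths are
cross-checked against `wilcox.test()` and against brute-force enumeration
in the test suite.

## The decision tree

`gini_tree()` is a from-scratch CART-style classifier on (ITD, CTA):
candidate thresholds are midpoints between consecutive distinct feature
values; each node takes the (feature, threshold) pair minimizing the
size-weighted mean child Gini impurity 1 − p²_low − p²_high, with exact
ties resolved toward the smaller threshold; splits are (≤ t, > t).
Defaults: `max_depth = 2` (a shallow, clinically readable tree),
`min_leaf = 5`, no pruning, leaf ties predict "low" (the conservative
call: treating a borderline cell as low-quality). `best_split()` is
verified against exhaustive search on 1000 random instances, and fitted
roots against `rpart` (which uses the same midpoint convention) to 1e-6.

Under the default study conditions the root split lands on CTA — the metric
whose class distributions barely overlap — at a threshold between the two
class medians (0.20 and 0.349). Note that Gini minimization with 150
low-score versus 100 high-score cells places that threshold nearer the
high-score distribution (typically ≈ 0.23–0.31 across seeds, median
≈ 0.27), a little below the midpoint of the class medians (≈ 0.275):
misclassifying the more numerous class costs more, so the boundary shifts
away from it. A balanced design would center the threshold slightly
higher.

## Problem sizes and determinism

The test suite validates round-trip recovery on the full 250-cell rendered
study (median absolute error ≤ 0.01 for both metrics, 95% of cells within
0.03), group-median recovery to ±0.02, the significance pattern over 20
generator seeds in truth-only mode (fast, no rendering), and the tree root
over 10 seeds; these sizes were chosen to keep the complete suite in the
minutes range on one CPU while leaving the statistical assertions
well-powered. Every random draw descends from a single design seed; the
ground-truth table is byte-identical across runs, rendering uses per-cell
derived seeds so truth-only runs reproduce the same truth, and a ±0.02
group-median band at these n is a 1–2 σ statement about a sample median —
a reminder that single-seed checks of medians sit close to the sampling
noise floor by construction.

## Known limitations

* The nucleus segmentation and the within-mask Otsu territory threshold
  are automated stand-ins for steps the original assay performed
  interactively; absolute CTA values depend on the thresholding convention.
* ITD normalization uses the mask's Feret diameter; a manually traced
  base-to-tip axis on a curved head could differ by a few percent.
* Moment-based splitting assumes a lone telomere candidate is an
  unresolved *pair*; on real data a genuine single signal (probe failure)
  would be mis-split into a near-zero ITD instead of being QC-failed.
* One nucleus per field is assumed; multi-cell fields need prior cropping.
* 2D projection: loci separated mainly along the optical axis appear
  closer than they are, an intrinsic limit of the assay this package
  reimplements.
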