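---
title: "Aggregation-free grid-level evaluation of WSI cancer detection"
author: "wsigrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aggregation-free grid-level evaluation of WSI cancer detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wsigrid)
```

## The evaluation problem

Most AI systems for whole-slide-image (WSI) diagnosis are validated only on
their slide-level output, produced by an aggregation model (pooling or a
second network) sitting on top of a patch classifier. That design makes the
slide call hard to audit: a correct slide label can coexist with wrong
localizations. `wsigrid` implements the alternative evaluation protocol in
which the slide is meshed into disjoint physical grids, the detector is
scored grid by grid against an adjudicated per-grid ground truth, and the
slide call is *derived* from the grid calls with no learned aggregation:

* a truth-positive slide is a **TP slide** iff the detector hits at least
  one truth-positive grid (false alarms elsewhere do not help), otherwise
  an FN slide;
* a truth-negative slide is a **TN slide** iff the detector raises no flag
  on any grid, otherwise an FP slide.

Because one hit among many lesion grids suffices, slide-level sensitivity
is mechanically higher than grid-level sensitivity, while slide-level
specificity is *lower* than grid-level specificity — a single stray flag
spoils a clean slide. Both consequences are visible in the reference
tables shipped with the package and in every simulation.

## Grid meshing and the labelling rule

A scan is a pixel raster with a known microns-per-pixel scale (MPP). The
mesh divides it into squares of physical edge $e$ (mm):

$$ n_\mathrm{cols} = \left\lceil \frac{W_\mathrm{px} \cdot \mathrm{MPP}}{1000\,e} \right\rceil, $$

and likewise for rows, so the grids are disjoint and jointly cover every
pixel; edge grids may be physically partial but are never dropped (a
partial grid can still hold enough tumour to matter). Prediction happens on
*fine* grids ($0.25 \times 0.25$ mm²); display happens on $0.5 \times 0.5$
mm² grids derived from the fine grids.

A fine grid is labelled positive when the cumulative area of positive
segmentation-mask pixels inside it **exceeds** 625 µm² — strictly greater
than, so a grid holding exactly 625.0 µm² stays negative (an inclusive
variant exists behind `strict = FALSE`, off by default). 625 µm² is 1% of
a full fine grid. Conventions the protocol leaves open, fixed here once:

* **Coordinates**: 0-based row/column indices, top-left origin, half-open
  pixel rectangles — the standard raster convention. (R matrices are
  1-based internally; every exported table and box uses 0-based indices.)
* **Rollup rule**: a display grid aggregates its up-to-$2\times2$ fine
  grids by logical OR (`min_positive = 1`). OR is the only rule under
  which the display view flags every localized detection; requiring more
  constituents is available as a config but would hide single-fine-grid
  detections, and re-thresholding area at the 0.5 mm scale would do the
  same for small lesions straddling grid borders.
* **Box colour**: viewer boxes are red when the 4-connected positive
  region supporting the box reaches 6400 µm², else yellow; a display grid
  touched by several regions is coloured by the largest. Colour is
  deliberately excluded from every metric. Connected components come from
  `EBImage::bwlabel` (4-connectivity).

## Ground-truth adjudication

Per-grid truth is established by two independent annotators plus the AI
output: unanimity makes the label; *any* disagreement — including the two
annotators agreeing with each other against the AI — escalates the grid to
a chief, whose label is final. The chief input is a full label map or a
callback receiving only grid identities, so the implementation cannot leak
the sources' labels to the chief; blinding holds by construction.
Annotation is adjudicated at display scale (where annotators work) and
broadcast to the fine lattice; slide truth is any-positive over grids.
Lesion area is measured as positive-fine-grid count × 0.0625 mm² — the
protocol reports areas without defining the measurement, and the
grid-derived area is the one quantity every input modality provides.

## Statistics

All intervals are Wald: $p \pm z\sqrt{p(1-p)/n}$ with $z = 1.96$, and
**not clipped** to $[0,1]$: the reference slide-level sensitivity of
163/164 prints an upper bound of 100.58%, which only an unclipped interval
reproduces. Likelihood ratios are $LR^+ = \mathrm{sens}/(1-\mathrm{spec})$
and $LR^- = (1-\mathrm{sens})/\mathrm{spec}$, computed from unrounded
proportions; degenerate rates follow the conventions the reference tables
use ($LR^- = 0$ at perfect sensitivity, $LR^+ = \infty$ at perfect
specificity; $LR^-$ at specificity 0 is undefined and reported as such).
Note that the subgroup $LR^+$ values in the original tables were evidently
computed from the two-decimal rounded percentages (e.g. 90.07/3.51 =
25.66, where raw counts give 25.64); this package always uses unrounded
proportions and rounds only for display, half-up to two decimals on the
percent scale.

```{r fixtures}
panel <- metric_panel(load_fixture("grid_overall"))
panel$sensitivity
panel$specificity
c(lr_pos = panel$lr_positive, lr_neg = panel$lr_negative)
```

ROC curves sweep every distinct score as a threshold and integrate by the
trapezoidal rule; tied scores cross together, which is exactly the
Mann-Whitney convention of half-crediting ties. For a detector that only
emits hard labels the package reports the single operating point and
refuses to extrapolate an AUC — a binary output has no curve, and
inventing one would overstate what was measured. (How the original
analysis obtained an AUC from an apparently binary grid output is not
documented; the package therefore attaches AUCs only to score-emitting
oracles.)

McNemar tests on revision counts use the exact binomial sign test for
fewer than 25 discordant pairs and the continuity-corrected chi-square
$(\,|b-c|-1)^2/(b+c)$ otherwise. The correction term is capped at
$|b-c|$: an uncapped correction at exact balance ($b=c$) produces a
spurious positive statistic ($p \approx 0.92$ at $b=c=40$) where the
exact test gives $p = 1$; capping keeps the two variants consistent where
they should agree. With no discordant pairs the test is degenerate and
reported as $p = 1$ with a flag.

Reader "average" performance is the **micro-average** (counts pooled
across readers) — the only average that is itself a binomial proportion
with a meaningful Wald interval; the macro-average of per-reader estimates
is reported alongside since the original analysis does not say which it
used.

One documented bookkeeping discrepancy: the reference analysis describes
its 3,169 pooled FN→TP revisions as "4.21% of all positive grids", but
3,169 / 75,914 = 4.17%. The package reports the ratio against the stated
positive-grid total and leaves the 4.21% unexplained. Likewise the four
per-reader revision rows sum to 3,386, not 3,169 — readers revised
overlapping grids, as the original footnote states — so fixture-total
invariants are only asserted for counts that actually add up (grids,
slides, positive grids).

## The synthetic cohort

No slides or model outputs from the reference study are deposited, so the
package ships a generator whose defaults emulate the study marginals:

| parameter | default | basis |
|---|---|---|
| slides | 1,418 (analyses use 400) | cohort size |
| positive-slide prevalence | 164/1418 ≈ 0.116 | slide truth counts |
| surgical fraction | 238/1418 | procedure mix |
| slide size | 90–110 fine grids per side | ~2,500 display grids/slide |
| lesion area | log-uniform, 0.5–349.25 mm² | observed min/max; log-uniform puts most mass on small lesions, matching a cohort where most positives are endoscopic polyps |
| oracle sens/spec | 0.9025 / 0.9660 | measured grid-level operating point |
| reader baseline sens/spec | 0.818 / 0.9993 | measured reader averages |

Lesions are grown as Eden-model blobs (uniformly random frontier
accretion), giving 4-connected regions of exactly the sampled grid count;
shape realism beyond contiguity is out of scope. The oracle flips labels
independently per grid by default; `spatial_correlation > 0` places the
same expected number of errors as connected clumps of geometric mean size
$1+sc$ (the error count is drawn first, so marginal rates are preserved).
Scores are Beta-distributed around the predicted label, solely to exercise
the ROC machinery. Readers revise only grids where the AI gives them a
reason (a missed grid the AI flagged, a false alarm the AI left clean),
with direction-specific flip probabilities; the default panel's
propensities are spread so that beneficial revisions dominate harmful ones
by about two orders of magnitude on positive grids, the structure observed
in the reference reader study.

**What the simulation does and does not show.** Passing tests on this
generator validate the *accounting machinery* — meshing, thresholding,
adjudication, confusion derivation, interval coverage, revision
conservation — under exactly known conditions. They do not validate
behaviour on real histology, and two divergences are worth naming. First,
with independent false alarms at 3.4% per grid, a ~10,000-grid negative
slide carries at least one flag with probability ≈ 1, so simulated
slide-level specificity degenerates to 0; the 68.26% observed on real
slides implies false alarms heavily concentrated on a subset of slides
(artefacts, inflamed tissue), a cross-slide overdispersion this
per-grid error model does not attempt to produce. Second, readers who err
independently per grid essentially never overlook *every* grid of a
multi-grid lesion, so whole-slide misses — the substrate of the
missed-slide Venn analysis — are vanishingly rare in simulation; real
misses are slide-level attention failures. Both analyses therefore
exercise their machinery on the published count structures as well as on
synthetic data. For the same reason the real-data AUCs are not
reproducible here and no attempt is made to match them.

## Numerical choices and degenerate inputs

* Pixel→grid assignment uses `floor(px · MPP / edge)` with a $10^{-9}$
  tolerance absorbed into ceilings, so representation noise at exact
  boundaries cannot shift a pixel across grids.
* Zero denominators (no positive units, empty stratum) raise typed
  `undefined-metric` errors naming the metric rather than returning NaN;
  the report writer catches them per quantity and emits NA.
* Confusion counts add with `+`, which is how per-slide contributions pool;
  granularities cannot be mixed.
* All simulation entry points are deterministic under their config seed;
  the pipeline derives per-stage seeds by fixed offsets from the master
  seed, so stages can be re-run independently.
* Problem sizes in the shipped analyses and tests (400-slide cohorts,
  10⁶-grid calibration replicates, 256×256 oracle masks) were chosen as the
  smallest sizes at which Monte-Carlo error is negligible relative to the
  tolerances being checked.

## Known limitations

* No pyramidal WSI decoding (SVS/NDPI): inputs are plain rasters or grid
  tables; mask ingestion covers PNG/TIFF single-channel images.
* The oracle's error model is exchangeable across slides; it cannot (and
  does not try to) reproduce cross-slide false-alarm concentration, hence
  synthetic slide specificity is not comparable to the reference value.
* The 6400 µm² colour rule measures the connected region within the slide
  mask; whether the original viewer measured per-grid or whole-component
  area is undocumented, and the choice affects no metric.
* Inter-annotator agreement statistics (kappa) are out of scope; the
  adjudication log records per-grid provenance if such analyses are wanted
  downstream.
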