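# wsigrid

Aggregation-free, grid-level evaluation of cancer detection on whole slide
images (WSI).

Slide-level AI validation usually scores only the output of an aggregation
model pooled over patches, which hides whether the system found the actual
cancer or got the slide right for the wrong reason. `wsigrid` implements
the alternative protocol: mesh the slide into disjoint physical grids,
score the detector grid by grid against an adjudicated per-grid ground
truth, and derive the slide call directly from the grid calls — a positive
slide needs at least one true-positive grid; a negative slide is clean only
if no grid is flagged. The package is aimed at computational-pathology
groups validating CADe systems at sub-slide granularity, and at anyone who
needs the surrounding statistics done exactly.

It provides:

* **Gridding** — meshing from pixel geometry and microns-per-pixel
  (`mesh_layout`), the 625 µm² cumulative-area labelling rule for
  segmentation masks (`mask_to_fine_labels`), 0.25 mm → 0.5 mm display
  rollup (`rollup_display`), and viewer annotation boxes with the 6400 µm²
  red/yellow rule (`boxes_from_labels`, GeoJSON export).
* **Ground truth** — two annotators + AI consensus with blinded chief
  escalation (`adjudicate`), any-positive slide truth and grid-derived
  lesion area (`slide_truth`).
* **Metrics** — grid and slide confusion (`grid_confusion`,
  `slide_confusion`), unclipped Wald intervals
  (sens = TP/(TP+FN), spec = TN/(TN+FP), p ± 1.96·√(p(1−p)/n)),
  likelihood ratios (LR+ = sens/(1−spec), LR− = (1−sens)/spec),
  trapezoidal ROC/AUC with Mann-Whitney tie handling (`roc_auc`), and
  procedure / lesion-area stratification (`stratify`).
* **Reader study** — the four revision directions FN→TP, TP→FN, FP→TN,
  TN→FP (`classify_revisions`), exact / continuity-corrected McNemar
  tests (`mcnemar_test`), paired with/without-AI performance
  (`paired_performance`), missed-slide sets and Venn overlaps
  (`missed_slides`, `venn_overlap`).
* **Synthetic data** — a cohort generator with contiguous Eden-growth
  lesions, a tunable detection oracle, and a reader-revision simulator
  (`generate_cohort`, `simulate_oracle`, `simulate_reader`), so the whole
  pipeline is testable without any image downloads.
* **Fixtures** — the published contingency tables of the reference
  validation cohort (1,418 slides, 3,589,476 grids), via `load_fixture()`.

## Worked example

Mesh a 4000×4000 px scan at 0.25 µm/px, label a mask region, roll up to
display grids, and extract viewer boxes:

```r
library(wsigrid)

lay  <- mesh_layout(4000, 4000, mpp = 0.25, grid_edge_mm = 0.25)
mask <- matrix(0L, 4000, 4000)
mask[101:500, 201:600] <- 1L           # a 100x100 um (10,000 um^2) region
fine <- mask_to_fine_labels(mask, lay) # 625 um^2 rule
disp <- rollup_display(fine)
boxes_from_labels(disp, fine)
slide_truth(fine, "slide_001")
```

```
<grid_layout> 4 x 4 grids of 0.25 mm (slide 4000 x 4000 px @ 0.2500 um/px)
  grid_row grid_col x0 y0   x1   y1 color region_area_um2
1        0        0  0  0 2000 2000   red           10000
<slide_truth> slide_001: positive (1 positive grids, 0.0625 mm^2)
```

The 10,000 µm² region exceeds the 625 µm² threshold in exactly one fine
grid, that grid carries its display grid, and the box is red because the
connected region is ≥ 6400 µm². The slide is positive because at least one
grid is.

Recompute the reference operating point from raw counts:

```r
panel <- metric_panel(load_fixture("grid_overall"))
panel$sensitivity
panel$specificity
```

```
sensitivity: 90.25%; 95%CI(90.04%, 90.46%) [n=75,914]
specificity: 96.60%; 95%CI(96.58%, 96.62%) [n=3,513,562]
```

with LR+ 26.54 and LR− 0.101: every flagged grid deserves scrutiny
(LR+ ≫ 10), and a clean grid is strong evidence of benignity. At the slide
level the same counts give sensitivity 99.39% with an *unclipped* Wald
upper bound of 100.58% — the interval is deliberately not truncated.

## Analysis workflow

The `analysis/` scripts run the emulated study end to end on a synthetic
cohort (400 slides at the reference marginals) and on the shipped count
fixtures, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R       # cohort + manifest
Rscript analysis/02_detector_performance.R  # oracle + stratified metrics
Rscript analysis/03_reader_study.R          # revisions, McNemar, Venn
Rscript analysis/04_reference_tables.R      # printed tables from raw counts
```

`run_pipeline()` performs the same stages as one call.

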