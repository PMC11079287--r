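# Contingency counts transcribed from the published external-validation
# cohort of the grid-level colorectal cancer detection system the package's
# evaluation machinery targets: 1,418 whole-slide images from 858
# consecutive patients, meshed into 3,589,476 grids of which 75,914
# contained cancer or high-grade dysplasia. Grid-level counts are split by
# slide category (cancer/HGD slides vs benign slides); pooled specificity
# uses TN/FP summed across both rows. Revision counts come from the paired
# four-reader study (three junior, one senior); per-reader revision rows
# overlap on grids, so their sum (3,386 positive-grid revisions) exceeds
# the 3,169 distinct revised grids.

.fixtures <- local({
  grid_rows <- list(
    overall_cancer_slides = c(tp = 68510, fn = 7404, tn = 211823, fp = 9666),
    overall_benign_slides = c(tp = 0, fn = 0, tn = 3182282, fp = 109791),
    endoscopic_cancer_slides = c(tp = 19961, fn = 2201, tn = 75028, fp = 6165),
    endoscopic_benign_slides = c(tp = 0, fn = 0, tn = 3079799, fp = 108713),
    surgical_cancer_slides = c(tp = 48549, fn = 5203, tn = 136795, fp = 3501),
    surgical_benign_slides = c(tp = 0, fn = 0, tn = 102483, fp = 1078)
  )
  pool <- function(a, b) grid_rows[[a]] + grid_rows[[b]]
  list(
    grid_overall = pool("overall_cancer_slides", "overall_benign_slides"),
    grid_overall_cancer_slides = grid_rows$overall_cancer_slides,
    grid_overall_benign_slides = grid_rows$overall_benign_slides,
    grid_endoscopic = pool("endoscopic_cancer_slides",
                           "endoscopic_benign_slides"),
    grid_surgical = pool("surgical_cancer_slides", "surgical_benign_slides"),
    slide_overall = c(tp = 163, fn = 1, tn = 856, fp = 398),
    slide_endoscopic = c(tp = 36, fn = 0, tn = 776, fp = 368),
    slide_surgical = c(tp = 127, fn = 1, tn = 80, fp = 30)
  )
})

.revision_fixture <- data.frame(
  reader_id = c("JP1", "JP2", "JP3", "SP"),
  seniority = c("junior", "junior", "junior", "senior"),
  fn_to_tp = c(122L, 540L, 1321L, 1403L),
  tp_to_fn = c(2L, 5L, 143L, 10L),
  fp_to_tn = c(15L, 536L, 823L, 594L),
  tn_to_fp = c(51L, 117L, 397L, 58L)
)

.cohort_totals <- c(
  n_slides = 1418, n_positive_slides = 164, n_negative_slides = 1254,
  n_grids = 3589476, n_positive_grids = 75914, n_negative_grids = 3513562,
  n_revised_positive_grids = 3169, n_revised_negative_grids = 2170
)

#' Published contingency-count fixtures
#'
#' Returns the transcribed counts of the reference validation cohort as
#' [confusion_counts()] (grid/slide performance tables), as a revision
#' data.frame (`"revisions"`), or as the cohort totals vector
#' (`"totals"`). Available confusion fixtures: `grid_overall`,
#' `grid_overall_cancer_slides`, `grid_overall_benign_slides`,
#' `grid_endoscopic`, `grid_surgical`, `slide_overall`,
#' `slide_endoscopic`, `slide_surgical`.
#'
#' @param name fixture name; `load_fixture()` with no arguments lists the
#'   available names.
#' @return a `confusion_counts`, a data.frame, or a named numeric vector.
#' @export
#' @examples
#' load_fixture("grid_overall")
#' sens_spec(load_fixture("slide_overall"))$sensitivity
load_fixture <- function(name) {
  if (missing(name)) {
    return(c(names(.fixtures), "revisions", "totals"))
  }
  if (identical(name, "revisions")) return(.revision_fixture)
  if (identical(name, "totals")) return(.cohort_totals)
  if (!name %in% names(.fixtures)) {
    stop_wsigrid(sprintf("unknown fixture '%s'", name), "wsigrid_lookup_error")
  }
  x <- .fixtures[[name]]
  confusion_counts(
    tp = x[["tp"]], fp = x[["fp"]], tn = x[["tn"]], fn = x[["fn"]],
    granularity = if (startsWith(name, "grid")) "grid" else "slide",
    stratum = sub("^(grid|slide)_", "", name)
  )
}
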