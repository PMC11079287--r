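#' Confusion-matrix tallies
#'
#' Container for TP/FP/TN/FN counts at grid or slide granularity, with an
#' optional stratum tag. Objects add with `+`, which is how per-slide
#' contributions pool into cohort counts.
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @param granularity `"grid"` or `"slide"`.
#' @param stratum free-form tag (`"overall"`, `"endoscopic"`, `"surgical"`,
#'   `"area_le_50mm2"`, ...).
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0,
                             granularity = c("grid", "slide"),
                             stratum = "overall") {
  granularity <- match.arg(granularity)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || anyNA(counts)) {
    stop_wsigrid("confusion counts must be non-negative", "wsigrid_config_error")
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         granularity = granularity, stratum = stratum),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts> [%s/%s] TP=%s FN=%s TN=%s FP=%s\n",
    x$granularity, x$stratum,
    format(x$tp, big.mark = ","), format(x$fn, big.mark = ","),
    format(x$tn, big.mark = ","), format(x$fp, big.mark = ",")
  ))
  invisible(x)
}

#' @export
`+.confusion_counts` <- function(e1, e2) {
  stopifnot(e1$granularity == e2$granularity)
  confusion_counts(
    tp = e1$tp + e2$tp, fp = e1$fp + e2$fp,
    tn = e1$tn + e2$tn, fn = e1$fn + e2$fn,
    granularity = e1$granularity,
    stratum = if (identical(e1$stratum, e2$stratum)) e1$stratum else "pooled"
  )
}

#' Grid-level confusion of a prediction map against truth
#'
#' Exhaustive per-grid cross-tabulation: a predicted-positive grid that truly
#' contains cancer is a TP, a predicted-negative cancer grid an FN, and so
#' on, over every grid of the mesh.
#'
#' @param pred,truth `grid_label_map`s on one layout and level.
#' @param stratum stratum tag for the result.
#' @return `confusion_counts` at grid granularity.
#' @export
grid_confusion <- function(pred, truth, stratum = "overall") {
  check_same_layout(pred, truth, "prediction and truth maps")
  if (!identical(pred$level, truth$level)) {
    stop_wsigrid("prediction and truth maps must be at the same grid level",
                 "wsigrid_level_error")
  }
  p <- pred$labels
  t <- truth$labels
  confusion_counts(
    tp = sum(p & t), fp = sum(p & !t),
    tn = sum(!p & !t), fn = sum(!p & t),
    granularity = "grid", stratum = stratum
  )
}

#' Slide-level confusion contribution of one slide
#'
#' Derives the slide call directly from grid-level results with no
#' aggregation model: a truth-positive slide is a TP when the prediction
#' hits at least one truth-positive grid and an FN otherwise — false-alarm
#' grids alone never rescue a positive slide. A truth-negative slide is a TN
#' exactly when the prediction is free of positive grids, else an FP.
#'
#' @inheritParams grid_confusion
#' @return one-hot `confusion_counts` at slide granularity.
#' @export
slide_confusion <- function(pred, truth, stratum = "overall") {
  check_same_layout(pred, truth, "prediction and truth maps")
  slide_positive <- any(truth$labels)
  if (slide_positive) {
    hit <- any(pred$labels & truth$labels)
    confusion_counts(tp = as.integer(hit), fn = as.integer(!hit),
                     granularity = "slide", stratum = stratum)
  } else {
    clean <- !any(pred$labels)
    confusion_counts(tn = as.integer(clean), fp = as.integer(!clean),
                     granularity = "slide", stratum = stratum)
  }
}

#' Stratified confusion counts over a cohort
#'
#' Aggregates grid- and slide-level confusion over a collection of slide
#' records, split by procedure type, by lesion area (positive slides at most
#' 50 mm² versus larger, truth-negative slides kept in both area strata so
#' specificity stays defined), or not at all.
#'
#' @param records list of slide records, each a list with at least `pred`
#'   and `truth` (`grid_label_map`s) plus `procedure` (`"endoscopic"` /
#'   `"surgical"`) and `cancer_area_mm2` as the key requires.
#' @param key `"all"`, `"procedure"` or `"cancer_area_le_50mm2"`.
#' @return named list of strata, each holding `grid` and `slide`
#'   `confusion_counts` and `n_slides`.
#' @export
stratify <- function(records, key = c("all", "procedure",
                                      "cancer_area_le_50mm2")) {
  key <- match.arg(key)
  membership <- switch(key,
    all = lapply(records, function(r) "overall"),
    procedure = lapply(records, function(r) {
      proc <- r$procedure
      if (is.null(proc) || !proc %in% c("endoscopic", "surgical")) {
        stop_wsigrid("each record needs procedure 'endoscopic' or 'surgical'",
                     "wsigrid_config_error")
      }
      proc
    }),
    cancer_area_le_50mm2 = lapply(records, function(r) {
      if (any(r$truth$labels)) {
        if (r$cancer_area_mm2 <= 50) "area_le_50mm2" else "area_gt_50mm2"
      } else {
        c("area_le_50mm2", "area_gt_50mm2") # negatives anchor specificity
      }
    })
  )
  strata <- sort(unique(unlist(membership)))
  out <- lapply(strata, function(s) {
    in_s <- vapply(membership, function(m) s %in% m, logical(1))
    grid_cc <- confusion_counts(granularity = "grid", stratum = s)
    slide_cc <- confusion_counts(granularity = "slide", stratum = s)
    for (r in records[in_s]) {
      grid_cc <- grid_cc + grid_confusion(r$pred, r$truth, stratum = s)
      slide_cc <- slide_cc + slide_confusion(r$pred, r$truth, stratum = s)
    }
    list(grid = grid_cc, slide = slide_cc, n_slides = sum(in_s))
  })
  names(out) <- strata
  out
}
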