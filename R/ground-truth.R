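#' Three-source ground-truth adjudication
#'
#' Implements the consensus protocol used to establish per-grid truth: two
#' independent pathologist annotation maps are compared with the AI output;
#' grids where all three agree take the unanimous label, and every other
#' grid — including grids where the pathologists agree with each other but
#' differ from the AI — is escalated to the chief pathologist, whose label
#' is final. The chief input is consulted only on disputed grids, which
#' enforces the protocol's blinding by construction: supplying the chief as
#' a callback means it can only ever see grid identities, never the three
#' sources' labels.
#'
#' @param annotator_a,annotator_b,ai `grid_label_map`s sharing one layout.
#' @param chief either a `grid_label_map` on the same layout, or a function
#'   `(row0, col0) -> logical` taking 0-based grid indices (vectorized);
#'   `NA` for a disputed grid raises an adjudication-incomplete error.
#' @return list with `truth` (a `grid_label_map`, source `"truth"`) and
#'   `records`, a data.frame with one row per grid: 0-based `row`/`col`,
#'   the three source labels, `consensus`, `final` and `decided_by`
#'   (`"consensus"` or `"chief"`).
#' @export
adjudicate <- function(annotator_a, annotator_b, ai, chief) {
  check_same_layout(annotator_a, annotator_b, "annotator maps")
  check_same_layout(annotator_a, ai, "annotator and AI maps")
  lay <- annotator_a$layout
  a <- annotator_a$labels
  b <- annotator_b$labels
  m <- ai$labels
  consensus <- (a == b) & (b == m)
  final <- a
  if (any(!consensus)) {
    idx <- which(!consensus, arr.ind = TRUE)
    if (inherits(chief, "grid_label_map")) {
      check_same_layout(annotator_a, chief, "annotator and chief maps")
      chief_lab <- chief$labels[idx]
    } else if (is.function(chief)) {
      chief_lab <- as.logical(chief(idx[, 1] - 1L, idx[, 2] - 1L))
    } else {
      stop_wsigrid("chief must be a grid_label_map or a resolver function",
                   "wsigrid_config_error")
    }
    if (anyNA(chief_lab)) {
      stop_wsigrid(
        sprintf("chief label missing for %d disputed grid(s): adjudication incomplete",
                sum(is.na(chief_lab))),
        "wsigrid_adjudication_incomplete"
      )
    }
    final[idx] <- chief_lab
  }
  rc <- which(matrix(TRUE, lay$n_rows, lay$n_cols), arr.ind = TRUE)
  records <- data.frame(
    row = rc[, 1] - 1L,
    col = rc[, 2] - 1L,
    annotator_a = as.vector(a),
    annotator_b = as.vector(b),
    ai = as.vector(m),
    consensus = as.vector(consensus),
    final = as.vector(final),
    decided_by = ifelse(as.vector(consensus), "consensus", "chief")
  )
  records <- records[order(records$row, records$col), , drop = FALSE]
  rownames(records) <- NULL
  list(
    truth = grid_label_map(lay, final, source = "truth"),
    records = records
  )
}

#' Slide-level ground truth from a grid truth map
#'
#' A slide is cancer-positive when any of its grids is positive; there is no
#' aggregation model. The cancer area is the positive-grid count times the
#' physical grid area (0.0625 mm² for 0.25 mm fine grids), which is how the
#' package measures lesion size for stratification.
#'
#' @param truth a `grid_label_map` of ground-truth labels.
#' @param slide_id optional slide identifier carried through.
#' @return a `slide_truth` list: `slide_id`, `label` (`"positive"` /
#'   `"negative"`), `n_positive_grids`, `cancer_area_mm2`.
#' @export
slide_truth <- function(truth, slide_id = NA_character_) {
  stopifnot(inherits(truth, "grid_label_map"))
  npos <- n_positive_grids(truth)
  structure(
    list(
      slide_id = slide_id,
      label = if (npos >= 1L) "positive" else "negative",
      n_positive_grids = npos,
      cancer_area_mm2 = npos * truth$layout$grid_edge_mm^2
    ),
    class = "slide_truth"
  )
}

#' @export
print.slide_truth <- function(x, ...) {
  cat(sprintf("<slide_truth> %s: %s (%d positive grids, %.4f mm^2)\n",
              x$slide_id, x$label, x$n_positive_grids, x$cancer_area_mm2))
  invisible(x)
}

#' Broadcast display-level truth down to the fine lattice
#'
#' Annotators label at the 0.5 mm display scale while the detector predicts
#' at the 0.25 mm fine scale; after adjudication at display scale the fine
#' truth is obtained by assigning every fine grid the label of the display
#' grid that contains it.
#'
#' @param display a display-level `grid_label_map`.
#' @param fine_layout the fine `grid_layout` to broadcast onto (same slide).
#' @return a fine-level `grid_label_map`.
#' @export
broadcast_fine <- function(display, fine_layout) {
  stopifnot(inherits(display, "grid_label_map"),
            inherits(fine_layout, "grid_layout"))
  lay_d <- display$layout
  if (!isTRUE(all.equal(lay_d$grid_edge_mm, 2 * fine_layout$grid_edge_mm)) ||
      lay_d$slide_width_px != fine_layout$slide_width_px ||
      lay_d$slide_height_px != fine_layout$slide_height_px) {
    stop_wsigrid("fine layout must be the 2x refinement of the display layout",
                 "wsigrid_level_error")
  }
  rows <- ceiling(seq_len(fine_layout$n_rows) / 2)
  cols <- ceiling(seq_len(fine_layout$n_cols) / 2)
  grid_label_map(fine_layout, display$labels[rows, cols, drop = FALSE],
                 source = display$source)
}
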