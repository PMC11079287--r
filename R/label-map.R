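#' Per-grid label map
#'
#' The central data structure of the pipeline: a rectangular lattice of
#' binary labels (and optionally continuous scores and per-grid positive
#' areas) aligned with a [mesh_layout()]. Internally labels are a logical
#' `n_rows x n_cols` matrix; exported tables use 0-based row/column indices
#' with a top-left origin.
#'
#' @param layout a `grid_layout`.
#' @param labels logical matrix of dimension `n_rows x n_cols` (`TRUE` =
#'   cancer-positive grid).
#' @param scores optional numeric matrix of the same dimension with scores in
#'   `[0, 1]`.
#' @param area_um2 optional numeric matrix with the positive-mask area (in
#'   square microns) inside each grid; filled in by [mask_to_fine_labels()]
#'   and used by the bounding-box colour rule.
#' @param level grid level tag; inferred from the layout edge when `NULL`
#'   (`"fine_0.25mm"`, `"display_0.5mm"` or `"custom_*"`).
#' @param source free-form provenance tag (`"ai"`, `"annotator"`, `"chief"`,
#'   `"truth"`, `"reader"`, ...).
#' @return a `grid_label_map` object.
#' @export
grid_label_map <- function(layout, labels, scores = NULL, area_um2 = NULL,
                           level = NULL, source = "unknown") {
  stopifnot(inherits(layout, "grid_layout"))
  if (is.vector(labels) && length(labels) == layout$n_rows * layout$n_cols) {
    labels <- matrix(as.logical(labels), layout$n_rows, layout$n_cols)
  }
  if (!is.matrix(labels) ||
      nrow(labels) != layout$n_rows || ncol(labels) != layout$n_cols) {
    stop_wsigrid(
      sprintf(
        "labels must be a %d x %d matrix to match the layout",
        layout$n_rows, layout$n_cols
      ),
      "wsigrid_shape_error"
    )
  }
  storage.mode(labels) <- "logical"
  if (anyNA(labels)) {
    stop_wsigrid("labels must not contain NA", "wsigrid_shape_error")
  }
  for (extra in list(scores, area_um2)) {
    if (!is.null(extra) && !identical(dim(extra), dim(labels))) {
      stop_wsigrid("scores/area_um2 must match the label dimensions",
                   "wsigrid_shape_error")
    }
  }
  structure(
    list(
      layout = layout,
      labels = labels,
      scores = scores,
      area_um2 = area_um2,
      level = level %||% layout_level(layout),
      source = source
    ),
    class = "grid_label_map"
  )
}

#' @export
print.grid_label_map <- function(x, ...) {
  cat(sprintf(
    "<grid_label_map> %s [%s, %s] %d/%d positive grids%s\n",
    format(x$layout), x$level, x$source, sum(x$labels), length(x$labels),
    if (is.null(x$scores)) "" else ", with scores"
  ))
  invisible(x)
}

n_positive_grids <- function(map) sum(map$labels)

check_same_layout <- function(a, b, what = "maps") {
  if (!same_layout(a$layout, b$layout)) {
    stop_wsigrid(
      sprintf("%s must share one grid layout (%s vs %s)",
              what, format(a$layout), format(b$layout)),
      "wsigrid_shape_error"
    )
  }
  invisible(TRUE)
}

#' Convert a binary segmentation mask to fine-grid labels
#'
#' Applies the cumulative-area labelling rule: a fine grid is positive when
#' the physical area of positive mask pixels falling inside it exceeds
#' `area_threshold_um2` (strictly greater than, so a grid holding exactly the
#' threshold area stays negative). Pixel area is `mpp^2` square microns; the
#' default threshold is 625 um², i.e. 1% of a full 0.25 x 0.25 mm² grid.
#'
#' @param mask logical or 0/1 matrix, `slide_height_px x slide_width_px`,
#'   nonzero = cancer-positive pixel.
#' @param layout fine-level `grid_layout` whose pixel dimensions equal
#'   `dim(mask)`.
#' @param area_threshold_um2 labelling threshold in square microns.
#' @param strict if `TRUE` (default) positivity requires area strictly above
#'   the threshold; `FALSE` switches to `>=`.
#' @param source provenance tag for the returned map.
#' @return a fine-level `grid_label_map` carrying per-grid positive areas in
#'   `area_um2`.
#' @export
mask_to_fine_labels <- function(mask, layout, area_threshold_um2 = 625,
                                strict = TRUE, source = "ai") {
  stopifnot(inherits(layout, "grid_layout"))
  if (!is.matrix(mask) ||
      nrow(mask) != layout$slide_height_px ||
      ncol(mask) != layout$slide_width_px) {
    stop_wsigrid(
      sprintf("mask must be %d x %d px to match the layout",
              layout$slide_height_px, layout$slide_width_px),
      "wsigrid_shape_error"
    )
  }
  if (area_threshold_um2 < 0) {
    stop_wsigrid("area_threshold_um2 must be >= 0", "wsigrid_config_error")
  }
  edge_um <- layout$grid_edge_mm * 1000
  m <- mask
  storage.mode(m) <- "double"
  m[m != 0] <- 1
  # aggregate positive-pixel counts into grid cells: group pixel rows into
  # grid rows, then pixel columns into grid columns
  row_grp <- pixel_grid_index(seq_len(nrow(m)) - 1L, layout$mpp, edge_um)
  col_grp <- pixel_grid_index(seq_len(ncol(m)) - 1L, layout$mpp, edge_um)
  by_row <- rowsum(m, row_grp, reorder = TRUE)
  counts <- t(rowsum(t(by_row), col_grp, reorder = TRUE))
  stopifnot(nrow(counts) == layout$n_rows, ncol(counts) == layout$n_cols)
  area <- counts * layout$mpp^2
  labels <- if (strict) area > area_threshold_um2 else area >= area_threshold_um2
  grid_label_map(layout, labels, area_um2 = area, source = source)
}

#' Roll fine prediction grids up to display grids
#'
#' Display (0.5 x 0.5 mm²) grids are derived from the fine (0.25 x 0.25 mm²)
#' prediction grids, never annotated independently: each display grid
#' aggregates its (up to) 2 x 2 constituent fine grids and is positive when
#' at least `min_positive` of them are positive. The default `min_positive =
#' 1` is the any-positive (logical OR) rule, the only aggregation under
#' which the display view flags every localized detection. When the fine map
#' carries scores the display score is the maximum over constituents;
#' per-grid positive areas are summed.
#'
#' @param fine a fine-level `grid_label_map`.
#' @param min_positive number of positive fine grids required to call the
#'   display grid positive (default 1 = OR).
#' @return a display-level `grid_label_map` covering the same slide.
#' @export
rollup_display <- function(fine, min_positive = 1L) {
  stopifnot(inherits(fine, "grid_label_map"))
  if (fine$level == "display_0.5mm") {
    stop_wsigrid("map is already at display level; pass the fine-level map",
                 "wsigrid_level_error")
  }
  lay_f <- fine$layout
  lay_d <- mesh_layout(lay_f$slide_width_px, lay_f$slide_height_px,
                       lay_f$mpp, lay_f$grid_edge_mm * 2)
  # fine grid r (1-based) belongs to display grid ceiling(r / 2); holds for
  # partial edge grids because ceil(ceil(x)/2) == ceil(x/2)
  row_grp <- ceiling(seq_len(lay_f$n_rows) / 2)
  col_grp <- ceiling(seq_len(lay_f$n_cols) / 2)
  stopifnot(max(row_grp) == lay_d$n_rows, max(col_grp) == lay_d$n_cols)
  pos <- fine$labels
  storage.mode(pos) <- "double"
  npos <- t(rowsum(t(rowsum(pos, row_grp)), col_grp))
  labels <- npos >= min_positive
  scores <- NULL
  if (!is.null(fine$scores)) {
    scores <- block_reduce_max(fine$scores)
  }
  area <- NULL
  if (!is.null(fine$area_um2)) {
    area <- t(rowsum(t(rowsum(fine$area_um2, row_grp)), col_grp))
    dimnames(area) <- NULL
  }
  dimnames(labels) <- NULL
  grid_label_map(lay_d, labels, scores = scores, area_um2 = area,
                 source = fine$source)
}

# max over 2x2 blocks (partial edge blocks allowed): pad to even extent
# with -Inf, then fold rows and columns pairwise
block_reduce_max <- function(x) {
  if (nrow(x) %% 2L) x <- rbind(x, -Inf)
  if (ncol(x) %% 2L) x <- cbind(x, -Inf)
  odd_r <- seq(1L, nrow(x), by = 2L)
  x <- pmax(x[odd_r, , drop = FALSE], x[odd_r + 1L, , drop = FALSE])
  odd_c <- seq(1L, ncol(x), by = 2L)
  pmax(x[, odd_c, drop = FALSE], x[, odd_c + 1L, drop = FALSE])
}
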