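#' Viewer annotation boxes from display grids
#'
#' Emits one bounding box per positive display grid, in slide pixel
#' coordinates, coloured by the size of the connected positive region
#' supporting the box: red when the region area is at least 6400 um²,
#' yellow below. Regions are 4-connected components of positive fine grids;
#' the area of a component is the sum of the positive-mask areas of its fine
#' grids when the fine map carries them (i.e. came from
#' [mask_to_fine_labels()]), otherwise the component's grid count times the
#' full fine-grid area. A display grid intersected by several components is
#' coloured by the largest one. Box colour is a pure viewer affordance and
#' never enters any downstream metric.
#'
#' @param display display-level `grid_label_map` derived from `fine`.
#' @param fine the fine-level `grid_label_map` it was derived from.
#' @return data.frame with one row per positive display grid: 0-based
#'   `grid_row`/`grid_col`, half-open pixel bounds `x0,y0,x1,y1`, `color`,
#'   and `region_area_um2`.
#' @export
boxes_from_labels <- function(display, fine) {
  stopifnot(inherits(display, "grid_label_map"),
            inherits(fine, "grid_label_map"))
  lay_d <- display$layout
  lay_f <- fine$layout
  if (!isTRUE(all.equal(lay_d$grid_edge_mm, 2 * lay_f$grid_edge_mm)) ||
      lay_d$slide_width_px != lay_f$slide_width_px ||
      lay_d$slide_height_px != lay_f$slide_height_px) {
    stop_wsigrid("display map must be the 2x rollup of the fine map",
                 "wsigrid_level_error")
  }
  pos_idx <- which(display$labels, arr.ind = TRUE)
  if (nrow(pos_idx) == 0L) {
    return(data.frame(
      grid_row = integer(), grid_col = integer(),
      x0 = integer(), y0 = integer(), x1 = integer(), y1 = integer(),
      color = character(), region_area_um2 = double()
    ))
  }
  comp <- EBImage::bwlabel(matrix(as.numeric(fine$labels),
                                  nrow(fine$labels), ncol(fine$labels)))
  grid_area_um2 <- (lay_f$grid_edge_mm * 1000)^2
  comp_ids <- seq_len(max(comp))
  comp_area <- vapply(comp_ids, function(k) {
    cells <- comp == k
    if (is.null(fine$area_um2)) sum(cells) * grid_area_um2
    else sum(fine$area_um2[cells])
  }, double(1))

  edge_um_d <- lay_d$grid_edge_mm * 1000
  n_boxes <- nrow(pos_idx)
  out <- data.frame(
    grid_row = pos_idx[, 1] - 1L,
    grid_col = pos_idx[, 2] - 1L,
    x0 = integer(n_boxes), y0 = integer(n_boxes),
    x1 = integer(n_boxes), y1 = integer(n_boxes),
    color = character(n_boxes),
    region_area_um2 = double(n_boxes)
  )
  for (i in seq_len(n_boxes)) {
    r <- pos_idx[i, 1]; c <- pos_idx[i, 2]
    out$x0[i] <- grid_pixel_start(c - 1L, lay_d$mpp, edge_um_d)
    out$x1[i] <- min(grid_pixel_start(c, lay_d$mpp, edge_um_d),
                     lay_d$slide_width_px)
    out$y0[i] <- grid_pixel_start(r - 1L, lay_d$mpp, edge_um_d)
    out$y1[i] <- min(grid_pixel_start(r, lay_d$mpp, edge_um_d),
                     lay_d$slide_height_px)
    fr <- (2L * r - 1L):min(2L * r, lay_f$n_rows)
    fc <- (2L * c - 1L):min(2L * c, lay_f$n_cols)
    comps_here <- setdiff(unique(as.vector(comp[fr, fc, drop = FALSE])), 0)
    area <- if (length(comps_here)) max(comp_area[comps_here]) else 0
    out$region_area_um2[i] <- area
    out$color[i] <- if (area >= 6400) "red" else "yellow"
  }
  # row-major deterministic order
  out <- out[order(out$grid_row, out$grid_col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write annotation boxes as GeoJSON
#'
#' Serializes boxes from [boxes_from_labels()] as a GeoJSON
#' FeatureCollection of pixel-coordinate polygons with properties `row`,
#' `col`, `color` and `region_area_um2`, the interchange format digital
#' pathology viewers consume.
#'
#' @param boxes data.frame from [boxes_from_labels()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
boxes_to_geojson <- function(boxes, path) {
  features <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    ring <- list(
      c(b$x0, b$y0), c(b$x1, b$y0), c(b$x1, b$y1), c(b$x0, b$y1),
      c(b$x0, b$y0)
    )
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(
        row = b$grid_row, col = b$grid_col, color = b$color,
        region_area_um2 = b$region_area_um2
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
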