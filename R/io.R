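#' Write grid label maps as a long-form CSV
#'
#' One row per grid in deterministic row-major order, columns `slide_id`,
#' `level`, `row`, `col`, `label`, `score` (0-based indices, `label` in
#' 0/1, `score` empty when absent). This is the interchange schema shared
#' by file-based and synthetic inputs.
#'
#' @param maps named list of `grid_label_map`s keyed by slide id.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(maps, path) {
  rows <- lapply(names(maps), function(sid) {
    m <- maps[[sid]]
    lay <- m$layout
    # row-major order: iterate rows outer, columns inner
    df <- data.frame(
      slide_id = sid,
      level = m$level,
      row = rep(seq_len(lay$n_rows) - 1L, each = lay$n_cols),
      col = rep(seq_len(lay$n_cols) - 1L, times = lay$n_rows),
      label = as.integer(t(m$labels)),
      score = if (is.null(m$scores)) NA_real_ else as.numeric(t(m$scores))
    )
    df
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read grid label maps from long-form CSV
#'
#' Inverse of [write_grid_csv()]. Grid geometry is not stored in the long
#' table, so the layouts must be supplied (e.g. from the cohort manifest).
#'
#' @param path CSV path.
#' @param layouts named list of `grid_layout`s keyed by slide id.
#' @param source provenance tag for the reconstructed maps.
#' @return named list of `grid_label_map`s.
#' @export
read_grid_csv <- function(path, layouts, source = "file") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  maps <- lapply(split(df, df$slide_id), function(d) {
    lay <- layouts[[d$slide_id[1]]]
    if (is.null(lay)) {
      stop_wsigrid(sprintf("no layout supplied for slide '%s'", d$slide_id[1]),
                   "wsigrid_lookup_error")
    }
    labels <- matrix(FALSE, lay$n_rows, lay$n_cols)
    labels[cbind(d$row + 1L, d$col + 1L)] <- d$label != 0
    scores <- NULL
    if (!all(is.na(d$score))) {
      scores <- matrix(NA_real_, lay$n_rows, lay$n_cols)
      scores[cbind(d$row + 1L, d$col + 1L)] <- d$score
    }
    grid_label_map(lay, labels, scores = scores, level = d$level[1],
                   source = source)
  })
  maps[order(names(maps))]
}

#' Write a cohort to disk (manifest + truth grids)
#'
#' Writes `manifest.yaml` holding per-slide metadata and geometry (id,
#' procedure, pixel dimensions, mpp, grid edge, positive-grid count, cancer
#' area) plus `truth_grids.csv` in the [write_grid_csv()] schema, making
#' synthetic and file-based cohorts interchangeable.
#'
#' @param records cohort from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(records, function(r) {
    lay <- r$truth$layout
    list(
      slide_id = r$slide_id,
      procedure = r$procedure,
      slide_width_px = lay$slide_width_px,
      slide_height_px = lay$slide_height_px,
      mpp = lay$mpp,
      grid_edge_mm = lay$grid_edge_mm,
      n_positive_grids = r$n_positive_grids,
      cancer_area_mm2 = r$cancer_area_mm2
    )
  })
  yaml::write_yaml(unname(manifest), file.path(dir, "manifest.yaml"))
  write_grid_csv(lapply(records, `[[`, "truth"),
                 file.path(dir, "truth_grids.csv"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list of slide records mirroring [generate_cohort()] output.
#' @export
read_cohort <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  layouts <- lapply(manifest, function(m) {
    mesh_layout(m$slide_width_px, m$slide_height_px, m$mpp, m$grid_edge_mm)
  })
  names(layouts) <- vapply(manifest, `[[`, character(1), "slide_id")
  truths <- read_grid_csv(file.path(dir, "truth_grids.csv"), layouts,
                          source = "truth")
  records <- lapply(manifest, function(m) {
    list(
      slide_id = m$slide_id,
      procedure = m$procedure,
      truth = truths[[m$slide_id]],
      n_positive_grids = m$n_positive_grids,
      cancer_area_mm2 = m$cancer_area_mm2
    )
  })
  names(records) <- names(layouts)
  records
}

#' Read a binary mask raster (PNG or TIFF)
#'
#' Single-channel image, nonzero = positive pixel. Requires the `png` or
#' `tiff` package matching the file extension.
#'
#' @param path image path.
#' @return logical matrix `height x width`.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_wsigrid(sprintf("unsupported mask format '%s'", ext),
                 "wsigrid_config_error")
  )
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img != 0
}

#' Write a stratified metrics report
#'
#' Emits the evaluation in three forms: a tidy CSV
#' (`stratum, granularity, metric, estimate, ci_low, ci_high, n`), a JSON
#' file with full-precision values, and a small markdown summary formatted
#' the way clinical performance tables print (percent scale, half-up to two
#' decimals).
#'
#' @param strata output of [stratify()].
#' @param dir output directory.
#' @param config_hash provenance stamp recorded in the file headers.
#' @return the tidy data.frame, invisibly.
#' @export
write_metrics_report <- function(strata, dir, config_hash = "unspecified") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  json <- list(config_hash = config_hash)
  # sens/spec and each LR fail independently (empty stratum, degenerate
  # rate); undefined quantities are reported as NA, not dropped wholesale
  safe_panel <- function(cc) {
    ss <- tryCatch(sens_spec(cc), wsigrid_undefined_metric = function(e) NULL)
    if (is.null(ss)) return(NULL)
    lr <- tryCatch(likelihood_ratios(ss$sensitivity, ss$specificity),
                   wsigrid_undefined_metric = function(e) {
                     list(lr_positive = ss$sensitivity$estimate /
                            (1 - ss$specificity$estimate),
                          lr_negative = NA_real_)
                   })
    c(ss, lr)
  }
  for (s in names(strata)) {
    for (gran in c("grid", "slide")) {
      cc <- strata[[s]][[gran]]
      panel <- safe_panel(cc)
      if (is.null(panel)) next
      for (metric in c("sensitivity", "specificity")) {
        m <- panel[[metric]]
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = s, granularity = gran, metric = metric,
          estimate = m$estimate, ci_low = m$ci_low, ci_high = m$ci_high,
          n = m$n
        )
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, granularity = gran, metric = "lr_positive",
        estimate = panel$lr_positive, ci_low = NA, ci_high = NA, n = NA
      )
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, granularity = gran, metric = "lr_negative",
        estimate = panel$lr_negative, ci_low = NA, ci_high = NA, n = NA
      )
      json[[s]][[gran]] <- list(
        counts = list(tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp),
        sensitivity = unclass(panel$sensitivity)[c("estimate", "ci_low", "ci_high", "n")],
        specificity = unclass(panel$specificity)[c("estimate", "ci_low", "ci_high", "n")],
        lr_positive = panel$lr_positive,
        lr_negative = panel$lr_negative
      )
    }
  }
  tidy <- do.call(rbind, rows)
  header <- sprintf("# config_hash: %s", config_hash)
  csv_path <- file.path(dir, "metrics.csv")
  writeLines(header, csv_path)
  suppressWarnings(
    utils::write.table(tidy, csv_path, append = TRUE, sep = ",",
                       row.names = FALSE, quote = FALSE)
  )
  jsonlite::write_json(json, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  md <- c("# Evaluation report", sprintf("config hash: `%s`", config_hash), "")
  for (s in names(strata)) {
    md <- c(md, sprintf("## %s", s))
    for (gran in c("grid", "slide")) {
      panel <- safe_panel(strata[[s]][[gran]])
      if (is.null(panel)) next
      md <- c(md, sprintf(
        "- %s: sensitivity %s | specificity %s | LR+ %.2f | LR- %.3f",
        gran, format_metric(panel$sensitivity),
        format_metric(panel$specificity),
        panel$lr_positive, panel$lr_negative
      ))
    }
    md <- c(md, "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(tidy)
}
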