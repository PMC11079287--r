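#' Study configuration for the end-to-end pipeline
#'
#' Bundles every knob of an emulated-study run so that a run is
#' reproducible from the config alone: the synthetic cohort spec, the
#' detection-oracle operating point, the reader panel, the grid/labelling
#' parameters and the statistical conventions. The FNV hash of the config
#' is stamped into every output file.
#'
#' @param cohort a [cohort_config()].
#' @param oracle an [oracle_config()].
#' @param readers list of [reader_profile()]s (may be empty to skip the
#'   reader study).
#' @param area_threshold_um2 mask labelling threshold (see
#'   [mask_to_fine_labels()]).
#' @param rollup_min_positive display rollup rule (see [rollup_display()]).
#' @param z Wald critical value.
#' @param mcnemar_method McNemar variant (see [mcnemar_test()]).
#' @param seed master seed for all pipeline randomness.
#' @return a `study_config` list.
#' @export
study_config <- function(cohort = cohort_config(),
                         oracle = oracle_config(),
                         readers = default_reader_panel(),
                         area_threshold_um2 = 625,
                         rollup_min_positive = 1L,
                         z = 1.96,
                         mcnemar_method = "auto",
                         seed = 20260101L) {
  structure(
    list(cohort = cohort, oracle = oracle, readers = readers,
         area_threshold_um2 = area_threshold_um2,
         rollup_min_positive = rollup_min_positive, z = z,
         mcnemar_method = mcnemar_method, seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Default four-reader panel
#'
#' Three junior readers and one senior, with baseline rates and revision
#' propensities spread around the measured reader averages; the senior
#' profile revises missed cancers most readily, mirroring the observed
#' pattern that the senior reader made the most beneficial revisions.
#'
#' @return list of four [reader_profile()]s.
#' @export
default_reader_panel <- function() {
  list(
    reader_profile("JP1", "junior", sensitivity = 0.80, specificity = 0.9991,
                   revision_probs = c(fn_to_tp = 0.05, tp_to_fn = 0.001,
                                      fp_to_tn = 0.10, tn_to_fp = 0.0004)),
    reader_profile("JP2", "junior", sensitivity = 0.81, specificity = 0.9992,
                   revision_probs = c(fn_to_tp = 0.10, tp_to_fn = 0.001,
                                      fp_to_tn = 0.25, tn_to_fp = 0.0005)),
    reader_profile("JP3", "junior", sensitivity = 0.79, specificity = 0.9990,
                   revision_probs = c(fn_to_tp = 0.20, tp_to_fn = 0.004,
                                      fp_to_tn = 0.30, tn_to_fp = 0.0012)),
    reader_profile("SP", "senior", sensitivity = 0.85, specificity = 0.9995,
                   revision_probs = c(fn_to_tp = 0.22, tp_to_fn = 0.0005,
                                      fp_to_tn = 0.35, tn_to_fp = 0.0003))
  )
}

#' Run the emulated study end to end
#'
#' Orchestrates generate -> detect -> adjudicate -> evaluate -> reader study
#' -> report on a synthetic cohort, writing every stage's output under
#' `out_dir`. Adjudication is exercised by deriving two display-scale
#' annotator views and a blinded chief from the generated truth, re-running
#' the consensus protocol, and verifying the re-derived truth matches the
#' generator's. Running the same config twice produces byte-identical
#' outputs.
#'
#' @param config a [study_config()].
#' @param out_dir output directory.
#' @param write_grids also write per-grid CSVs (large for big cohorts)?
#' @return list with the cohort records, stratified metrics, reader-study
#'   results, miss sets and Venn overlap, invisibly.
#' @export
run_pipeline <- function(config = study_config(), out_dir,
                         write_grids = FALSE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- fnv1a(config[setdiff(names(config), "readers")])
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  cat(sprintf("wsigrid run, config hash %s, seed %d\n", hash, config$seed),
      file = log_path)

  # stage 1: cohort
  cohort_cfg <- config$cohort
  cohort_cfg$seed <- config$seed
  records <- generate_cohort(cohort_cfg)
  logf("generated %d slides (%d positive)", length(records),
       sum(vapply(records, function(r) any(r$truth$labels), logical(1))))

  # stage 2: detection oracle + display rollup
  set.seed(config$seed + 1L)
  for (sid in names(records)) {
    records[[sid]]$pred <- simulate_oracle(records[[sid]]$truth,
                                           config$oracle)
    records[[sid]]$pred_display <- rollup_display(
      records[[sid]]$pred, min_positive = config$rollup_min_positive
    )
  }
  logf("simulated detector on %d slides", length(records))

  # stage 3: adjudication exercise — rebuild truth from two noisy
  # display-scale annotators plus the AI, with the generator's truth as the
  # blinded chief; the re-derived fine truth must equal the generator's
  set.seed(config$seed + 2L)
  n_disputed <- 0L
  for (sid in names(records)) {
    r <- records[[sid]]
    display_truth <- rollup_display(r$truth)
    ann <- lapply(1:2, function(i) {
      noisy <- simulate_oracle(display_truth,
                               oracle_config(sensitivity = 0.97,
                                             specificity = 0.999),
                               scores = FALSE)
      noisy$source <- "annotator"
      noisy
    })
    adj <- adjudicate(ann[[1]], ann[[2]], r$pred_display, display_truth)
    records[[sid]]$adjudication <- adj$records
    n_disputed <- n_disputed + sum(!adj$records$consensus)
    fine_truth <- broadcast_fine(adj$truth, r$truth$layout)
    if (!identical(fine_truth$labels,
                   broadcast_fine(display_truth, r$truth$layout)$labels)) {
      stop_wsigrid(
        sprintf("stage adjudicate: slide %s truth mismatch", sid),
        "wsigrid_pipeline_error"
      )
    }
  }
  logf("adjudicated (%d grids escalated to chief)", n_disputed)

  # stage 4: standalone evaluation
  strata <- c(
    stratify(records, "all"),
    stratify(records, "procedure"),
    stratify(records, "cancer_area_le_50mm2")
  )
  write_metrics_report(strata, out_dir, config_hash = hash)
  logf("wrote metrics for %d strata", length(strata))

  # stage 5: reader study
  reader_out <- NULL
  if (length(config$readers)) {
    set.seed(config$seed + 3L)
    truth_maps <- lapply(records, `[[`, "truth")
    readers <- lapply(config$readers, function(prof) {
      pairs <- lapply(records, function(r) {
        simulate_reader(r$truth, r$pred, prof)
      })
      list(
        reader_id = prof$reader_id,
        before = lapply(pairs, `[[`, "before"),
        after = lapply(pairs, `[[`, "after")
      )
    })
    perf <- paired_performance(readers, truth_maps, z = config$z)
    revisions <- do.call(rbind, lapply(readers, function(rd) {
      revision_table(rd$reader_id, rd$before, rd$after, truth_maps,
                     method = config$mcnemar_method)
    }))
    utils::write.csv(revisions, file.path(out_dir, "revisions.csv"),
                     row.names = FALSE)
    utils::write.csv(perf$summary, file.path(out_dir, "reader_summary.csv"),
                     row.names = FALSE)
    miss_sets <- c(
      lapply(readers, function(rd) {
        missed_slides(rd$before, truth_maps, observer_id = rd$reader_id)
      }),
      list(missed_slides(lapply(records, `[[`, "pred"), truth_maps,
                         observer_id = "AI"))
    )
    venn <- venn_overlap(miss_sets)
    jsonlite::write_json(
      list(exclusive = as.list(venn$exclusive),
           per_observer = as.list(venn$per_observer),
           union_size = venn$union_size),
      file.path(out_dir, "venn.json"), auto_unbox = TRUE, digits = NA
    )
    reader_out <- list(performance = perf, revisions = revisions,
                       miss_sets = miss_sets, venn = venn)
    logf("reader study: %d readers, %d missed slides in union",
         length(readers), venn$union_size)
  }

  if (write_grids) {
    write_cohort(records, file.path(out_dir, "cohort"))
    write_grid_csv(lapply(records, `[[`, "pred"),
                   file.path(out_dir, "pred_grids.csv"))
    logf("wrote grid tables")
  }
  logf("done")
  invisible(list(records = records, strata = strata, reader = reader_out,
                 config_hash = hash))
}
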