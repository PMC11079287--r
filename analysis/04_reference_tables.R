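#!/usr/bin/env Rscript
# Stage 4: recompute the published performance tables from their raw
# contingency counts (shipped as fixtures) through the package's Wald /
# likelihood-ratio machinery, and print them in table format. This is the
# fixture-only path: no simulation, everything derives from counts.

suppressPackageStartupMessages(library(wsigrid))

out_dir <- "results"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (nm in c("grid_overall", "grid_endoscopic", "grid_surgical",
             "slide_overall", "slide_endoscopic", "slide_surgical")) {
  cc <- load_fixture(nm)
  p <- metric_panel(cc)
  cat(sprintf("%-18s sens %s  spec %s  LR+ %6.2f  LR- %.3f\n",
              nm, format_metric(p$sensitivity), format_metric(p$specificity),
              p$lr_positive, p$lr_negative))
  rows[[nm]] <- data.frame(
    table = nm, tp = cc$tp, fn = cc$fn, tn = cc$tn, fp = cc$fp,
    sensitivity_pct = round_half_up(100 * p$sensitivity$estimate, 2),
    sens_ci_low_pct = round_half_up(100 * p$sensitivity$ci_low, 2),
    sens_ci_high_pct = round_half_up(100 * p$sensitivity$ci_high, 2),
    specificity_pct = round_half_up(100 * p$specificity$estimate, 2),
    spec_ci_low_pct = round_half_up(100 * p$specificity$ci_low, 2),
    spec_ci_high_pct = round_half_up(100 * p$specificity$ci_high, 2),
    lr_positive = round_half_up(p$lr_positive, 2),
    lr_negative = round_half_up(p$lr_negative, 3)
  )
}
out <- do.call(rbind, rows)
write.csv(out, file.path(out_dir, "reference_tables.csv"), row.names = FALSE)

# revision counts with McNemar p-values
revs <- load_fixture("revisions")
cat("\nreader revisions (McNemar on discordant pairs):\n")
for (i in seq_len(nrow(revs))) {
  r <- revs[i, ]
  p_pos <- mcnemar_test(r$fn_to_tp, r$tp_to_fn)$p_value
  p_neg <- mcnemar_test(r$fp_to_tn, r$tn_to_fp)$p_value
  cat(sprintf("  %-4s FN->TP %4d vs TP->FN %3d (p=%.2g) | FP->TN %4d vs TN->FP %3d (p=%.2g)\n",
              r$reader_id, r$fn_to_tp, r$tp_to_fn, p_pos,
              r$fp_to_tn, r$tn_to_fp, p_neg))
  stopifnot(p_pos < 1e-4, p_neg < 1e-4)
}
totals <- load_fixture("totals")
cat(sprintf("\npooled FN->TP revisions: %d = %.2f%% of the %s positive grids\n",
            totals[["n_revised_positive_grids"]] - 158,
            100 * 3169 / totals[["n_positive_grids"]],
            format(totals[["n_positive_grids"]], big.mark = ",")))
cat("wrote results/reference_tables.csv\n")
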