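#' Classify a reader's grid revisions after AI exposure
#'
#' Compares the correctness status of every grid before and after the
#' reader saw the AI output, against ground truth, and tallies the grids
#' whose status changed into the four revision directions: FN->TP and
#' FP->TN (beneficial), TP->FN and TN->FP (harmful). Unrevised grids are
#' not tallied; each revised grid falls in exactly one direction.
#'
#' @param before,after reader `grid_label_map`s for the two conditions.
#' @param truth ground-truth `grid_label_map` on the same layout.
#' @return named integer vector `fn_to_tp`, `tp_to_fn`, `fp_to_tn`,
#'   `tn_to_fp`.
#' @export
classify_revisions <- function(before, after, truth) {
  check_same_layout(before, after, "before/after maps")
  check_same_layout(before, truth, "reader and truth maps")
  b <- before$labels
  a <- after$labels
  t <- truth$labels
  c(
    fn_to_tp = sum(t & !b & a),
    tp_to_fn = sum(t & b & !a),
    fp_to_tn = sum(!t & b & !a),
    tn_to_fp = sum(!t & !b & a)
  )
}

#' McNemar test on discordant revision counts
#'
#' Two-sided paired test of whether one revision direction outweighs its
#' opposite, on the discordant counts `b` and `c` (e.g. FN->TP vs TP->FN).
#' Uses the exact binomial sign test when `b + c < 25` and the
#' continuity-corrected chi-square statistic `(|b - c| - 1)^2 / (b + c)`
#' otherwise; `method` forces a variant. The correction term is capped at
#' `|b - c|` so it never pushes the statistic past zero — under exact
#' balance the statistic is 0 and `p = 1`, matching the exact test instead
#' of the spurious positive statistic an uncapped correction produces.
#' With no discordant pairs at all the test is degenerate and `p = 1` by
#' convention.
#'
#' @param b,c non-negative discordant counts.
#' @param method `"auto"` (default), `"exact"` or `"chisq"`.
#' @return list `p_value`, `statistic` (chi-square variant only),
#'   `method_used`, `degenerate`.
#' @export
mcnemar_test <- function(b, c, method = c("auto", "exact", "chisq")) {
  method <- match.arg(method)
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0) {
    return(list(p_value = 1.0, statistic = NA_real_,
                method_used = "degenerate", degenerate = TRUE))
  }
  if (method == "auto") method <- if (n < 25) "exact" else "chisq"
  if (method == "exact") {
    p <- stats::binom.test(b, n, p = 0.5)$p.value
    list(p_value = p, statistic = NA_real_, method_used = "exact",
         degenerate = FALSE)
  } else {
    stat <- max(0, abs(b - c) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    list(p_value = p, statistic = stat, method_used = "chisq_cc",
         degenerate = FALSE)
  }
}

#' Per-reader revision table with McNemar tests
#'
#' Builds one row of the revision report for a reader over a set of slides:
#' pooled counts of the four revision directions plus McNemar p-values for
#' the positive-grid pair (FN->TP vs TP->FN) and the negative-grid pair
#' (FP->TN vs TN->FP).
#'
#' @param reader_id identifier for the row.
#' @param before,after,truth named lists of `grid_label_map`s keyed by
#'   slide id (identical key sets).
#' @param method McNemar variant passed to [mcnemar_test()].
#' @return one-row data.frame: `reader_id`, the four direction counts,
#'   `mcnemar_p_positive`, `mcnemar_p_negative`.
#' @export
revision_table <- function(reader_id, before, after, truth,
                           method = "auto") {
  slides <- names(truth)
  check_slide_keys(before, after, truth, reader_id)
  tot <- c(fn_to_tp = 0L, tp_to_fn = 0L, fp_to_tn = 0L, tn_to_fp = 0L)
  for (s in slides) {
    tot <- tot + classify_revisions(before[[s]], after[[s]], truth[[s]])
  }
  p_pos <- mcnemar_test(tot[["fn_to_tp"]], tot[["tp_to_fn"]], method)$p_value
  p_neg <- mcnemar_test(tot[["fp_to_tn"]], tot[["tn_to_fp"]], method)$p_value
  data.frame(
    reader_id = reader_id,
    fn_to_tp = tot[["fn_to_tp"]], tp_to_fn = tot[["tp_to_fn"]],
    fp_to_tn = tot[["fp_to_tn"]], tn_to_fp = tot[["tn_to_fp"]],
    mcnemar_p_positive = p_pos, mcnemar_p_negative = p_neg
  )
}

check_slide_keys <- function(before, after, truth, reader_id) {
  slides <- names(truth)
  missing_b <- setdiff(slides, names(before))
  missing_a <- setdiff(slides, names(after))
  if (length(missing_b) || length(missing_a)) {
    stop_wsigrid(
      sprintf(
        "reader %s is missing annotations for slide(s): %s",
        reader_id,
        paste(unique(c(missing_b, missing_a)), collapse = ", ")
      ),
      "wsigrid_pairing_error"
    )
  }
  invisible(TRUE)
}

#' Paired reader performance with and without AI
#'
#' Computes each reader's pooled grid- and slide-level confusion in both
#' conditions, the micro-average across readers (counts pooled, the
#' package's primary "average"), and a macro-average of the per-reader
#' estimates. Every reader must have annotated every slide in both
#' conditions; an incomplete pairing errors up front listing the missing
#' cells.
#'
#' @param readers list of reader entries, each a list with `reader_id`,
#'   and `before`/`after` named lists of `grid_label_map`s keyed by slide.
#' @param truth named list of ground-truth `grid_label_map`s.
#' @param z critical value for the Wald intervals.
#' @return list with `per_reader` (nested confusion + metric panels per
#'   condition), `pooled` (micro-average panels per condition and
#'   granularity), and `summary`, a long data.frame of estimates.
#' @export
paired_performance <- function(readers, truth, z = 1.96) {
  slides <- names(truth)
  for (rd in readers) check_slide_keys(rd$before, rd$after, truth, rd$reader_id)

  condition_counts <- function(maps) {
    g <- confusion_counts(granularity = "grid")
    s <- confusion_counts(granularity = "slide")
    for (sl in slides) {
      g <- g + grid_confusion(maps[[sl]], truth[[sl]])
      s <- s + slide_confusion(maps[[sl]], truth[[sl]])
    }
    list(grid = g, slide = s)
  }

  per_reader <- lapply(readers, function(rd) {
    list(
      reader_id = rd$reader_id,
      without_ai = condition_counts(rd$before),
      with_ai = condition_counts(rd$after)
    )
  })
  names(per_reader) <- vapply(readers, `[[`, character(1), "reader_id")

  pool <- function(condition, granularity) {
    cc <- confusion_counts(granularity = granularity)
    for (pr in per_reader) cc <- cc + pr[[condition]][[granularity]]
    cc
  }
  pooled <- list()
  summary_rows <- list()
  for (cond in c("without_ai", "with_ai")) {
    for (gran in c("grid", "slide")) {
      cc <- pool(cond, gran)
      ss <- sens_spec(cc, z = z)
      pooled[[cond]][[gran]] <- list(counts = cc, sensitivity = ss$sensitivity,
                                     specificity = ss$specificity)
      macro_sens <- mean(vapply(per_reader, function(pr) {
        cc_i <- pr[[cond]][[gran]]
        cc_i$tp / (cc_i$tp + cc_i$fn)
      }, double(1)))
      macro_spec <- mean(vapply(per_reader, function(pr) {
        cc_i <- pr[[cond]][[gran]]
        cc_i$tn / (cc_i$tn + cc_i$fp)
      }, double(1)))
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        condition = cond, granularity = gran,
        sensitivity = ss$sensitivity$estimate,
        sens_ci_low = ss$sensitivity$ci_low,
        sens_ci_high = ss$sensitivity$ci_high,
        specificity = ss$specificity$estimate,
        spec_ci_low = ss$specificity$ci_low,
        spec_ci_high = ss$specificity$ci_high,
        macro_sensitivity = macro_sens,
        macro_specificity = macro_spec
      )
    }
  }
  list(
    per_reader = per_reader,
    pooled = pooled,
    summary = do.call(rbind, summary_rows)
  )
}

#' Missed slides for one observer
#'
#' A missed slide is a truth-positive slide on which the observer marked
#' none of the truth-positive grids — false alarms elsewhere on the slide do
#' not save it.
#'
#' @param annotations named list of the observer's `grid_label_map`s keyed
#'   by slide id; must cover every truth-positive slide.
#' @param truth named list of ground-truth maps.
#' @param observer_id identifier carried in the result.
#' @return list `observer_id`, `missed_slide_ids` (character vector).
#' @export
missed_slides <- function(annotations, truth, observer_id = "observer") {
  pos_slides <- names(truth)[vapply(truth, function(m) any(m$labels),
                                    logical(1))]
  not_covered <- setdiff(pos_slides, names(annotations))
  if (length(not_covered)) {
    stop_wsigrid(
      sprintf("observer %s lacks annotations for positive slide(s): %s",
              observer_id, paste(not_covered, collapse = ", ")),
      "wsigrid_pairing_error"
    )
  }
  missed <- pos_slides[vapply(pos_slides, function(s) {
    !any(annotations[[s]]$labels & truth[[s]]$labels)
  }, logical(1))]
  list(observer_id = observer_id, missed_slide_ids = missed)
}

#' Venn overlap structure of miss sets
#'
#' Exact intersection cardinality for every non-empty subset of observers,
#' the exclusive (subset-only) region sizes of the Venn diagram, and the
#' union size. Exclusive regions partition the union.
#'
#' @param miss_sets list of [missed_slides()] results (or named list of
#'   character vectors).
#' @return list `intersections` and `exclusive` (named integer vectors,
#'   subset names joined with `"&"`), `per_observer` totals and
#'   `union_size`.
#' @export
venn_overlap <- function(miss_sets) {
  sets <- lapply(miss_sets, function(s) {
    if (is.list(s) && !is.null(s$missed_slide_ids)) s$missed_slide_ids
    else as.character(s)
  })
  ids <- names(sets)
  if (is.null(ids) || any(ids == "")) {
    ids <- vapply(seq_along(miss_sets), function(i) {
      s <- miss_sets[[i]]
      if (is.list(s) && !is.null(s$observer_id)) s$observer_id
      else paste0("observer_", i)
    }, character(1))
    names(sets) <- ids
  }
  k <- length(sets)
  if (k < 2L) {
    stop_wsigrid("venn_overlap needs at least two observers",
                 "wsigrid_config_error")
  }
  universe <- unique(unlist(sets))
  membership <- do.call(cbind, lapply(sets, function(s) universe %in% s))
  if (is.null(membership)) membership <- matrix(logical(0), 0, k)
  inter <- integer(0)
  excl <- integer(0)
  for (bits in seq_len(2^k - 1L)) {
    in_subset <- as.logical(bitwAnd(bits, 2^(seq_len(k) - 1L)))
    nm <- paste(ids[in_subset], collapse = "&")
    rows_all <- apply(membership[, in_subset, drop = FALSE], 1L, all)
    inter[nm] <- sum(rows_all)
    rows_excl <- rows_all &
      !apply(membership[, !in_subset, drop = FALSE], 1L, any)
    excl[nm] <- sum(rows_excl)
  }
  list(
    intersections = inter,
    exclusive = excl,
    per_observer = vapply(sets, length, integer(1)),
    union_size = length(universe)
  )
}
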