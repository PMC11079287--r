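#' Proportion estimate with a Wald interval
#'
#' The workhorse interval of the evaluation: `p +/- z * sqrt(p(1-p)/n)`.
#' Deliberately NOT clipped to `[0, 1]` — near-perfect rates on small
#' denominators legitimately produce bounds above 100% (e.g. a slide
#' sensitivity of 163/164 has Wald upper bound 100.58%), and reporting the
#' raw bound keeps the interval honest about its normal approximation.
#' A clipped variant is available via `clip = TRUE` but is off by default.
#'
#' @param successes,n numerator and denominator counts (`n > 0`).
#' @param z normal critical value; 1.96 for two-sided 95% intervals.
#' @param clip clip the bounds to `[0, 1]`? Default `FALSE`.
#' @param metric name used in error messages and reports.
#' @return a `metric_result`: `estimate`, `ci_low`, `ci_high`, `n`, `z`.
#' @export
prop_wald <- function(successes, n, z = 1.96, clip = FALSE,
                      metric = "proportion") {
  if (is.na(n) || n <= 0) {
    stop_wsigrid(
      sprintf("%s is undefined: denominator is zero", metric),
      "wsigrid_undefined_metric"
    )
  }
  p <- successes / n
  se <- sqrt(p * (1 - p) / n)
  lo <- p - z * se
  hi <- p + z * se
  if (clip) {
    lo <- max(0, lo)
    hi <- min(1, hi)
  }
  structure(
    list(estimate = p, ci_low = lo, ci_high = hi, n = n, z = z,
         metric = metric),
    class = "metric_result"
  )
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("%s: %s%%; 95%%CI(%s%%, %s%%) [n=%s]\n",
              x$metric,
              format(round_half_up(100 * x$estimate, 2), nsmall = 2),
              format(round_half_up(100 * x$ci_low, 2), nsmall = 2),
              format(round_half_up(100 * x$ci_high, 2), nsmall = 2),
              format(x$n, big.mark = ",")))
  invisible(x)
}

#' Format a metric the way the clinical tables print it
#'
#' Percent scale, half-up rounding to two decimals.
#'
#' @param m a `metric_result`.
#' @return string like `"90.25%; 95%CI(90.04%, 90.46%)"`.
#' @export
format_metric <- function(m) {
  sprintf("%.2f%%; 95%%CI(%.2f%%, %.2f%%)",
          round_half_up(100 * m$estimate, 2),
          round_half_up(100 * m$ci_low, 2),
          round_half_up(100 * m$ci_high, 2))
}

#' Sensitivity and specificity with Wald intervals
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), each with the Wald
#' interval of [prop_wald()]. Applies identically at grid and slide
#' granularity.
#'
#' @param counts a `confusion_counts`.
#' @param z normal critical value (default 1.96).
#' @param clip clip CI bounds to `[0,1]`? Default `FALSE`.
#' @return list with `metric_result` elements `sensitivity` and
#'   `specificity`.
#' @export
sens_spec <- function(counts, z = 1.96, clip = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  list(
    sensitivity = prop_wald(counts$tp, counts$tp + counts$fn, z = z,
                            clip = clip, metric = "sensitivity"),
    specificity = prop_wald(counts$tn, counts$tn + counts$fp, z = z,
                            clip = clip, metric = "specificity")
  )
}

#' Diagnostic likelihood ratios
#'
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`, from unrounded
#' proportions. An LR+ well above 10 means every flagged grid deserves
#' scrutiny; an LR- near 0 supports using a clean result to rule out
#' disease. Degenerate rates are tolerated the way the reported tables
#' tolerate them: perfect specificity gives `LR+ = Inf`, perfect
#' sensitivity gives `LR- = 0`; only `spec = 0` (LR- undefined) errors.
#'
#' @param sens,spec proportions in `[0, 1]`, or `metric_result`s.
#' @return list `lr_positive`, `lr_negative`.
#' @export
likelihood_ratios <- function(sens, spec) {
  if (inherits(sens, "metric_result")) sens <- sens$estimate
  if (inherits(spec, "metric_result")) spec <- spec$estimate
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  if (spec == 0) {
    stop_wsigrid("negative likelihood ratio is undefined at specificity 0",
                 "wsigrid_undefined_metric")
  }
  lr_pos <- if (spec == 1) Inf else sens / (1 - spec)
  list(lr_positive = lr_pos, lr_negative = (1 - sens) / spec)
}

#' Full metric panel for one confusion table
#'
#' Convenience wrapper producing the row structure of the performance
#' tables: counts, sensitivity and specificity with Wald CIs, and both
#' likelihood ratios.
#'
#' @inheritParams sens_spec
#' @return list `counts`, `sensitivity`, `specificity`, `lr_positive`,
#'   `lr_negative`.
#' @export
metric_panel <- function(counts, z = 1.96) {
  ss <- sens_spec(counts, z = z)
  lr <- likelihood_ratios(ss$sensitivity, ss$specificity)
  c(list(counts = counts), ss, lr)
}
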