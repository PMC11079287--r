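#' ROC curve by threshold sweep
#'
#' Sweeps every distinct score value as a positivity threshold (score >=
#' threshold calls positive) and records the true- and false-positive rates.
#' Tied scores cross the threshold simultaneously, so ties contribute a
#' single diagonal segment — under trapezoidal integration this is exactly
#' the rank-statistic convention of crediting ties 0.5.
#'
#' @param scores numeric vector of per-unit scores (higher = more suspicious).
#' @param truth logical vector (or 0/1) of per-unit true labels.
#' @return data.frame `threshold`, `tpr`, `fpr`, ordered from the (0,0)
#'   corner to (1,1); the first row's threshold is `Inf`.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop_wsigrid("ROC is undefined with a single-class truth vector",
                 "wsigrid_undefined_metric")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  t <- truth[ord]
  # collapse tied scores: cumulative counts at the last index of each tie run
  last_of_run <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(t)[last_of_run]
  fp <- cumsum(!t)[last_of_run]
  data.frame(
    threshold = c(Inf, s[last_of_run]),
    tpr = c(0, tp / n_pos),
    fpr = c(0, fp / n_neg)
  )
}

#' Area under the ROC curve, trapezoidal rule
#'
#' Integrates the threshold-sweep ROC of [roc_curve()] with the trapezoidal
#' rule. Equivalent to the Mann-Whitney statistic
#' `P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)`.
#'
#' @inheritParams roc_curve
#' @return AUC scalar in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  rc <- roc_curve(scores, truth)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}
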