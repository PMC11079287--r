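#' Synthetic cohort configuration
#'
#' Defines the marginals of a simulated slide cohort. Defaults emulate the
#' validation cohort the package's evaluation machinery was designed for:
#' 1,418 slides of which 164 are cancer-positive (prevalence 164/1418),
#' 238/1418 from surgical resections, slides of roughly 100x100 fine
#' (0.25 mm) grids (~25 x 25 mm tissue, matching ~2,500 display grids per
#' slide), and lesion areas log-uniform on [0.5, 349.25] mm² — the observed
#' range from the smallest to the largest cancerous region.
#'
#' @param n_slides number of slides.
#' @param prevalence probability a slide is cancer-positive.
#' @param prop_surgical probability a slide comes from surgical resection
#'   (vs endoscopic removal).
#' @param slide_grids integer range `c(min, max)`: fine-grid rows and
#'   columns are drawn uniformly from this range per slide.
#' @param lesion_area_mm2 range `c(min, max)` of the log-uniform lesion-area
#'   distribution.
#' @param mpp microns per pixel recorded in the slide geometry.
#' @param seed integer seed making the cohort fully reproducible.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_slides = 1418,
                          prevalence = 164 / 1418,
                          prop_surgical = 238 / 1418,
                          slide_grids = c(90L, 110L),
                          lesion_area_mm2 = c(0.5, 349.25),
                          mpp = 0.25,
                          seed = 20260101L) {
  stopifnot(
    n_slides >= 1, prevalence >= 0, prevalence <= 1,
    prop_surgical >= 0, prop_surgical <= 1,
    length(slide_grids) == 2, slide_grids[1] >= 2,
    slide_grids[2] >= slide_grids[1],
    length(lesion_area_mm2) == 2, lesion_area_mm2[1] > 0,
    lesion_area_mm2[2] >= lesion_area_mm2[1], mpp > 0
  )
  fine_area <- 0.25^2
  min_grids_needed <- max(1L, round(lesion_area_mm2[1] / fine_area))
  if (min_grids_needed > 0.8 * slide_grids[1]^2) {
    stop_wsigrid("smallest lesion does not fit the smallest slide",
                 "wsigrid_config_error")
  }
  structure(
    list(n_slides = n_slides, prevalence = prevalence,
         prop_surgical = prop_surgical, slide_grids = as.integer(slide_grids),
         lesion_area_mm2 = lesion_area_mm2, mpp = mpp, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Eden-model blob growth: start from a seed cell and repeatedly absorb a
# uniformly chosen frontier cell, yielding a 4-connected lesion of exactly
# n_grids cells (possible whenever n_grids <= n_rows * n_cols). Cells are
# handled as column-major integer ids with a preallocated frontier buffer
# (duplicates allowed, skipped on pop) so growth is amortized linear.
grow_lesion <- function(n_rows, n_cols, n_grids) {
  stopifnot(n_grids >= 1, n_grids <= n_rows * n_cols)
  in_blob <- matrix(FALSE, n_rows, n_cols)
  frontier <- integer(max(64L, 8L * n_grids))
  f_len <- 0L
  push <- function(ids) {
    k <- length(ids)
    if (f_len + k > length(frontier)) {
      frontier <<- c(frontier, integer(length(frontier) + k))
    }
    frontier[f_len + seq_len(k)] <<- ids
    f_len <<- f_len + k
  }
  nb_ids <- function(id) {
    r <- (id - 1L) %% n_rows + 1L
    c <- (id - 1L) %/% n_rows + 1L
    ids <- c(if (r > 1L) id - 1L, if (r < n_rows) id + 1L,
             if (c > 1L) id - n_rows, if (c < n_cols) id + n_rows)
    ids[!in_blob[ids]]
  }
  seed_id <- sample.int(n_rows * n_cols, 1L)
  in_blob[seed_id] <- TRUE
  push(nb_ids(seed_id))
  n <- 1L
  while (n < n_grids) {
    # pop until a fresh cell appears; the frontier is never exhausted
    # while the blob is smaller than the lattice
    repeat {
      j <- sample.int(f_len, 1L)
      cell <- frontier[j]
      frontier[j] <- frontier[f_len]
      f_len <- f_len - 1L
      if (!in_blob[cell]) break
    }
    in_blob[cell] <- TRUE
    n <- n + 1L
    push(nb_ids(cell))
  }
  in_blob
}

neighbours4 <- function(r, c, n_rows, n_cols) {
  nb <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
  nb[nb[, 1] >= 1L & nb[, 1] <= n_rows & nb[, 2] >= 1L & nb[, 2] <= n_cols,
     , drop = FALSE]
}

#' Generate a synthetic slide cohort
#'
#' Draws slide geometry, procedure type and positivity per
#' [cohort_config()]; each positive slide receives one contiguous
#' (4-connected) lesion grown to the grid count matching its sampled area
#' (area / 0.0625 mm², so the grid-derived area matches the sampled area
#' within one grid), rejected and redrawn if it would exceed 80% of the
#' slide. Negative slides are all-negative. Fully deterministic under the
#' config seed.
#'
#' @param config a `cohort_config`.
#' @return list of slide records: `slide_id`, `procedure`, `truth`
#'   (fine-level `grid_label_map`), `n_positive_grids`, `cancer_area_mm2`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  fine_area <- 0.25^2
  lr <- log(config$lesion_area_mm2)
  records <- vector("list", config$n_slides)
  for (i in seq_len(config$n_slides)) {
    nr <- sample(config$slide_grids[1]:config$slide_grids[2], 1L)
    nc <- sample(config$slide_grids[1]:config$slide_grids[2], 1L)
    edge_px <- 250 / config$mpp # 0.25 mm in pixels
    layout <- mesh_layout(ceiling(nc * edge_px), ceiling(nr * edge_px),
                          config$mpp, 0.25)
    positive <- stats::runif(1) < config$prevalence
    labels <- matrix(FALSE, layout$n_rows, layout$n_cols)
    if (positive) {
      cap <- floor(0.8 * layout$n_rows * layout$n_cols)
      for (try in 1:100) {
        area <- exp(stats::runif(1, lr[1], lr[2]))
        n_grids <- max(1L, as.integer(round(area / fine_area)))
        if (n_grids <= cap) break
        if (try == 100) {
          stop_wsigrid("could not fit a lesion on the slide",
                       "wsigrid_config_error")
        }
      }
      labels <- grow_lesion(layout$n_rows, layout$n_cols, n_grids)
    }
    truth <- grid_label_map(layout, labels, source = "truth")
    records[[i]] <- list(
      slide_id = sprintf("S%04d", i),
      procedure = if (stats::runif(1) < config$prop_surgical) "surgical"
                  else "endoscopic",
      truth = truth,
      n_positive_grids = sum(labels),
      cancer_area_mm2 = sum(labels) * fine_area
    )
  }
  names(records) <- vapply(records, `[[`, character(1), "slide_id")
  records
}

#' Detection-oracle configuration
#'
#' A tunable per-grid detector standing in for a trained segmentation CNN.
#' Defaults put it at the operating point measured for the real system:
#' per-grid sensitivity 0.9025 and specificity 0.9660.
#'
#' @param sensitivity probability a truth-positive grid is flagged.
#' @param specificity probability a truth-negative grid is left clean.
#' @param spatial_correlation error clumping parameter (>= 0). 0 (default)
#'   gives independent per-grid errors; positive values place the same
#'   expected number of errors as 4-connected clumps of mean size
#'   `1 + spatial_correlation`, mimicking the spatial coherence of real
#'   CNN failures without changing the marginal rates.
#' @param score_beta_pos,score_beta_neg `c(shape1, shape2)` of the Beta
#'   distributions dressing predicted-positive / predicted-negative grids
#'   with continuous scores (for ROC analyses); the label is recoverable by
#'   thresholding scores at 0.5.
#' @return an `oracle_config` list.
#' @export
oracle_config <- function(sensitivity = 0.9025, specificity = 0.9660,
                          spatial_correlation = 0,
                          score_beta_pos = c(8, 2),
                          score_beta_neg = c(2, 8)) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, spatial_correlation >= 0)
  structure(
    list(sensitivity = sensitivity, specificity = specificity,
         spatial_correlation = spatial_correlation,
         score_beta_pos = score_beta_pos, score_beta_neg = score_beta_neg),
    class = "oracle_config"
  )
}

#' Simulate the detection oracle on a truth map
#'
#' Flags each truth-positive grid with probability `sensitivity` and each
#' truth-negative grid with probability `1 - specificity`, independently by
#' default or in connected clumps under `spatial_correlation > 0`, and
#' dresses every grid with a Beta-distributed score consistent with its
#' predicted label.
#'
#' @param truth a `grid_label_map` of ground truth.
#' @param config an [oracle_config()].
#' @param scores attach continuous scores? Default `TRUE`.
#' @return a `grid_label_map` (source `"ai"`) with labels and, optionally,
#'   scores.
#' @export
simulate_oracle <- function(truth, config = oracle_config(), scores = TRUE) {
  stopifnot(inherits(truth, "grid_label_map"), inherits(config, "oracle_config"))
  t <- truth$labels
  n <- length(t)
  if (config$spatial_correlation == 0) {
    p_flag <- ifelse(t, config$sensitivity, 1 - config$specificity)
    pred <- matrix(stats::runif(n) < p_flag, nrow(t), ncol(t))
  } else {
    pred <- t
    pred[clumped_errors(t, TRUE, 1 - config$sensitivity,
                        config$spatial_correlation)] <- FALSE
    pred[clumped_errors(t, FALSE, 1 - config$specificity,
                        config$spatial_correlation)] <- TRUE
  }
  sc <- NULL
  if (scores) {
    sc <- matrix(0, nrow(t), ncol(t))
    npos <- sum(pred)
    sc[pred] <- 0.5 + 0.5 * stats::rbeta(npos, config$score_beta_pos[1],
                                         config$score_beta_pos[2])
    sc[!pred] <- 0.5 * stats::rbeta(n - npos, config$score_beta_neg[1],
                                    config$score_beta_neg[2])
  }
  grid_label_map(truth$layout, pred, scores = sc, source = "ai")
}

# place Binomial(n_class, rate) error grids as 4-connected clumps of
# geometric mean size 1 + sc within the given truth class; the error count
# is drawn first so the marginal rate is preserved exactly in expectation
clumped_errors <- function(t, class_value, rate, sc) {
  cells <- which(t == class_value)
  err <- matrix(FALSE, nrow(t), ncol(t))
  n_err <- stats::rbinom(1, length(cells), rate)
  placed <- 0L
  while (placed < n_err && length(cells) > 0L) {
    target <- min(1L + stats::rgeom(1, 1 / (1 + sc)), n_err - placed)
    seed <- cells[sample.int(length(cells), 1L)]
    current <- seed
    for (k in seq_len(target)) {
      rc <- arrayInd(current, dim(t))
      err[current] <- TRUE
      placed <- placed + 1L
      nb <- neighbours4(rc[1], rc[2], nrow(t), ncol(t))
      nb_idx <- nb[, 1] + (nb[, 2] - 1L) * nrow(t)
      nb_idx <- nb_idx[t[nb_idx] == class_value & !err[nb_idx]]
      if (length(nb_idx) == 0L || placed >= n_err) break
      current <- nb_idx[sample.int(length(nb_idx), 1L)]
    }
    cells <- cells[!err[cells]]
  }
  err
}

#' Reader behaviour profile
#'
#' Generative model of a pathologist reading grids before and after seeing
#' the AI overlay. Baseline per-grid rates default to the measured reader
#' averages (sensitivity 81.80%, specificity 99.93%). Revisions act only on
#' grids where the AI overlay gives the reader a reason to change: a
#' missed cancer grid can be revised to positive only when the AI flagged
#' it, a false alarm withdrawn only when the AI left it clean, and so on;
#' `revision_probs` are the per-grid flip probabilities conditional on that
#' opportunity. Defaults are calibrated so pooled revision tallies have the
#' marginal structure observed in the reader study (beneficial revisions
#' dominating harmful ones by roughly two orders of magnitude on positive
#' grids).
#'
#' @param reader_id identifier.
#' @param seniority `"junior"` or `"senior"`.
#' @param sensitivity,specificity baseline per-grid rates before AI.
#' @param revision_probs named numeric: `fn_to_tp`, `tp_to_fn`, `fp_to_tn`,
#'   `tn_to_fp` flip probabilities in `[0, 1]`.
#' @return a `reader_profile` list.
#' @export
reader_profile <- function(reader_id, seniority = c("junior", "senior"),
                           sensitivity = 0.818, specificity = 0.9993,
                           revision_probs = c(fn_to_tp = 0.11,
                                              tp_to_fn = 0.002,
                                              fp_to_tn = 0.25,
                                              tn_to_fp = 0.0005)) {
  seniority <- match.arg(seniority)
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            all(revision_probs >= 0), all(revision_probs <= 1),
            setequal(names(revision_probs),
                     c("fn_to_tp", "tp_to_fn", "fp_to_tn", "tn_to_fp")))
  structure(
    list(reader_id = reader_id, seniority = seniority,
         sensitivity = sensitivity, specificity = specificity,
         revision_probs = revision_probs),
    class = "reader_profile"
  )
}

#' Simulate one reader's before/after annotation pair
#'
#' The before-map is drawn from the profile's baseline rates against truth;
#' the after-map applies direction-specific flips conditional on the AI
#' label per the profile's `revision_probs` (see [reader_profile()]).
#'
#' @param truth ground-truth `grid_label_map`.
#' @param ai_pred the AI `grid_label_map` the reader is exposed to.
#' @param profile a [reader_profile()].
#' @return list `before` and `after` `grid_label_map`s (source `"reader"`).
#' @export
simulate_reader <- function(truth, ai_pred, profile) {
  check_same_layout(truth, ai_pred, "truth and AI maps")
  stopifnot(inherits(profile, "reader_profile"))
  t <- truth$labels
  ai <- ai_pred$labels
  n <- length(t)
  p_mark <- ifelse(t, profile$sensitivity, 1 - profile$specificity)
  before <- matrix(stats::runif(n) < p_mark, nrow(t), ncol(t))
  rp <- profile$revision_probs
  u <- matrix(stats::runif(n), nrow(t), ncol(t))
  after <- before
  after[t & !before & ai & u < rp[["fn_to_tp"]]] <- TRUE
  after[t & before & !ai & u < rp[["tp_to_fn"]]] <- FALSE
  after[!t & before & !ai & u < rp[["fp_to_tn"]]] <- FALSE
  after[!t & !before & ai & u < rp[["tn_to_fp"]]] <- TRUE
  list(
    before = grid_label_map(truth$layout, before, source = "reader"),
    after = grid_label_map(truth$layout, after, source = "reader")
  )
}
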