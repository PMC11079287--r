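# Independent brute-force oracles used to cross-check the vectorized
# implementation paths. These deliberately share no code with the package
# internals: plain per-pixel / per-grid / per-pair loops.

# per-pixel loop over positive pixels, accumulating positive area per grid
brute_mask_labels <- function(mask, mpp, edge_mm, threshold_um2,
                              strict = TRUE) {
  edge_um <- edge_mm * 1000
  n_rows <- as.integer(ceiling(nrow(mask) * mpp / edge_um))
  n_cols <- as.integer(ceiling(ncol(mask) * mpp / edge_um))
  area <- matrix(0, n_rows, n_cols)
  pos <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pos)) {
    for (i in seq_len(nrow(pos))) {
      y0 <- pos[i, 1] - 1L
      x0 <- pos[i, 2] - 1L
      r <- floor(y0 * mpp / edge_um) + 1L
      c <- floor(x0 * mpp / edge_um) + 1L
      area[r, c] <- area[r, c] + mpp^2
    }
  }
  if (strict) area > threshold_um2 else area >= threshold_um2
}

# per-grid double loop confusion tally
brute_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (truth[i, j] && pred[i, j]) tp <- tp + 1L
      else if (truth[i, j] && !pred[i, j]) fn <- fn + 1L
      else if (!truth[i, j] && pred[i, j]) fp <- fp + 1L
      else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# per-grid loop over revision directions
brute_revisions <- function(before, after, truth) {
  out <- c(fn_to_tp = 0L, tp_to_fn = 0L, fp_to_tn = 0L, tn_to_fp = 0L)
  for (k in seq_along(truth)) {
    if (truth[k] && !before[k] && after[k]) out["fn_to_tp"] <- out["fn_to_tp"] + 1L
    if (truth[k] && before[k] && !after[k]) out["tp_to_fn"] <- out["tp_to_fn"] + 1L
    if (!truth[k] && before[k] && !after[k]) out["fp_to_tn"] <- out["fp_to_tn"] + 1L
    if (!truth[k] && !before[k] && after[k]) out["tn_to_fp"] <- out["tn_to_fp"] + 1L
  }
  out
}

# AUC as the Mann-Whitney pair statistic: P(s+ > s-) + 0.5 P(s+ = s-)
brute_pair_auc <- function(scores, truth) {
  sp <- scores[as.logical(truth)]
  sn <- scores[!as.logical(truth)]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# flood fill from the first positive cell; TRUE iff all positives form one
# 4-connected component
is_4connected <- function(m) {
  idx <- which(m)
  if (length(idx) <= 1L) return(TRUE)
  seen <- matrix(FALSE, nrow(m), ncol(m))
  queue <- idx[1]
  seen[idx[1]] <- TRUE
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    r <- (cur - 1L) %% nrow(m) + 1L
    c <- (cur - 1L) %/% nrow(m) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr >= 1 && rr <= nrow(m) && cc >= 1 && cc <= ncol(m)) {
        k <- rr + (cc - 1L) * nrow(m)
        if (m[k] && !seen[k]) {
          seen[k] <- TRUE
          queue <- c(queue, k)
        }
      }
    }
  }
  all(seen[idx])
}

# convenience constructors for small label maps
toy_layout <- function(n_rows, n_cols, edge_mm = 0.25, mpp = 0.25) {
  edge_px <- edge_mm * 1000 / mpp
  mesh_layout(n_cols * edge_px, n_rows * edge_px, mpp, edge_mm)
}

toy_map <- function(labels, edge_mm = 0.25, source = "truth") {
  lay <- toy_layout(nrow(labels), ncol(labels), edge_mm = edge_mm)
  grid_label_map(lay, labels, source = source)
}

random_map <- function(n_rows, n_cols, p = 0.5, edge_mm = 0.25,
                       source = "truth") {
  toy_map(matrix(runif(n_rows * n_cols) < p, n_rows, n_cols),
          edge_mm = edge_mm, source = source)
}
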