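test_that("mesh_layout covers the slide with ceiling division", {
  lay <- mesh_layout(20000, 10000, mpp = 0.25, grid_edge_mm = 0.5)
  expect_equal(lay$n_cols, 10L)
  expect_equal(lay$n_rows, 5L)

  # one extra pixel forces a partial column
  expect_equal(mesh_layout(20001, 10000, 0.25, 0.5)$n_cols, 11L)

  # non-integer mpp: ceil(4096 * 0.2524 / 250) = ceil(4.135...) = 5
  lay2 <- mesh_layout(4096, 4096, mpp = 0.2524, grid_edge_mm = 0.25)
  expect_equal(lay2$n_cols, 5L)
  expect_equal(lay2$n_rows, 5L)
})

test_that("mesh_layout rejects invalid geometry", {
  expect_error(mesh_layout(0, 100, 0.25, 0.5), class = "wsigrid_invalid_geometry")
  expect_error(mesh_layout(100, -5, 0.25, 0.5), class = "wsigrid_invalid_geometry")
  expect_error(mesh_layout(100, 100, 0, 0.5), class = "wsigrid_invalid_geometry")
  expect_error(mesh_layout(100, 100, 0.25, 0), class = "wsigrid_invalid_geometry")
})

test_that("every pixel belongs to exactly one grid and grids tile the slide", {
  # exhaustive pixel -> grid assignment on small lattices, several geometries
  for (geom in list(c(37, 23, 0.31, 0.25), c(64, 64, 0.25, 0.5),
                    c(101, 53, 0.2524, 0.25))) {
    lay <- mesh_layout(geom[1], geom[2], geom[3], geom[4])
    edge_um <- geom[4] * 1000
    assignment <- matrix(0L, lay$n_rows, lay$n_cols)
    for (x in seq_len(geom[1]) - 1L) {
      for (y in seq_len(geom[2]) - 1L) {
        r <- floor(y * geom[3] / edge_um) + 1
        c <- floor(x * geom[3] / edge_um) + 1
        expect_true(r >= 1 && r <= lay$n_rows && c >= 1 && c <= lay$n_cols)
        assignment[r, c] <- assignment[r, c] + 1L
      }
    }
    expect_equal(sum(assignment), geom[1] * geom[2]) # partition, no pixel lost
    expect_true(all(assignment > 0L))                # no empty grid
  }
})

test_that("area threshold is strictly 'exceeds': 625.0 um2 stays negative", {
  lay <- mesh_layout(1000, 1000, mpp = 0.25, grid_edge_mm = 0.25)
  mask <- matrix(0L, 1000, 1000)
  mask[1:100, 1:100] <- 1L # 10,000 px * 0.0625 um2 = exactly 625 um2
  expect_false(any(mask_to_fine_labels(mask, lay)$labels))

  mask[100, 101] <- 1L # 10,001 px -> 625.0625 um2
  expect_true(mask_to_fine_labels(mask, lay)$labels[1, 1])

  # inclusive variant flips the boundary case
  mask[100, 101] <- 0L
  expect_true(mask_to_fine_labels(mask, lay, strict = FALSE)$labels[1, 1])
})

test_that("saturated masks label all grids accordingly", {
  lay <- mesh_layout(500, 750, mpp = 0.25, grid_edge_mm = 0.25)
  zeros <- matrix(0L, 750, 500)
  expect_false(any(mask_to_fine_labels(zeros, lay)$labels))
  ones <- matrix(1L, 750, 500)
  expect_true(all(mask_to_fine_labels(ones, lay)$labels))
})

test_that("mask dimension mismatch raises a shape error", {
  lay <- mesh_layout(500, 500, 0.25, 0.25)
  expect_error(mask_to_fine_labels(matrix(0L, 100, 100), lay),
               class = "wsigrid_shape_error")
})

test_that("mask labelling agrees with the per-pixel brute-force oracle", {
  set.seed(41)
  for (rep in 1:6) {
    mpp <- c(0.25, 0.2524, 0.5)[(rep - 1) %% 3 + 1]
    h <- sample(150:256, 1)
    w <- sample(150:256, 1)
    mask <- matrix(rbinom(h * w, 1, 0.25), h, w)
    lay <- mesh_layout(w, h, mpp, 0.25)
    got <- mask_to_fine_labels(mask, lay)$labels
    want <- brute_mask_labels(mask, mpp, 0.25, 625)
    expect_identical(unname(got), unname(want))
  }
})

test_that("raising the area threshold never increases positive grids", {
  set.seed(42)
  mask <- matrix(rbinom(300 * 300, 1, 0.1), 300, 300)
  lay <- mesh_layout(300, 300, 0.3, 0.25)
  thresholds <- c(0, 100, 625, 1500, 5000)
  npos <- vapply(thresholds, function(th) {
    sum(mask_to_fine_labels(mask, lay, area_threshold_um2 = th)$labels)
  }, double(1))
  expect_true(all(diff(npos) <= 0))
})

test_that("display rollup is any-positive over up to 2x2 fine grids", {
  fine <- toy_map(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  disp <- rollup_display(fine)
  expect_equal(disp$layout$n_rows, 1L)
  expect_true(disp$labels[1, 1])

  expect_false(any(rollup_display(toy_map(matrix(FALSE, 2, 2)))$labels))

  # odd extent: 3x3 fine -> 2x2 display; corner display grid covers a
  # single fine grid
  m <- matrix(FALSE, 3, 3)
  m[3, 3] <- TRUE
  disp3 <- rollup_display(toy_map(m))
  expect_equal(dim(disp3$labels), c(2L, 2L))
  expect_identical(unname(disp3$labels),
                   matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
})

test_that("rollup rejects display-level input and respects min_positive", {
  fine <- toy_map(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  disp <- rollup_display(fine)
  expect_error(rollup_display(disp), class = "wsigrid_level_error")
  # with min_positive = 3 the two positives are not enough
  expect_false(any(rollup_display(fine, min_positive = 3)$labels))
})

test_that("rollup consistency invariants hold on random maps", {
  set.seed(43)
  for (rep in 1:10) {
    fine <- random_map(sample(3:15, 1), sample(3:15, 1), p = runif(1, 0, 0.4))
    disp <- rollup_display(fine)
    expect_lte(sum(disp$labels), sum(fine$labels))
    expect_equal(any(disp$labels), any(fine$labels))
    # every positive fine grid is covered by a positive display grid
    if (any(fine$labels)) {
      idx <- which(fine$labels, arr.ind = TRUE)
      covered <- disp$labels[cbind(ceiling(idx[, 1] / 2),
                                   ceiling(idx[, 2] / 2))]
      expect_true(all(covered))
    }
  }
})

test_that("display scores roll up as the max over constituent fine grids", {
  lay <- toy_layout(3, 3)
  sc <- matrix(seq(0.1, 0.9, by = 0.1), 3, 3)
  fine <- grid_label_map(lay, matrix(TRUE, 3, 3), scores = sc)
  disp <- rollup_display(fine)
  expect_equal(disp$scores[1, 1], max(sc[1:2, 1:2]))
  expect_equal(disp$scores[2, 2], sc[3, 3])
})

test_that("boxes appear for positive display grids with the 6400 um2 colour rule", {
  # 4x4 fine grids -> 2x2 display grids at mpp 0.25 (fine grid = 1000 px)
  lay <- mesh_layout(4000, 4000, 0.25, 0.25)
  mask <- matrix(0L, 4000, 4000)
  # region of 160x160 px = 1600 um2 < 6400 -> yellow, display grid (1,1)
  mask[1:160, 1:160] <- 1L
  # region of 500x500 px = 15625 um2 >= 6400 -> red, display grid (2,2)
  mask[3200:3699, 3200:3699] <- 1L
  fine <- mask_to_fine_labels(mask, lay)
  disp <- rollup_display(fine)
  boxes <- boxes_from_labels(disp, fine)
  expect_true(all(c("red", "yellow") %in% boxes$color))
  yellow <- boxes[boxes$color == "yellow", ]
  expect_true(all(yellow$region_area_um2 < 6400))
  red <- boxes[boxes$color == "red", ]
  expect_true(all(red$region_area_um2 >= 6400))
  # one box per positive display grid, pixel bounds inside the slide
  expect_equal(nrow(boxes), sum(disp$labels))
  expect_true(all(boxes$x1 <= 4000 & boxes$y1 <= 4000))
  expect_true(all(boxes$x0 < boxes$x1 & boxes$y0 < boxes$y1))
})

test_that("an all-negative map yields no boxes", {
  fine <- toy_map(matrix(FALSE, 4, 4))
  boxes <- boxes_from_labels(rollup_display(fine), fine)
  expect_equal(nrow(boxes), 0L)
})

test_that("boxes serialize to a GeoJSON FeatureCollection", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE
  fine <- toy_map(m)
  boxes <- boxes_from_labels(rollup_display(fine), fine)
  path <- withr::local_tempfile(fileext = ".geojson")
  boxes_to_geojson(boxes, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, nrow(boxes))
  expect_equal(gj$features[[1]]$properties$color, boxes$color[1])
})
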