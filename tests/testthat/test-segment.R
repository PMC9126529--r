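test_that("segment_tile handles degenerate inputs per contract", {
  expect_error(segment_tile(matrix(0, 10, 10)), "RGB")
  # all-background tile: empty result
  bg <- array(rep(c(242, 222, 232), each = 64 * 64), c(64, 64, 3))
  seg <- segment_tile(bg)
  expect_length(seg$cells, 0)
  expect_equal(max(seg$labels), 0)
})

test_that("known placements are detected and classified", {
  # 3 large round blasts + 2 small WBCs at hand-picked centres
  n <- 256
  img <- array(rep(c(242, 222, 232), each = n * n), c(n, n, 3))
  put <- function(img, cy, cx, r, col) {
    sel <- blastprs:::ellipse_sel(n, cy, cx, r, r, 0)
    blastprs:::paint(img, sel, col)
  }
  blasts <- list(c(60, 60), c(60, 190), c(190, 60))
  wbcs <- list(c(190, 190), c(128, 128))
  for (b in blasts) img <- put(img, b[1], b[2], 18, c(125, 72, 168))
  for (w in wbcs) img <- put(img, w[1], w[2], 7, c(92, 48, 138))
  seg <- segment_tile(img)
  cls <- vapply(seg$cells, function(cc) cc$cell_class, character(1))
  expect_equal(sum(cls == "myeloblast"), 3)
  expect_equal(sum(cls == "other_wbc"), 2)
  # centroid containment: each truth centre falls in an instance of the
  # right class
  for (b in blasts) {
    l <- seg$labels[b[1], b[2]]
    expect_gt(l, 0)
    expect_equal(seg$cells[[l]]$cell_class, "myeloblast")
  }
  # instances pairwise disjoint by construction of the label image
  areas <- vapply(seg$cells, function(cc) cc$area_px, numeric(1))
  expect_equal(sum(areas), sum(seg$labels > 0))
})

test_that("watershed splits two tangent blasts", {
  n <- 192
  img <- array(rep(c(242, 222, 232), each = n * n), c(n, n, 3))
  put <- function(img, cy, cx, r, col) {
    sel <- blastprs:::ellipse_sel(n, cy, cx, r, r, 0)
    blastprs:::paint(img, sel, col)
  }
  # discs of radius 16 touching at one tangent point
  img <- put(img, 96, 64, 16, c(125, 72, 168))
  img <- put(img, 96, 96, 16, c(125, 72, 168))
  seg <- segment_tile(img)
  cls <- vapply(seg$cells, function(cc) cc$cell_class, character(1))
  expect_equal(sum(cls == "myeloblast"), 2)
})

test_that("Otsu foreground is invariant to common intensity scaling", {
  p <- tiny_params(seed = 21)
  set.seed(21)
  tile <- render_tile(p, h = 1)
  seg1 <- segment_tile(tile$rgb)
  scaled <- tile$rgb
  storage.mode(scaled) <- "double"
  scaled <- round(scaled * 0.8)
  seg2 <- segment_tile(scaled)
  expect_equal(length(seg2$cells), length(seg1$cells))
})

test_that("evaluate_segmentation reproduces hand-counted confusion tables", {
  truth <- matrix(FALSE, 4, 4); truth[1:2, 1:2] <- TRUE  # 4 positive px
  pred <- matrix(FALSE, 4, 4)
  pred[1, 1:2] <- TRUE          # 2 true positives
  pred[3, 3:4] <- TRUE          # 2 false positives
  pm <- evaluate_segmentation(pred, truth)
  expect_equal(pm$tpr, 0.5)
  expect_equal(pm$tnr, 10 / 12)
  expect_equal(pm$f1, 0.5)
  expect_equal(pm$n_pixels, 16)

  # identity and total disagreement
  id <- evaluate_segmentation(truth, truth)
  expect_equal(c(id$tpr, id$tnr, id$f1), c(1, 1, 1))
  cmp <- evaluate_segmentation(!truth, truth)
  expect_equal(c(cmp$tpr, cmp$tnr, cmp$f1), c(0, 0, 0))

  # empty-denominator conventions
  none <- matrix(FALSE, 2, 2)
  expect_equal(evaluate_segmentation(none, none)$tpr, 1)
  expect_equal(evaluate_segmentation(none, none)$f1, 1)
  expect_error(evaluate_segmentation(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)),
               "shape mismatch")
})

test_that("segmenter recovers counts and pixels on rendered tiles", {
  p <- tiny_params(seed = 33)
  set.seed(33)
  ok_count <- 0; f1s <- numeric(20)
  for (i in 1:20) {
    tile <- render_tile(p, h = runif(1, 0, 2.5))
    seg <- segment_tile(tile$rgb)
    cls <- vapply(seg$cells, function(cc) cc$cell_class, character(1))
    ok_count <- ok_count + (sum(cls == "myeloblast") == max(tile$blast_mask))
    pm <- evaluate_segmentation(segmentation_class_mask(seg, "myeloblast"),
                                tile$blast_mask > 0)
    f1s[i] <- pm$f1
  }
  expect_gte(ok_count, 19)
  expect_gte(min(f1s), 0.9)
})

test_that("mask-ingest instances mirror the truth masks exactly", {
  p <- tiny_params(seed = 41)
  set.seed(41)
  tile <- render_tile(p, h = 1.5)
  inst <- instances_from_masks(tile$blast_mask, tile$wbc_mask)
  cls <- vapply(inst$cells, function(cc) cc$cell_class, character(1))
  expect_equal(sum(cls == "myeloblast"), max(tile$blast_mask))
  expect_equal(sum(cls == "other_wbc"), max(tile$wbc_mask))
  expect_equal(sum(inst$labels > 0),
               sum(tile$blast_mask > 0) + sum(tile$wbc_mask > 0))
})
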