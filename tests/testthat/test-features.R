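test_that("first-order statistics match hand computations", {
  m <- matrix(TRUE, 2, 2)
  # constant region: degenerate conventions
  f0 <- first_order_features(matrix(5, 2, 2), m)
  expect_equal(unname(f0[c("fo_variance", "fo_range", "fo_entropy",
                           "fo_skewness", "fo_kurtosis")]),
               c(0, 0, 0, 0, 0))
  expect_equal(unname(f0["fo_energy"]), 1)

  # {1,2,3}: symmetric sample
  m3 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  f1 <- first_order_features(matrix(c(1, 2, 3, 99), 2, 2), m3)
  expect_equal(unname(f1["fo_mean"]), 2)
  expect_equal(unname(f1["fo_skewness"]), 0)
  expect_equal(unname(f1["fo_mad"]), 1)

  # {0,0,0,8}: population variance
  f2 <- first_order_features(matrix(c(0, 0, 0, 8), 2, 2), m)
  expect_equal(unname(f2["fo_mean"]), 2)
  expect_equal(unname(f2["fo_variance"]), 12)
})

test_that("shape features meet the circle and ellipse geometry checks", {
  disc <- disc_mask(50)
  sf <- shape_features(disc)
  expect_gte(sf[["mo_circularity"]], 0.95)
  expect_lte(sf[["mo_circularity"]], 1.05)
  expect_lt(sf[["mo_eccentricity"]], 0.1)
  expect_equal(sf[["mo_area"]], sum(disc))
  expect_equal(sf[["efd_1"]], 1)
  expect_equal(sf[["ir_concavity_rate"]], 0)

  # translation leaves Hu moments unchanged
  n <- nrow(disc)
  d2 <- matrix(FALSE, n + 40, n + 40)
  d2[(1:n) + 17, (1:n) + 23] <- disc
  sf2 <- shape_features(d2)
  hu <- paste0("hu_", 1:7)
  expect_equal(sf[hu], sf2[hu], tolerance = 1e-6)

  # 2:1 ellipse vs 90-degree rotated copy
  e1 <- ellipse_mask(20, 40)
  s1 <- shape_features(e1)
  s2 <- shape_features(rot90_mask(e1))
  expect_equal(s1[["mo_aspect_ratio"]], 2, tolerance = 0.05)
  expect_equal(s1[hu], s2[hu], tolerance = 1e-3)
  expect_gt(s1[["mo_eccentricity"]], 0.8)
})

test_that("degenerate masks are rejected with informative errors", {
  line <- matrix(FALSE, 20, 20); line[10, 3:18] <- TRUE
  expect_error(shape_features(line), "degenerate")
  tiny <- matrix(FALSE, 5, 5); tiny[3, 3] <- TRUE
  expect_error(shape_features(tiny), "degenerate")
})

test_that("catalog is frozen at 53 descriptors / 214 patient features", {
  expect_length(feature_catalog(), 53)
  expect_false(anyDuplicated(feature_catalog()) > 0)
  expect_length(patient_feature_names(), 214)
  expect_identical(tail(patient_feature_names(), 2),
                   c("blast_count", "blast_percentage"))
  # order is stable across calls
  expect_identical(patient_feature_names(), patient_feature_names())
})

test_that("tile aggregation follows the stated statistic conventions", {
  one <- matrix(rnorm(53), 1, dimnames = list(NULL, feature_catalog()))
  a1 <- aggregate_tile(one)
  expect_equal(a1[, "mean"], a1[, "median"])
  expect_equal(unname(a1[, "sd"]), rep(0, 53))
  expect_equal(unname(a1[, "skewness"]), rep(0, 53))

  tri <- matrix(0, 3, 53, dimnames = list(NULL, feature_catalog()))
  tri[, "har_contrast"] <- c(1, 2, 3)
  a3 <- aggregate_tile(tri)
  expect_equal(unname(a3["har_contrast", ]),
               c(2, 2, 1, 0))
  tri[, "har_contrast"] <- c(1, 1, 4)
  a4 <- aggregate_tile(tri)
  expect_equal(a4["har_contrast", "skewness"], sqrt(0.5), tolerance = 1e-6)
})

test_that("patient aggregation yields the 214-vector with correct counts", {
  set.seed(3)
  cells <- matrix(rnorm(5 * 53), 5, dimnames = list(NULL, feature_catalog()))
  st <- aggregate_tile(cells)
  v <- aggregate_patient(rep(list(st), 6), n_blasts = rep(5, 6),
                         n_wbc = rep(20, 6))
  expect_length(v, 214)
  expect_identical(names(v), patient_feature_names())
  # identical tiles: patient values equal the common tile values
  expect_equal(unname(v["har_contrast_mean"]), unname(st["har_contrast", "mean"]))
  expect_equal(unname(v["blast_count"]), 30)
  expect_equal(unname(v["blast_percentage"]), 0.25)
  # missing tiles are excluded from the average
  v2 <- aggregate_patient(c(rep(list(st), 2), list(NULL)),
                          n_blasts = c(5, 5, 0), n_wbc = c(20, 20, 3))
  expect_equal(unname(v2["har_contrast_mean"]), unname(st["har_contrast", "mean"]))
  expect_equal(unname(v2["blast_percentage"]), 10 / 43)
  expect_error(aggregate_patient(list(NULL, NULL), 0, 0), "all tiles missing")
})

test_that("full per-cell extraction returns the catalog for a rendered cell", {
  p <- tiny_params(seed = 5)
  set.seed(5)
  tile <- render_tile(p, h = 1)
  inst <- instances_from_masks(tile$blast_mask, tile$wbc_mask)
  tf <- extract_tile_features(tile$rgb, inst)
  expect_equal(ncol(tf$cells), 53)
  expect_identical(colnames(tf$cells), feature_catalog())
  expect_equal(tf$n_blasts, max(tile$blast_mask))
  expect_equal(tf$n_wbc, max(tile$blast_mask) + max(tile$wbc_mask))
  expect_false(anyNA(tf$cells))
  v <- aggregate_patient(list(tf$stats), tf$n_blasts, tf$n_wbc)
  expect_length(v, 214)
})
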