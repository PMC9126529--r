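test_that("render_tile honors counts, masks and determinism", {
  p <- tiny_params(blasts_per_tile_range = c(2, 2), seed = 1)
  set.seed(1)
  tile <- render_tile(p, h = 1)
  # count forced by parameters
  expect_equal(max(tile$blast_mask), 2)
  expect_equal(length(unique(tile$blast_mask[tile$blast_mask > 0])), 2)
  # masks disjoint, inside the tile, and each label 8-connected
  expect_equal(sum(tile$blast_mask > 0 & tile$wbc_mask > 0), 0)
  for (l in seq_len(max(tile$blast_mask))) {
    cc <- blastprs:::.cc_label(tile$blast_mask == l, 8L)
    expect_equal(max(cc), 1)
  }
  # rendered nuclei agree exactly with the masks (nuclei are darker than
  # the pink background in the blue-excess channel)
  b <- tile$rgb[, , 3] - (tile$rgb[, , 1] + tile$rgb[, , 2]) / 2
  expect_gt(min(b[tile$blast_mask > 0]), max(b[tile$blast_mask == 0 &
                                                 tile$wbc_mask == 0]) - 1e-9)

  # bit-identical under a fixed seed
  set.seed(99); t1 <- render_tile(p, h = 0.5)
  set.seed(99); t2 <- render_tile(p, h = 0.5)
  expect_identical(t1$rgb, t2$rgb)
  expect_identical(t1$blast_mask, t2$blast_mask)

  # h outside the declared range is rejected
  expect_error(render_tile(p, h = 99), "heterogeneity_range")
})

test_that("placement fails cleanly when the tile cannot hold the cells", {
  p <- sim_params(n_patients = 2, tile_px = 64,
                  blasts_per_tile_range = c(12, 12),
                  other_wbc_per_tile_range = c(0, 0), rbc_per_tile = 0)
  set.seed(2)
  expect_error(render_tile(p, h = 1), "placement")
})

test_that("heterogeneity drives across-cell contrast variance in images", {
  p <- tiny_params(blasts_per_tile_range = c(4, 7), seed = 1)
  hs <- seq(0.1, 2.4, length.out = 5)
  set.seed(31)
  mv <- vapply(hs, function(h) {
    mean(replicate(8, {
      tile <- render_tile(p, h)
      tf <- extract_tile_features(
        tile$rgb, instances_from_masks(tile$blast_mask, tile$wbc_mask))
      var(tf$cells[, "har_contrast"])
    }))
  }, numeric(1))
  expect_gt(cor(hs, mv, method = "spearman"), 0.8)
  expect_gt(mv[5], mv[1])
})

test_that("cohort geometry matches the study design", {
  p <- sim_params(n_patients = 92, tiles_per_patient = 6, seed = 4)
  co <- simulate_cohort(p, mode = "features")
  expect_equal(nrow(co$manifest), 552)
  expect_equal(length(unique(co$manifest$patient_id)), 92)
  expect_setequal(colnames(co$manifest),
                  c("patient_id", "split", "tile", "tile_path", "rfs_days",
                    "event", "relapse_1yr", "age", "sex",
                    "comorbidity_index"))
  # outcome invariants
  pt <- co$patients
  expect_true(all(pt$rfs_days > 0))
  expect_true(all(pt$event %in% 0:1))
  expect_true(all(pt$event[pt$relapse_1yr == 1] == 1))
  expect_true(all(pt$rfs_days[pt$relapse_1yr == 1] <= 365))
  expect_true(all(pt$age >= 18 & pt$age <= 80))
  # feature matrix shape and count features
  expect_equal(dim(co$features), c(92, 215))
  expect_true(all(co$features$blast_percentage <= 1))
})

test_that("simulated survival honors the proportional-hazards structure", {
  # null link: no association between h and event
  p0 <- sim_params(n_patients = 500, beta_texture = 0, seed = 8)
  co0 <- simulate_cohort(p0, mode = "features")
  tau <- cor(co0$patients$h, co0$patients$event, method = "kendall")
  expect_lt(abs(tau), 0.1)

  # positive link: empirical hazard ratio (events / person-time) above the
  # h median exceeds that below it
  p1 <- sim_params(n_patients = 1000, beta_texture = 1, seed = 9)
  co1 <- simulate_cohort(p1, mode = "features")
  pt <- co1$patients
  hi <- pt$h > median(pt$h)
  rate_hi <- sum(pt$event[hi]) / sum(pt$rfs_days[hi])
  rate_lo <- sum(pt$event[!hi]) / sum(pt$rfs_days[!hi])
  expect_gt(rate_hi / rate_lo, 1)

  # Monte-Carlo event fraction under the documented example parameters,
  # checked against the closed-form expectation for this censoring model
  p2 <- sim_params(n_patients = 300, beta_texture = 1,
                   baseline_hazard = 1 / 400, censor_horizon = 1500,
                   seed = 10)
  co2 <- simulate_cohort(p2, mode = "features")
  want <- oracle_event_fraction(1, 1 / 400, 1500, p2$heterogeneity_range)
  se <- sqrt(want * (1 - want) / 300)
  expect_gte(mean(co2$patients$event), 0.4)
  expect_lt(abs(mean(co2$patients$event) - want), 4 * se)

  # and under the package defaults the cohort is well inside (0.4, 0.9)
  pd <- sim_params(n_patients = 300, seed = 10)
  cod <- simulate_cohort(pd, mode = "features")
  expect_gte(mean(cod$patients$event), 0.4)
  expect_lte(mean(cod$patients$event), 0.9)
})

test_that("fixed seed reproduces the cohort byte-for-byte", {
  p <- sim_params(n_patients = 6, tiles_per_patient = 2, seed = 77)
  a <- simulate_cohort(p, mode = "features")
  b <- simulate_cohort(p, mode = "features")
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$features, b$features)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_cohort(sim_params(n_patients = 2), mode = "features"),
               NA)
  expect_warning(sim_params(heterogeneity_range = c(1, 1)), "degenerate")
})

test_that("image-mode cohort writes tiles, masks and CSVs that round-trip", {
  out <- tempfile("cohort")
  p <- tiny_params(n_patients = 2, seed = 12)
  co <- simulate_cohort(p, mode = "image", out_dir = out)
  expect_equal(nrow(co$manifest), 4)
  expect_true(all(file.exists(file.path(out, co$manifest$tile_path))))
  man <- read.csv(file.path(out, "manifest.csv"))
  expect_equal(nrow(man), 4)
  expect_true(file.exists(file.path(out, "truth.csv")))
  # PNM round trip preserves pixel content exactly
  key <- sub("\\.ppm$", "", basename(co$manifest$tile_path[1]))
  rgb <- read_ppm(file.path(out, co$manifest$tile_path[1]))
  msk <- read_pgm(file.path(out, "masks", paste0(key, "_blast.pgm")))
  set.seed(p$seed)  # regenerate first patient's first tile
  h1 <- runif(p$n_patients, p$heterogeneity_range[1],
              p$heterogeneity_range[2])[1]
  expect_equal(dim(rgb), c(192, 192, 3))
  expect_true(max(msk) >= p$blasts_per_tile_range[1])
  unlink(out, recursive = TRUE)
})

test_that("PNM writer/reader round-trips 8- and 16-bit data", {
  arr <- array(sample(0:255, 5 * 7 * 3, TRUE), c(5, 7, 3))
  f <- tempfile(fileext = ".ppm")
  write_ppm(arr, f)
  expect_identical(read_ppm(f), arr)
  m <- matrix(sample(0:60000, 35, TRUE), 5, 7)
  f2 <- tempfile(fileext = ".pgm")
  write_pgm(m, f2)
  expect_identical(read_pgm(f2), m)
})
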