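#' Simulate a synthetic aspirate cohort
#'
#' Draws per-patient latent heterogeneity h ~ Uniform(heterogeneity_range),
#' event times T ~ Exponential(baseline_hazard * exp(beta_texture * h)),
#' censoring U ~ Uniform(0, censor_horizon); observed RFS = min(T, U) with
#' event = [T <= U], and the relapse label = event within 365 days.
#' Clinical covariates (age, sex, comorbidity index) are simulated
#' independently of h. Patients are assigned to train/validation splits by
#' seeded random sampling at the patient level.
#'
#' Two modes:
#' \describe{
#'   \item{`"image"`}{renders `tiles_per_patient` tiles per patient with
#'     [render_tile()]; with `out_dir` set, writes tiles (PPM), ground-truth
#'     label masks (16-bit PGM), `manifest.csv` and — kept separate from
#'     pipeline inputs — `truth.csv`.}
#'   \item{`"features"`}{the desk-scale route: skips rendering and draws
#'     per-cell base descriptors directly from the same latent laws the
#'     renderer uses (across-cell contrast variance proportional to h;
#'     correlation from a skewed law whose skewness decreases with h; all
#'     other descriptors uninformative noise), then aggregates them with
#'     the real [aggregate_tile()]/[aggregate_patient()] code into the
#'     214-feature patient matrix.}
#' }
#'
#' @param params a [sim_params()] object.
#' @param mode `"image"` or `"features"`.
#' @param out_dir optional output directory for tiles/masks/CSVs.
#' @return list of class `synthetic_cohort`: `manifest` (one row per
#'   tile), `truth` (patient_id, h, true_event_time), `patients`
#'   (per-patient outcome table), `features` (feature-mode only: patients x
#'   214 matrix as data.frame with patient_id), `tiles` (image mode without
#'   `out_dir`: in-memory tile list), `params`, `out_dir`.
#' @export
simulate_cohort <- function(params, mode = c("image", "features"),
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (params$n_patients < 2) stop("simulate_cohort: n_patients must be >= 2")
  set.seed(params$seed)
  n <- params$n_patients
  rng <- params$heterogeneity_range
  h <- runif(n, rng[1], rng[2])
  rate <- params$baseline_hazard * exp(params$beta_texture * h)
  Tt <- rexp(n, rate)
  U <- runif(n, 0, params$censor_horizon)
  rfs <- pmin(Tt, U)
  event <- as.integer(Tt <= U)
  relapse <- as.integer(event == 1L & Tt <= 365)
  age <- round(rtrunc_norm(n, 55, 10, 18, 80))
  sex <- rbinom(n, 1, 0.5)
  comorb <- rpois(n, 2)
  pid <- sprintf("P%03d", seq_len(n))
  n_train <- max(1, min(n - 1, round(params$train_frac * n)))
  split <- rep("val", n)
  split[sample.int(n, n_train)] <- "train"

  patients <- data.frame(
    patient_id = pid, split = split, h = h, rfs_days = rfs, event = event,
    relapse_1yr = relapse, age = age, sex = sex, comorbidity_index = comorb,
    stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = pid, h = h, true_event_time = Tt,
                      stringsAsFactors = FALSE)

  res <- list(params = params, truth = truth, patients = patients,
              out_dir = out_dir)
  if (mode == "image") {
    res <- c(res, simulate_tiles(params, patients, out_dir))
  } else {
    res <- c(res, simulate_feature_mode(params, patients))
  }
  res$manifest <- merge_manifest(res$tile_table, patients)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
    write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
    if (!is.null(res$features))
      write.csv(res$features, file.path(out_dir, "features.csv"),
                row.names = FALSE)
  }
  class(res) <- "synthetic_cohort"
  res
}

merge_manifest <- function(tile_table, patients) {
  m <- merge(tile_table, patients[, c("patient_id", "split", "rfs_days",
                                      "event", "relapse_1yr", "age", "sex",
                                      "comorbidity_index")],
             by = "patient_id", sort = FALSE)
  m <- m[order(m$patient_id, m$tile), ]
  rownames(m) <- NULL
  m[, c("patient_id", "split", "tile", "tile_path", "rfs_days", "event",
        "relapse_1yr", "age", "sex", "comorbidity_index")]
}

simulate_tiles <- function(params, patients, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "tiles"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE,
               showWarnings = FALSE)
  }
  tiles <- list()
  rows <- list()
  for (i in seq_len(nrow(patients))) {
    for (t in seq_len(params$tiles_per_patient)) {
      tile <- render_tile(params, patients$h[i])
      key <- sprintf("%s_t%d", patients$patient_id[i], t)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path("tiles", paste0(key, ".ppm"))
        write_ppm(tile$rgb, file.path(out_dir, path))
        write_pgm(tile$blast_mask,
                  file.path(out_dir, "masks", paste0(key, "_blast.pgm")))
        write_pgm(tile$wbc_mask,
                  file.path(out_dir, "masks", paste0(key, "_wbc.pgm")))
      } else {
        tiles[[key]] <- tile
      }
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patients$patient_id[i], tile = t, tile_path = path,
        stringsAsFactors = FALSE)
    }
  }
  list(tile_table = do.call(rbind, rows),
       tiles = if (length(tiles)) tiles else NULL)
}

# Feature-mode generator: per-cell descriptor draws sharing the renderer's
# latent laws, pushed through the real aggregation code.
simulate_feature_mode <- function(params, patients) {
  cat_names <- feature_catalog()
  causal <- c("har_contrast", "har_correlation")
  rows <- list()
  feats <- matrix(NA_real_, nrow(patients), 214,
                  dimnames = list(NULL, patient_feature_names()))
  for (i in seq_len(nrow(patients))) {
    h <- patients$h[i]
    tile_stats <- vector("list", params$tiles_per_patient)
    nb <- nw <- integer(params$tiles_per_patient)
    for (t in seq_len(params$tiles_per_patient)) {
      nb[t] <- sample_int_range(params$blasts_per_tile_range)
      nw[t] <- sample_int_range(params$other_wbc_per_tile_range)
      cells <- matrix(rnorm(nb[t] * length(cat_names)), nb[t],
                      dimnames = list(NULL, cat_names))
      # across-cell contrast variance proportional to h
      cells[, "har_contrast"] <- 20 + rnorm(nb[t], 0, sqrt(4 * h))
      # correlation: left-skewed law, |skewness| = 2/sqrt(2+4h) shrinking in h
      sh <- 2 + 4 * h
      cells[, "har_correlation"] <-
        0.6 - stats::rgamma(nb[t], shape = sh, rate = sh / 0.15)
      tile_stats[[t]] <- aggregate_tile(cells)
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = patients$patient_id[i], tile = t,
        tile_path = NA_character_, stringsAsFactors = FALSE)
    }
    feats[i, ] <- aggregate_patient(tile_stats, nb, nb + nw)
  }
  features <- data.frame(patient_id = patients$patient_id,
                         feats, check.names = FALSE,
                         stringsAsFactors = FALSE)
  list(tile_table = do.call(rbind, rows), features = features)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- out < lo | out > hi
  while (any(bad)) {
    out[bad] <- rnorm(sum(bad), mean, sd)
    bad <- out < lo | out > hi
  }
  out
}
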