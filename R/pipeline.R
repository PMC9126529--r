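#' Pipeline run configuration
#'
#' Bundles all module configurations plus seeds and stage toggles. The
#' resolved configuration is snapshotted to `config.json` in the run
#' directory, which is sufficient to reproduce the run bit-for-bit.
#'
#' @param out_dir run directory for artifacts.
#' @param seed master seed; the simulator uses `seed`, the CV fold
#'   assignment `seed + 1000`.
#' @param mode `"image"` (render/segment/extract) or `"features"`
#'   (desk-scale feature-level simulation).
#' @param use_truth_masks skip the segmenter and ingest the ground-truth
#'   masks (the mask-ingest path for external segmenters).
#' @param sim a [sim_params()]; its seed is overridden by `seed`.
#' @param seg a [segmentation_config()].
#' @param n_levels GLCM gray levels.
#' @param n_folds LASSO cross-validation folds.
#' @param stages stages to run, in order, from
#'   simulate/segment/extract/train/evaluate.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("blastprs_run"), seed = 1L,
                       mode = c("image", "features"),
                       use_truth_masks = FALSE,
                       sim = sim_params(n_patients = 60, tile_px = 256,
                                        blasts_per_tile_range = c(3, 6),
                                        other_wbc_per_tile_range = c(4, 8)),
                       seg = segmentation_config(),
                       n_levels = 16, n_folds = 10,
                       stages = c("simulate", "segment", "extract",
                                  "train", "evaluate")) {
  mode <- match.arg(mode)
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), mode = mode,
                 use_truth_masks = use_truth_masks, sim = sim, seg = seg,
                 n_levels = n_levels, n_folds = n_folds,
                 stages = match.arg(stages, several.ok = TRUE),
                 version = as.character(utils::packageVersion("blastprs"))),
            class = "run_config")
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in order
#' simulate -> segment -> extract -> train -> evaluate against the run
#' directory, logging patient/tile/cell counts and exclusions at every
#' stage. Training only ever reads training-split rows. The final report
#' compares the texture-feature PRS against the machine blast-percentage
#' baseline with identical evaluation machinery on identical splits.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the `report`, the report file hash
#'   (`report_hash`, md5 of report.json), and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  log_line <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  cfg_snapshot <- config
  cfg_snapshot$out_dir <- NULL   # paths excluded so reruns hash identically
  jsonlite::write_json(unclass_deep(cfg_snapshot),
                       file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  for (stage in config$stages) {
    log_line("[stage] ", stage)
    switch(stage,
      simulate = stage_simulate(config, log_line),
      segment = stage_segment(config, log_line),
      extract = stage_extract(config, log_line),
      train = stage_train(config, log_line),
      evaluate = stage_evaluate(config, log_line))
  }
  res <- list(out_dir = out)
  rp <- file.path(out, "report.json")
  if (file.exists(rp)) {
    res$report <- jsonlite::read_json(rp, simplifyVector = TRUE)
    res$report_hash <- unname(tools::md5sum(rp))
  }
  invisible(res)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

require_artifact <- function(path, stage_needed) {
  if (!file.exists(path))
    stop("missing artifact '", basename(path),
         "': rerun the '", stage_needed, "' stage first", call. = FALSE)
  path
}

stage_simulate <- function(config, log_line) {
  cohort <- simulate_cohort(config$sim, mode = config$mode,
                            out_dir = config$out_dir)
  log_line("  patients: ", nrow(cohort$patients),
           "; tiles: ", nrow(cohort$manifest),
           "; events: ", sum(cohort$patients$event))
  invisible(cohort)
}

stage_segment <- function(config, log_line) {
  if (config$mode == "features" || config$use_truth_masks) {
    log_line("  skipped (", config$mode, " mode / truth masks)")
    return(invisible(NULL))
  }
  out <- config$out_dir
  manifest <- read.csv(require_artifact(file.path(out, "manifest.csv"),
                                        "simulate"))
  dir.create(file.path(out, "masks_pred"), showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    tile_path <- file.path(out, manifest$tile_path[i])
    require_artifact(tile_path, "simulate")
    rgb <- read_ppm(tile_path)
    seg <- segment_tile(rgb, config$seg)
    key <- sub("\\.ppm$", "", basename(tile_path))
    bl <- class_label_mask(seg, "myeloblast")
    wb <- class_label_mask(seg, "other_wbc")
    write_pgm(bl, file.path(out, "masks_pred", paste0(key, "_blast.pgm")))
    write_pgm(wb, file.path(out, "masks_pred", paste0(key, "_wbc.pgm")))
    truth <- read_pgm(file.path(out, "masks", paste0(key, "_blast.pgm")))
    if (config$seg$metric_class == "nuclei") {
      truth_w <- read_pgm(file.path(out, "masks", paste0(key, "_wbc.pgm")))
      pm <- evaluate_segmentation(bl > 0 | wb > 0, truth > 0 | truth_w > 0)
    } else {
      pm <- evaluate_segmentation(bl > 0, truth > 0)
    }
    rows[[i]] <- data.frame(tile_path = manifest$tile_path[i],
                            tpr = pm$tpr, tnr = pm$tnr, f1 = pm$f1)
  }
  met <- do.call(rbind, rows)
  write.csv(met, file.path(out, "seg_metrics.csv"), row.names = FALSE)
  log_line("  tiles segmented: ", nrow(met),
           "; mean F1: ", round(mean(met$f1), 3))
  invisible(met)
}

# full-tile label image restricted to one class, labels preserved
class_label_mask <- function(seg, class) {
  keep <- which(vapply(seg$cells, function(cc) cc$cell_class == class,
                       logical(1)))
  m <- seg$labels
  m[!(m %in% keep)] <- 0L
  m
}

stage_extract <- function(config, log_line) {
  out <- config$out_dir
  if (config$mode == "features") {
    require_artifact(file.path(out, "features.csv"), "simulate")
    log_line("  features mode: using simulator feature matrix")
    return(invisible(NULL))
  }
  manifest <- read.csv(require_artifact(file.path(out, "manifest.csv"),
                                        "simulate"))
  mask_dir <- if (config$use_truth_masks) "masks" else "masks_pred"
  exclusions <- list()
  feats <- list()
  for (pid in unique(manifest$patient_id)) {
    rows <- manifest[manifest$patient_id == pid, ]
    tile_stats <- list(); nb <- nw <- integer(0)
    for (i in seq_len(nrow(rows))) {
      key <- sub("\\.ppm$", "", basename(rows$tile_path[i]))
      bl <- read_pgm(require_artifact(
        file.path(out, mask_dir, paste0(key, "_blast.pgm")),
        if (config$use_truth_masks) "simulate" else "segment"))
      wb <- read_pgm(file.path(out, mask_dir, paste0(key, "_wbc.pgm")))
      rgb <- read_ppm(file.path(out, rows$tile_path[i]))
      inst <- instances_from_masks(bl, wb)
      tf <- extract_tile_features(rgb, inst, n_levels = config$n_levels)
      if (tf$n_blasts == 0)
        exclusions[[length(exclusions) + 1]] <- data.frame(
          patient_id = pid, tile = rows$tile[i], reason = "no_myeloblasts")
      tile_stats[[i]] <- tf$stats
      nb <- c(nb, tf$n_blasts); nw <- c(nw, tf$n_wbc)
    }
    if (all(vapply(tile_stats, is.null, logical(1)))) {
      exclusions[[length(exclusions) + 1]] <- data.frame(
        patient_id = pid, tile = NA, reason = "all_tiles_missing")
      next
    }
    feats[[pid]] <- c(patient_id = pid,
                      as.list(aggregate_patient(tile_stats, nb, nw)))
  }
  fdf <- do.call(rbind, lapply(feats, function(x)
    data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)))
  write.csv(fdf, file.path(out, "features.csv"), row.names = FALSE)
  exdf <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(patient_id = character(0), tile = integer(0),
               reason = character(0))
  write.csv(exdf, file.path(out, "exclusions.csv"), row.names = FALSE)
  log_line("  patients with features: ", nrow(fdf),
           "; exclusions: ", nrow(exdf))
  invisible(fdf)
}

# Per-patient outcome table from the per-tile manifest
patient_table <- function(manifest) {
  p <- manifest[!duplicated(manifest$patient_id),
                c("patient_id", "split", "rfs_days", "event", "relapse_1yr",
                  "age", "sex", "comorbidity_index")]
  rownames(p) <- NULL
  p
}

read_features <- function(out) {
  f <- read.csv(require_artifact(file.path(out, "features.csv"), "extract"),
                check.names = FALSE)
  f
}

stage_train <- function(config, log_line) {
  out <- config$out_dir
  feats <- read_features(out)
  manifest <- read.csv(require_artifact(file.path(out, "manifest.csv"),
                                        "simulate"))
  pats <- patient_table(manifest)
  df <- merge(feats, pats, by = "patient_id")
  tr <- df[df$split == "train", ]    # training rows only, ever
  X <- as.matrix(tr[, patient_feature_names(), drop = FALSE])
  model <- lasso_cox_select(survival_data(tr$rfs_days, tr$event, X),
                            n_folds = config$n_folds,
                            seed = config$seed + 1000L)
  jsonlite::write_json(
    list(selected = model$selected, beta = as.list(model$beta),
         lambda = model$lambda, threshold = model$threshold,
         center = as.list(model$center), scale = as.list(model$scale)),
    file.path(out, "model.json"), auto_unbox = TRUE, digits = NA)
  log_line("  selected features: ", paste(model$selected, collapse = ", "))
  invisible(model)
}

read_prs_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(selected = m$selected, beta = unlist(m$beta),
                 lambda = m$lambda, threshold = m$threshold,
                 center = unlist(m$center), scale = unlist(m$scale)),
            class = "prs_model")
}

stage_evaluate <- function(config, log_line) {
  out <- config$out_dir
  feats <- read_features(out)
  manifest <- read.csv(require_artifact(file.path(out, "manifest.csv"),
                                        "simulate"))
  model <- read_prs_model(require_artifact(file.path(out, "model.json"),
                                           "train"))
  pats <- patient_table(manifest)
  df <- merge(feats, pats, by = "patient_id")

  texture <- evaluate_feature_set(df, model$selected, "texture_prs")
  baseline <- blast_percentage_baseline(df)

  report <- list(
    version = config$version, seed = config$seed, mode = config$mode,
    n_patients = nrow(df),
    n_train = sum(df$split == "train"), n_val = sum(df$split == "val"),
    selected_features = model$selected,
    lambda = model$lambda,
    methods = list(texture_prs = texture$metrics,
                   blast_percentage = baseline$metrics))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  write.csv(rbind(cbind(method = "texture_prs", texture$km),
                  cbind(method = "blast_percentage", baseline$km)),
            file.path(out, "km_curves.csv"), row.names = FALSE)
  preds <- rbind(cbind(method = "texture_prs", texture$predictions),
                 cbind(method = "blast_percentage", baseline$predictions))
  write.csv(preds, file.path(out, "predictions.csv"), row.names = FALSE)
  write_report_md(report, file.path(out, "report.md"))
  log_line("  report written: texture val AUC = ",
           round(report$methods$texture_prs$val$auc, 3),
           "; baseline val AUC = ",
           round(report$methods$blast_percentage$val$auc, 3))
  invisible(report)
}

#' Evaluate a feature set as a risk model
#'
#' The shared evaluation machinery behind both the texture PRS and the
#' blast-percentage baseline: fit a Cox model on the training split over
#' the given feature columns (standardized on training data) to obtain a
#' PRS, dichotomize both splits at the training-mean PRS, and report per
#' split: the log-rank test, the univariate Cox HR of the PRS (per SD),
#' Harrell's C of the PRS, plus LDA relapse classification metrics
#' (AUC and operating-point accuracy/sensitivity/specificity/precision).
#'
#' @param df merged per-patient data.frame (features + split + outcomes).
#' @param columns feature column names to use.
#' @param label method label used in outputs.
#' @return list: `metrics` (per split), `km` (curve points), `predictions`.
#' @export
evaluate_feature_set <- function(df, columns, label = "method") {
  bad <- !stats::complete.cases(df[, columns, drop = FALSE])
  if (any(bad)) {
    message("excluding ", sum(bad), " patient(s) with missing '",
            paste(columns, collapse = ","), "'")
    df <- df[!bad, ]
  }
  tr <- df[df$split == "train", ]
  ctr <- colMeans(tr[, columns, drop = FALSE])
  scl <- vapply(tr[, columns, drop = FALSE], sd, numeric(1))
  scl[scl == 0] <- 1
  std <- function(d) scale(as.matrix(d[, columns, drop = FALSE]),
                           center = ctr, scale = scl)
  cox_tr <- fit_cox(survival_data(tr$rfs_days, tr$event, std(tr)))
  prs_all <- as.vector(std(df) %*% cox_tr$beta)
  thr <- mean(prs_all[df$split == "train"])
  groups <- dichotomize(prs_all, thr)

  lda <- fit_lda(std(tr), tr$relapse_1yr)
  scores <- predict_lda(lda, std(df))

  metrics <- list(); km <- list()
  for (sp in c("train", "val")) {
    sel <- df$split == sp
    m <- list()
    roc <- roc_curve(scores[sel], df$relapse_1yr[sel])
    m$auc <- roc$auc
    m <- c(m, as.list(roc$oop_metrics))
    cx <- fit_cox(survival_data(df$rfs_days[sel], df$event[sel],
                                matrix(prs_all[sel],
                                       dimnames = list(NULL, "prs"))))
    m$hr <- unname(cx$hr); m$ci_lower <- unname(cx$ci_lower)
    m$ci_upper <- unname(cx$ci_upper); m$cox_p <- unname(cx$wald_p)
    m$cindex <- harrell_c(prs_all[sel], df$rfs_days[sel], df$event[sel])
    g <- droplevels(groups[sel])
    if (nlevels(g) == 2) {
      lr <- km_logrank(df$rfs_days[sel], df$event[sel], g)
      m$logrank_p <- lr$p
      km[[sp]] <- cbind(split = sp, lr$curves)
    } else m$logrank_p <- NA_real_
    metrics[[sp]] <- m
  }
  list(metrics = metrics,
       km = if (length(km)) do.call(rbind, km) else NULL,
       predictions = data.frame(patient_id = df$patient_id,
                                split = df$split, prs = prs_all,
                                risk_group = as.character(groups),
                                lda_score = scores,
                                stringsAsFactors = FALSE))
}

#' Machine blast-percentage baseline
#'
#' Evaluates the single machine-counted feature — segmented myeloblasts
#' per patient normalized by the patient's total WBC count — through the
#' identical machinery as the texture PRS. Patients with missing
#' percentage (zero WBCs) are excluded with a log message.
#'
#' @param df merged per-patient data.frame (must contain
#'   `blast_percentage`).
#' @return as [evaluate_feature_set()].
#' @export
blast_percentage_baseline <- function(df) {
  evaluate_feature_set(df, "blast_percentage", "blast_percentage")
}

write_report_md <- function(report, path) {
  fm <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 3,
                                                   format = "g"))
  lines <- c(
    "# Pipeline comparison report", "",
    sprintf("- patients: %d (train %d / val %d)", report$n_patients,
            report$n_train, report$n_val),
    sprintf("- selected features: %s",
            paste(report$selected_features, collapse = ", ")), "",
    "| method | split | AUC | accuracy | sensitivity | precision | HR | C-index | log-rank p |",
    "|---|---|---|---|---|---|---|---|---|")
  for (meth in names(report$methods))
    for (sp in c("train", "val")) {
      m <- report$methods[[meth]][[sp]]
      lines <- c(lines, sprintf(
        "| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
        meth, sp, fm(m$auc), fm(m$accuracy), fm(m$sensitivity),
        fm(m$precision), fm(m$hr), fm(m$cindex), fm(m$logrank_p)))
    }
  writeLines(lines, path)
}
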