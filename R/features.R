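#' Per-cell base descriptors
#'
#' Computes the 53-descriptor catalog for one segmented cell: Haralick
#' texture on the 4-direction symmetric GLCM of the Rec.601 luma inside the
#' nucleus mask, first-order intensity statistics, and shape descriptors of
#' the mask.
#'
#' @param gray numeric intensity matrix (tile or patch).
#' @param mask logical matrix selecting the cell's pixels.
#' @param n_levels GLCM gray levels.
#' @return named numeric vector of length 53, ordered per
#'   [feature_catalog()].
#' @export
cell_base_features <- function(gray, mask, n_levels = 16) {
  g <- compute_glcm(gray, mask, n_levels = n_levels)
  out <- c(haralick_features(g), first_order_features(gray, mask),
           shape_features(mask))
  out[feature_catalog()]
}

#' Tile-level statistics across myeloblasts
#'
#' Summarizes each base descriptor across the myeloblasts of one tile with
#' four statistics: mean, median, sample standard deviation (n - 1
#' denominator; 0 when a single cell) and Fisher-Pearson skewness
#' g1 = m3 / m2^(3/2) on population moments (0 when fewer than three cells
#' or when m2 = 0).
#'
#' @param cells numeric matrix, one row per myeloblast, 53 catalog columns.
#' @return 53 x 4 matrix (rows = descriptors, columns = mean, median, sd,
#'   skewness).
#' @export
aggregate_tile <- function(cells) {
  if (is.null(dim(cells))) cells <- matrix(cells, nrow = 1,
                                           dimnames = list(NULL, names(cells)))
  if (nrow(cells) < 1) stop("aggregate_tile: no myeloblasts")
  cells <- cells[, feature_catalog(), drop = FALSE]
  n <- nrow(cells)
  mu <- colMeans(cells)
  if (n > 1) {
    ctr <- sweep(cells, 2, mu)
    m2 <- colMeans(ctr^2)
    sdv <- sqrt(colSums(ctr^2) / (n - 1))
    skew <- if (n >= 3)
      ifelse(m2 > 0, colMeans(ctr^3) / m2^1.5, 0) else rep(0, ncol(cells))
    # column-wise sort in one shot, then read the median rows
    srt <- matrix(cells[order(col(cells), cells)], n)
    med <- if (n %% 2) srt[(n + 1) / 2, ] else
      (srt[n / 2, ] + srt[n / 2 + 1, ]) / 2
  } else {
    sdv <- skew <- rep(0, ncol(cells))
    med <- mu
  }
  out <- cbind(mean = mu, median = med, sd = sdv, skewness = skew)
  rownames(out) <- feature_catalog()
  out
}

#' Patient-level feature vector
#'
#' Averages each tile statistic over the patient's non-missing tiles (tiles
#' with zero myeloblasts are excluded upstream) and appends the two count
#' features: total blast count and blast percentage (total blasts / total
#' WBCs). This yields the 214-element patient vector; the two headline
#' texture features read as the across-tile averages of the per-tile
#' contrast standard deviation and correlation skewness.
#'
#' @param tile_stats list of 53 x 4 matrices from [aggregate_tile()].
#' @param n_blasts,n_wbc integer vectors, per tile counts of myeloblasts
#'   and of all WBCs (blasts + other leukocytes).
#' @return named numeric vector of length 214.
#' @export
aggregate_patient <- function(tile_stats, n_blasts, n_wbc) {
  ok <- !vapply(tile_stats, is.null, logical(1))
  if (!any(ok)) stop("aggregate_patient: all tiles missing")
  stats_mean <- Reduce(`+`, tile_stats[ok]) / sum(ok)
  blast_total <- sum(n_blasts)
  wbc_total <- sum(n_wbc)
  vec <- c(as.vector(t(stats_mean)),
           blast_total,
           if (wbc_total > 0) blast_total / wbc_total else NA_real_)
  stats::setNames(vec, patient_feature_names())
}

#' Extract per-tile features from an image and its cell instances
#'
#' @param rgb H x W x 3 tile.
#' @param instances result of [segment_tile()] (or built from truth masks
#'   via [instances_from_masks()]).
#' @param n_levels GLCM gray levels.
#' @return list with `cells` (matrix of per-myeloblast base descriptors),
#'   `stats` (53 x 4 tile statistics or NULL when the tile holds no
#'   myeloblast), `n_blasts`, `n_wbc`.
#' @export
extract_tile_features <- function(rgb, instances, n_levels = 16) {
  gray <- rgb_to_gray(rgb)
  classes <- vapply(instances$cells, function(cc) cc$cell_class, character(1))
  blasts <- instances$cells[classes == "myeloblast"]
  n_b <- length(blasts)
  n_w <- length(instances$cells)
  if (n_b == 0)
    return(list(cells = NULL, stats = NULL, n_blasts = 0L, n_wbc = n_w))
  rows <- lapply(blasts, function(cc) {
    sub <- cc$bbox
    patch_g <- gray[sub[1]:sub[2], sub[3]:sub[4], drop = FALSE]
    cell_base_features(patch_g, cc$mask, n_levels = n_levels)
  })
  cells <- do.call(rbind, rows)
  list(cells = cells, stats = aggregate_tile(cells),
       n_blasts = n_b, n_wbc = n_w)
}
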