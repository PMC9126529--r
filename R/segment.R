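#' Segmentation configuration
#'
#' Parameters of the classical nucleus segmenter. Defaults are tuned for
#' the synthetic renderer's cell geometry (blast semi-axes 14-22 px,
#' other-WBC lobes 5-8 px) and work unchanged at any tile size.
#'
#' @param min_area,max_area component area bounds in px^2.
#' @param blast_min_area minimum area for the myeloblast class.
#' @param min_solidity minimum area / convex-hull-area.
#' @param blast_min_circularity minimum 4 pi A / P^2 for the myeloblast
#'   class.
#' @param opening_radius disc radius (px) of the morphological opening.
#' @param peak_min_distance minimum separation (px) of watershed seeds.
#' @param metric_class which truth class pixel metrics refer to by default:
#'   "blast" (myeloblast pixels only) or "nuclei" (all WBC nuclei).
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(min_area = 60, max_area = 2500,
                                blast_min_area = 500, min_solidity = 0.8,
                                blast_min_circularity = 0.7,
                                opening_radius = 2, peak_min_distance = 16,
                                metric_class = c("blast", "nuclei")) {
  stopifnot(min_area > 0, min_area < blast_min_area,
            blast_min_area <= max_area,
            min_solidity > 0, min_solidity <= 1,
            blast_min_circularity > 0, blast_min_circularity <= 1)
  structure(list(min_area = min_area, max_area = max_area,
                 blast_min_area = blast_min_area,
                 min_solidity = min_solidity,
                 blast_min_circularity = blast_min_circularity,
                 opening_radius = opening_radius,
                 peak_min_distance = peak_min_distance,
                 metric_class = match.arg(metric_class)),
            class = "segmentation_config")
}

# Otsu's threshold on a numeric vector (256-bin histogram). Returns Inf for
# constant input so that `x > thr` selects nothing.
otsu_threshold <- function(v, nbins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(Inf)
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * nbins),
                     nbins - 1) + 1L, nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mut <- mu[nbins]
  sigma2 <- (mut * omega - mu)^2 / (omega * (1 - omega))
  sigma2[!is.finite(sigma2)] <- 0
  k <- which.max(sigma2)
  rng[1] + k / nbins * diff(rng)
}

#' Segment WBC nuclei on an RGB tile
#'
#' Classical stand-in for a learned segmenter: (1) blue-excess channel
#' b = B - (R + G)/2 isolates the purple nuclei from the pink background
#' and red cells; (2) global Otsu threshold on b; (3) morphological opening
#' and hole filling; (4) chamfer-distance watershed seeded at suppressed
#' local maxima to split touching nuclei; (5) area/solidity filtering;
#' (6) classification as myeloblast (large, round) versus other WBC by
#' area and circularity. Labels are assigned in raster order of component
#' centroids. Components touching the tile border are kept.
#'
#' @param rgb H x W x 3 array, 8-bit values.
#' @param config a [segmentation_config()].
#' @return list of class `segmentation`: `labels` (H x W integer label
#'   image) and `cells`, a list of instances each holding `label`,
#'   `cell_class`, `area_px`, `bbox` (y1, y2, x1, x2), `centroid`,
#'   `circularity`, `solidity` and `mask` (logical patch over the bbox).
#' @export
segment_tile <- function(rgb, config = segmentation_config()) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("segment_tile: input must be an H x W x 3 RGB array")
  b <- rgb[, , 3] - (rgb[, , 1] + rgb[, , 2]) / 2
  thr <- otsu_threshold(as.vector(b))
  fg <- b > thr
  if (!any(fg)) return(empty_segmentation(dim(b)))
  fg <- binary_open(fg, config$opening_radius)
  fg <- .fill_holes(fg)
  if (!any(fg)) return(empty_segmentation(dim(b)))

  dist <- .chamfer_dist(fg)
  peaks <- .find_peaks(dist, fg, config$peak_min_distance)
  seeds <- matrix(0L, nrow(fg), ncol(fg))
  seeds[peaks] <- seq_len(nrow(peaks))
  labels <- .watershed_seeded(dist, seeds, fg)

  cells <- list()
  for (l in seq_len(nrow(peaks))) {
    sel <- labels == l
    area <- sum(sel)
    if (area < config$min_area || area > config$max_area) next
    pts <- which(sel, arr.ind = TRUE)
    y1 <- min(pts[, 1]); y2 <- max(pts[, 1])
    x1 <- min(pts[, 2]); x2 <- max(pts[, 2])
    patch <- sel[y1:y2, x1:x2, drop = FALSE]
    geom <- tryCatch({
      ct <- mask_contour(patch)
      hull <- ct[rev(grDevices::chull(ct[, 2], ct[, 1])), , drop = FALSE]
      perim <- poly_perimeter(ct)
      list(solidity = area / poly_area(hull),
           circularity = 4 * pi * area / perim^2)
    }, error = function(e) list(solidity = 0, circularity = 0))
    if (geom$solidity < config$min_solidity) next
    cls <- if (area >= config$blast_min_area &&
               geom$circularity >= config$blast_min_circularity)
      "myeloblast" else "other_wbc"
    cells[[length(cells) + 1]] <- list(
      label = l, cell_class = cls, area_px = area,
      bbox = c(y1, y2, x1, x2),
      centroid = c(mean(pts[, 1]), mean(pts[, 2])),
      circularity = geom$circularity, solidity = geom$solidity,
      mask = patch)
  }
  relabel_raster(cells, dim(b), labels)
}

empty_segmentation <- function(dm) {
  structure(list(labels = matrix(0L, dm[1], dm[2]), cells = list()),
            class = "segmentation")
}

# Renumber surviving instances 1..K in raster order of their centroids and
# rebuild the label image accordingly.
relabel_raster <- function(cells, dm, old_labels) {
  if (!length(cells)) return(empty_segmentation(dm))
  cy <- vapply(cells, function(cc) cc$centroid[1], numeric(1))
  cx <- vapply(cells, function(cc) cc$centroid[2], numeric(1))
  ord <- order(round(cy), round(cx))
  cells <- cells[ord]
  labels <- matrix(0L, dm[1], dm[2])
  for (k in seq_along(cells)) {
    cc <- cells[[k]]
    sub <- labels[cc$bbox[1]:cc$bbox[2], cc$bbox[3]:cc$bbox[4], drop = FALSE]
    sub[cc$mask] <- k
    labels[cc$bbox[1]:cc$bbox[2], cc$bbox[3]:cc$bbox[4]] <- sub
    cells[[k]]$label <- k
  }
  structure(list(labels = labels, cells = cells), class = "segmentation")
}

#' Build cell instances from ground-truth label masks
#'
#' The mask-ingest path: accepts externally produced label masks (for
#' instance the simulator's ground truth) and emits the same instance
#' structure as [segment_tile()], so any learned segmenter can be slotted
#' in upstream.
#'
#' @param blast_mask,wbc_mask integer label matrices (0 = background).
#' @return a `segmentation` object.
#' @export
instances_from_masks <- function(blast_mask, wbc_mask = NULL) {
  dm <- dim(blast_mask)
  cells <- list()
  add <- function(cells, lab_img, cls) {
    for (l in sort(unique(lab_img[lab_img > 0]))) {
      sel <- lab_img == l
      pts <- which(sel, arr.ind = TRUE)
      y1 <- min(pts[, 1]); y2 <- max(pts[, 1])
      x1 <- min(pts[, 2]); x2 <- max(pts[, 2])
      cells[[length(cells) + 1]] <- list(
        label = NA_integer_, cell_class = cls, area_px = nrow(pts),
        bbox = c(y1, y2, x1, x2),
        centroid = c(mean(pts[, 1]), mean(pts[, 2])),
        circularity = NA_real_, solidity = NA_real_,
        mask = sel[y1:y2, x1:x2, drop = FALSE])
    }
    cells
  }
  cells <- add(cells, blast_mask, "myeloblast")
  if (!is.null(wbc_mask)) cells <- add(cells, wbc_mask, "other_wbc")
  relabel_raster(cells, dm, NULL)
}

#' Per-pixel segmentation metrics
#'
#' True-positive rate TP/(TP+FN), true-negative rate TN/(TN+FP) and
#' F1 = 2TP/(2TP+FP+FN) between a predicted and a ground-truth binary
#' mask. A rate whose truth class is absent (empty denominator) is defined
#' as 1.
#'
#' @param pred,truth logical matrices of equal shape.
#' @return list of class `pixel_metrics`: tpr, tnr, f1, n_pixels.
#' @export
evaluate_segmentation <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("evaluate_segmentation: shape mismatch")
  pred <- pred > 0; truth <- truth > 0
  tp <- sum(pred & truth); fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth); fp <- sum(pred & !truth)
  structure(list(
    tpr = if (tp + fn == 0) 1 else tp / (tp + fn),
    tnr = if (tn + fp == 0) 1 else tn / (tn + fp),
    f1 = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    n_pixels = length(pred)), class = "pixel_metrics")
}

#' Binary mask of one class from a segmentation
#' @param seg a `segmentation` object.
#' @param class cell class to select.
#' @return logical matrix.
#' @export
segmentation_class_mask <- function(seg, class = "myeloblast") {
  keep <- vapply(seg$cells, function(cc) cc$cell_class == class, logical(1))
  m <- matrix(FALSE, nrow(seg$labels), ncol(seg$labels))
  if (any(keep))
    m <- matrix(seg$labels %in% which(keep), nrow(seg$labels))
  m
}
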