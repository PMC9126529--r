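#' Shape descriptors of a segmented cell mask
#'
#' Computes 32 shape descriptors of a single connected binary mask:
#' 10 morphometrics, 7 Hu invariant moments (signed log-magnitude scale),
#' 10 elliptic Fourier harmonic magnitudes (scale-normalized by harmonic 1),
#' and 5 irregularity measures. The cell outline is the 0.5-level
#' marching-squares contour of the mask, so perimeter-type quantities refer
#' to that sub-pixel polygon. Axis lengths follow the image-moments
#' convention (length = 4 sqrt(eigenvalue of the pixel covariance)), which
#' recovers the true axes of filled ellipses.
#'
#' @param mask logical matrix containing one 8-connected component.
#' @return named numeric vector of length 32.
#' @export
shape_features <- function(mask) {
  stopifnot(is.matrix(mask))
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 8) stop("shape_features: degenerate mask (fewer than 8 pixels)")
  contour <- mask_contour(mask)
  if (nrow(contour) < 8)
    stop("shape_features: degenerate mask (contour under 8 vertices)")

  area <- nrow(pts)
  # staircase-corrected outline: resampled + circularly smoothed contour;
  # all perimeter-type quantities are measured on this polygon
  sct <- smooth_closed(contour)
  perim <- poly_perimeter(sct)
  ys <- pts[, 1]; xs <- pts[, 2]
  cy <- mean(ys); cx <- mean(xs)
  # pixel covariance (population) + 1/12 point-spread correction as in
  # moment-based axis estimation of rasterized shapes
  cyy <- central_moment(ys, 2) + 1 / 12
  cxx <- central_moment(xs, 2) + 1 / 12
  cxy <- mean((ys - cy) * (xs - cx))
  ev <- eigen(matrix(c(cyy, cxy, cxy, cxx), 2, 2), symmetric = TRUE)$values
  l1 <- max(ev[1], 0); l2 <- max(ev[2], 0)
  if (l2 <= 1 / 12 + 1e-6)
    stop("shape_features: degenerate mask (zero minor axis)")
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  hull <- sct[rev(grDevices::chull(sct[, 2], sct[, 1])), , drop = FALSE]
  hull_area <- poly_area(hull)
  hull_perim <- poly_perimeter(hull)
  bbox_area <- (max(ys) - min(ys) + 1) * (max(xs) - min(xs) + 1)

  morpho <- stats::setNames(
    c(area, perim, sqrt(4 * area / pi),
      sqrt(1 - l2 / l1), major, minor, major / minor,
      area / hull_area, area / bbox_area,
      4 * pi * area / perim^2),
    morpho_names())

  hu <- hu_moments(ys, xs)
  efd <- efd_magnitudes(sct, n_harm = 10)
  irr <- irregularity_features(mask, sct, perim, hull_perim)
  c(morpho, hu, efd, irr)
}

morpho_names <- function() {
  paste0("mo_", c("area", "perimeter", "equiv_diameter", "eccentricity",
                  "major_axis", "minor_axis", "aspect_ratio", "solidity",
                  "extent", "circularity"))
}

# --- contour extraction ------------------------------------------------

# Ordered closed outline of a binary mask: marching-squares isoline at 0.5
# of the zero-padded mask, oriented counter-clockwise (positive signed
# area), columns (row, col) in original pixel coordinates.
mask_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  z <- matrix(0, nr + 2, nc + 2)
  z[2:(nr + 1), 2:(nc + 1)] <- mask * 1
  cl <- grDevices::contourLines(x = seq_len(nr + 2), y = seq_len(nc + 2),
                                z = z, levels = 0.5)
  if (!length(cl)) stop("mask_contour: no contour found")
  lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
  cc <- cl[[which.max(lens)]]
  p <- cbind(cc$x - 1, cc$y - 1)          # (row, col), un-pad
  if (all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  if (poly_signed_area(p) < 0) p <- p[nrow(p):1, , drop = FALSE]
  p
}

poly_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

poly_area <- function(p) abs(poly_signed_area(p))

# Resample a closed polygon and apply a circular moving average: removes
# the marching-squares staircase so perimeter-type measures approach the
# continuous outline (a digital disc then scores circularity ~1).
smooth_closed <- function(p, w = 5) {
  n <- min(512L, max(64L, nrow(p)))
  q <- resample_closed(p, n)
  half <- (w - 1L) %/% 2L
  out <- q * 0
  for (k in -half:half)
    out <- out + q[(seq_len(n) + k - 1L) %% n + 1L, , drop = FALSE]
  out / w
}

poly_perimeter <- function(p) {
  xn <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((xn - p)^2)))
}

# Resample a closed polygon to n points equally spaced in arc length.
resample_closed <- function(p, n) {
  # drop consecutive duplicate vertices
  if (nrow(p) > 1) {
    d <- sqrt(rowSums((p - p[c(nrow(p), 1:(nrow(p) - 1)), , drop = FALSE])^2))
    d[1] <- 1  # always keep the first vertex
    p <- p[d > 1e-12, , drop = FALSE]
  }
  q <- rbind(p, p[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(q)^2))
  t <- c(0, cumsum(seg))
  tt <- seq(0, t[length(t)], length.out = n + 1)[-(n + 1)]
  cbind(stats::approx(t, q[, 1], tt)$y, stats::approx(t, q[, 2], tt)$y)
}

# --- Hu invariant moments ----------------------------------------------

# Seven Hu moment invariants of the pixel set, reported on the signed
# log10-magnitude scale h' = -sign(h) log10|h| (0 stays 0).
hu_moments <- function(ys, xs) {
  n <- length(ys)
  x <- xs - mean(xs); y <- ys - mean(ys)
  mu <- function(p, q) sum(x^p * y^q)
  m00 <- n
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    (n30 + n12)^2 + (n21 + n03)^2,
    (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2))
  out <- ifelse(abs(h) < 1e-300, 0, -sign(h) * log10(abs(h)))
  stats::setNames(out, paste0("hu_", 1:7))
}

# --- elliptic Fourier descriptors --------------------------------------

# Kuhl-Giardina elliptic Fourier coefficients of the closed contour;
# returns per-harmonic magnitudes sqrt(a^2+b^2+c^2+d^2) divided by the
# harmonic-1 magnitude (scale invariance; harmonic 1 is identically 1).
efd_magnitudes <- function(contour, n_harm = 10) {
  q <- rbind(contour, contour[1, , drop = FALSE])
  d <- diff(q)
  seg <- sqrt(rowSums(d^2))
  keep <- seg > 1e-12
  d <- d[keep, , drop = FALSE]; seg <- seg[keep]
  t <- c(0, cumsum(seg)); T <- t[length(t)]
  phi1 <- 2 * pi * t[-length(t)] / T
  phi2 <- 2 * pi * t[-1] / T
  mags <- numeric(n_harm)
  for (n in seq_len(n_harm)) {
    const <- T / (2 * n^2 * pi^2)
    dcos <- (cos(n * phi2) - cos(n * phi1)) / seg
    dsin <- (sin(n * phi2) - sin(n * phi1)) / seg
    a <- const * sum(d[, 2] * dcos)   # x = col
    b <- const * sum(d[, 2] * dsin)
    cc <- const * sum(d[, 1] * dcos)  # y = row
    dd <- const * sum(d[, 1] * dsin)
    mags[n] <- sqrt(a^2 + b^2 + cc^2 + dd^2)
  }
  if (mags[1] <= 0) stop("shape_features: degenerate contour (no harmonic 1)")
  stats::setNames(mags / mags[1], paste0("efd_", seq_len(n_harm)))
}

# --- irregularity ------------------------------------------------------

irregularity_features <- function(mask, contour, perim, hull_perim) {
  # boundary pixels: mask pixels with a 4-neighbour outside the mask
  er <- shift_mat(mask, 1, 0, FALSE) & shift_mat(mask, -1, 0, FALSE) &
    shift_mat(mask, 0, 1, FALSE) & shift_mat(mask, 0, -1, FALSE)
  bd <- which(mask & !er, arr.ind = TRUE)
  fractal <- boxcount_dimension(bd)

  cy <- mean(which(mask, arr.ind = TRUE)[, 1])
  cx <- mean(which(mask, arr.ind = TRUE)[, 2])
  r <- sqrt((contour[, 1] - cy)^2 + (contour[, 2] - cx)^2)
  radial_var <- central_moment(r, 2) / mean(r)^2

  rs <- resample_closed(contour, 128)
  # light circular smoothing before differencing
  sm <- function(v) {
    out <- v
    for (k in c(-2, -1, 1, 2)) out <- out + v[(seq_along(v) + k - 1) %% length(v) + 1]
    out / 5
  }
  x <- sm(rs[, 2]); y <- sm(rs[, 1])
  del <- poly_perimeter(rs) / nrow(rs)
  ip <- c(2:nrow(rs), 1); im <- c(nrow(rs), 1:(nrow(rs) - 1))
  x1 <- (x[ip] - x[im]) / (2 * del); y1 <- (y[ip] - y[im]) / (2 * del)
  x2 <- (x[ip] - 2 * x + x[im]) / del^2; y2 <- (y[ip] - 2 * y + y[im]) / del^2
  denom <- (x1^2 + y1^2)^1.5
  kappa <- ifelse(denom > 1e-12, (x1 * y2 - y1 * x2) / denom, 0)
  if (mean(kappa) < 0) kappa <- -kappa    # orient so convex curvature > 0
  bending <- mean(kappa^2)

  thr <- 0.2 / mean(r)
  conc <- kappa < -thr
  runs <- sum(conc & !conc[c(length(conc), 1:(length(conc) - 1))])
  stats::setNames(
    c(fractal, radial_var, bending, runs / perim, hull_perim / perim),
    paste0("ir_", c("fractal_dim", "radial_var", "bending_energy",
                    "concavity_rate", "convex_perim_ratio")))
}

# Box-counting dimension of the boundary pixel set.
boxcount_dimension <- function(bd) {
  if (nrow(bd) < 4) return(1)
  ext <- max(max(bd[, 1]) - min(bd[, 1]), max(bd[, 2]) - min(bd[, 2])) + 1
  sizes <- 2^(0:4)
  sizes <- sizes[sizes <= max(2, ext / 2)]
  if (length(sizes) < 2) sizes <- c(1, 2)
  counts <- vapply(sizes, function(s) {
    bx <- floor((bd[, 1] - min(bd[, 1])) / s)
    by <- floor((bd[, 2] - min(bd[, 2])) / s)
    length(unique(bx * 1e6 + by))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(sizes))
  -unname(coef(fit)[2])
}
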