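#' Gray-level co-occurrence matrix within a mask
#'
#' Quantizes the masked intensities to `n_levels` equal-width bins over the
#' masked min-max range (a constant region maps entirely to level 1) and
#' accumulates co-occurring level pairs over the given pixel offsets. A pair
#' contributes only when both pixels lie inside the mask. With
#' `symmetric = TRUE` each pair is counted in both orders. Counts are pooled
#' over all offsets before normalization, Haralick's canonical
#' direction-averaged configuration.
#'
#' @param gray numeric matrix of intensities.
#' @param mask logical matrix, same shape; must contain at least one pixel.
#' @param n_levels number of gray levels Ng (>= 2).
#' @param offsets list of integer `c(dy, dx)` displacement vectors; default
#'   the four distance-1 directions (0, 45, 90, 135 degrees).
#' @param symmetric count each pair in both orders.
#' @return object of class `glcm`: list with `p` (Ng x Ng probability
#'   matrix), `n_levels`, `offsets`, `symmetric`, and `degenerate` (TRUE
#'   when no valid pixel pair exists, in which case `p` is all zero).
#' @export
compute_glcm <- function(gray, mask, n_levels = 16,
                         offsets = list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1)),
                         symmetric = TRUE) {
  stopifnot(is.matrix(gray), identical(dim(gray), dim(mask)))
  if (!any(mask)) stop("compute_glcm: empty mask")
  if (n_levels < 2) stop("compute_glcm: n_levels must be >= 2")
  v <- gray[mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(0L, nrow(gray), ncol(gray))
  if (hi > lo)
    q[mask] <- pmin(as.integer(floor((v - lo) / (hi - lo) * n_levels)),
                    n_levels - 1L)
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(gray); nc <- ncol(gray)
  for (off in offsets) {
    dy <- off[1]; dx <- off[2]
    ys <- max(1, 1 - dy):min(nr, nr - dy)
    xs <- max(1, 1 - dx):min(nc, nc - dx)
    if (!length(ys) || !length(xs)) next
    m1 <- mask[ys, xs, drop = FALSE]
    m2 <- mask[ys + dy, xs + dx, drop = FALSE]
    sel <- m1 & m2
    if (!any(sel)) next
    a <- q[ys, xs, drop = FALSE][sel]
    b <- q[ys + dy, xs + dx, drop = FALSE][sel]
    tab <- tabulate(a * n_levels + b + 1L, nbins = n_levels * n_levels)
    counts <- counts + matrix(tab, n_levels, n_levels, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  degenerate <- tot == 0
  p <- if (degenerate) counts else counts / tot
  structure(list(p = p, n_levels = n_levels, offsets = offsets,
                 symmetric = symmetric, degenerate = degenerate),
            class = "glcm")
}

#' Haralick texture descriptors of a GLCM
#'
#' Computes Haralick's 13 descriptors from a normalized co-occurrence
#' matrix. Level indices run 1..Ng; logarithms are base 2 with
#' 0 log 0 := 0. Correlation is defined as 0 when either marginal standard
#' deviation vanishes. A degenerate GLCM (no valid pairs) yields an
#' all-zero vector carrying attribute `degenerate = TRUE`.
#'
#' @param glcm a [compute_glcm()] result (or a bare probability matrix).
#' @return named numeric vector of length 13.
#' @export
haralick_features <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$p else glcm
  nm <- haralick_names()
  degenerate <- if (inherits(glcm, "glcm")) glcm$degenerate else sum(p) == 0
  if (degenerate) {
    out <- stats::setNames(numeric(13), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ng <- nrow(p)
  i <- matrix(seq_len(ng), ng, ng)        # row index
  j <- t(i)                               # col index
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sdx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(ng) - muy)^2 * py))

  contrast <- sum((i - j)^2 * p)
  correlation <- if (sdx > 0 && sdy > 0)
    (sum(i * j * p) - mux * muy) / (sdx * sdy) else 0
  energy <- sum(p^2)
  variance <- sum((i - mux)^2 * p)        # sum of squares about mu_x
  homogeneity <- sum(p / (1 + (i - j)^2))

  # p_{x+y}(k), k = 2..2Ng and p_{x-y}(k), k = 0..Ng-1
  psum <- tapply(as.vector(p), as.vector(i + j), sum)
  ks <- as.numeric(names(psum))
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlog2(psum))

  pdiff <- tapply(as.vector(p), as.vector(abs(i - j)), sum)
  kd <- as.numeric(names(pdiff))
  mud <- sum(kd * pdiff)
  diff_variance <- sum((kd - mud)^2 * pdiff)
  diff_entropy <- -sum(xlog2(pdiff))

  entropy <- -sum(xlog2(p))
  hx <- -sum(xlog2(px)); hy <- -sum(xlog2(py))
  # joint entropies against the product measure
  pxy <- outer(px, py)
  hxy1 <- -sum(p * ifelse(pxy > 0, log2(pxy), 0))
  hxy2 <- -sum(xlog2(pxy))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  out <- c(contrast, correlation, energy, variance, homogeneity,
           sum_average, sum_variance, sum_entropy, entropy,
           diff_variance, diff_entropy, imc1, imc2)
  stats::setNames(out, nm)
}

haralick_names <- function() {
  paste0("har_", c("contrast", "correlation", "energy", "variance",
                   "homogeneity", "sum_average", "sum_variance",
                   "sum_entropy", "entropy", "diff_variance",
                   "diff_entropy", "imc1", "imc2"))
}
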