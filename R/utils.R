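#' @useDynLib blastprs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp rbinom rpois sd median quantile
#'   coef pchisq var dist lm
#' @importFrom grDevices contourLines chull
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 0*log2(0) := 0, used throughout the texture entropies
xlog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}

# Shift a matrix by (dy, dx), padding with `fill`.
shift_mat <- function(m, dy, dx, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sy <- max(1, 1 + dy):min(nr, nr + dy)
  sx <- max(1, 1 + dx):min(nc, nc + dx)
  out[sy, sx] <- m[sy - dy, sx - dx]
  out
}

# Integer offsets of a disc of radius r (includes the origin).
disc_offsets <- function(r) {
  s <- -r:r
  g <- expand.grid(dy = s, dx = s)
  g[g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

binary_dilate <- function(fg, r) {
  off <- disc_offsets(r)
  out <- matrix(FALSE, nrow(fg), ncol(fg))
  for (k in seq_len(nrow(off)))
    out <- out | shift_mat(fg, off$dy[k], off$dx[k], FALSE)
  out
}

binary_erode <- function(fg, r) {
  off <- disc_offsets(r)
  out <- matrix(TRUE, nrow(fg), ncol(fg))
  for (k in seq_len(nrow(off)))
    out <- out & shift_mat(fg, off$dy[k], off$dx[k], TRUE)
  out
}

binary_open <- function(fg, r) binary_dilate(binary_erode(fg, r), r)

# Separable Gaussian blur with edge replication.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(x) {       # columns of x
    n <- nrow(x)
    xp <- x[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (i in seq_along(k))
      out <- out + k[i] * xp[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

# Rec.601 luma of an HxWx3 array in [0,255]
rgb_to_gray <- function(rgb) {
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

# Population central moments
central_moment <- function(x, k) mean((x - mean(x))^k)

# Fisher-Pearson skewness g1 (population moments), 0 for degenerate input
skewness_g1 <- function(x) {
  if (length(x) < 3) return(0)
  m2 <- central_moment(x, 2)
  if (m2 <= 0) return(0)
  central_moment(x, 3) / m2^1.5
}
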