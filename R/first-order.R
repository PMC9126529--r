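#' First-order intensity statistics within a mask
#'
#' Histogram-free moments use population conventions (divide by n); the
#' histogram entropy/energy use 16 equal-width bins spanning the masked
#' min-max range, so a constant region has entropy 0 and energy 1.
#'
#' @param gray numeric intensity matrix.
#' @param mask logical matrix of the same shape, at least one pixel.
#' @return named numeric vector of length 8: mean, variance, skewness,
#'   excess kurtosis, histogram entropy (bits), histogram energy, range,
#'   median absolute deviation (unscaled).
#' @export
first_order_features <- function(gray, mask) {
  stopifnot(identical(dim(gray), dim(mask)))
  if (!any(mask)) stop("first_order_features: empty mask")
  x <- gray[mask]
  m <- mean(x)
  m2 <- central_moment(x, 2)
  skew <- if (m2 > 0) central_moment(x, 3) / m2^1.5 else 0
  kurt <- if (m2 > 0) central_moment(x, 4) / m2^2 - 3 else 0
  rng <- max(x) - min(x)
  if (rng > 0) {
    bins <- pmin(floor((x - min(x)) / rng * 16), 15)
    p <- tabulate(bins + 1L, 16) / length(x)
  } else p <- c(1, numeric(15))
  stats::setNames(
    c(m, m2, skew, kurt, -sum(xlog2(p)), sum(p^2), rng,
      median(abs(x - median(x)))),
    first_order_names())
}

first_order_names <- function() {
  paste0("fo_", c("mean", "variance", "skewness", "kurtosis",
                  "entropy", "energy", "range", "mad"))
}
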