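#' The frozen feature catalog
#'
#' The per-cell catalog has 53 base descriptors in fixed order: 13 Haralick
#' texture descriptors, 8 first-order intensity statistics, 10
#' morphometrics, 7 Hu invariant moments, 10 elliptic Fourier harmonic
#' magnitudes and 5 irregularity measures. Each is summarized across the
#' myeloblasts of a tile by four statistics (mean, median, sd, skewness)
#' and averaged across tiles, then the total blast count and the blast
#' percentage (blasts / total WBCs) are appended, giving the
#' 53 x 4 + 2 = 214-element patient vector.
#'
#' @return `feature_catalog()`: character vector of the 53 base descriptor
#'   names; `patient_feature_names()`: the 214 patient-level feature names.
#' @export
feature_catalog <- function() {
  c(haralick_names(), first_order_names(), morpho_names(),
    paste0("hu_", 1:7), paste0("efd_", 1:10),
    paste0("ir_", c("fractal_dim", "radial_var", "bending_energy",
                    "concavity_rate", "convex_perim_ratio")))
}

#' @rdname feature_catalog
#' @export
patient_feature_names <- function() {
  base <- feature_catalog()
  c(as.vector(t(outer(base, tile_stat_names(), paste, sep = "_"))),
    "blast_count", "blast_percentage")
}

tile_stat_names <- function() c("mean", "median", "sd", "skewness")
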