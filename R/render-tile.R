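#' Render one synthetic aspirate tile
#'
#' Draws an aspirate-like RGB tile on a pale pink background: elliptical
#' red-cell discs, small lobed dark-purple other-WBC nuclei, and large
#' round purple myeloblast nuclei, all placed without overlap. Myeloblast
#' chromatin is a Gaussian random field: the per-cell amplitude of the
#' smoothed component is drawn with between-cell variance proportional to
#' the patient's latent heterogeneity h (on top of a fixed fine-grain
#' component, so the GLCM contrast of a cell moves with its amplitude and
#' the across-cell contrast variance grows with h), and the smoothing
#' width is drawn from a right-skewed Gamma law whose skewness decreases
#' with h (driving the across-cell skewness of GLCM correlation). Texture
#' is added equally to all three channels, which leaves the blue-excess
#' channel used by the segmenter untouched.
#'
#' Consumes the current RNG stream; seed upstream for reproducibility.
#'
#' @param params a [sim_params()] object.
#' @param h latent heterogeneity, inside `params$heterogeneity_range`.
#' @return list of class `synthetic_tile`: `rgb` (H x W x 3 integer),
#'   `blast_mask` and `wbc_mask` (integer label images, labels in raster
#'   order of centroids), `cells` (data.frame of placed objects).
#' @export
render_tile <- function(params, h) {
  rng <- params$heterogeneity_range
  if (h < rng[1] - 1e-9 || h > rng[2] + 1e-9)
    stop("render_tile: h outside heterogeneity_range")
  n <- params$tile_px
  pal <- sim_palette()

  nb <- sample_int_range(params$blasts_per_tile_range)
  nw <- sample_int_range(params$other_wbc_per_tile_range)
  nr_rbc <- params$rbc_per_tile

  # non-overlap placement by rejection on centre distances
  placed <- data.frame(y = numeric(0), x = numeric(0), r = numeric(0),
                       kind = character(0))
  place <- function(placed, r, kind, required = TRUE) {
    for (it in 1:300) {
      y <- runif(1, r + 2, n - r - 1)
      x <- runif(1, r + 2, n - r - 1)
      if (!nrow(placed) ||
          all((placed$y - y)^2 + (placed$x - x)^2 >
              (placed$r + r + 3)^2)) {
        return(rbind(placed, data.frame(y = y, x = x, r = r, kind = kind)))
      }
    }
    if (required)
      stop("render_tile: placement failed after bounded retries ",
           "(tile too small for the requested cell counts)")
    placed
  }
  blast_geom <- vector("list", nb)
  for (k in seq_len(nb)) {
    a <- runif(1, 14, 22)
    b <- a * runif(1, 0.85, 1)
    th <- runif(1, 0, pi)
    placed <- place(placed, a, "blast")
    blast_geom[[k]] <- list(a = a, b = b, theta = th)
  }
  wbc_geom <- vector("list", nw)
  for (k in seq_len(nw)) {
    r0 <- runif(1, 5, 8)
    nl <- sample(2:3, 1)
    ang <- runif(nl, 0, 2 * pi)
    rl <- r0 * runif(nl, 0.8, 1)
    off <- runif(nl, 0, 0.9 * r0)
    off[1] <- 0
    placed <- place(placed, 2 * r0, "wbc")
    wbc_geom[[k]] <- list(r0 = r0, ang = ang, rl = rl, off = off)
  }
  for (k in seq_len(nr_rbc)) {
    a <- runif(1, 10, 16)
    placed <- place(placed, a, "rbc", required = FALSE)
  }

  img <- array(0, c(n, n, 3))
  for (ch in 1:3)
    img[, , ch] <- pal$background[ch] + matrix(rnorm(n * n, 0, 2.5), n, n)
  blast_mask <- matrix(0L, n, n)
  wbc_mask <- matrix(0L, n, n)

  idx <- list(blast = 0L, wbc = 0L)
  for (row in seq_len(nrow(placed))) {
    ob <- placed[row, ]
    if (ob$kind == "rbc") {
      a <- ob$r; b <- a * runif(1, 0.8, 1)
      sel <- ellipse_sel(n, ob$y, ob$x, a, b, runif(1, 0, pi))
      img <- paint(img, sel, pal$rbc)
    } else if (ob$kind == "blast") {
      idx$blast <- idx$blast + 1L
      g <- blast_geom[[idx$blast]]
      sel <- ellipse_sel(n, ob$y, ob$x, g$a, g$b, g$theta)
      img <- paint(img, sel, pal$blast)
      # chromatin texture: h-dependent smooth amplitude + fixed fine grain
      amp <- max(2, 16 + rnorm(1, 0, sqrt(25 * h)))
      shape <- 2 + 4 * h
      width <- 0.8 + stats::rgamma(1, shape = shape, rate = shape / 1.2)
      img <- add_texture(img, sel, amp, width, fine_amp = 5)
      blast_mask[sel$lin] <- idx$blast
    } else {
      idx$wbc <- idx$wbc + 1L
      g <- wbc_geom[[idx$wbc]]
      lin <- integer(0)
      for (l in seq_along(g$rl)) {
        cyl <- ob$y + g$off[l] * sin(g$ang[l])
        cxl <- ob$x + g$off[l] * cos(g$ang[l])
        sl <- ellipse_sel(n, cyl, cxl, g$rl[l], g$rl[l], 0)
        lin <- union(lin, sl$lin)
      }
      sel <- list(lin = lin,
                  bbox = lin_bbox(lin, n))
      img <- paint(img, sel, pal$wbc)
      img <- add_texture(img, sel, amp = 6, width = 1, fine_amp = 3)
      wbc_mask[sel$lin] <- idx$wbc
    }
  }

  img <- clamp(round(img), 0, 255)
  storage.mode(img) <- "integer"
  blast_mask <- relabel_mask_raster(blast_mask)
  wbc_mask <- relabel_mask_raster(wbc_mask)
  structure(list(rgb = img, blast_mask = blast_mask, wbc_mask = wbc_mask,
                 cells = placed), class = "synthetic_tile")
}

sample_int_range <- function(rg) {
  rg[1] + sample.int(rg[2] - rg[1] + 1L, 1) - 1L
}

# linear indices + bbox of a rotated ellipse clipped to the tile
ellipse_sel <- function(n, cy, cx, a, b, theta) {
  y1 <- max(1, floor(cy - a - 1)); y2 <- min(n, ceiling(cy + a + 1))
  x1 <- max(1, floor(cx - a - 1)); x2 <- min(n, ceiling(cx + a + 1))
  ys <- y1:y2; xs <- x1:x2
  Y <- matrix(ys, length(ys), length(xs))
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  u <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  v <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  lin <- (rep(xs, each = length(ys)) - 1L) * n + rep(ys, length(xs))
  list(lin = lin[as.vector(inside)], bbox = c(y1, y2, x1, x2))
}

lin_bbox <- function(lin, n) {
  ys <- (lin - 1L) %% n + 1L
  xs <- (lin - 1L) %/% n + 1L
  c(min(ys), max(ys), min(xs), max(xs))
}

paint <- function(img, sel, col) {
  n <- dim(img)[1]
  for (ch in 1:3) img[sel$lin + (ch - 1L) * n * n] <- col[ch]
  img
}

# Add base + fine Gaussian-field texture equally to all channels inside sel
add_texture <- function(img, sel, amp, width, fine_amp) {
  n <- dim(img)[1]
  bb <- sel$bbox
  hgt <- bb[2] - bb[1] + 1L; wid <- bb[4] - bb[3] + 1L
  smooth <- gauss_blur(matrix(rnorm(hgt * wid), hgt, wid), width)
  s <- stats::sd(as.vector(smooth))
  if (s > 0) smooth <- smooth / s
  tex <- amp * smooth + fine_amp * matrix(rnorm(hgt * wid), hgt, wid)
  ys <- (sel$lin - 1L) %% n + 1L
  xs <- (sel$lin - 1L) %/% n + 1L
  tv <- tex[cbind(ys - bb[1] + 1L, xs - bb[3] + 1L)]
  for (ch in 1:3) img[sel$lin + (ch - 1L) * n * n] <-
      img[sel$lin + (ch - 1L) * n * n] + tv
  img
}

# renumber positive labels 1..K in raster order of component centroids
relabel_mask_raster <- function(m) {
  labs <- sort(unique(m[m > 0]))
  if (!length(labs)) return(m)
  cen <- t(vapply(labs, function(l) {
    pts <- which(m == l, arr.ind = TRUE)
    c(mean(pts[, 1]), mean(pts[, 2]))
  }, numeric(2)))
  ord <- order(round(cen[, 1]), round(cen[, 2]))
  out <- matrix(0L, nrow(m), ncol(m))
  for (k in seq_along(ord)) out[m == labs[ord[k]]] <- k
  out
}
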