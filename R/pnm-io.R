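#' Read and write NetPBM images
#'
#' Tiles are stored as binary PPM (P6, 8-bit RGB) and label masks as binary
#' PGM (P5, 16-bit big-endian), the plain-raster formats every imaging tool
#' understands. These stand in for the usual PNG containers; the pixel
#' content is identical.
#'
#' @param img for [write_ppm()] an H x W x 3 integer array in 0..255; for
#'   [write_pgm()] an H x W integer matrix in 0..maxval.
#' @param path file path.
#' @param maxval maximum gray value for PGM (65535 gives 16-bit masks).
#' @return `write_*` return `path` invisibly; `read_ppm()` returns an
#'   H x W x 3 integer array, `read_pgm()` an integer matrix.
#' @name pnm_io
NULL

#' @rdname pnm_io
#' @export
write_ppm <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P6", paste(w, h), "255"), con, sep = "\n")
  # interleave RGB, row-major
  px <- aperm(img, c(3, 2, 1))  # channel, col, row
  writeBin(as.integer(px), con, size = 1, useBytes = TRUE)
  invisible(path)
}

#' @rdname pnm_io
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_pnm_header(con, "P6")
  raw <- readBin(con, "integer", n = 3 * hd$w * hd$h, size = 1, signed = FALSE)
  aperm(array(raw, c(3, hd$w, hd$h)), c(3, 2, 1))
}

#' @rdname pnm_io
#' @export
write_pgm <- function(img, path, maxval = 65535L) {
  stopifnot(is.matrix(img))
  h <- nrow(img); w <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(w, h), as.character(maxval)), con, sep = "\n")
  sz <- if (maxval > 255) 2 else 1
  writeBin(as.integer(t(img)), con, size = sz, endian = "big", useBytes = TRUE)
  invisible(path)
}

#' @rdname pnm_io
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hd <- read_pnm_header(con, "P5")
  sz <- if (hd$maxval > 255) 2 else 1
  raw <- readBin(con, "integer", n = hd$w * hd$h, size = sz,
                 signed = FALSE, endian = "big")
  matrix(raw, hd$h, hd$w, byrow = TRUE)
}

# Byte-wise header scan: 4 whitespace-separated tokens (magic, w, h, maxval),
# '#' comments allowed; leaves the connection at the first data byte.
read_pnm_header <- function(con, magic) {
  tok <- character(0)
  cur <- ""
  in_comment <- FALSE
  while (length(tok) < 4 || nzchar(cur)) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0 || !nzchar(ch)) stop("truncated PNM header")
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
      next
    }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("[ \t\r\n]", ch)) {
      if (nzchar(cur)) { tok <- c(tok, cur); cur <- "" }
      if (length(tok) == 4) break   # single whitespace after maxval
    } else cur <- paste0(cur, ch)
  }
  if (tok[1] != magic)
    stop("expected ", magic, " file, got magic '", tok[1], "'")
  list(w = as.integer(tok[2]), h = as.integer(tok[3]),
       maxval = as.integer(tok[4]))
}
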