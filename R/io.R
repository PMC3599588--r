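# Grayscale image input/output.

read_pgm <- function(path) {
  # Minimal PGM (P2 ASCII / P5 binary) reader; no installed package handles
  # this format.
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  while (length(tok) < 4L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1L]
  w <- as.integer(tok[2L]); h <- as.integer(tok[3L]); mx <- as.numeric(tok[4L])
  if (magic == "P5") {
    vals <- as.numeric(readBin(con, "integer", n = w * h,
                               size = if (mx < 256) 1L else 2L,
                               signed = FALSE, endian = "big"))
  } else if (magic == "P2") {
    vals <- scan(con, what = numeric(), n = w * h, quiet = TRUE)
  } else stop("not a PGM file")
  matrix(vals, h, w, byrow = TRUE) / mx
}

#' Read a grayscale image
#'
#' Reads PNG, TIFF, or PGM into a matrix of values in `[0, 1]`; color
#' channels are averaged.
#'
#' @param path Image file path.
#' @return A numeric matrix (rows = image rows).
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF images")
      tiff::readTIFF(path)
    },
    pgm = read_pgm(path),
    stop(sprintf("unsupported image format '%s'", ext)))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3L]),
                                               drop = FALSE], c(1L, 2L), mean)
  img
}

#' Write a map as a grayscale PNG
#'
#' Rescales to `[0, 1]` by the map maximum and writes an 8-bit grayscale
#' PNG; the raw values can be kept alongside with `raw_path`.
#'
#' @param map Numeric matrix.
#' @param path Output PNG path.
#' @param raw_path Optional path for the unscaled matrix (RDS).
#' @return `path`, invisibly.
#' @export
write_map_png <- function(map, path, raw_path = NULL) {
  m <- unclass(map)
  png::writePNG(norm_peak(pmax(m, 0)), path)
  if (!is.null(raw_path)) saveRDS(m, raw_path)
  invisible(path)
}
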