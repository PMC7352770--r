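#' Read a raster from TIFF, PNG or CSV grid
#'
#' Single-channel rasters are returned as numeric matrices, RGB images as
#' `h x w x 3` arrays with values in `[0, 1]` (8-bit files are rescaled).
#' CSV grids (no header) are read as numeric matrices, which is the exchange
#' format used for film dose maps.
#'
#' @param path File path; format is chosen by extension
#'   (`.tif`/`.tiff`, `.png`, `.csv`).
#' @return Numeric matrix or 3-d array.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("the 'png' package is required to read PNG rasters")
      png::readPNG(path)
    },
    csv = as.matrix(utils::read.csv(path, header = FALSE)),
    stop("unsupported raster format: ", ext)
  )
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3]  # drop alpha
  if (length(dim(x)) == 3L && dim(x)[3] == 1L) dim(x) <- dim(x)[1:2]
  storage.mode(x) <- "double"
  unname(x)
}

#' Write a raster to TIFF or CSV grid
#'
#' Matrices and RGB arrays are written as 32-bit float TIFF (values are not
#' rescaled); `.csv` writes a headerless numeric grid.
#'
#' @param x Numeric matrix or `h x w x 3` array.
#' @param path Output path (`.tif`/`.tiff` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 32L,
                           compression = "none"),
    csv = utils::write.table(x, path, sep = ",", row.names = FALSE,
                             col.names = FALSE),
    stop("unsupported raster format: ", ext)
  )
  invisible(path)
}
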