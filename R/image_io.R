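#' Validate a grayscale image matrix
#'
#' The pipeline's universal currency is a plain numeric matrix: rows are image
#' rows (origin top-left), values are intensities in arbitrary units.  This
#' helper checks the contract every downstream operation relies on: a 2-D
#' numeric matrix with all values finite.
#'
#' @param image object to validate.
#' @param min_dim minimum number of rows and columns required (the
#'   decomposition stages require at least 8).
#' @return the validated matrix, invisibly coerced to numeric storage.
#' @export
as_gray_image <- function(image, min_dim = 1L) {
  if (!is.matrix(image) || !is.numeric(image))
    stop_validation("image must be a numeric matrix")
  if (nrow(image) < min_dim || ncol(image) < min_dim)
    stop_validation("image must be at least ", min_dim, " x ", min_dim,
                    " (got ", nrow(image), " x ", ncol(image), ")")
  if (!all(is.finite(image)))
    stop_validation("image contains non-finite values")
  storage.mode(image) <- "double"
  image
}

#' Read a grayscale micrograph
#'
#' Reads a TIFF (any page count; page 1 is used) or PNG raster and returns a
#' numeric intensity matrix.  Multi-channel inputs are collapsed to grayscale
#' by the unweighted channel mean: fluorescence micrographs are single-dye, so
#' perceptual luminance weighting would be inappropriate.  Integer TIFFs are
#' returned on their native integer scale (0..255 or 0..65535); float TIFFs
#' verbatim; PNGs on the \[0, 1\] scale used by the PNG decoder.
#'
#' @param path file path to a `.tif`/`.tiff` or `.png` image.
#' @return numeric matrix with attribute `source` recording `path`.
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop_validation("path must be a single file path")
  if (!file.exists(path)) stop_io("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  read_tiff <- function(p) {
    info <- tiff::readTIFF(p, payload = FALSE)
    is_float <- !is.null(info$sample.format) &&
      any(info$sample.format == "float")
    # integer rasters keep their native scale; floats are read verbatim
    tiff::readTIFF(p, as.is = !is_float)
  }
  raw <- tryCatch(
    switch(ext,
           tif = , tiff = read_tiff(path),
           png = png::readPNG(path),
           stop_validation("unsupported image format '.", ext, "': ", path)),
    error = function(e) {
      if (inherits(e, "mttex_validation_error")) stop(e)
      stop_io("cannot read image ", path, ": ", conditionMessage(e))
    })
  if (is.list(raw)) raw <- raw[[1L]]          # multi-page: take page 1
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] == 2L || dim(raw)[3L] == 4L)  # drop alpha channel
      raw <- raw[, , -dim(raw)[3L], drop = FALSE]
    raw <- apply(raw, c(1L, 2L), mean)
  }
  if (!is.matrix(raw) || nrow(raw) == 0L || ncol(raw) == 0L)
    stop_validation("zero-sized raster: ", path)
  img <- as_gray_image(raw)
  attr(img, "source") <- path
  img
}

# minimal uncompressed little-endian 32-bit float grayscale TIFF writer;
# the installed TIFF writer cannot store values outside [0, 1], which signed
# IMF rasters require
write_float_tiff <- function(image, path) {
  h <- nrow(image); w <- ncol(image)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)      # header, IFD at byte 8
  n_tags <- 9L
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  tag <- function(id, type, count, value) { w2(id); w2(type); w4(count); w4(value) }
  w2(n_tags)
  tag(256L, 3L, 1L, w)             # ImageWidth
  tag(257L, 3L, 1L, h)             # ImageLength
  tag(258L, 3L, 1L, 32L)           # BitsPerSample
  tag(259L, 3L, 1L, 1L)            # Compression = none
  tag(262L, 3L, 1L, 1L)            # Photometric = BlackIsZero
  tag(273L, 4L, 1L, data_offset)   # StripOffsets
  tag(278L, 3L, 1L, h)             # RowsPerStrip
  tag(279L, 4L, 1L, h * w * 4L)    # StripByteCounts
  tag(339L, 3L, 1L, 3L)            # SampleFormat = IEEE float
  w4(0L)                           # next IFD: none
  writeBin(as.numeric(t(image)), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a grayscale image
#'
#' TIFF output (the default) stores 32-bit IEEE floats, so signed intrinsic
#' mode functions survive a round trip bit-for-bit at single precision.  PNG
#' output is 8-bit and therefore only accepts values already on a display
#' scale: either within \[0, 1\] or integers within 0..255 (use
#' [rescale_to_8bit()] first); anything else is a validation error rather
#' than a silent clip.
#'
#' @param image numeric matrix (finite values).
#' @param path output path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  image <- as_gray_image(image)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop_io("parent directory does not exist: ", dir)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_float_tiff(image, path)
  } else if (ext == "png") {
    rng <- range(image)
    if (rng[1] >= 0 && rng[2] <= 1) {
      png::writePNG(image, path)
    } else if (rng[1] >= 0 && rng[2] <= 255 && all(image == round(image))) {
      png::writePNG(image / 255, path)
    } else {
      stop_validation("PNG output needs values in [0,1] or integers 0..255; ",
                      "rescale_to_8bit() the image first")
    }
  } else {
    stop_validation("unsupported output format '.", ext, "'")
  }
  invisible(path)
}

#' Rescale an image to 8-bit display range
#'
#' Linear min-max map onto integers 0..255.  A constant (zero-range) image
#' maps to all zeros by convention so that pipelines survive blank frames.
#'
#' @param image numeric matrix.
#' @return integer-valued matrix in 0..255.
#' @export
rescale_to_8bit <- function(image) {
  image <- as_gray_image(image)
  rng <- range(image)
  if (rng[2] == rng[1]) return(matrix(0, nrow(image), ncol(image)))
  round((image - rng[1]) / (rng[2] - rng[1]) * 255)
}
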