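## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_binary <- function(mask, arg = "mask") {
  if (is.logical(mask)) return(matrix(mask, nrow(mask), ncol(mask)))
  if (!is.numeric(mask)) stopf("'%s' must be a logical or 0/1 numeric matrix", arg)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1))) stopf("'%s' must be binary (0/1)", arg)
  matrix(as.logical(mask), nrow(mask), ncol(mask))
}

#' Read an image file into an array
#'
#' Reads a TIFF or PNG image and returns it as a base-R array in row-major
#' (height, width\[, channel\]) order with intensities scaled to \[0, 1\].
#'
#' @param path Path to a TIFF or PNG file.
#' @return A numeric matrix (grayscale) or height x width x channels array.
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
}

#' Write an image array to a file
#'
#' Writes a (height, width\[, channel\]) array with values in \[0, 1\] to TIFF
#' or PNG (chosen from the file extension).
#'
#' @param image Numeric matrix or 3-channel array, values in \[0, 1\].
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @param bits Bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8L) {
  image[] <- pmin(pmax(image, 0), 1)
  if (length(dim(image)) == 2L) {
    obj <- EBImage::Image(t(image))
  } else {
    obj <- EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = "Color")
  }
  type <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "tiff"
  if (type == "tiff") {
    EBImage::writeImage(obj, path, type = "tiff", bits.per.sample = as.integer(bits))
  } else {
    EBImage::writeImage(obj, path, type = "png")
  }
  invisible(path)
}

## convert a gray/RGB array to luminance
to_gray <- function(image) {
  if (length(dim(image)) == 2L) return(image)
  0.2126 * image[, , 1] + 0.7152 * image[, , 2] + 0.0722 * image[, , 3]
}
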