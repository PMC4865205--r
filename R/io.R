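# Image input/output. Grayscale images travel as plain numeric matrices in
# [0,1]; masks as logical matrices. PNG and TIFF are supported (8-bit PNG is
# the native fixture format).

#' Read a grayscale image
#'
#' Reads a PNG or TIFF file into a numeric matrix with intensities in [0,1]
#' (8-bit samples are divided by 255 by the decoders). Multi-channel images
#' are converted by averaging the color channels.
#'
#' @param path file path; format chosen by extension (.png, .tif, .tiff).
#' @return numeric matrix (rows = image rows).
#' @export
readGrayImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (PNG and TIFF are supported)"))
  if (length(dim(arr)) == 3L)
    arr <- apply(arr[, , seq_len(min(3L, dim(arr)[3L])), drop = FALSE],
                 c(1L, 2L), mean)
  arr
}

#' Write a grayscale image
#'
#' Writes a numeric matrix as an 8-bit grayscale PNG. Values are clipped to
#' [0,1]; set \code{rescale = TRUE} to map the value range linearly onto
#' [0,1] first (useful for feature images and filter spectra dumps).
#'
#' @param image numeric matrix.
#' @param path output path (.png).
#' @param rescale linearly rescale to full range before writing.
#' @return \code{path}, invisibly.
#' @export
writeGrayImage <- function(image, path, rescale = FALSE) {
  stopifnot(is.matrix(image))
  if (rescale) {
    rg <- range(image)
    image <- if (diff(rg) > 0) (image - rg[1L]) / diff(rg) else image * 0
  }
  image[image < 0] <- 0
  image[image > 1] <- 1
  # quantize to 8 bit so a written image re-reads bit-exactly
  png::writePNG(round(image * 255) / 255, path)
  invisible(path)
}

#' Read / write a binary mask
#'
#' Masks are 8-bit PNG images, 0 = background, 255 = foreground. On reading,
#' any strictly positive pixel counts as foreground by default
#' (\code{polarity = "light"}); \code{polarity = "dark"} inverts, and
#' \code{polarity = "auto"} guesses by taking the class covering the image
#' center's 25% central window as foreground (useful for externally marked
#' masks whose display polarity is inverted).
#'
#' @param path file path.
#' @param polarity \code{"light"}, \code{"dark"} or \code{"auto"}.
#' @return \code{readMask}: logical matrix.
#' @export
readMask <- function(path, polarity = c("light", "dark", "auto")) {
  polarity <- match.arg(polarity)
  m <- readGrayImage(path) > 0
  switch(polarity,
    light = m,
    dark = !m,
    auto = {
      nr <- nrow(m); nc <- ncol(m)
      rs <- round(nr * 3 / 8):round(nr * 5 / 8)
      cs <- round(nc * 3 / 8):round(nc * 5 / 8)
      if (mean(m[rs, cs]) >= 0.5) m else !m
    })
}

#' @rdname readMask
#' @param mask logical matrix.
#' @param invert write with display polarity inverted (ROI black on white).
#' @export
writeMask <- function(mask, path, invert = FALSE) {
  stopifnot(is.matrix(mask))
  m <- (mask & !is.na(mask)) * 1
  if (invert) m <- 1 - m
  png::writePNG(m, path)
  invisible(path)
}
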