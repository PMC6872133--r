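# Binary seed masks: construction, cleanup (opening/closing, hole filling,
# speck removal) and reading from PNG/TIFF files.

#' Construct a binary image
#'
#' @param mask logical (or 0/1) matrix, `mask[row, col]` with row 1 at the
#'   top; `TRUE`/nonzero is foreground (seed).
#' @param pixel_scale physical length per pixel (kept as metadata; all
#'   measurements are in pixel units by default).
#' @return An object of class `binary_image`.
#' @export
binary_image <- function(mask, pixel_scale = 1) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  structure(list(mask = mask != 0, pixel_scale = pixel_scale),
            class = "binary_image")
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px, %d foreground\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Clean a binary seed mask
#'
#' Morphological opening then closing with a 3x3 cross structuring element
#' (one pass each), hole filling, removal of components smaller than
#' `min_component_px`, and retention of the single largest 8-connected
#' component. This mirrors the usual erosion/dilation cleanup applied to
#' scanned seed images before boundary tracing.
#'
#' @param img a [binary_image].
#' @param min_component_px components with fewer foreground pixels are
#'   dropped (default 8).
#' @return A cleaned [binary_image] with exactly one hole-free foreground
#'   component.
#' @export
clean_binary <- function(img, min_component_px = 8L) {
  if (!inherits(img, "binary_image")) img <- binary_image(img)
  if (!any(img$mask)) stop("no seed found")
  kern <- EBImage::makeBrush(3L, shape = "diamond")   # 3x3 cross
  x <- EBImage::Image(t(img$mask) * 1)                # EBImage indexes [x, y]
  x <- EBImage::closing(EBImage::opening(x, kern), kern)
  x <- EBImage::fillHull(x)
  lab <- EBImage::bwlabel(x)
  tab <- table(lab[lab > 0])
  if (length(tab) == 0L) stop("no seed found")
  keep <- names(tab)[tab >= min_component_px]
  if (length(keep) == 0L) stop("no seed found")
  biggest <- keep[which.max(tab[keep])]
  mask <- t(EBImage::imageData(lab) == as.numeric(biggest))
  # a largest component could still carry holes reopened by labelling; fill
  mask <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(mask) * 1))) > 0)
  binary_image(mask, img$pixel_scale)
}

#' Count 8-connected foreground components
#'
#' @param img a [binary_image] or logical matrix.
#' @return Integer component count.
#' @export
count_components <- function(img) {
  mask <- if (inherits(img, "binary_image")) img$mask else img != 0
  lab <- EBImage::bwlabel(EBImage::Image(t(mask) * 1))
  max(EBImage::imageData(lab))
}

#' Read a binary mask from a PNG or TIFF file
#'
#' Nonzero pixels are foreground. Multi-channel images are collapsed by
#' maximum over channels.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_scale passed to [binary_image()].
#' @return A [binary_image].
#' @export
read_mask <- function(path, pixel_scale = 1) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = { requireNamespace("png"); png::readPNG(path) },
    tif = ,
    tiff = { requireNamespace("tiff"); tiff::readTIFF(path) },
    stop("unsupported mask format: ", ext))
  if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), max)
  binary_image(arr > 0, pixel_scale)
}

#' Write a binary mask to PNG
#'
#' @param img a [binary_image].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(img, path) {
  requireNamespace("png")
  png::writePNG(img$mask * 1, path)
  invisible(path)
}
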