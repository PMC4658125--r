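#' Raster images
#'
#' A `source_image` holds an 8-bit RGB raster as an integer array of dimension
#' height x width x 3 (values 0--255), together with the path it was read from
#' (if any). Grayscale inputs are promoted to three identical channels; alpha
#' channels are dropped.
#'
#' @param pixels Integer array, `H x W x 3`, values in 0--255. A plain matrix
#'   is promoted to three identical channels.
#' @param path Optional path the raster was read from.
#' @return A `source_image` object.
#' @export
source_image <- function(pixels, path = NA_character_) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_param("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_param("image must be at least 1 x 1")
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, path = path), class = "source_image")
}

#' @export
print.source_image <- function(x, ...) {
  cat(sprintf("<source_image> %d x %d px, 3 channels%s\n",
              img_width(x), img_height(x),
              if (is.na(x$path)) "" else paste0(" (", x$path, ")")))
  invisible(x)
}

#' @rdname source_image
#' @param image A `source_image`.
#' @export
img_width <- function(image) dim(image$pixels)[2]

#' @rdname source_image
#' @export
img_height <- function(image) dim(image$pixels)[1]

# EBImage stores [x = width, y = height, channel] in [0, 1]
from_ebimage <- function(img, path = NA_character_) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  nc <- dim(a)[3]
  if (nc == 1L) a <- array(rep(a, 3L), dim = c(dim(a)[1:2], 3L))
  if (nc == 2L) a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L)) # gray + alpha
  if (nc > 3L) a <- a[, , 1:3, drop = FALSE]
  px <- aperm(a, c(2L, 1L, 3L))
  source_image(array(as.integer(round(clamp(px, 0, 1) * 255)), dim = dim(px)), path = path)
}

to_ebimage <- function(image) {
  a <- aperm(image$pixels / 255, c(2L, 1L, 3L))
  EBImage::Image(a, colormode = "Color")
}

#' Read a raster image
#'
#' Decodes a TIFF, JPEG or PNG file into a [source_image]. Grayscale images
#' are promoted to three channels.
#'
#' @param path Path to the image file.
#' @return A [source_image].
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_input(sprintf("image file not found: %s", path))
  img <- tryCatch(
    suppressWarnings(EBImage::readImage(path)),
    error = function(e) stop_format(sprintf("cannot decode image %s: %s", path, conditionMessage(e)))
  )
  from_ebimage(img, path = path)
}

#' Write a raster image
#'
#' @param image A [source_image].
#' @param path Output path; format chosen from the extension (jpg/jpeg, png,
#'   tif/tiff).
#' @param quality JPEG quality (ignored for other formats).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, quality = 95L) {
  EBImage::writeImage(to_ebimage(image), path, quality = quality)
  invisible(path)
}

#' Scale an image down to a thumbnail
#'
#' Interactive and algorithmic work happens on a reduced-width JPEG copy of
#' the scan; the full-resolution file is only touched for cropping. The width
#' default follows the standard document layout (4,096 px). Images already
#' narrower than the target are returned unscaled: a thumbnail is
#' lower-resolution by definition, so no upscaling is performed.
#'
#' @param image A [source_image].
#' @param target_width Target width in pixels (default 4096).
#' @return A [source_image] of width `min(width, target_width)`; height scaled
#'   to preserve aspect ratio (rounded).
#' @export
make_thumbnail <- function(image, target_width = 4096L) {
  if (!is_count(target_width)) stop_param("`target_width` must be a positive integer")
  w <- img_width(image)
  if (w <= target_width) return(image)
  h <- as.integer(round(img_height(image) * target_width / w))
  out <- EBImage::resize(to_ebimage(image), w = as.integer(target_width), h = max(h, 1L))
  from_ebimage(out, path = image$path)
}
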