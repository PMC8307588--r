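#' @importFrom stats var sd quantile predict rnorm runif setNames
#' @importFrom utils head tail
NULL

#' Construct a color image
#'
#' Images are plain numeric arrays in row/column (height x width) layout with
#' 8-bit channel values, RGB channel order, origin at the top-left corner.
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 255]`.
#' @return the validated array, with class `caries_rgb`.
#' @export
color_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("color image must be an H x W x 3 array", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(pixels, class = c("caries_rgb", class(pixels)))
}

#' Construct a binary mask
#'
#' @param pixels numeric `H x W` matrix containing only the values 0 and 255
#'   (logical matrices are promoted: `TRUE` -> 255).
#' @param role stage name tag carried through the detection pipeline
#'   (e.g. `"binary_img"`, `"thick_mask"`, `"mask_lesion"`, `"ground_truth"`).
#' @return integer matrix of 0/255 with attribute `role`.
#' @export
binary_image <- function(pixels, role = "mask") {
  if (is.logical(pixels)) pixels <- ifelse(pixels, 255L, 0L)
  if (!is.matrix(pixels)) stop("binary image must be a matrix", call. = FALSE)
  if (!all(pixels %in% c(0, 255)))
    stop("binary image may contain only the values 0 and 255", call. = FALSE)
  out <- matrix(as.integer(pixels), nrow(pixels), ncol(pixels))
  attr(out, "role") <- role
  out
}

#' @rdname binary_image
#' @param mask object to test.
#' @export
is_binary_image <- function(mask) {
  is.matrix(mask) && all(mask %in% c(0, 255))
}

assert_gray <- function(img) {
  if (!is.matrix(img) || anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("expected an 8-bit grayscale matrix", call. = FALSE)
  invisible(img)
}

assert_same_shape <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    stop("image shapes differ", call. = FALSE)
  invisible(NULL)
}

# BT.601 full-range RGB <-> YCbCr, on [0, 255] doubles.
rgb_to_ycbcr <- function(img) {
  r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
  y  <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 128 - 0.168736 * r - 0.331264 * g + 0.5 * b
  cr <- 128 + 0.5 * r - 0.418688 * g - 0.081312 * b
  list(y = y, cb = cb, cr = cr)
}

ycbcr_to_rgb <- function(y, cb, cr) {
  r <- y + 1.402 * (cr - 128)
  g <- y - 0.344136 * (cb - 128) - 0.714136 * (cr - 128)
  b <- y + 1.772 * (cb - 128)
  out <- array(0, dim = c(dim(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  pmin(pmax(out, 0), 255)
}

#' Read / write images as PNG
#'
#' Thin wrappers over the \pkg{png} package that keep the package's 0..255
#' row-major conventions. Masks are written as single-channel PNGs.
#'
#' @param path file path.
#' @return `read_image()` returns a `H x W x 3` color array; `read_mask()` a
#'   0/255 matrix.
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  color_image(round(px[, , 1:3, drop = FALSE] * 255))
}

#' @rdname read_image
#' @param img color image array.
#' @export
write_image <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  binary_image(ifelse(px > 0.5, 255L, 0L))
}

#' @rdname read_image
#' @param mask binary 0/255 matrix.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, target = path)
  invisible(path)
}

# foreground pixel count of a 0/255 mask
fg_count <- function(mask) sum(mask == 255)
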