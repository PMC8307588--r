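#' Bounding rectangle of a mask
#'
#' Minimal axis-aligned rectangle covering all foreground pixels.
#'
#' @param mask binary 0/255 matrix.
#' @return one-row tibble with `top`, `left` (0-based), `height`, `width`;
#'   all zero for an empty mask.
#' @export
bounding_rect <- function(mask) {
  idx <- which(mask == 255, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(tibble::tibble(top = 0L, left = 0L, height = 0L, width = 0L))
  tibble::tibble(top = min(idx[, 1]) - 1L, left = min(idx[, 2]) - 1L,
                 height = diff(range(idx[, 1])) + 1L,
                 width = diff(range(idx[, 2])) + 1L)
}

#' Lesion length and width
#'
#' Orientation-invariant: length is the longer side of the bounding
#' rectangle, width the shorter.
#'
#' @param rect one-row tibble from [bounding_rect()].
#' @return named numeric vector `c(length = , width = )` in pixels.
#' @export
length_width <- function(rect) {
  c(length = max(rect$height, rect$width),
    width = min(rect$height, rect$width))
}

#' Lesion area ratio
#'
#' Fraction of the occlusal surface covered by the lesion:
#' `|lesion intersect tooth| / |tooth|`.
#'
#' @param lesion_mask,tooth_mask binary 0/255 matrices of equal shape.
#' @return ratio in `[0, 1]`.
#' @export
area_ratio <- function(lesion_mask, tooth_mask) {
  assert_same_shape(lesion_mask, tooth_mask)
  tooth <- fg_count(tooth_mask)
  if (tooth == 0L) stop("no occlusal surface", call. = FALSE)
  sum(lesion_mask == 255 & tooth_mask == 255) / tooth
}

# pixel count of the rasterized convex hull of mask foreground
# (hull of pixel centers; boundary pixels included)
convex_hull_area_px <- function(mask) {
  idx <- which(mask == 255, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(0L)
  if (n <= 2L) return(n)
  hull <- grDevices::chull(idx[, 2], idx[, 1])     # (x = col, y = row)
  hx <- idx[hull, 2]; hy <- idx[hull, 1]
  if (length(unique(hx)) == 1L || length(unique(hy)) == 1L ||
      length(hull) < 3L) {
    # collinear foreground: hull degenerates to the pixel set's line
    return(nrow(unique(idx)))
  }
  rows <- min(idx[, 1]):max(idx[, 1])
  cols <- min(idx[, 2]):max(idx[, 2])
  grid <- expand.grid(row = rows, col = cols)
  inside <- pracma::inpolygon(grid$col, grid$row, hx, hy, boundary = TRUE)
  sum(inside)
}

#' Convex area of a lesion
#'
#' Area of the convex hull of the lesion's foreground pixels (hull of pixel
#' centers, rasterized) divided by the occlusal-surface area, so it shares
#' the scale of [area_ratio()] and `convex_area >= ratio` always holds.
#'
#' @inheritParams area_ratio
#' @return value in `[0, 1]`; 0 for an empty lesion.
#' @export
convex_area <- function(lesion_mask, tooth_mask) {
  assert_same_shape(lesion_mask, tooth_mask)
  tooth <- fg_count(tooth_mask)
  if (tooth == 0L) stop("no occlusal surface", call. = FALSE)
  convex_hull_area_px(lesion_mask) / tooth
}

#' Lesion smoothness
#'
#' First-order texture smoothness `S = 1 - 1 / (1 + sigma^2)` where
#' `sigma^2` is the population variance of the lesion-pixel intensities
#' rescaled to `[0, 1]`. 0 for a constant-intensity or empty lesion; grows
#' monotonically with intensity spread; always `< 1`.
#'
#' @param gray grayscale matrix (0..255).
#' @param lesion_mask binary 0/255 matrix of the same shape.
#' @return value in `[0, 1)`.
#' @export
smoothness <- function(gray, lesion_mask) {
  assert_same_shape(gray, lesion_mask)
  v <- gray[lesion_mask == 255] / 255
  if (length(v) == 0L) return(0)
  s2 <- mean((v - mean(v))^2)
  1 - 1 / (1 + s2)
}

#' Five-feature quantification of a detected lesion
#'
#' Composes [bounding_rect()], [length_width()], [smoothness()],
#' [area_ratio()] and [convex_area()]. When no caries was detected the
#' all-zero feature row is returned.
#'
#' @param det a `caries_detection` from [extract_lesion()].
#' @param gray grayscale matrix of the *original* photograph (lesion texture
#'   is measured on unenhanced intensities).
#' @param tooth_mask binary occlusal-surface mask; defaults to the detection's
#'   own tooth region.
#' @return one-row tibble: `length`, `width`, `smoothness`, `ratio`,
#'   `convex_area`.
#' @export
extract_features <- function(det, gray = NULL, tooth_mask = tooth_region(det)) {
  if (is.null(gray)) gray <- det$intermediates$gray_img
  if (!det$caries_detected)
    return(tibble::tibble(length = 0, width = 0, smoothness = 0,
                          ratio = 0, convex_area = 0))
  lw <- length_width(bounding_rect(det$lesion_mask))
  tibble::tibble(length = unname(lw["length"]), width = unname(lw["width"]),
                 smoothness = smoothness(gray, det$lesion_mask),
                 ratio = area_ratio(det$lesion_mask, tooth_mask),
                 convex_area = convex_area(det$lesion_mask, tooth_mask))
}

feature_columns <- c("length", "width", "smoothness", "ratio", "convex_area")

#' Read / write feature tables
#'
#' CSV dialect with the fixed header
#' `id,length,width,smoothness,ratio,convex_area,label`; the round-trip is
#' lossless. A missing label is stored as an empty field and read back as
#' `NA`.
#'
#' @param records tibble with columns `id`, the five features, and optionally
#'   `label`.
#' @param path CSV file path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the records tibble.
#' @export
write_feature_table <- function(records, path) {
  stopifnot(all(c("id", feature_columns) %in% names(records)))
  if (!"label" %in% names(records)) records$label <- NA_character_
  out <- records[, c("id", feature_columns, "label")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character", label = "character"))
  expected <- c("id", feature_columns, "label")
  if (!identical(names(df), expected))
    stop("malformed feature table header: expected ",
         paste(expected, collapse = ","), call. = FALSE)
  for (j in feature_columns) {
    bad <- which(is.na(df[[j]]))
    if (length(bad))
      stop("malformed row at line ", bad[1] + 1L, ": missing ", j, call. = FALSE)
  }
  df$label[df$label == ""] <- NA_character_
  tibble::as_tibble(df)
}
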