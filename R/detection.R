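#' Detection pipeline configuration
#'
#' Settings for the ten-step lesion-extraction pipeline run by
#' [extract_lesion()].
#'
#' @param contrast_factor global contrast factor applied per channel around the
#'   mid-gray 128 before equalization (`v -> 128 + f * (v - 128)`, clipped).
#'   The default 2.8 saturates sound enamel to a single white level so that the
#'   subsequent rank-based equalization cannot spread the enamel mode across
#'   the intensity range; see the methods vignette. Set to 1 for a plain
#'   equalize-only enhancement.
#' @param equalize apply histogram equalization to the luminance channel
#'   (chroma preserved)?
#' @param binarize_method `"otsu"` (default) or `"fixed"`.
#' @param threshold fixed binarization threshold in 0..255, required when
#'   `binarize_method = "fixed"`.
#' @param min_tooth_area smallest enclosed area (px) accepted as the tooth.
#' @param min_lesion_area smallest filled lesion region (px) that counts as a
#'   caries detection; smaller contours are retained in the result but do not
#'   set `caries_detected`.
#' @param opening apply a light morphological opening to the candidate lesion
#'   image before the second contour search (default off).
#' @param opening_size brush size of the opening kernel.
#' @return a list of class `caries_detect_config`.
#' @export
detect_config <- function(contrast_factor = 2.8,
                          equalize = TRUE,
                          binarize_method = c("otsu", "fixed"),
                          threshold = NULL,
                          min_tooth_area = 100,
                          min_lesion_area = 25,
                          opening = FALSE,
                          opening_size = 3) {
  binarize_method <- match.arg(binarize_method)
  if (binarize_method == "fixed" && is.null(threshold))
    stop("fixed binarization requires a threshold", call. = FALSE)
  structure(list(contrast_factor = contrast_factor, equalize = equalize,
                 binarize_method = binarize_method, threshold = threshold,
                 min_tooth_area = min_tooth_area,
                 min_lesion_area = min_lesion_area,
                 opening = opening, opening_size = opening_size),
            class = "caries_detect_config")
}

# classic discrete CDF histogram equalization of one 0..255 channel:
# v -> round(255 * (cdf(v) - cdf_min) / (n - cdf_min))
equalize_channel <- function(v) {
  iv <- pmin(pmax(round(v), 0), 255)
  h <- tabulate(iv + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf_min <- cdf[which(h > 0)[1]]
  n <- length(iv)
  if (n == cdf_min) return(v)  # single occupied level: nothing to equalize
  map <- round(255 * (cdf - cdf_min) / (n - cdf_min))
  matrix(map[iv + 1L], nrow(v), ncol(v))
}

#' Contrast enhancement (pipeline step 1)
#'
#' Applies an optional global contrast factor per RGB channel, then histogram
#' equalization on the luminance (Y) channel of a YCbCr decomposition with the
#' chroma channels carried through unchanged, so the hue of any lesion crop
#' restored later is preserved.
#'
#' @param img color image array (`H x W x 3`, 0..255).
#' @param factor global contrast factor (1 = none), applied before
#'   equalization.
#' @param equalize equalize the luminance channel?
#' @return enhanced color image, same shape. A degenerate image (all pixels
#'   identical) is returned unchanged with a warning.
#' @export
enhance_contrast <- function(img, factor = 1, equalize = TRUE) {
  px <- matrix(img, ncol = 3L)
  if (all(px[, 1] == px[1, 1]) && all(px[, 2] == px[1, 2]) &&
      all(px[, 3] == px[1, 3])) {
    warning("degenerate image (all pixels identical): returned unchanged")
    return(img)
  }
  out <- img
  if (factor != 1)
    out <- pmin(pmax(128 + factor * (out - 128), 0), 255)
  if (equalize) {
    yc <- rgb_to_ycbcr(out)
    y_eq <- equalize_channel(yc$y)
    out <- ycbcr_to_rgb(y_eq, yc$cb, yc$cr)
  }
  round(out)
}

#' Grayscale conversion (pipeline step 2)
#'
#' BT.601 luma: `round(0.299 R + 0.587 G + 0.114 B)`, clipped to 0..255.
#'
#' @param img color image array.
#' @return integer grayscale matrix.
#' @export
to_grayscale <- function(img) {
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(as.integer(pmin(pmax(round(g), 0), 255)), dim(img)[1], dim(img)[2])
}

#' Binarization (pipeline step 3)
#'
#' Pixels strictly above the threshold map to 255, all others to 0. Under the
#' default Otsu rule the threshold maximizes the between-class variance of the
#' grayscale histogram.
#'
#' @param img grayscale matrix (0..255).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold in 0..255, required for `method = "fixed"`.
#' @return binary 0/255 matrix with role `"binary_img"` and attribute
#'   `threshold` (the value actually used).
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  assert_gray(img)
  if (method == "otsu") {
    vals <- unique(as.vector(img))
    if (length(vals) == 1L) {
      warning("constant image: Otsu threshold set to the constant, output all zero")
      threshold <- vals
    } else {
      threshold <- 255 * EBImage::otsu(EBImage::Image(t(img) / 255),
                                       range = c(0, 1), levels = 256)
    }
  } else if (is.null(threshold)) {
    stop("fixed binarization requires a threshold", call. = FALSE)
  }
  out <- binary_image(ifelse(img > threshold, 255L, 0L), role = "binary_img")
  attr(out, "threshold") <- as.numeric(threshold)
  out
}

#' Largest external contour (pipeline steps 4 and 8)
#'
#' Finds the external boundary of the connected foreground component (8-way
#' connectivity) with the largest enclosed area, holes filled. Ties are broken
#' by the component whose first foreground pixel comes first in row-major
#' order.
#'
#' @param mask binary 0/255 matrix.
#' @param min_area discard contours whose enclosed area is below this.
#' @return an object of class `caries_contour` — a list with `points` (n x 2
#'   matrix of 0-based (row, col) boundary coordinates in tracing order),
#'   `area` (enclosed pixel count, holes filled) and `shape` — or `NULL` when
#'   the mask has no qualifying foreground.
#' @export
largest_contour <- function(mask, min_area = 0) {
  fg <- mask == 255
  if (!any(fg)) return(NULL)
  lab_img <- EBImage::bwlabel(EBImage::Image(t(fg)))
  filled <- EBImage::fillHull(lab_img)
  areas <- tabulate(as.integer(EBImage::imageData(filled)))
  best <- max(areas)
  if (best < min_area) return(NULL)
  cand <- which(areas == best)
  lab <- t(EBImage::imageData(lab_img))  # back to H x W
  if (length(cand) > 1L) {
    # first occurrence in row-major scan order (rows, then columns)
    first_idx <- vapply(cand, function(i) {
      pos <- which(lab == i)
      min((pos - 1L) %% nrow(lab) * ncol(lab) + (pos - 1L) %/% nrow(lab))
    }, numeric(1))
    cand <- cand[which.min(first_idx)]
  }
  comp <- EBImage::Image(t(lab == cand[1]))
  pts <- EBImage::ocontour(comp)[[1]]  # 0-based (x, y)
  points <- cbind(row = pts[, 2], col = pts[, 1])
  structure(list(points = points, area = best, shape = dim(mask)),
            class = "caries_contour")
}

# Rasterize the strict interior of a closed pixel-chain polygon by even-odd
# scanline counting. Chain pixels themselves are boundary, never interior.
contour_interior <- function(points, shape) {
  interior <- matrix(FALSE, shape[1], shape[2])
  n <- nrow(points)
  if (n < 3L) return(interior)
  r1 <- points[, 1]; c1 <- points[, 2]
  r2 <- points[c(2:n, 1L), 1]; c2 <- points[c(2:n, 1L), 2]
  keep <- r1 != r2
  if (!any(keep)) return(interior)
  # half-open rule: each non-horizontal chain edge crosses exactly one
  # scanline, at the column of its lower-row endpoint
  cross_row <- pmin(r1[keep], r2[keep])          # 0-based
  cross_col <- ifelse(r1[keep] < r2[keep], c1[keep], c2[keep])
  for (r in unique(cross_row)) {
    xs <- sort(cross_col[cross_row == r])
    for (i in seq(1L, length(xs) - 1L, by = 2L)) {
      lo <- xs[i] + 1L; hi <- xs[i + 1L] - 1L
      if (lo <= hi) interior[r + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  interior[(points[, 2]) * shape[1] + points[, 1] + 1L] <- FALSE  # clear chain
  interior
}

# boundary-chain pixels as a logical matrix
contour_chain <- function(points, shape) {
  chain <- matrix(FALSE, shape[1], shape[2])
  chain[(points[, 2]) * shape[1] + points[, 1] + 1L] <- TRUE
  chain
}

#' Contour to masks (pipeline steps 4–5)
#'
#' Rasterizes a contour into `mask_binary` (boundary pixels foreground) and
#' `thick_mask` (everything outside the contour — including the boundary —
#' set to 255, the interior left 0).
#'
#' @param contour a `caries_contour`, or `NULL`.
#' @param shape integer `c(H, W)`; defaults to the contour's own shape.
#' @return list with elements `mask_binary` and `thick_mask`, both binary.
#'   A `NULL` contour degenerates to an all-255 `thick_mask`.
#' @export
contour_to_masks <- function(contour, shape = contour$shape) {
  if (is.null(contour)) {
    if (is.null(shape)) stop("shape required when contour is NULL", call. = FALSE)
    return(list(
      mask_binary = binary_image(matrix(0L, shape[1], shape[2]), "mask_binary"),
      thick_mask  = binary_image(matrix(255L, shape[1], shape[2]), "thick_mask")))
  }
  chain <- contour_chain(contour$points, shape)
  interior <- contour_interior(contour$points, shape)
  thick <- matrix(255L, shape[1], shape[2])
  thick[interior] <- 0L
  list(mask_binary = binary_image(chain, "mask_binary"),
       thick_mask  = binary_image(thick, "thick_mask"))
}

#' Mask inversion (pipeline step 6)
#'
#' Per-pixel `255 - v`. Inverting a `thick_mask` yields the tooth interior
#' image (`tooth_contour_img`).
#'
#' @param mask binary 0/255 matrix.
#' @return inverted binary matrix, role-tagged `tooth_contour_img` when the
#'   input role was `thick_mask`.
#' @export
invert_mask <- function(mask) {
  role <- attr(mask, "role")
  out_role <- if (identical(role, "thick_mask")) "tooth_contour_img"
              else paste0("inverted_", role %||% "mask")
  binary_image(255L - mask, out_role)
}

#' Saturated mask subtraction (pipeline step 7)
#'
#' Per-pixel `max(a - b, 0)`. With `a` the tooth interior image and `b` the
#' binary image, the result is foreground exactly where the tooth interior is
#' dark — the candidate carious-lesion image.
#'
#' @param a,b binary 0/255 matrices of equal shape.
#' @return binary matrix; role `lesion_area_img` when subtracting a
#'   `binary_img` from a `tooth_contour_img`.
#' @export
saturated_subtract <- function(a, b) {
  assert_same_shape(a, b)
  role <- if (identical(attr(a, "role"), "tooth_contour_img") &&
              identical(attr(b, "role"), "binary_img")) "lesion_area_img"
          else "difference"
  binary_image(pmax(a - b, 0L), role)
}

#' Lesion extraction (pipeline steps 1–10)
#'
#' Runs the full mask-algebra pipeline on one occlusal photograph: contrast
#' enhancement, grayscale conversion, binarization, tooth contour finding,
#' thick-mask construction, inversion, saturated subtraction, lesion contour
#' finding, and restoration of the original pixels inside the lesion contour.
#' Every intermediate mask is recorded. Deterministic: identical input and
#' configuration give identical output.
#'
#' @param img color image array (`H x W x 3`, 0..255).
#' @param cfg a [detect_config()].
#' @return object of class `caries_detection`: list with `intermediates`
#'   (named masks `gray_img`, `binary_img`, `mask_binary`, `thick_mask`,
#'   `tooth_contour_img`, `lesion_area_img`, and `mask_lesion` when a lesion
#'   contour exists), `tooth_contour`, `lesion_contour` (or `NULL`),
#'   `lesion_mask` (filled lesion region), `lesion_image` (white outside the
#'   lesion contour, original pixels inside), and `caries_detected`.
#' @export
extract_lesion <- function(img, cfg = detect_config()) {
  shape <- dim(img)[1:2]
  enh <- enhance_contrast(img, factor = cfg$contrast_factor,
                          equalize = cfg$equalize)
  gray <- to_grayscale(enh)
  bin <- binarize(gray, cfg$binarize_method, cfg$threshold)
  tooth_contour <- largest_contour(bin, min_area = cfg$min_tooth_area)
  if (is.null(tooth_contour)) stop("no tooth located", call. = FALSE)
  tm <- contour_to_masks(tooth_contour, shape)
  tooth_contour_img <- invert_mask(tm$thick_mask)
  lesion_area_img <- saturated_subtract(tooth_contour_img, bin)
  candidate <- lesion_area_img
  if (isTRUE(cfg$opening)) {
    brush <- EBImage::makeBrush(cfg$opening_size, shape = "box")
    opened <- EBImage::opening(EBImage::Image(t(candidate == 255)), brush)
    candidate <- binary_image(t(EBImage::imageData(opened)) > 0,
                              "lesion_area_img")
  }
  lesion_contour <- largest_contour(candidate)

  empty <- matrix(0L, shape[1], shape[2])
  if (is.null(lesion_contour)) {
    lesion_mask <- binary_image(empty, "mask_lesion")
    mask_lesion <- NULL
  } else {
    lm <- contour_to_masks(lesion_contour, shape)
    filled <- lm$thick_mask == 0 | lm$mask_binary == 255
    lesion_mask <- binary_image(filled, "mask_lesion")
    mask_lesion <- binary_image(255L - ifelse(filled, 255L, 0L), "mask_lesion")
  }
  lesion_image <- array(255, dim = dim(img))
  inside <- lesion_mask == 255
  for (ch in 1:3) {
    plane <- lesion_image[, , ch]
    plane[inside] <- img[, , ch][inside]
    lesion_image[, , ch] <- plane
  }
  caries_detected <- fg_count(lesion_mask) >= cfg$min_lesion_area

  intermediates <- list(gray_img = gray, binary_img = bin,
                        mask_binary = tm$mask_binary,
                        thick_mask = tm$thick_mask,
                        tooth_contour_img = tooth_contour_img,
                        lesion_area_img = lesion_area_img)
  if (!is.null(mask_lesion)) intermediates$mask_lesion <- mask_lesion
  structure(list(intermediates = intermediates,
                 tooth_contour = tooth_contour,
                 lesion_contour = lesion_contour,
                 lesion_mask = lesion_mask,
                 lesion_image = lesion_image,
                 caries_detected = caries_detected,
                 config = cfg),
            class = "caries_detection")
}

#' Tooth-region mask of a detection result
#'
#' Filled interior of the tooth contour (boundary included): the occlusal
#' surface the feature ratios are normalized by.
#'
#' @param det a `caries_detection`.
#' @return binary 0/255 matrix.
#' @export
tooth_region <- function(det) {
  filled <- det$intermediates$thick_mask == 0 |
    det$intermediates$mask_binary == 255
  binary_image(filled, "tooth_region")
}

#' @export
print.caries_detection <- function(x, ...) {
  cat("<caries_detection> ", paste(dim(x$intermediates$gray_img), collapse = " x "),
      " px; caries_detected = ", x$caries_detected,
      "; lesion area = ", fg_count(x$lesion_mask), " px\n", sep = "")
  invisible(x)
}

#' Write every pipeline intermediate to a directory
#'
#' @param det a `caries_detection`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
dump_intermediates <- function(det, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(det$intermediates)) {
    m <- det$intermediates[[nm]]
    png::writePNG(m / 255, file.path(dir, paste0(nm, ".png")))
  }
  write_mask(det$lesion_mask, file.path(dir, "lesion_mask.png"))
  write_image(det$lesion_image, file.path(dir, "lesion_image.png"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
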