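test_that("contrast enhancement follows the discrete CDF mapping and flattens histograms", {
  # degenerate: constant image passes through unchanged
  img <- flat_image(8, 8, c(128, 128, 128))
  expect_warning(out <- enhance_contrast(img), "degenerate")
  expect_identical(out, img)

  # two-level gray image {50, 200} at equal frequency: expected mapping
  # computed here from the discrete CDF, T(v) = round(255 (F(v) - Fmin) / (n - Fmin))
  m <- matrix(c(rep(50, 32), rep(200, 32)), 8, 8)
  counts <- c(`50` = 32, `200` = 32)
  cdf <- cumsum(counts)
  expected <- round(255 * (cdf - cdf[1]) / (64 - cdf[1]))  # 0 and 255
  out <- enhance_contrast(gray_as_rgb(m), factor = 1, equalize = TRUE)
  g <- to_grayscale(out)
  expect_setequal(unique(as.vector(g)), unname(expected))
  expect_true(all(g[m == 50] < g[m == 200]))  # ranking preserved

  # any image: luminance histogram at least as flat (chi^2 vs uniform)
  set.seed(42)
  noisy <- matrix(pmin(pmax(round(c(rnorm(500, 80, 10), rnorm(524, 190, 12))), 0), 255), 32, 32)
  before <- chi2_vs_uniform(noisy)
  eq <- to_grayscale(enhance_contrast(gray_as_rgb(noisy), factor = 1))
  expect_lte(chi2_vs_uniform(eq), before)
})

test_that("grayscale conversion is BT.601 luma", {
  expect_equal(to_grayscale(flat_image(2, 2, c(255, 255, 255)))[1, 1], 255L)
  expect_equal(to_grayscale(flat_image(2, 2, c(255, 0, 0)))[1, 1], 76L)
  m <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  expect_equal(to_grayscale(gray_as_rgb(m)), matrix(as.integer(m), 8, 8))
})

test_that("Otsu binarization matches an exhaustive threshold scan", {
  set.seed(1)
  # bimodal image, modes 40 and 220 at equal mass
  g <- matrix(sample(c(rep(40, 128), rep(220, 128))), 16, 16)
  b <- binarize(g, "otsu")
  thr <- attr(b, "threshold")
  expect_gt(thr, 40); expect_lt(thr, 220)
  expect_equal(sum(b == 255), 128)
  # partition agrees with the exhaustive-scan oracle on noisy bimodal data
  for (s in 1:5) {
    set.seed(s)
    g <- matrix(pmin(pmax(round(c(rnorm(120, 60, 12), rnorm(136, 200, 15))), 0), 255), 16, 16)
    t_oracle <- oracle_otsu_thresholds(g)
    b <- binarize(g, "otsu")
    expect_true(any(vapply(t_oracle, function(t)
      identical(b == 255, g > t), logical(1))),
      info = paste("seed", s))
  }
})

test_that("fixed-threshold binarization is idempotent and respects the strict rule", {
  g <- matrix(sample(1:255, 64, replace = TRUE), 8, 8)
  b <- binarize(g, "fixed", threshold = 0)
  expect_true(all(b == 255))
  b1 <- binarize(g, "fixed", threshold = 128)
  b2 <- binarize(b1, "fixed", threshold = 128)
  expect_equal(b1, b2, ignore_attr = TRUE)
  expect_warning(bc <- binarize(matrix(7L, 4, 4), "otsu"), "constant")
  expect_true(all(bc == 0))
})

test_that("largest contour picks the component with maximum enclosed area", {
  expect_null(largest_contour(matrix(0L, 10, 10)))
  m <- matrix(0L, 30, 30)
  m[3:12, 3:12] <- 255L   # 10x10
  m[20:22, 20:22] <- 255L # 3x3
  ct <- largest_contour(binary_image(m))
  expect_equal(ct$area, 100)
  expect_true(all(ct$points[, 1] >= 2 & ct$points[, 1] <= 11))  # 0-based rows
  # enclosed area counts filled holes
  ring <- matrix(0L, 20, 20)
  ring[5:15, 5:15] <- 255L
  ring[8:12, 8:12] <- 0L
  expect_equal(largest_contour(binary_image(ring))$area, 121)
  # single-pixel component is degenerate and removable by min_area
  px <- matrix(0L, 5, 5); px[3, 3] <- 255L
  expect_lte(largest_contour(binary_image(px))$area, 1)
  expect_null(largest_contour(binary_image(px), min_area = 2))
})

test_that("contour rasterization separates boundary, interior and outside", {
  sq <- rect_mask(100, 100, 40:59, 30:69)
  ct <- largest_contour(sq)
  masks <- contour_to_masks(ct, c(100, 100))
  expect_true(is_binary_image(masks$mask_binary))
  expect_true(is_binary_image(masks$thick_mask))
  # interior pixel count = strict inside of a 20x40 rectangle
  expect_equal(sum(masks$thick_mask == 0), 18 * 38)
  # boundary is foreground in mask_binary and excluded from the interior
  expect_true(all(masks$thick_mask[masks$mask_binary == 255] == 255))

  # contour tracing the full image border -> interior is all but the border
  full <- binary_image(matrix(255L, 20, 20))
  mf <- contour_to_masks(largest_contour(full), c(20, 20))
  expect_equal(sum(mf$thick_mask == 0), 18 * 18)

  # none contour -> thick mask all 255
  mn <- contour_to_masks(NULL, shape = c(7, 9))
  expect_true(all(mn$thick_mask == 255))
  expect_true(all(mn$mask_binary == 0))
})

test_that("mask inversion and saturated subtraction obey their algebra", {
  m <- rect_mask(10, 10, 2:5, 3:8)
  expect_equal(invert_mask(invert_mask(m)), m, ignore_attr = TRUE)
  expect_true(all(invert_mask(binary_image(matrix(255L, 4, 4))) == 0))
  thick <- binary_image(ifelse(matrix(runif(100), 10, 10) < 0.4, 255L, 0L),
                        role = "thick_mask")
  tci <- invert_mask(thick)
  expect_equal(attr(tci, "role"), "tooth_contour_img")
  expect_equal(sum(tci == 255), 100 - sum(thick == 255))

  expect_true(all(saturated_subtract(m, m) == 0))
  zero <- binary_image(matrix(0L, 10, 10))
  expect_equal(saturated_subtract(m, zero), m, ignore_attr = TRUE)
  expect_error(saturated_subtract(m, binary_image(matrix(0L, 5, 5))),
               "shapes differ")
  # tooth interior 40x25 = 1000 px with 120 dark pixels -> 120 px lesion area
  tooth_interior <- rect_mask(60, 60, 11:50, 11:35)
  attr(tooth_interior, "role") <- "tooth_contour_img"
  bright <- matrix(255L, 60, 60)
  bright[15:26, 15:24] <- 0L  # 120 dark px inside the interior
  bin <- binary_image(bright, role = "binary_img")
  lesion <- saturated_subtract(tooth_interior, bin)
  expect_equal(attr(lesion, "role"), "lesion_area_img")
  expect_equal(sum(lesion == 255), 120)
})

test_that("lesion extraction finds planted lesions, stays silent on sound teeth, and never crashes on artifacts", {
  # sound tooth: no caries reported
  ph0 <- generate_phantom(phantom_spec("NSC", seed = 101))
  det0 <- extract_lesion(ph0$image)
  expect_false(det0$caries_detected)

  # planted dark blob: recovered with >= 60% coverage of the ground truth
  ph1 <- generate_phantom(phantom_spec("C", seed = 102))
  det1 <- extract_lesion(ph1$image)
  expect_true(det1$caries_detected)
  ov <- overlap_fraction(det1$lesion_mask, ph1$lesion_mask)
  expect_gte(ov$overlap, 0.6)

  # specular highlight on a sound tooth: documented failure mode, no crash
  ph2 <- generate_phantom(phantom_spec("NSC", seed = 103,
    artifact_rates = list(specular = 1, stain = 0, plaque = 0)))
  det2 <- expect_no_error(extract_lesion(ph2$image))
  expect_type(det2$caries_detected, "logical")

  # all-dark image: no tooth to find
  dark <- flat_image(32, 32, c(10, 10, 10))
  expect_error(suppressWarnings(extract_lesion(dark)), "no tooth located")
})

test_that("the pipeline is pure and its intermediates satisfy the mask invariants", {
  ph <- generate_phantom(phantom_spec("VNC", seed = 104))
  d1 <- extract_lesion(ph$image)
  d2 <- extract_lesion(ph$image)
  expect_identical(d1$intermediates, d2$intermediates)
  expect_identical(d1$lesion_mask, d2$lesion_mask)
  for (nm in setdiff(names(d1$intermediates), "gray_img"))
    expect_true(is_binary_image(d1$intermediates[[nm]]), info = nm)
  # lesion candidates lie inside the tooth interior
  expect_true(all(d1$intermediates$tooth_contour_img[
    d1$intermediates$lesion_area_img == 255] == 255))
  # detection gate matches the configured minimum lesion area
  expect_equal(d1$caries_detected,
               sum(d1$lesion_mask == 255) >= d1$config$min_lesion_area)
})

test_that("candidate lesion image equals a brute-force point-in-polygon set difference", {
  cfg <- detect_config()
  for (s in 1:4) {
    cl <- c("VNC", "C", "VNC", "C")[s]
    ph <- generate_phantom(phantom_spec(cl, seed = 300 + s, canvas = c(64L, 64L)))
    enh <- enhance_contrast(ph$image, cfg$contrast_factor, cfg$equalize)
    g <- to_grayscale(enh)
    b <- binarize(g)
    tc <- largest_contour(b, min_area = cfg$min_tooth_area)
    lesion <- saturated_subtract(invert_mask(contour_to_masks(tc, dim(g))$thick_mask), b)
    grid <- expand.grid(row = 0:(nrow(g) - 1), col = 0:(ncol(g) - 1))
    inside <- pracma::inpolygon(grid$col, grid$row,
                                tc$points[, 2], tc$points[, 1],
                                boundary = FALSE)
    oracle <- matrix(FALSE, nrow(g), ncol(g))
    oracle[cbind(grid$row + 1, grid$col + 1)] <- inside
    oracle <- oracle & (b == 0)
    expect_identical(unname(lesion == 255), unname(oracle), label = paste("seed", 300 + s))
  }
})

test_that("intermediates can be dumped as PNGs with their stage names", {
  ph <- generate_phantom(phantom_spec("C", seed = 105, canvas = c(64L, 64L)))
  det <- extract_lesion(ph$image)
  dir <- withr::local_tempdir()
  dump_intermediates(det, dir)
  expect_true(all(file.exists(file.path(dir, paste0(
    c("gray_img", "binary_img", "mask_binary", "thick_mask",
      "tooth_contour_img", "lesion_area_img"), ".png")))))
  rt <- read_mask(file.path(dir, "lesion_mask.png"))
  expect_equal(rt, det$lesion_mask, ignore_attr = TRUE)
})
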