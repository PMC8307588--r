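test_that("bounding rectangle and length/width are exact on constructed masks", {
  expect_equal(unlist(bounding_rect(binary_image(matrix(0L, 6, 6)))),
               c(top = 0L, left = 0L, height = 0L, width = 0L))
  one <- matrix(0L, 10, 10); one[6, 8] <- 255L
  r <- bounding_rect(binary_image(one))
  expect_equal(unlist(r), c(top = 5L, left = 7L, height = 1L, width = 1L))
  # 20 rows x 10 cols of foreground -> that rectangle exactly
  r2 <- bounding_rect(rect_mask(40, 40, 5:24, 11:20))
  expect_equal(unlist(r2), c(top = 4L, left = 10L, height = 20L, width = 10L))
  expect_equal(length_width(r2), c(length = 20L, width = 10L))
  # orientation-invariant
  r3 <- bounding_rect(rect_mask(40, 40, 5:14, 11:30))
  expect_equal(length_width(r3), c(length = 20L, width = 10L))
  expect_equal(length_width(bounding_rect(rect_mask(20, 20, 3:17, 3:17))),
               c(length = 15L, width = 15L))
})

test_that("area ratio is lesion-over-tooth pixel counting", {
  tooth <- rect_mask(120, 120, 11:110, 11:110)  # 10000 px
  lesion <- rect_mask(120, 120, 51:60, 51:70)   # 200 px inside
  expect_equal(area_ratio(lesion, tooth), 0.02)
  expect_equal(area_ratio(tooth, tooth), 1)
  expect_equal(area_ratio(binary_image(matrix(0L, 120, 120)), tooth), 0)
  expect_error(area_ratio(lesion, binary_image(matrix(0L, 120, 120))),
               "no occlusal surface")
})

test_that("convex area matches the half-plane brute force on small grids", {
  tooth <- binary_image(matrix(255L, 32, 32))  # 1024 px
  # convex lesion: hull adds nothing
  rect <- rect_mask(32, 32, 10:15, 8:19)
  expect_equal(convex_area(rect, tooth), area_ratio(rect, tooth))
  # L-shaped lesion: hull strictly larger
  L <- matrix(0L, 32, 32)
  L[5:20, 5:8] <- 255L
  L[17:20, 5:20] <- 255L
  L <- binary_image(L)
  expect_gt(convex_area(L, tooth), area_ratio(L, tooth))
  expect_equal(convex_area(L, tooth), oracle_hull_area(L) / 1024)
  # random blobs against the oracle
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(0L, 24, 24)
    pts <- cbind(sample(4:20, 12, TRUE), sample(4:20, 12, TRUE))
    m[pts] <- 255L
    m <- binary_image(m)
    t24 <- binary_image(matrix(255L, 24, 24))
    expect_equal(convex_area(m, t24), oracle_hull_area(m) / 576,
                 info = paste("seed", s))
  }
  # collinear one-pixel-wide line: hull degenerates to the line itself
  line <- rect_mask(32, 32, 10:18, 12:12)
  expect_equal(convex_area(line, tooth), area_ratio(line, tooth))
})

test_that("smoothness is the variance-based texture descriptor", {
  mask <- rect_mask(10, 10, 3:6, 3:6)
  expect_equal(smoothness(matrix(77L, 10, 10), mask), 0)
  # half 0 / half 255: variance on [0,1] is 0.25 -> S = 1 - 1/1.25 = 0.2
  g <- matrix(0L, 10, 10)
  g[3:6, 3:4] <- 0L; g[3:6, 5:6] <- 255L
  expect_equal(smoothness(g, mask), 0.2)
  expect_equal(smoothness(matrix(5L, 4, 4), binary_image(matrix(0L, 4, 4))), 0)
  # monotone in spread
  spreads <- c(10, 40, 90, 127)
  s_vals <- vapply(spreads, function(d) {
    g <- matrix(128L, 10, 10)
    g[3:6, 3:4] <- 128L - d; g[3:6, 5:6] <- 128L + d
    smoothness(g, mask)
  }, numeric(1))
  expect_true(all(diff(s_vals) > 0))
  expect_true(all(s_vals >= 0 & s_vals < 1))
})

test_that("feature extraction composes the five descriptors and zeroes non-detections", {
  tooth <- rect_mask(120, 120, 11:110, 11:110)      # 10000 px
  lesion <- rect_mask(120, 120, 41:60, 31:40)       # 20 x 10 rectangle
  gray <- matrix(40L, 120, 120)
  det <- detection_stub(lesion, gray)
  f <- extract_features(det, gray = gray, tooth_mask = tooth)
  expect_equal(unlist(f),
               c(length = 20, width = 10, smoothness = 0,
                 ratio = 0.02, convex_area = 0.02))
  # non-detection -> the all-zero row
  f0 <- extract_features(detection_stub(lesion, gray, detected = FALSE))
  expect_equal(unlist(f0), setNames(rep(0, 5), names(unlist(f0))))
  # contract invariants on a detected phantom lesion
  ph <- generate_phantom(phantom_spec("C", seed = 21))
  d <- extract_lesion(ph$image)
  fv <- extract_features(d, gray = to_grayscale(ph$image))
  expect_gte(fv$length, fv$width)
  expect_lte(fv$ratio, fv$convex_area)
  expect_lte(fv$convex_area, 1)
  expect_lt(fv$smoothness, 1)
})

test_that("features are invariant to joint translation", {
  base_lesion <- rect_mask(100, 100, 30:44, 20:31)
  base_tooth <- rect_mask(100, 100, 11:90, 11:90)
  set.seed(3)
  gray <- matrix(sample(0:255, 1e4, TRUE), 100, 100)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  f1 <- extract_features(detection_stub(base_lesion, gray),
                         gray = gray, tooth_mask = base_tooth)
  f2 <- extract_features(
    detection_stub(binary_image(shift(base_lesion, 5, 7)), NULL),
    gray = shift(gray, 5, 7),
    tooth_mask = binary_image(shift(base_tooth, 5, 7)))
  expect_equal(f1, f2)
})

test_that("feature recovery from phantom ground truth is exact for rectangles and close for ellipses", {
  # planted rectangle via the ground-truth path: dimensions recovered exactly
  tooth <- rect_mask(150, 150, 11:140, 11:140)
  lesion <- rect_mask(150, 150, 60:79, 50:59)
  f <- extract_features(detection_stub(lesion, matrix(0L, 150, 150)),
                        gray = matrix(0L, 150, 150), tooth_mask = tooth)
  expect_equal(c(f$length, f$width), c(20, 10))
  # elliptical phantom lesions: ground-truth area ratio within 5 percent
  for (s in 1:5) {
    ph <- generate_phantom(phantom_spec("C", seed = 700 + s))
    sp <- ph$spec$lesion
    # closed-form blob area: aspect * integral of r(phi)^2 / 2 over the circle
    expected_area <- pi * sp$r0^2 * sp$aspect *
      (1 + (sp$harm$a1^2 + sp$harm$a2^2) / 2)
    got <- sum(ph$lesion_mask == 255)
    expect_lt(abs(got - expected_area) / expected_area, 0.05,
              label = paste("seed", 700 + s))
  }
})

test_that("feature tables round-trip through CSV losslessly", {
  rec <- tibble::tibble(id = c("a", "b", "c"),
                        length = c(20, 0, 7.5), width = c(10, 0, 3.25),
                        smoothness = c(0.2, 0, 0.125),
                        ratio = c(0.02, 0, 0.004),
                        convex_area = c(0.02, 0, 0.005),
                        label = c("C", "NSC", NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(rec, path)
  back <- read_feature_table(path)
  expect_equal(back, rec)
  # header-only file
  write_feature_table(rec[0, ], path)
  expect_equal(nrow(read_feature_table(path)), 0)
  expect_equal(readLines(path)[1],
               "\"id\",\"length\",\"width\",\"smoothness\",\"ratio\",\"convex_area\",\"label\"")
  # malformed row reported with its line number
  writeLines(c("\"id\",\"length\",\"width\",\"smoothness\",\"ratio\",\"convex_area\",\"label\"",
               "x,1,2,0.1,,0.2,C"), path)
  expect_error(read_feature_table(path), "line 2")
})
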