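# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation they check.

# exhaustive Otsu: all 256 candidate thresholds, between-class variance
# computed from first principles; returns every argmax threshold
oracle_otsu_thresholds <- function(gray) {
  v <- as.vector(gray)
  n <- length(v)
  sigma_b <- vapply(0:255, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) return(-Inf)
    w0 <- length(lo) / n; w1 <- 1 - w0
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  (0:255)[sigma_b == max(sigma_b)]
}

# half-plane convex-hull membership: a grid point is in the hull of the
# foreground pixel centers iff no supporting line through two foreground
# points separates it from the rest
oracle_hull_area <- function(mask) {
  pts <- which(mask == 255, arr.ind = TRUE)  # (row, col)
  np <- nrow(pts)
  if (np == 0L) return(0L)
  if (np <= 2L) return(np)
  grid <- as.matrix(expand.grid(row = seq_len(nrow(mask)),
                                col = seq_len(ncol(mask))))
  inside <- rep(TRUE, nrow(grid))
  eps <- 1e-9
  collinear <- TRUE
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (i == j) next
      a <- pts[i, ]; b <- pts[j, ]
      d <- b - a
      cr_pts <- d[1] * (pts[, 2] - a[2]) - d[2] * (pts[, 1] - a[1])
      if (any(abs(cr_pts) > eps)) collinear <- FALSE
      if (all(cr_pts >= -eps)) {  # supporting line: all foreground on one side
        cr_grid <- d[1] * (grid[, 2] - a[2]) - d[2] * (grid[, 1] - a[1])
        inside <- inside & (cr_grid >= -eps)
      }
    }
  }
  if (collinear) return(nrow(unique(pts)))
  sum(inside)
}

# AUC by enumerating every positive-negative pair, ties worth one half
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# chi-squared statistic of an intensity histogram against uniform, over
# coarse bins (flatness of the distribution's shape, not of individual
# 8-bit levels, which equalization merely relocates)
chi2_vs_uniform <- function(v, nbins = 16L) {
  h <- tabulate(pmin(floor(v / 256 * nbins), nbins - 1L) + 1L, nbins = nbins)
  e <- length(v) / nbins
  sum((h - e)^2 / e)
}

# constant-color test image
flat_image <- function(h, w, rgb) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  carieslens::color_image(img)
}

# grayscale matrix replicated into three channels
gray_as_rgb <- function(m) {
  carieslens::color_image(array(rep(m, 3L), dim = c(dim(m), 3L)))
}

# rectangular 0/255 mask
rect_mask <- function(h, w, rows, cols) {
  m <- matrix(0L, h, w)
  m[rows, cols] <- 255L
  carieslens::binary_image(m)
}

# minimal detection-result stub for feature tests (only the fields
# extract_features() reads)
detection_stub <- function(lesion_mask, gray, detected = TRUE) {
  structure(list(caries_detected = detected, lesion_mask = lesion_mask,
                 intermediates = list(gray_img = gray)),
            class = "caries_detection")
}
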