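# Class-conditional lesion appearance ranges. The cavitated (C) range is
# strictly deeper and larger than the visually non-cavitated (VNC) range:
# late lesions are darker and at least ~2x the area of early ones on average.
# Radii are fractions of the tooth's minor semi-axis so phantoms scale with
# the canvas.
.lesion_ranges <- list(
  VNC = list(r0 = c(0.10, 0.21), depth = c(60, 90)),
  C   = list(r0 = c(0.19, 0.33), depth = c(120, 170))
)

#' Specify a tooth phantom
#'
#' Draws a fully-determined rendering specification for one synthetic
#' occlusal-surface photograph: a bright, roughly elliptical tooth with a
#' gentle radial shading gradient on a dark background, dark fissure lines,
#' a class-conditioned lesion blob (absent for NSC, shallow-contrast for VNC,
#' dark and large for C), and optional confounder artifacts (specular
#' highlight with an under-exposed surround, dark extrinsic-stain speckles,
#' an enamel-colored plaque patch). All random choices happen here, so
#' [generate_phantom()] is a pure function of the returned spec.
#'
#' @param class `"NSC"`, `"VNC"` or `"C"`.
#' @param seed integer seed; drives every random choice in the spec and the
#'   rendering noise.
#' @param canvas `c(H, W)` in pixels.
#' @param artifact_rates named list of Bernoulli rates for `specular`,
#'   `stain` and `plaque` layers (all 0 by default: clean phantoms).
#' @param noise_sd Gaussian pixel-noise standard deviation (8-bit units).
#' @return a list of class `caries_phantom_spec`.
#' @export
phantom_spec <- function(class = c("NSC", "VNC", "C"), seed,
                         canvas = c(160L, 160L),
                         artifact_rates = list(specular = 0, stain = 0,
                                               plaque = 0),
                         noise_sd = 2.5) {
  class <- match.arg(class)
  stopifnot(length(canvas) == 2L, all(canvas >= 64L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed %% 2147483647))

  h <- canvas[1]; w <- canvas[2]
  tooth <- list(
    center = c(h / 2 + runif(1, -6, 6), w / 2 + runif(1, -6, 6)),
    semi_axes = c(runif(1, 0.30, 0.36) * h, runif(1, 0.27, 0.33) * w),
    rotation = runif(1, 0, pi),
    color = c(232, 222, 210),
    shading = 0.08)

  n_f <- sample(2:4, 1)
  fissures <- lapply(seq_len(n_f), function(i) list(
    angle = runif(1, 0, pi),
    offset = runif(1, -0.25, 0.25),
    amp = runif(1, 2, 5),
    freq = runif(1, 0.8, 2),
    phase = runif(1, 0, 2 * pi),
    width = sample(1:2, 1),
    depth = runif(1, 10, 18),
    extent = runif(1, 0.45, 0.6)))

  lesion <- NULL
  if (class != "NSC") {
    rg <- .lesion_ranges[[class]]
    lesion <- list(
      center_polar = c(runif(1, 0, 0.45), runif(1, 0, 2 * pi)),
      r0 = runif(1, rg$r0[1], rg$r0[2]) * min(tooth$semi_axes),
      aspect = runif(1, 0.7, 1),
      rotation = runif(1, 0, pi),
      harm = list(a1 = runif(1, 0, 0.2), p1 = runif(1, 0, 2 * pi),
                  a2 = runif(1, 0, 0.15), p2 = runif(1, 0, 2 * pi)),
      depth = runif(1, rg$depth[1], rg$depth[2]))
  }

  rate <- function(nm) {
    r <- artifact_rates[[nm]]
    if (is.null(r)) 0 else r
  }
  specular <- NULL
  if (runif(1) < rate("specular")) {
    specular <- lapply(seq_len(sample(1:2, 1)), function(i) list(
      center_polar = c(runif(1, 0, 0.55), runif(1, 0, 2 * pi)),
      radius = runif(1, 4, 7),
      penumbra_width = runif(1, 3, 5),
      penumbra_depth = runif(1, 65, 85)))
  }
  stains <- NULL
  if (runif(1) < rate("stain")) {
    stains <- lapply(seq_len(sample(3:8, 1)), function(i) list(
      center_polar = c(runif(1, 0, 0.8), runif(1, 0, 2 * pi)),
      radius = runif(1, 1.2, 3),
      depth = c(runif(1, 80, 110), runif(1, 90, 120), runif(1, 110, 140))))
  }
  plaque <- NULL
  if (runif(1) < rate("plaque")) {
    plaque <- list(center_polar = c(runif(1, 0, 0.5), runif(1, 0, 2 * pi)),
                   radius = runif(1, 9, 14), opacity = runif(1, 0.35, 0.6),
                   color = c(214, 208, 176))
  }

  structure(list(canvas = c(h, w), seed = as.integer(seed %% 2147483647),
                 label = class, background = c(26, 28, 32),
                 noise_sd = noise_sd, tooth = tooth, fissures = fissures,
                 lesion = lesion,
                 artifacts = list(specular = specular, stains = stains,
                                  plaque = plaque)),
            class = "caries_phantom_spec")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# unit-ellipse coordinates of every pixel relative to the tooth:
# list(u, v) scaled so u^2 + v^2 <= 1 is the tooth
.tooth_coords <- function(spec) {
  h <- spec$canvas[1]; w <- spec$canvas[2]
  rr <- matrix(seq_len(h), h, w) - spec$tooth$center[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - spec$tooth$center[2]
  th <- spec$tooth$rotation
  u <- (cos(th) * cc + sin(th) * rr) / spec$tooth$semi_axes[2]
  v <- (-sin(th) * cc + cos(th) * rr) / spec$tooth$semi_axes[1]
  list(u = u, v = v, rr = rr, cc = cc)
}

# pixel-space position of a point given in tooth polar coordinates
.polar_to_px <- function(spec, rho, ang) {
  th <- spec$tooth$rotation
  du <- rho * cos(ang) * spec$tooth$semi_axes[2]
  dv <- rho * sin(ang) * spec$tooth$semi_axes[1]
  c(row = spec$tooth$center[1] + sin(th) * du + cos(th) * dv,
    col = spec$tooth$center[2] + cos(th) * du - sin(th) * dv)
}

# logical mask of an irregular lesion blob; NULL lesion -> all-FALSE
.lesion_blob <- function(spec) {
  h <- spec$canvas[1]; w <- spec$canvas[2]
  les <- spec$lesion
  if (is.null(les)) return(matrix(FALSE, h, w))
  ctr <- .polar_to_px(spec, les$center_polar[1], les$center_polar[2])
  rr <- matrix(seq_len(h), h, w) - ctr["row"]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr["col"]
  ps <- les$rotation
  u <- cos(ps) * cc + sin(ps) * rr
  v <- (-sin(ps) * cc + cos(ps) * rr) / les$aspect
  ang <- atan2(v, u)
  rmod <- les$r0 * (1 + les$harm$a1 * sin(ang + les$harm$p1) +
                      les$harm$a2 * sin(2 * ang + les$harm$p2))
  d <- sqrt(u^2 + v^2)
  list(mask = d < rmod, d_rel = pmin(d / pmax(rmod, 1e-9), 1))
}

.disc_mask <- function(spec, center_polar, radius) {
  h <- spec$canvas[1]; w <- spec$canvas[2]
  ctr <- .polar_to_px(spec, center_polar[1], center_polar[2])
  rr <- matrix(seq_len(h), h, w) - ctr["row"]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr["col"]
  sqrt(rr^2 + cc^2) < radius
}

#' Render a tooth phantom
#'
#' Pure function of a [phantom_spec()]: renders background, shaded tooth
#' ellipse, fissures, the class-conditioned lesion, artifacts, then Gaussian
#' noise, clipping to 0..255. Ground-truth masks are rendered before noise
#' and are therefore noise-independent. Identical specs give bit-identical
#' samples.
#'
#' @param spec a `caries_phantom_spec`.
#' @return object of class `caries_phantom`: list with `image` (color array),
#'   `tooth_mask` and `lesion_mask` (binary ground truth), `label`, `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "caries_phantom_spec"))
  h <- spec$canvas[1]; w <- spec$canvas[2]
  tc <- .tooth_coords(spec)
  rho2 <- tc$u^2 + tc$v^2
  tooth <- rho2 <= 1

  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- spec$background[ch]
  shade <- 1 - spec$tooth$shading * rho2
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[tooth] <- (spec$tooth$color[ch] * shade)[tooth]
    img[, , ch] <- plane
  }

  # fissures: wobbly dark lines through the inner occlusal region
  for (f in spec$fissures) {
    t_seq <- seq(-f$extent, f$extent, length.out = 4 * max(h, w))
    wob <- f$amp * sin(2 * pi * f$freq * t_seq + f$phase)
    # straight path through the tooth center in direction f$angle with
    # perpendicular sinusoidal wobble, in pixel space
    dirv <- c(sin(f$angle), cos(f$angle))
    perp <- c(-dirv[2], dirv[1])
    half_len <- f$extent * min(spec$tooth$semi_axes)
    ctr <- spec$tooth$center + f$offset * min(spec$tooth$semi_axes) * perp
    pr <- round(ctr[1] + t_seq / f$extent * half_len * dirv[1] + wob * perp[1])
    pc <- round(ctr[2] + t_seq / f$extent * half_len * dirv[2] + wob * perp[2])
    keep <- pr >= 1 & pr <= h & pc >= 1 & pc <= w
    pix <- unique(cbind(pr[keep], pc[keep]))
    if (f$width >= 2 && nrow(pix) > 0) {
      pix <- unique(rbind(pix, cbind(pix[, 1] + 1L, pix[, 2]),
                          cbind(pix[, 1], pix[, 2] + 1L)))
      pix <- pix[pix[, 1] <= h & pix[, 2] <= w, , drop = FALSE]
    }
    if (nrow(pix) > 0) {
      idx <- (pix[, 2] - 1L) * h + pix[, 1]
      inner <- rho2[idx] < 0.6  # fissures stay in the inner region
      idx <- idx[inner]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- plane[idx] - f$depth
        img[, , ch] <- plane
      }
    }
  }

  # lesion: irregular blob, deeper toward its center, brownish tint
  blob <- .lesion_blob(spec)
  lesion_mask_log <- if (is.null(spec$lesion)) matrix(FALSE, h, w) else blob$mask
  if (!is.null(spec$lesion)) {
    if (any(lesion_mask_log & rho2 > 1))
      stop("lesion outside tooth", call. = FALSE)
    depth_map <- spec$lesion$depth * (0.85 + 0.3 * (1 - blob$d_rel^2))
    tint <- c(1, 1.05, 1.3)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[blob$mask] <- plane[blob$mask] -
        (depth_map * tint[ch])[blob$mask]
      img[, , ch] <- plane
    }
  }

  # artifacts
  for (sp in spec$artifacts$specular %||% list()) {
    hot <- .disc_mask(spec, sp$center_polar, sp$radius) & tooth
    ring <- .disc_mask(spec, sp$center_polar, sp$radius + sp$penumbra_width) &
      !(.disc_mask(spec, sp$center_polar, sp$radius)) & tooth
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[hot] <- plane[hot] + 0.9 * (255 - plane[hot])
      plane[ring] <- plane[ring] - sp$penumbra_depth
      img[, , ch] <- plane
    }
  }
  for (st in spec$artifacts$stains %||% list()) {
    m <- .disc_mask(spec, st$center_polar, st$radius) & tooth
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- plane[m] - st$depth[ch]
      img[, , ch] <- plane
    }
  }
  if (!is.null(spec$artifacts$plaque)) {
    pl <- spec$artifacts$plaque
    m <- .disc_mask(spec, pl$center_polar, pl$radius) & tooth
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- (1 - pl$opacity) * plane[m] + pl$opacity * pl$color[ch]
      img[, , ch] <- plane
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed((spec$seed + 1L) %% 2147483647)
  if (spec$noise_sd > 0)
    img <- img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
  img <- round(pmin(pmax(img, 0), 255))

  structure(list(id = NULL,
                 image = color_image(img),
                 tooth_mask = binary_image(tooth, "ground_truth"),
                 lesion_mask = binary_image(lesion_mask_log, "ground_truth"),
                 label = spec$label, spec = spec),
            class = "caries_phantom")
}

#' @export
print.caries_phantom <- function(x, ...) {
  cat("<caries_phantom> label =", x$label, "| lesion",
      fg_count(x$lesion_mask), "px | tooth", fg_count(x$tooth_mask), "px\n")
  invisible(x)
}

# per-sample child seed derived from the master seed; stable under
# regeneration of subsets, always below 2^31
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + 7919 * as.numeric(i)) %% 2147483629)
}

#' Generate a phantom dataset
#'
#' Renders `n_nsc + n_vnc + n_c` phantoms with per-sample seeds derived from
#' the master seed, and builds a manifest. When `dir` is given, images and
#' ground-truth masks are written as PNGs, the manifest as CSV, and each
#' sample's spec as YAML.
#'
#' @param n_nsc,n_vnc,n_c samples per class. The study's class balance is
#'   roughly 73:220:294 (NSC:VNC:C); pass counts in that proportion for a
#'   dataset resembling it.
#' @param seed master seed.
#' @param artifact_rates passed to [phantom_spec()].
#' @param canvas passed to [phantom_spec()].
#' @param dir optional output directory.
#' @return list with `samples` (list of `caries_phantom`, each with `id` set)
#'   and `manifest` (tibble: id, image, tooth_mask, lesion_mask, label, seed).
#' @export
generate_dataset <- function(n_nsc, n_vnc, n_c, seed,
                             artifact_rates = list(specular = 0, stain = 0,
                                                   plaque = 0),
                             canvas = c(160L, 160L), dir = NULL) {
  stopifnot(n_nsc >= 0, n_vnc >= 0, n_c >= 0)
  labels <- c(rep("NSC", n_nsc), rep("VNC", n_vnc), rep("C", n_c))
  n <- length(labels)
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    child <- derive_seed(seed, i)
    sp <- phantom_spec(labels[i], seed = child, canvas = canvas,
                       artifact_rates = artifact_rates)
    s <- generate_phantom(sp)
    s$id <- sprintf("ph%04d_%s", i, labels[i])
    samples[[i]] <- s
    paths <- c(image = NA_character_, tooth = NA_character_,
               lesion = NA_character_)
    if (!is.null(dir)) {
      paths["image"] <- file.path(dir, paste0(s$id, ".png"))
      paths["tooth"] <- file.path(dir, paste0(s$id, "_tooth.png"))
      paths["lesion"] <- file.path(dir, paste0(s$id, "_lesion.png"))
      write_image(s$image, paths["image"])
      write_mask(s$tooth_mask, paths["tooth"])
      write_mask(s$lesion_mask, paths["lesion"])
      yaml::write_yaml(rapply(unclass(sp), as.vector, how = "replace"),
                       file.path(dir, paste0(s$id, ".yaml")))
    }
    rows[[i]] <- tibble::tibble(id = s$id, image = paths[["image"]],
                                tooth_mask = paths[["tooth"]],
                                lesion_mask = paths[["lesion"]],
                                label = labels[i], seed = child)
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  list(samples = samples, manifest = manifest)
}
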