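# The expressive triad: structure, color, and texture features from
# the interior portion of the face.

#' Similarity-normalize a landmark set
#'
#' Aligns landmarks so the eye midpoint sits at the origin, the eye
#' line is horizontal, and the interocular distance equals 1. The
#' output is invariant (to ~1e-6) under translation, rotation and
#' uniform scaling of the input; structure features computed from it
#' therefore measure shape only.
#'
#' @param landmarks 42x2 matrix on the fixed template (pixel
#'   coordinates, x rightward, y downward).
#' @return object of class `normalized_landmarks` with `points`
#'   (42x2, unitless).
#' @export
normalize_landmarks <- function(landmarks) {
  stopifnot(is.matrix(landmarks), nrow(landmarks) == 42,
            ncol(landmarks) == 2, all(is.finite(landmarks)))
  ec <- eye_centers(landmarks)
  v <- ec["right", ] - ec["left", ]
  iod <- sqrt(sum(v^2))
  if (iod < 1e-8) stop("degenerate landmarks: eye centers coincide")
  mid <- colMeans(ec)
  ang <- atan2(v[2], v[1])
  R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
  pts <- sweep(landmarks, 2, mid) %*% t(R) / iod
  colnames(pts) <- c("x", "y")
  structure(list(points = pts), class = "normalized_landmarks")
}

#' Interior face mask and named region polygons
#'
#' The interior mask is the filled convex hull of all template points.
#' Region masks cover the brows (thickened brow lines), eyes (lid
#' quads), nose, mouth (lip outline) and cheeks (interior skin: hull
#' minus all other regions, so eye and mouth pixels never enter skin
#' statistics).
#'
#' @param landmarks 42x2 matrix, inside the image.
#' @param image_dims c(height, width) in pixels.
#' @return list with `mask` (logical HxW), `regions` (named list of
#'   logical HxW masks: brows, eyes, nose, mouth, cheeks), and
#'   `hull` (polygon vertices of the interior hull).
#' @export
interior_region <- function(landmarks, image_dims) {
  stopifnot(length(image_dims) == 2)
  h <- image_dims[1]; w <- image_dims[2]
  if (any(landmarks[, 1] < 0 | landmarks[, 1] > w - 1 |
          landmarks[, 2] < 0 | landmarks[, 2] > h - 1))
    stop("landmarks must lie inside the image")
  hull_idx <- grDevices::chull(landmarks)
  hull <- landmarks[hull_idx, , drop = FALSE]
  if (nrow(hull) < 3 || abs(pracma::polyarea(hull[, 1], hull[, 2])) < 1e-6)
    stop("degenerate landmark set: interior hull is empty")
  mask <- polygon_mask(hull[, 1], hull[, 2], h, w)
  if (!any(mask)) stop("interior mask is empty")

  g <- face_template()$groups
  thick_brow <- function(idx) polyline_mask(landmarks[idx, ], 2, h, w)
  quad <- function(idx) polygon_mask(landmarks[idx, 1], landmarks[idx, 2], h, w)
  brows <- thick_brow(g$brow_l) | thick_brow(g$brow_r)
  eyes <- quad(g$eye_l) | quad(g$eye_r)
  nose_hull <- landmarks[g$nose, , drop = FALSE]
  nh <- grDevices::chull(nose_hull)
  nose <- polygon_mask(nose_hull[nh, 1], nose_hull[nh, 2], h, w)
  mouth <- quad(g$mouth)
  regions <- list(brows = brows & mask, eyes = eyes & mask,
                  nose = nose & mask, mouth = mouth & mask)
  regions$cheeks <- mask & !(brows | eyes | nose | mouth)
  list(mask = mask, regions = regions, hull = hull)
}

new_feature_vector <- function(metric, values) {
  stopifnot(all(is.finite(values)), !is.null(names(values)))
  structure(values, metric = metric, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector %s: %d features>\n",
              attr(x, "metric"), length(x)))
  invisible(x)
}

#' Structure features: normalized geometry
#'
#' Concatenates the 84 normalized coordinates with a small set of
#' interpretable inter-landmark distances: brow-eye gaps (left/right),
#' mouth width, mouth-corner curvature (negative = corners above the
#' lip centers, i.e. smile-like), eye-to-mouth distance, and nose
#' length, all in interocular units.
#'
#' @param norm a [normalize_landmarks()] result.
#' @return `feature_vector` with metric `"structure"`.
#' @export
extract_structure <- function(norm) {
  stopifnot(inherits(norm, "normalized_landmarks"))
  p <- norm$points
  g <- face_template()$groups
  ec <- eye_centers(p)
  coords <- as.vector(t(p))
  names(coords) <- paste0(rep(c("x", "y"), 42), rep(1:42, each = 2))
  brow_eye_l <- ec["left", 2] - mean(p[g$brow_l, 2])
  brow_eye_r <- ec["right", 2] - mean(p[g$brow_r, 2])
  mouth_width <- sqrt(sum((p[30, ] - p[24, ])^2))
  mouth_curve <- mean(p[c(24, 30), 2]) - mean(p[c(27, 33), 2])
  mouth_center <- colMeans(p[g$mouth, , drop = FALSE])
  eye_mouth <- sqrt(sum((mouth_center - colMeans(ec))^2))
  nose_len <- sqrt(sum((p[22, ] - p[19, ])^2))
  new_feature_vector("structure", c(
    coords,
    brow_eye_gap_l = brow_eye_l, brow_eye_gap_r = brow_eye_r,
    mouth_width = mouth_width, mouth_curve = mouth_curve,
    eye_mouth_dist = eye_mouth, nose_length = nose_len))
}

rgb_to_lab <- function(px) {
  # px: n x 3 matrix of sRGB in [0,1]
  grDevices::convertColor(px, from = "sRGB", to = "Lab")
}

#' Color features: per-region CIELAB statistics plus contrast
#'
#' Per region (brows, eyes, nose, mouth, cheeks): mean and SD of the
#' CIELAB L, a, b channels. Two contrast features measure the linear
#' luminance (mean of RGB) difference between the cheeks and the eye
#' region, and between the cheeks and the mouth region -- the
#' eye/mouth-to-skin contrast dimension known to carry gender and
#' impression information.
#'
#' @param image HxWx3 array in `[0, 1]`.
#' @param regions `regions` list from [interior_region()].
#' @return `feature_vector` with metric `"color"`.
#' @export
extract_color <- function(image, regions) {
  stopifnot(length(regions) > 0)
  vals <- c()
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  lum_means <- c()
  for (rn in names(regions)) {
    m <- regions[[rn]]
    if (!any(m)) stop("region has zero pixels: ", rn)
    px <- cbind(image[, , 1][m], image[, , 2][m], image[, , 3][m])
    lab <- rgb_to_lab(px)
    mu <- colMeans(lab); sdv <- apply(lab, 2, stats::sd)
    sdv[is.na(sdv)] <- 0
    v <- c(mu, sdv)
    names(v) <- paste0(rn, "_", c("L_mean", "a_mean", "b_mean",
                                  "L_sd", "a_sd", "b_sd"))
    vals <- c(vals, v)
    lum_means[rn] <- mean(lum[m])
  }
  contrasts <- c(
    eye_cheek_contrast = unname(lum_means["cheeks"] - lum_means["eyes"]),
    mouth_cheek_contrast = unname(lum_means["cheeks"] - lum_means["mouth"]))
  contrasts <- contrasts[!is.na(contrasts)]
  new_feature_vector("color", c(vals, contrasts))
}

#' Gabor filter bank
#'
#' Complex Gabor kernels at the given orientations and wavelengths;
#' the even (cosine) part is mean-corrected so a constant image gives
#' exactly zero response. `sigma = 0.56 * wavelength` (about one
#' octave bandwidth).
#'
#' @param orientations_deg filter orientations in degrees (direction of
#'   intensity variation).
#' @param wavelengths_px carrier wavelengths in pixels.
#' @return list of filters, each with `even`, `odd` kernel matrices and
#'   `orientation`, `wavelength`.
#' @export
gabor_bank <- function(orientations_deg = c(0, 45, 90, 135),
                       wavelengths_px = c(4, 8, 16)) {
  filters <- list()
  for (lam in wavelengths_px) {
    sigma <- 0.56 * lam
    hs <- ceiling(2.5 * sigma)
    xs <- -hs:hs
    X <- matrix(rep(xs, each = length(xs)), length(xs))
    Y <- matrix(rep(xs, times = length(xs)), length(xs))
    for (th in orientations_deg) {
      a <- th * pi / 180
      xp <- X * cos(a) + Y * sin(a)
      env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
      even <- env * cos(2 * pi * xp / lam)
      odd <- env * sin(2 * pi * xp / lam)
      even <- even - mean(even)           # zero DC
      filters[[sprintf("o%d_w%d", th, lam)]] <-
        list(even = even, odd = odd, orientation = th, wavelength = lam)
    }
  }
  filters
}

# Circular FFT convolution of an image with a (small, odd-sized) kernel.
fft_convolve <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  pad <- matrix(0, h, w)
  pad[1:kh, 1:kw] <- kernel
  # center the kernel at (1,1) so the convolution is phase-aligned
  cy <- (kh + 1) / 2; cx <- (kw + 1) / 2
  pad <- pad[((seq_len(h) - 1 + cy - 1) %% h) + 1,
             ((seq_len(w) - 1 + cx - 1) %% w) + 1]
  Re(stats::fft(stats::fft(img) * Conj(stats::fft(pad)), inverse = TRUE)) / (h * w)
}

#' Texture features: Gabor energies over the interior mask
#'
#' Convolves the luminance channel with the filter bank and reports,
#' per filter, the mean modulus and the modulus SD over the masked
#' pixels. Default bank: 4 orientations x 3 wavelengths = 24 features.
#'
#' @param image HxWx3 array in `[0, 1]`.
#' @param mask logical HxW interior mask.
#' @param bank filter bank from [gabor_bank()].
#' @return `feature_vector` with metric `"texture"`.
#' @export
extract_texture <- function(image, mask, bank = gabor_bank()) {
  stopifnot(any(mask))
  kmax <- max(vapply(bank, function(f) nrow(f$even), 0L))
  ys <- range(which(rowSums(mask) > 0)); xs <- range(which(colSums(mask) > 0))
  if (diff(ys) + 1 < kmax || diff(xs) + 1 < kmax)
    stop("mask smaller than the largest filter support (", kmax, " px)")
  lum <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  vals <- c()
  for (fn in names(bank)) {
    f <- bank[[fn]]
    re <- fft_convolve(lum, f$even)
    im <- fft_convolve(lum, f$odd)
    mod <- sqrt(re^2 + im^2)[mask]
    sdv <- stats::sd(mod); if (is.na(sdv)) sdv <- 0
    v <- c(mean(mod), sdv)
    names(v) <- paste0(fn, c("_mean", "_sd"))
    vals <- c(vals, v)
  }
  new_feature_vector("texture", vals)
}

#' Extract the full triad for every face in a cohort
#'
#' Convenience wrapper: per face, normalize landmarks, build regions,
#' and compute structure, color and texture vectors.
#'
#' @param cohort a `face_cohort` (or plain list of `face_record`s).
#' @param bank Gabor bank for the texture channel.
#' @return list of three numeric matrices (`structure`, `color`,
#'   `texture`), one row per face, rownames = face ids.
#' @export
cohort_features <- function(cohort, bank = gabor_bank()) {
  records <- if (inherits(cohort, "face_cohort")) cohort$records else cohort
  feats <- list(structure = NULL, color = NULL, texture = NULL)
  rows <- lapply(records, function(r) {
    reg <- interior_region(r$landmarks, dim(r$image)[1:2])
    list(structure = extract_structure(normalize_landmarks(r$landmarks)),
         color = extract_color(r$image, reg$regions),
         texture = extract_texture(r$image, reg$mask, bank))
  })
  ids <- vapply(records, `[[`, "", "face_id")
  for (m in names(feats)) {
    feats[[m]] <- do.call(rbind, lapply(rows, function(x) unclass(x[[m]])))
    rownames(feats[[m]]) <- ids
  }
  feats
}

#' Write feature matrices to CSV (one file per metric)
#' @param features list from [cohort_features()].
#' @param dir output directory.
#' @return paths, invisibly.
#' @export
write_features <- function(features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (m in names(features)) {
    p <- file.path(dir, paste0("features_", m, ".csv"))
    utils::write.csv(data.frame(face_id = rownames(features[[m]]),
                                features[[m]], check.names = FALSE),
                     p, row.names = FALSE)
    paths[m] <- p
  }
  invisible(paths)
}

#' @rdname write_features
#' @export
read_features <- function(dir) {
  out <- list()
  for (m in c("structure", "color", "texture")) {
    p <- file.path(dir, paste0("features_", m, ".csv"))
    if (!file.exists(p)) next
    df <- utils::read.csv(p, check.names = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$face_id
    out[[m]] <- mat
  }
  out
}
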