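# Synthetic face cohorts with planted, recoverable structure.
#
# Faces are drawn procedurally (no external assets): a skin-toned oval,
# brows/eyes/nose/mouth rasterized from a fixed 42-point landmark
# template, cheek color gradients, and additive band-limited noise for
# surface texture. Emotions are realized as landmark displacement
# fields plus cheek color shifts plus texture-amplitude shifts, so each
# of the three feature channels (structure, color, texture) carries its
# own recoverable signal.

#' Fixed 42-point landmark template
#'
#' Canonical landmark layout on a 128x128 canvas (0-based pixel
#' coordinates, x rightward, y downward): 10 brow points (5 per brow),
#' 8 eye points (4 per eye: left corner, top, right corner, bottom),
#' 5 nose points, 12 mouth-outline points, 7 jaw/cheek points.
#' Coordinates scale linearly with `image_size`.
#'
#' @param image_size canvas side in pixels (square), >= 64.
#' @return list with `points` (42x2 matrix, columns x,y), `groups`
#'   (named list of row indices), and `image_size`.
#' @export
face_template <- function(image_size = 128) {
  stopifnot(image_size >= 64)
  pts <- rbind(
    # left brow (1-5)
    cbind(c(30, 36, 42, 48, 54), c(40, 38, 37, 38, 40)),
    # right brow (6-10)
    cbind(c(73, 79, 85, 91, 97), c(40, 38, 37, 38, 40)),
    # left eye (11-14): left corner, top, right corner, bottom
    cbind(c(36, 44, 52, 44), c(52, 49, 52, 55)),
    # right eye (15-18)
    cbind(c(75, 83, 91, 83), c(52, 49, 52, 55)),
    # nose (19-23): bridge top, bridge low, left base, tip, right base
    cbind(c(63.5, 63.5, 56, 63.5, 71), c(52, 62, 72, 74, 72)),
    # mouth (24-35): left corner, upper lip (5), right corner, lower lip (5)
    cbind(c(47, 51, 57, 63.5, 70, 76, 80, 76, 70, 63.5, 57, 51),
          c(88, 85, 83, 84, 83, 85, 88, 91, 93, 94, 93, 91)),
    # jaw / cheeks (36-42)
    cbind(c(26, 30, 45, 63.5, 82, 97, 101),
          c(70, 90, 106, 110, 106, 90, 70))
  )
  colnames(pts) <- c("x", "y")
  pts <- pts * (image_size / 128)
  groups <- list(
    brow_l = 1:5, brow_r = 6:10,
    eye_l = 11:14, eye_r = 15:18,
    nose = 19:23, mouth = 24:35, jaw = 36:42
  )
  list(points = pts, groups = groups, image_size = image_size)
}

#' Eye-center coordinates for a landmark set
#'
#' Centers are the means of the four points of each eye group.
#' @param points 42x2 landmark matrix.
#' @return 2x2 matrix, rows = left eye, right eye.
#' @export
eye_centers <- function(points) {
  g <- face_template()$groups
  rbind(left = colMeans(points[g$eye_l, , drop = FALSE]),
        right = colMeans(points[g$eye_r, , drop = FALSE]))
}

# Default per-emotion landmark displacement fields (pixels on the
# 128-canvas). Directions follow textbook action tendencies; the
# magnitudes are free parameters of the generator, not claims about
# real expressions.
default_displacements <- function(image_size = 128) {
  tpl <- face_template(128)
  g <- tpl$groups
  zero <- function() matrix(0, 42, 2, dimnames = list(NULL, c("x", "y")))
  d <- list()

  anger <- zero()                      # brows down and in, corners down
  anger[c(g$brow_l, g$brow_r), 2] <- 3
  anger[g$brow_l[4:5], 1] <- 2;  anger[g$brow_r[1:2], 1] <- -2
  anger[c(24, 30), 2] <- 2
  d$anger <- anger

  disgust <- zero()                    # nose wrinkle, upper lip raised
  disgust[c(g$brow_l, g$brow_r), 2] <- 2
  disgust[19:20, 2] <- -2
  disgust[25:29, 2] <- -3
  d$disgust <- disgust

  fear <- zero()                       # brows raised, eyes wide, lips apart
  fear[c(g$brow_l, g$brow_r), 2] <- -4
  fear[c(12, 16), 2] <- -2;  fear[c(14, 18), 2] <- 2
  fear[31:35, 2] <- 3
  d$fear <- fear

  happy <- zero()                      # lip corners up/out, cheeks raised
  happy[c(24, 30), 2] <- -4
  happy[24, 1] <- -3;  happy[30, 1] <- 3
  happy[g$jaw[c(2, 6)], 2] <- -2
  happy[c(12, 16), 2] <- 1
  d$happy <- happy

  sad <- zero()                        # inner brows up, corners down
  sad[g$brow_l[4:5], 2] <- -3;  sad[g$brow_r[1:2], 2] <- -3
  sad[c(24, 30), 2] <- 3
  d$sad <- sad

  surprise <- zero()                   # brows high, eyes and mouth open
  surprise[c(g$brow_l, g$brow_r), 2] <- -5
  surprise[c(12, 16), 2] <- -3;  surprise[c(14, 18), 2] <- 3
  surprise[31:35, 2] <- 6
  surprise[24, 1] <- 2;  surprise[30, 1] <- -2
  d$surprise <- surprise

  d$neutral <- zero()
  lapply(d[EMOTIONS], function(m) m * (image_size / 128))
}

# Default per-emotion cheek color shifts (RGB deltas, channel units)
# and texture-amplitude deltas: each emotion gets a distinct shift so
# the color and texture channels are informative on their own.
default_emotion_color <- function() {
  list(anger    = c(0.08, -0.02, -0.02),
       disgust  = c(-0.02, 0.05, -0.02),
       fear     = c(-0.05, -0.05, -0.02),
       happy    = c(0.06, 0.02, -0.01),
       sad      = c(-0.03, -0.01, 0.04),
       surprise = c(0.03, 0.03, 0.03),
       neutral  = c(0, 0, 0))
}

default_emotion_texture <- function() {
  c(anger = 0.040, disgust = 0.028, fear = 0.018, sad = 0.010,
    neutral = 0, surprise = -0.010, happy = -0.018)
}

# Oriented "grain": each emotion adds a sinusoidal surface component at
# a characteristic orientation x wavelength (random phase per face), so
# the texture channel carries an orientation signature on top of the
# roughness-amplitude shift. c(theta_deg, wavelength_px, amplitude).
default_emotion_grain <- function() {
  list(anger    = c(0, 4, 0.030),
       disgust  = c(45, 4, 0.030),
       fear     = c(90, 4, 0.030),
       sad      = c(135, 4, 0.030),
       surprise = c(0, 8, 0.030),
       happy    = c(90, 8, 0.030),
       neutral  = c(0, 4, 0))
}

#' Parameters of the synthetic face generator
#'
#' Bundles the landmark template, per-emotion displacement fields,
#' per-emotion color and texture shifts, the gender offsets, and the
#' noise levels. Defaults are moderate: emotions are well separated but
#' not trivially so once `idiosyncrasy_sd` and `pixel_noise_sd` are
#' nonzero.
#'
#' @param image_size square canvas side in pixels, >= 64.
#' @param emotion_displacements named list (all 7 classes) of 42x2
#'   landmark offset matrices in pixels; neutral must be all zero by
#'   convention (enforced only in the default).
#' @param emotion_color named list of length-3 RGB cheek shifts.
#' @param emotion_texture named numeric vector of texture-amplitude
#'   deltas.
#' @param emotion_grain named list of `c(theta_deg, wavelength_px,
#'   amplitude)` oriented-grain signatures (see
#'   [default_emotion_grain()]).
#' @param gender_shape_offset 42x2 matrix added to male templates
#'   (default: slightly heavier brow, wider jaw).
#' @param gender_color_offset length-3 RGB cheek shift for male faces.
#' @param gender_texture_offset texture-amplitude delta for male faces.
#' @param texture_base_amp baseline amplitude of the band-limited
#'   surface noise (channel units).
#' @param idiosyncrasy_sd per-face landmark jitter SD in pixels, >= 0.
#' @param pixel_noise_sd additive white pixel noise SD, >= 0.
#' @param seed default seed used by [make_cohort()] when none is given.
#' @return object of class `face_gen_params`.
#' @export
face_gen_params <- function(image_size = 128,
                            emotion_displacements = default_displacements(image_size),
                            emotion_color = default_emotion_color(),
                            emotion_texture = default_emotion_texture(),
                            emotion_grain = default_emotion_grain(),
                            gender_shape_offset = default_gender_shape(image_size),
                            gender_color_offset = c(-0.02, -0.01, -0.01),
                            gender_texture_offset = 0.012,
                            texture_base_amp = 0.03,
                            idiosyncrasy_sd = 1.0,
                            pixel_noise_sd = 0.01,
                            seed = 1L) {
  stopifnot(image_size >= 64)
  if (idiosyncrasy_sd < 0 || pixel_noise_sd < 0 || texture_base_amp < 0)
    stop("all noise SDs and amplitudes must be >= 0")
  missing_e <- setdiff(EMOTIONS, names(emotion_displacements))
  if (length(missing_e))
    stop("emotion_displacements missing classes: ",
         paste(missing_e, collapse = ", "))
  for (e in EMOTIONS) {
    m <- emotion_displacements[[e]]
    if (!is.matrix(m) || !all(dim(m) == c(42, 2)))
      stop("displacement field for '", e, "' must be a 42x2 matrix")
  }
  if (!all(EMOTIONS %in% names(emotion_color)))
    stop("emotion_color must cover all 7 classes")
  if (!all(EMOTIONS %in% names(emotion_texture)))
    stop("emotion_texture must cover all 7 classes")
  if (!all(EMOTIONS %in% names(emotion_grain)))
    stop("emotion_grain must cover all 7 classes")
  structure(list(
    image_size = as.integer(image_size),
    n_landmarks = 42L,
    emotion_displacements = emotion_displacements,
    emotion_color = emotion_color,
    emotion_texture = emotion_texture,
    emotion_grain = emotion_grain,
    gender_shape_offset = gender_shape_offset,
    gender_color_offset = gender_color_offset,
    gender_texture_offset = gender_texture_offset,
    texture_base_amp = texture_base_amp,
    idiosyncrasy_sd = idiosyncrasy_sd,
    pixel_noise_sd = pixel_noise_sd,
    seed = as.integer(seed)
  ), class = "face_gen_params")
}

#' @rdname face_gen_params
#' @export
default_gender_shape <- function(image_size = 128) {
  g <- face_template(128)$groups
  m <- matrix(0, 42, 2, dimnames = list(NULL, c("x", "y")))
  m[c(g$brow_l, g$brow_r), 2] <- 1.5          # heavier brow
  m[g$jaw[1:2], 1] <- -2; m[g$jaw[6:7], 1] <- 2  # wider jaw
  m * (image_size / 128)
}

# Deterministic (pre-jitter) landmark positions for one cell of the
# design; this is the generator's own stored offset, usable as an
# oracle for planted-effect recovery.
planted_landmarks <- function(params, emotion, gender, confound_spec = NULL) {
  tpl <- face_template(params$image_size)
  pts <- tpl$points
  if (gender == "male") pts <- pts + params$gender_shape_offset
  pts <- pts + params$emotion_displacements[[emotion]]
  if (emotion == "neutral" && !is.null(confound_spec)) {
    cf <- confound_spec[[gender]]
    for (e in names(cf))
      pts <- pts + cf[[e]] * params$emotion_displacements[[e]]
  }
  pts
}

# Per-face substream seed: derived by counter so cohorts are
# order-independent; kept below 2^31 - 1.
face_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 7919) %% 2147483629)
}

check_confound_spec <- function(confound_spec) {
  if (is.null(confound_spec)) return(invisible(NULL))
  stopifnot(is.list(confound_spec))
  bad_g <- setdiff(names(confound_spec), c("female", "male"))
  if (length(bad_g)) stop("confound_spec genders must be female/male")
  for (g in names(confound_spec)) {
    bad <- setdiff(names(confound_spec[[g]]), EMOTIONS)
    if (length(bad))
      stop("unknown emotion name in confound_spec: ",
           paste(bad, collapse = ", "))
  }
  invisible(NULL)
}

#' Generate a balanced synthetic face cohort
#'
#' Draws `n_per_cell` faces for every emotion x gender cell (7 x 2
#' cells). The optional `confound_spec` plants a gender-to-emotion
#' resemblance shift on *neutral* faces only: e.g.
#' `list(male = c(anger = 0.5), female = c(fear = 0.5))` moves male
#' neutrals half-way along the anger displacement/color/texture fields
#' and female neutrals half-way along fear, emulating the stereotypic
#' gender-emotion confound.
#'
#' @param params a [face_gen_params()] object.
#' @param n_per_cell faces per emotion x gender cell, >= 1.
#' @param confound_spec named list (`female`, `male`) of named numeric
#'   vectors: fraction (usually in `[0, 1]`) of each emotion's planted
#'   fields to add to that gender's neutral faces.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param render if FALSE, skip image rasterization (records carry
#'   NULL images); landmark streams are unchanged, so landmark-level
#'   results are identical either way.
#' @return list of class `face_cohort` with `records` (list of
#'   `face_record`), `metadata` (data.frame: face_id, gender, emotion),
#'   `params`, `confound_spec`, `seed`.
#' @export
make_cohort <- function(params, n_per_cell, confound_spec = NULL,
                        seed = params$seed, render = TRUE) {
  stopifnot(inherits(params, "face_gen_params"), n_per_cell >= 1)
  check_confound_spec(confound_spec)
  design <- expand.grid(rep = seq_len(n_per_cell), gender = c("female", "male"),
                        emotion = EMOTIONS, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
  records <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    gender <- design$gender[i]; emotion <- design$emotion[i]
    pts0 <- planted_landmarks(params, emotion, gender, confound_spec)
    set.seed(face_seed(seed, i))
    pts <- pts0
    if (params$idiosyncrasy_sd > 0)
      pts <- pts + matrix(stats::rnorm(84, 0, params$idiosyncrasy_sd), 42, 2)
    # keep landmarks strictly inside the canvas
    pts[, 1] <- pmin(pmax(pts[, 1], 2), params$image_size - 3)
    pts[, 2] <- pmin(pmax(pts[, 2], 2), params$image_size - 3)
    colnames(pts) <- c("x", "y")

    cheek_shift <- params$emotion_color[[emotion]]
    tex_amp <- params$texture_base_amp + params$emotion_texture[[emotion]]
    grains <- list(params$emotion_grain[[emotion]])
    if (gender == "male") {
      cheek_shift <- cheek_shift + params$gender_color_offset
      tex_amp <- tex_amp + params$gender_texture_offset
    }
    if (emotion == "neutral" && !is.null(confound_spec)) {
      cf <- confound_spec[[gender]]
      for (e in names(cf)) {
        cheek_shift <- cheek_shift + cf[[e]] * params$emotion_color[[e]]
        tex_amp <- tex_amp + cf[[e]] * params$emotion_texture[[e]]
        gr <- params$emotion_grain[[e]]
        grains <- c(grains, list(c(gr[1], gr[2], cf[[e]] * gr[3])))
      }
    }
    if (render) {
      img <- draw_face(pts, params$image_size, cheek_shift, max(tex_amp, 0),
                       grains)
      if (params$pixel_noise_sd > 0)
        img <- img + array(stats::rnorm(length(img), 0, params$pixel_noise_sd),
                           dim = dim(img))
      img[img < 0] <- 0; img[img > 1] <- 1
    } else img <- NULL
    records[[i]] <- face_record(
      image = img, landmarks = pts,
      face_id = sprintf("f%04d", i), gender = gender, emotion = emotion,
      image_size = params$image_size)
  }
  metadata <- data.frame(
    face_id = vapply(records, `[[`, "", "face_id"),
    gender = design$gender, emotion = design$emotion,
    stringsAsFactors = FALSE)
  structure(list(records = records, metadata = metadata, params = params,
                 confound_spec = confound_spec, seed = as.integer(seed)),
            class = "face_cohort")
}

#' A single face record
#'
#' @param image HxWx3 array, channels in `[0, 1]`, or NULL for a
#'   landmark-only record (then `image_size` is required).
#' @param landmarks 42x2 matrix of 0-based pixel coordinates
#'   (x rightward, y downward), inside the image bounds.
#' @param face_id identifier string.
#' @param gender `"female"` or `"male"`.
#' @param emotion one of [EMOTIONS] or `"unlabeled"`.
#' @param image_size canvas size for landmark-only records.
#' @return object of class `face_record`.
#' @export
face_record <- function(image, landmarks, face_id,
                        gender = c("female", "male"),
                        emotion = "unlabeled", image_size = NULL) {
  gender <- match.arg(gender)
  stopifnot(is.matrix(landmarks), ncol(landmarks) == 2)
  if (!all(is.finite(landmarks))) stop("landmarks must be finite")
  if (is.null(image)) {
    if (is.null(image_size)) stop("landmark-only records need image_size")
    h <- w <- image_size
  } else {
    stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
    h <- dim(image)[1]; w <- dim(image)[2]
  }
  if (any(landmarks[, 1] < 0 | landmarks[, 1] > w - 1 |
          landmarks[, 2] < 0 | landmarks[, 2] > h - 1))
    stop("landmarks must lie inside the image bounds")
  if (!emotion %in% c(EMOTIONS, "unlabeled")) stop("unknown emotion label")
  structure(list(image = image, landmarks = landmarks, face_id = face_id,
                 gender = gender, emotion = emotion), class = "face_record")
}

#' @export
print.face_record <- function(x, ...) {
  sz <- if (is.null(x$image)) "landmarks only"
        else paste0(dim(x$image)[1], "x", dim(x$image)[2])
  cat(sprintf("<face_record %s: %s %s, %s>\n", x$face_id, x$gender,
              x$emotion, sz))
  invisible(x)
}

#' @export
print.face_cohort <- function(x, ...) {
  cat(sprintf("<face_cohort: %d faces, %d px, seed %d>\n",
              length(x$records), x$params$image_size, x$seed))
  invisible(x)
}

# ---- procedural rendering -------------------------------------------------

# Fill a polygon on an integer pixel grid (0-based pixel centers).
polygon_mask <- function(poly_x, poly_y, h, w) {
  xr <- floor(max(0, min(poly_x) - 1)):ceiling(min(w - 1, max(poly_x) + 1))
  yr <- floor(max(0, min(poly_y) - 1)):ceiling(min(h - 1, max(poly_y) + 1))
  if (!length(xr) || !length(yr)) return(matrix(FALSE, h, w))
  gx <- rep(xr, each = length(yr)); gy <- rep(yr, times = length(xr))
  inside <- pracma::inpolygon(gx, gy, poly_x, poly_y, boundary = TRUE)
  m <- matrix(FALSE, h, w)
  m[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- TRUE
  m
}

# Thick polyline mask: pixels within `width` of any segment.
polyline_mask <- function(pts, width, h, w) {
  m <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    x0 <- floor(max(0, min(a[1], b[1]) - width - 1))
    x1 <- ceiling(min(w - 1, max(a[1], b[1]) + width + 1))
    y0 <- floor(max(0, min(a[2], b[2]) - width - 1))
    y1 <- ceiling(min(h - 1, max(a[2], b[2]) + width + 1))
    xr <- x0:x1; yr <- y0:y1
    gx <- rep(xr, each = length(yr)); gy <- rep(yr, times = length(xr))
    ab <- b - a; len2 <- sum(ab^2)
    t <- if (len2 > 0) ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len2 else 0
    t <- pmin(pmax(t, 0), 1)
    d2 <- (gx - (a[1] + t * ab[1]))^2 + (gy - (a[2] + t * ab[2]))^2
    hit <- d2 <= width^2
    m[cbind(gy[hit] + 1L, gx[hit] + 1L)] <- TRUE
  }
  m
}

# Band-limited noise field: smoothed white noise, zero-mean, unit-SD.
band_noise <- function(h, w) {
  z <- matrix(stats::rnorm(h * w), h, w)
  k <- stats::dnorm(-3:3, sd = 1.2); k <- k / sum(k)
  sm <- t(apply(apply(z, 2, function(col) as.numeric(
    stats::filter(col, k, circular = TRUE))), 1, function(row) as.numeric(
      stats::filter(row, k, circular = TRUE))))
  sm <- sm - mean(sm)
  sm / stats::sd(sm)
}

# Render one face from its landmarks. Uses the RNG stream (texture
# pattern); callers seed a per-face substream first.
draw_face <- function(pts, image_size, cheek_shift = c(0, 0, 0),
                      tex_amp = 0.03, grains = list()) {
  h <- w <- image_size
  g <- face_template()$groups
  img <- array(0.78, dim = c(h, w, 3))

  jaw <- pts[g$jaw, , drop = FALSE]
  brows <- pts[c(g$brow_l, g$brow_r), , drop = FALSE]
  left <- min(jaw[, 1]); right <- max(jaw[, 1])
  top <- min(brows[, 2]) - 18 * image_size / 128
  bottom <- max(jaw[, 2]) + 4 * image_size / 128
  cx <- (left + right) / 2; cy <- (top + bottom) / 2
  rx <- (right - left) / 2; ry <- (bottom - top) / 2

  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  face <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1

  skin <- c(0.85, 0.72, 0.60)
  grad <- 1 - 0.08 * (Y - top) / (bottom - top)
  for (c3 in 1:3) {
    ch <- img[, , c3]
    ch[face] <- (skin[c3] * grad)[face]
    img[, , c3] <- ch
  }

  # cheek blush + planted color shifts, gaussian falloff around cheeks
  ec <- eye_centers(pts)
  nose_base_y <- pts[22, 2]
  cheek_c <- rbind(c(ec[1, 1] - 3, nose_base_y + 2),
                   c(ec[2, 1] + 3, nose_base_y + 2))
  sigma <- 11 * image_size / 128
  blob <- exp(-((X - cheek_c[1, 1])^2 + (Y - cheek_c[1, 2])^2) / (2 * sigma^2)) +
    exp(-((X - cheek_c[2, 1])^2 + (Y - cheek_c[2, 2])^2) / (2 * sigma^2))
  base_blush <- c(0.05, -0.01, -0.02)
  for (c3 in 1:3) {
    ch <- img[, , c3]
    ch[face] <- ch[face] +
      ((base_blush[c3] + cheek_shift[c3]) * blob)[face]
    img[, , c3] <- ch
  }

  paint <- function(mask, col) {
    for (c3 in 1:3) {
      ch <- img[, , c3]; ch[mask] <- col[c3]; img[, , c3] <<- ch
    }
  }
  lw <- image_size / 128
  paint(polyline_mask(pts[g$brow_l, ], 1.8 * lw, h, w), c(0.25, 0.18, 0.12))
  paint(polyline_mask(pts[g$brow_r, ], 1.8 * lw, h, w), c(0.25, 0.18, 0.12))
  for (eye in list(g$eye_l, g$eye_r)) {
    q <- pts[eye, ]
    paint(polygon_mask(q[, 1], q[, 2], h, w), c(0.95, 0.95, 0.95))
  }
  for (i in 1:2) {
    iris <- (X - ec[i, 1])^2 + (Y - ec[i, 2])^2 <= (2.8 * lw)^2
    paint(iris, c(0.25, 0.22, 0.20))
  }
  nose_m <- polyline_mask(pts[g$nose, ], 1.1 * lw, h, w)
  for (c3 in 1:3) {
    ch <- img[, , c3]; ch[nose_m] <- ch[nose_m] * 0.90; img[, , c3] <- ch
  }
  mouth <- pts[g$mouth, ]
  paint(polygon_mask(mouth[, 1], mouth[, 2], h, w), c(0.62, 0.33, 0.33))

  if (tex_amp > 0) {
    tex <- band_noise(h, w) * tex_amp
    for (c3 in 1:3) {
      ch <- img[, , c3]; ch[face] <- ch[face] + tex[face]; img[, , c3] <- ch
    }
  }
  for (gr in grains) {
    if (length(gr) < 3 || gr[3] <= 0) next
    a <- gr[1] * pi / 180
    phase <- stats::runif(1, 0, 2 * pi)
    wave <- gr[3] * sin(2 * pi * (X * cos(a) + Y * sin(a)) / gr[2] + phase)
    for (c3 in 1:3) {
      ch <- img[, , c3]; ch[face] <- ch[face] + wave[face]; img[, , c3] <- ch
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

# ---- rating and trial tables ----------------------------------------------

#' Generate a normed-rating table from planted latents
#'
#' Each face gets latent dominance and affiliation scores (standard
#' normal), and each trait rating is a planted linear function of the
#' latents plus Gaussian noise. Masculinity is planted on latent
#' dominance; femininity is the negated masculinity plus noise, which
#' reproduces the strongly negative masculinity-femininity correlation
#' seen in normed face-rating data.
#'
#' @param metadata data.frame with a `face_id` column (and optionally
#'   `gender`, carried through).
#' @param rating_model list with `weights` (traits x 2 matrix, columns
#'   `dominance`, `affiliation`), `intercept`, `noise_sd`,
#'   `masc_weight`, `masc_noise_sd`.
#' @param seed integer seed.
#' @return data.frame: face_id, latent_dominance, latent_affiliation,
#'   one column per trait, masculinity, femininity.
#' @export
make_ratings <- function(metadata, rating_model = default_rating_model(),
                         seed = 1L) {
  stopifnot(is.data.frame(metadata), "face_id" %in% names(metadata))
  rm <- rating_model
  if (rm$noise_sd < 0 || rm$masc_noise_sd < 0)
    stop("noise SDs must be >= 0")
  stopifnot(is.matrix(rm$weights), ncol(rm$weights) == 2)
  n <- nrow(metadata)
  set.seed(as.integer(seed))
  lat <- cbind(dominance = stats::rnorm(n), affiliation = stats::rnorm(n))
  traits <- rownames(rm$weights)
  ratings <- lat %*% t(rm$weights) + rm$intercept +
    matrix(stats::rnorm(n * length(traits), 0, rm$noise_sd), n)
  colnames(ratings) <- traits
  masc <- rm$masc_weight * lat[, "dominance"] +
    stats::rnorm(n, 0, rm$masc_noise_sd)
  fem <- -masc + stats::rnorm(n, 0, rm$masc_noise_sd)
  out <- data.frame(face_id = metadata$face_id,
                    latent_dominance = lat[, "dominance"],
                    latent_affiliation = lat[, "affiliation"],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(ratings),
               masculinity = masc, femininity = fem)
  if ("gender" %in% names(metadata)) out$gender <- metadata$gender
  out
}

#' @rdname make_ratings
#' @export
default_rating_model <- function() {
  w <- matrix(0, length(TRAITS), 2,
              dimnames = list(TRAITS, c("dominance", "affiliation")))
  w["dominant", ] <- c(1, 0)
  w["angry", ] <- c(0.6, -0.5)
  w["trustworthy", ] <- c(-0.3, 0.8)
  w["happy", ] <- c(0, 0.7)
  w["healthy", ] <- c(0.2, 0.3)
  w["attractive", ] <- c(0, 0.4)
  w["babyish", ] <- c(-0.6, 0.3)
  w["smart", ] <- c(0.1, 0.2)
  list(weights = w, intercept = 0, noise_sd = 0.3,
       masc_weight = 1, masc_noise_sd = 0.2)
}

#' Generate a participant trial table with plantable contamination
#'
#' Simulates a rating session: each participant rates each face on each
#' trait with a 1-7 integer response and a lognormal reaction time.
#' Contamination is planted exactly: `n_low_sd` participants respond
#' with (near) constant values, and `n_fast`/`n_slow` trials among the
#' clean participants get out-of-range reaction times. The planted
#' ground truth is attached as the `manifest` attribute (also returned
#' by [trial_manifest()]).
#'
#' @param ratings rating table from [make_ratings()] (trait columns
#'   drive the response means).
#' @param n_participants participants to simulate.
#' @param n_faces_each faces rated per participant (sampled without
#'   replacement).
#' @param contamination list: `n_low_sd`, `n_fast`, `n_slow`,
#'   `rt_fast_ms` (default 20), `rt_slow_ms` (default 20000).
#' @param seed integer seed.
#' @return data.frame of class `trial_table`: participant_id, face_id,
#'   trait, response (1-7), rt_ms; attribute `manifest`.
#' @export
make_trials <- function(ratings, n_participants = 20, n_faces_each = 10,
                        contamination = list(n_low_sd = 0, n_fast = 0,
                                             n_slow = 0),
                        seed = 1L) {
  stopifnot(is.data.frame(ratings), "face_id" %in% names(ratings))
  cm <- utils::modifyList(list(n_low_sd = 0, n_fast = 0, n_slow = 0,
                               rt_fast_ms = 20, rt_slow_ms = 20000),
                          contamination)
  if (cm$n_low_sd > n_participants)
    stop("n_low_sd exceeds the number of participants")
  n_faces_each <- min(n_faces_each, nrow(ratings))
  set.seed(as.integer(seed))
  traits <- intersect(TRAITS, names(ratings))
  pid <- sprintf("p%03d", seq_len(n_participants))
  low_sd <- if (cm$n_low_sd > 0) pid[seq_len(cm$n_low_sd)] else character(0)
  rows <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    faces <- sample(ratings$face_id, n_faces_each)
    grid <- expand.grid(face_id = faces, trait = traits,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    mu <- mapply(function(f, tr) ratings[[tr]][ratings$face_id == f],
                 grid$face_id, grid$trait)
    if (pid[i] %in% low_sd) {
      resp <- rep(4L, nrow(grid))
    } else {
      resp <- pmin(pmax(round(4 + mu + stats::rnorm(nrow(grid), 0, 1)), 1), 7)
    }
    rows[[i]] <- data.frame(participant_id = pid[i], face_id = grid$face_id,
                            trait = grid$trait, response = as.integer(resp),
                            rt_ms = stats::rlnorm(nrow(grid), log(800), 0.4),
                            stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, rows)
  clean_rows <- which(!trials$participant_id %in% low_sd)
  if (cm$n_fast + cm$n_slow > length(clean_rows))
    stop("contaminated trial counts exceed the available clean trials")
  pick <- sample(clean_rows, cm$n_fast + cm$n_slow)
  fast_idx <- pick[seq_len(cm$n_fast)]
  slow_idx <- setdiff(pick, fast_idx)
  trials$rt_ms[fast_idx] <- cm$rt_fast_ms
  trials$rt_ms[slow_idx] <- cm$rt_slow_ms
  attr(trials, "manifest") <- list(
    low_sd_participants = low_sd,
    fast_trial_rows = sort(fast_idx), slow_trial_rows = sort(slow_idx),
    n_fast = cm$n_fast, n_slow = cm$n_slow, seed = as.integer(seed))
  class(trials) <- c("trial_table", "data.frame")
  trials
}

#' @rdname make_trials
#' @param trials a trial table from [make_trials()].
#' @export
trial_manifest <- function(trials) attr(trials, "manifest")

# ---- on-disk formats ------------------------------------------------------

#' Write / read face records as PNG + JSON landmark files
#'
#' Images go to `<dir>/<face_id>.png`, landmarks to
#' `<dir>/<face_id>.json` as a JSON array of `[x, y]` pairs.
#'
#' @param record a `face_record`.
#' @param dir output directory (created if needed).
#' @return (write) the two file paths, invisibly; (read) a
#'   `face_record`.
#' @export
write_face_record <- function(record, dir) {
  stopifnot(inherits(record, "face_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png_path <- file.path(dir, paste0(record$face_id, ".png"))
  json_path <- file.path(dir, paste0(record$face_id, ".json"))
  png::writePNG(record$image, png_path)
  jsonlite::write_json(unname(split(record$landmarks, row(record$landmarks))),
                       json_path, digits = NA)
  invisible(c(png = png_path, landmarks = json_path))
}

#' @rdname write_face_record
#' @param face_id stem of the PNG/JSON pair inside `dir`.
#' @param gender,emotion metadata for the rebuilt record.
#' @export
read_face_record <- function(dir, face_id, gender = "female",
                             emotion = "unlabeled") {
  img <- png::readPNG(file.path(dir, paste0(face_id, ".png")))
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  lm <- jsonlite::read_json(file.path(dir, paste0(face_id, ".json")),
                            simplifyVector = TRUE)
  lm <- matrix(unlist(lm), ncol = 2, byrow = is.list(lm))
  if (is.matrix(lm) && nrow(lm) == 2 && ncol(lm) != 2) lm <- t(lm)
  colnames(lm) <- c("x", "y")
  face_record(img, lm, face_id, gender, emotion)
}

#' Write a whole cohort to disk
#'
#' PNG + JSON per face, `metadata.csv`, and a `manifest.json` recording
#' the generator parameters, seed and planted confound.
#' @param cohort a `face_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "face_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in cohort$records) write_face_record(r, dir)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  manifest <- list(seed = cohort$seed,
                   image_size = cohort$params$image_size,
                   n_faces = length(cohort$records),
                   confound_spec = cohort$confound_spec,
                   idiosyncrasy_sd = cohort$params$idiosyncrasy_sd,
                   pixel_noise_sd = cohort$params$pixel_noise_sd)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
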