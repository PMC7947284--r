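# Landmark-based face morphing: 50-50 shape/color blends of
# close-to-origin base faces with quadrant/emotion prototype donors.
#
# The warp is piecewise-affine over a Delaunay triangulation of the
# landmark template, computed once on the mean template and reused for
# every face (so triangle correspondence is fixed). Pixels outside all
# triangles pass through unchanged; sampling is bilinear and
# out-of-gamut values are clipped.

#' Delaunay triangulation (Bowyer-Watson)
#'
#' Plain Bowyer-Watson incremental triangulation; adequate for the
#' 42-point template (computed once and cached by [template_triangles()]).
#'
#' @param pts n x 2 coordinate matrix.
#' @return integer matrix, one triangle per row (vertex indices).
#' @export
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  # super-triangle enclosing all points
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  d <- max(diff(range(pts[, 1])), diff(range(pts[, 2]))) * 10 + 10
  P <- rbind(pts, c(cx - 2 * d, cy - d), c(cx + 2 * d, cy - d), c(cx, cy + 2 * d))
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  circum <- function(tr) {
    a <- P[tr[1], ]; b <- P[tr[2], ]; c3 <- P[tr[3], ]
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx2 <- c3[1]; cy2 <- c3[2]
    dd <- 2 * (ax * (by - cy2) + bx * (cy2 - ay) + cx2 * (ay - by))
    if (abs(dd) < 1e-12) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy2) + (bx^2 + by^2) * (cy2 - ay) +
             (cx2^2 + cy2^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx2 - bx) + (bx^2 + by^2) * (ax - cx2) +
             (cx2^2 + cy2^2) * (bx - ax)) / dd
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  ccache <- list(circum(tris[[1]]))
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- which(vapply(ccache, function(cc)
      (p[1] - cc[1])^2 + (p[2] - cc[2])^2 < cc[3] - 1e-9, TRUE))
    if (!length(bad)) bad <- 1L  # numerical fallback: rebuild around 1st
    # boundary polygon = edges of bad triangles not shared by two
    edges <- do.call(rbind, lapply(tris[bad], function(tr)
      rbind(tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    edges <- edges[keep, , drop = FALSE]
    tris <- tris[-bad]; ccache <- ccache[-bad]
    for (k in seq_len(nrow(edges))) {
      tr <- c(edges[k, 1], edges[k, 2], ip)
      tris <- c(tris, list(tr))
      ccache <- c(ccache, list(circum(tr)))
    }
  }
  out <- do.call(rbind, tris)
  out <- out[apply(out <= n, 1, all), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

.triangle_cache <- new.env(parent = emptyenv())

#' Fixed triangulation of the landmark template
#'
#' Triangulates the mean template once and caches the result; every
#' warp reuses the same triangle list so correspondence is stable.
#' @param image_size template canvas size.
#' @return integer triangle matrix.
#' @export
template_triangles <- function(image_size = 128) {
  key <- as.character(image_size)
  if (is.null(.triangle_cache[[key]]))
    .triangle_cache[[key]] <- delaunay_triangulate(
      face_template(image_size)$points)
  .triangle_cache[[key]]
}

#' Blend two landmark sets
#'
#' Pointwise `(1 - alpha) * a + alpha * b`.
#' @param landmarks_a,landmarks_b 42x2 matrices on the same template.
#' @param alpha blend proportion in `[0, 1]`.
#' @return 42x2 matrix.
#' @export
average_shape <- function(landmarks_a, landmarks_b, alpha = 0.5) {
  if (!all(dim(landmarks_a) == dim(landmarks_b)))
    stop("landmark templates do not match")
  stopifnot(alpha >= 0, alpha <= 1)
  (1 - alpha) * landmarks_a + alpha * landmarks_b
}

# Bilinear sample of one channel at fractional 0-based (x, y).
bilinear_sample <- function(ch, x, y) {
  h <- nrow(ch); w <- ncol(ch)
  x <- pmin(pmax(x, 0), w - 1); y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  ch[i00] * (1 - fx) * (1 - fy) + ch[i01] * fx * (1 - fy) +
    ch[i10] * (1 - fx) * fy + ch[i11] * fx * fy
}

#' Piecewise-affine landmark warp
#'
#' Warps `image` so that `src_landmarks` move to `dst_landmarks`, using
#' the fixed template triangulation. For each destination triangle the
#' inverse affine map is applied to its pixels and the source is
#' sampled bilinearly; pixels outside all triangles are copied through.
#'
#' @param image HxWx3 array.
#' @param src_landmarks,dst_landmarks 42x2 matrices; `dst` must lie
#'   inside the canvas.
#' @return warped HxWx3 array.
#' @export
warp_image <- function(image, src_landmarks, dst_landmarks) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!all(dim(src_landmarks) == dim(dst_landmarks)))
    stop("landmark templates do not match")
  if (any(dst_landmarks[, 1] < 0 | dst_landmarks[, 1] > w - 1 |
          dst_landmarks[, 2] < 0 | dst_landmarks[, 2] > h - 1))
    stop("destination landmarks outside the canvas")
  tris <- template_triangles(dim(image)[1])
  out <- image
  for (t_i in seq_len(nrow(tris))) {
    idx <- tris[t_i, ]
    D <- dst_landmarks[idx, , drop = FALSE]
    S <- src_landmarks[idx, , drop = FALSE]
    det2 <- (D[2, 1] - D[1, 1]) * (D[3, 2] - D[1, 2]) -
      (D[3, 1] - D[1, 1]) * (D[2, 2] - D[1, 2])
    if (abs(det2) < 1e-9)
      stop("degenerate destination triangle at index ", t_i)
    x0 <- max(0, floor(min(D[, 1]))); x1 <- min(w - 1, ceiling(max(D[, 1])))
    y0 <- max(0, floor(min(D[, 2]))); y1 <- min(h - 1, ceiling(max(D[, 2])))
    if (x1 < x0 || y1 < y0) next
    gx <- rep(x0:x1, each = y1 - y0 + 1)
    gy <- rep(y0:y1, times = x1 - x0 + 1)
    # barycentric coordinates w.r.t. destination triangle
    l1 <- ((D[2, 2] - D[3, 2]) * (gx - D[3, 1]) +
             (D[3, 1] - D[2, 1]) * (gy - D[3, 2])) / det2
    l2 <- ((D[3, 2] - D[1, 2]) * (gx - D[3, 1]) +
             (D[1, 1] - D[3, 1]) * (gy - D[3, 2])) / det2
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inside)) next
    sx <- l1[inside] * S[1, 1] + l2[inside] * S[2, 1] + l3[inside] * S[3, 1]
    sy <- l1[inside] * S[1, 2] + l2[inside] * S[2, 2] + l3[inside] * S[3, 2]
    pix <- cbind(gy[inside] + 1L, gx[inside] + 1L)
    for (c3 in 1:3) {
      ch <- out[, , c3]
      ch[pix] <- bilinear_sample(image[, , c3], sx, sy)
      out[, , c3] <- ch
    }
  }
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' Blend two gender-matched face records
#'
#' Output landmarks are the alpha-blend of the two shapes; the output
#' image averages both faces warped onto the blended shape:
#' `(1 - alpha) * warp(base) + alpha * warp(donor)`, clipped to
#' `[0, 1]`. At the default `alpha = 0.5` this is the 50-50 transform
#' used to move a close-to-origin neutral face toward a prototype.
#'
#' @param base,donor `face_record`s sharing template and gender.
#' @param alpha blend proportion in `[0, 1]`.
#' @param output_id id for the blended record.
#' @return a `face_record` (emotion `"unlabeled"`).
#' @export
blend_transform <- function(base, donor, alpha = 0.5,
                            output_id = paste0(base$face_id, "_x_",
                                               donor$face_id)) {
  stopifnot(inherits(base, "face_record"), inherits(donor, "face_record"))
  if (base$gender != donor$gender)
    stop("base and donor must be gender matched")
  stopifnot(alpha >= 0, alpha <= 1)
  lm <- average_shape(base$landmarks, donor$landmarks, alpha)
  wb <- warp_image(base$image, base$landmarks, lm)
  wd <- warp_image(donor$image, donor$landmarks, lm)
  img <- (1 - alpha) * wb + alpha * wd
  img[img < 0] <- 0; img[img > 1] <- 1
  face_record(img, lm, output_id, base$gender, "unlabeled")
}

#' Automated quality-control flag for a morphed record
#'
#' Checks that landmarks stay inside the canvas with a margin and that
#' the image is not degenerate (pixel range inside `[0, 1]`, nonzero
#' interior variance). Stands in for manual artifact inspection.
#'
#' @param record a `face_record`.
#' @param margin_px landmark margin from the border.
#' @return TRUE if the record passes.
#' @export
qc_pass <- function(record, margin_px = 1) {
  h <- dim(record$image)[1]; w <- dim(record$image)[2]
  lm_ok <- all(record$landmarks[, 1] >= margin_px &
                 record$landmarks[, 1] <= w - 1 - margin_px &
                 record$landmarks[, 2] >= margin_px &
                 record$landmarks[, 2] <= h - 1 - margin_px)
  px_ok <- all(record$image >= 0 & record$image <= 1) &&
    stats::sd(record$image) > 1e-4
  isTRUE(lm_ok && px_ok)
}

#' Build a morphed stimulus set
#'
#' For every base x category, samples `reps_per_category` donors from
#' the gender-matched pool (without replacement when the pool is large
#' enough, with replacement and a flag otherwise) and produces the
#' alpha-blend of each pair. The manifest records every pairing.
#'
#' @param records named list of `face_record`s (by face_id) covering
#'   bases and all pool members.
#' @param bases named list (`female`, `male`) of base face ids.
#' @param pools named list `"<category>.<gender>"` of donor id pools,
#'   e.g. from [select_prototypes()].
#' @param reps_per_category donors sampled per base x category.
#' @param alpha blend proportion.
#' @param seed integer seed.
#' @return list: `records` (morphed `face_record`s), `manifest`
#'   (data.frame: output_id, base_id, donor_id, category, gender, rep,
#'   alpha, replacement flag, qc_pass, seed).
#' @export
build_stimulus_set <- function(records, bases, pools, reps_per_category = 4,
                               alpha = 0.5, seed = 1L) {
  stopifnot(length(pools) > 0, reps_per_category >= 1)
  categories <- unique(sub("\\.[^.]+$", "", names(pools)))
  rows <- list(); out_records <- list()
  set.seed(as.integer(seed))
  for (g in names(bases)) for (b in bases[[g]]) {
    for (cat in categories) {
      pool <- pools[[paste0(cat, ".", g)]]
      if (is.null(pool) || !length(pool))
        stop("empty gender-matched pool for category ", cat, " / ", g)
      pool <- setdiff(pool, b)
      replace <- length(pool) < reps_per_category
      donors <- sample(pool, reps_per_category, replace = replace)
      for (r in seq_along(donors)) {
        oid <- sprintf("%s_%s_r%d_%s", b, cat, r, donors[r])
        rec <- blend_transform(records[[b]], records[[donors[r]]],
                               alpha, output_id = oid)
        out_records[[oid]] <- rec
        rows[[length(rows) + 1]] <- data.frame(
          output_id = oid, base_id = b, donor_id = donors[r],
          category = cat, gender = g, rep = r, alpha = alpha,
          with_replacement = replace, qc_pass = qc_pass(rec),
          seed = as.integer(seed), stringsAsFactors = FALSE)
      }
    }
  }
  list(records = out_records, manifest = do.call(rbind, rows))
}
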