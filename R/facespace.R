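# Dominance-affiliation face space: projection of emotion outputs onto
# the interpersonal circumplex, polar position, quadrant assignment,
# and prototype / base-face selection.

#' Knutson circumplex loadings for the six emotions
#'
#' Per-emotion dominance (y axis) and affiliation (x axis) loadings.
#' Defaults are the published circumplex values: dominance
#' (anger 1, disgust 0.6, happy 1, fear -0.5, sad -1, surprise -0.5)
#' and affiliation (anger -1.5, disgust -1, happy 2, fear 0.5,
#' sad 0.1, surprise 0.1).
#'
#' @param dominance,affiliation named numeric vectors covering exactly
#'   the six expressive emotions.
#' @return object of class `knutson_coefficients`: a 2x6 matrix with
#'   rows `dominance`, `affiliation`.
#' @export
knutson_coefficients <- function(
    dominance = c(anger = 1, disgust = 0.6, happy = 1, fear = -0.5,
                  sad = -1, surprise = -0.5),
    affiliation = c(anger = -1.5, disgust = -1, happy = 2, fear = 0.5,
                    sad = 0.1, surprise = 0.1)) {
  if (!setequal(names(dominance), EMOTIONS6) ||
      !setequal(names(affiliation), EMOTIONS6))
    stop("coefficients must cover exactly the six expressive emotions")
  m <- rbind(dominance = dominance[EMOTIONS6],
             affiliation = affiliation[EMOTIONS6])
  colnames(m) <- EMOTIONS6
  structure(m, class = c("knutson_coefficients", "matrix"))
}

#' Project emotion outputs into dominance-affiliation space
#'
#' `D_hat = sum_i Y_i^d * I_i` and `A_hat = sum_i X_i^a * I_i` over the
#' six expressive emotions. A neutral probability, if present, is
#' dropped and the remaining six entries are *not* renormalized.
#'
#' @param emotion_output named numeric vector, or matrix with emotion
#'   columns (rows = faces). Must name all six expressive emotions.
#' @param coeffs a [knutson_coefficients()] table.
#' @return data.frame with columns `D_hat`, `A_hat` (one row per face).
#' @export
project_emotions <- function(emotion_output, coeffs = knutson_coefficients()) {
  if (is.null(dim(emotion_output)))
    emotion_output <- matrix(emotion_output, 1,
                             dimnames = list(NULL, names(emotion_output)))
  missing_e <- setdiff(EMOTIONS6, colnames(emotion_output))
  if (length(missing_e))
    stop("emotion output is missing classes: ",
         paste(missing_e, collapse = ", "))
  I6 <- emotion_output[, EMOTIONS6, drop = FALSE]
  data.frame(D_hat = as.vector(I6 %*% coeffs["dominance", EMOTIONS6]),
             A_hat = as.vector(I6 %*% coeffs["affiliation", EMOTIONS6]),
             row.names = rownames(emotion_output))
}

#' Polar face-space position
#'
#' Euclidean distance from the origin and angle in degrees, with
#' x = affiliation and y = dominance: `theta = atan2(D, A)` mapped to
#' `[0, 360)`. The origin maps to distance 0 and angle 0 by convention.
#'
#' @param D_hat,A_hat dominance / affiliation coordinates (vectors).
#' @return data.frame with `E_hat`, `theta_deg`.
#' @export
polar_position <- function(D_hat, A_hat) {
  if (!all(is.finite(D_hat)) || !all(is.finite(A_hat)))
    stop("non-finite face-space coordinates")
  E <- sqrt(D_hat^2 + A_hat^2)
  theta <- atan2(D_hat, A_hat) * 180 / pi
  theta <- theta %% 360
  theta[E == 0] <- 0
  data.frame(E_hat = E, theta_deg = theta)
}

#' Default quadrant angle windows
#'
#' Inclusive angle intervals (degrees from the positive affiliation
#' axis) and the minimum origin distance a face must exceed to count as
#' a quadrant prototype. Quadrant I (high dominance, high affiliation)
#' spans 10-80, II (high dominance, low affiliation) 100-170, III
#' (low/low) 190-260, IV (low dominance, high affiliation) 280-350.
#'
#' @param windows named list of `c(lo, hi)` degree intervals.
#' @param min_distance faces with `E_hat` at or below this are
#'   unassigned.
#' @return object of class `quadrant_windows`.
#' @export
quadrant_windows <- function(windows = list(I = c(10, 80), II = c(100, 170),
                                            III = c(190, 260),
                                            IV = c(280, 350)),
                             min_distance = 0.15) {
  stopifnot(min_distance >= 0)
  for (w in windows)
    if (length(w) != 2 || w[1] > w[2] || w[1] < 0 || w[2] >= 360)
      stop("each window must be c(lo, hi) within [0, 360)")
  nm <- names(windows)
  for (i in seq_along(windows)) for (j in seq_along(windows)) {
    if (i >= j) next
    if (windows[[i]][1] <= windows[[j]][2] &&
        windows[[j]][1] <= windows[[i]][2])
      stop("overlapping quadrant windows: ", nm[i], " and ", nm[j])
  }
  structure(list(windows = windows, min_distance = min_distance),
            class = "quadrant_windows")
}

#' Assign faces to face-space quadrants
#'
#' A face gets the unique quadrant whose (inclusive) angle window
#' contains its angle, provided its distance from the origin strictly
#' exceeds the minimum; otherwise `"none"`.
#'
#' @param theta_deg angles in `[0, 360)`.
#' @param E_hat distances from the origin.
#' @param windows a [quadrant_windows()] object.
#' @return character vector of quadrant labels.
#' @export
assign_quadrant <- function(theta_deg, E_hat, windows = quadrant_windows()) {
  stopifnot(inherits(windows, "quadrant_windows"),
            all(theta_deg >= 0 & theta_deg < 360))
  out <- rep("none", length(theta_deg))
  for (nm in names(windows$windows)) {
    w <- windows$windows[[nm]]
    hit <- theta_deg >= w[1] & theta_deg <= w[2] &
      E_hat > windows$min_distance
    out[hit] <- nm
  }
  out
}

#' Full face-space position table for an emotion-output matrix
#'
#' @param emotion_output matrix (rows = faces) with emotion columns.
#' @param coeffs coefficient table.
#' @param windows quadrant windows.
#' @param metadata optional data.frame with face_id, gender to join.
#' @return data.frame: face_id, (gender,) D_hat, A_hat, E_hat,
#'   theta_deg, quadrant.
#' @export
face_space_positions <- function(emotion_output,
                                 coeffs = knutson_coefficients(),
                                 windows = quadrant_windows(),
                                 metadata = NULL) {
  proj <- project_emotions(emotion_output, coeffs)
  pol <- polar_position(proj$D_hat, proj$A_hat)
  pos <- cbind(face_id = rownames(emotion_output), proj, pol)
  pos$quadrant <- assign_quadrant(pol$theta_deg, pol$E_hat, windows)
  rownames(pos) <- NULL
  if (!is.null(metadata))
    pos <- merge(metadata[, intersect(c("face_id", "gender"),
                                      names(metadata)), drop = FALSE],
                 pos, by = "face_id", sort = TRUE)
  pos
}

# descending/ascending sort with lexical face_id tie-break
rank_select <- function(ids, key, k, decreasing) {
  ord <- order(key, ids, decreasing = c(decreasing, FALSE),
               method = "radix")
  ids[ord][seq_len(min(k, length(ids)))]
}

#' Select quadrant or emotion prototype pools
#'
#' Quadrant mode: within each quadrant x gender, the `k` eligible faces
#' with the largest distance from the origin (descending, ties broken
#' by face id). Emotion mode: per gender, the `k` faces with the
#' largest probability for the named emotion.
#'
#' @param positions position table from [face_space_positions()] with a
#'   `gender` column.
#' @param k pool size per cell (default 20).
#' @param mode `"quadrant"` or `"emotion"`.
#' @param emotion_output required in emotion mode: probability matrix
#'   with rownames = face ids.
#' @param emotion emotion name (emotion mode).
#' @param windows quadrant windows (labels must match the `quadrant`
#'   column).
#' @return named list of character vectors of face ids
#'   (`<cell>.<gender>`); attribute `short` flags cells with fewer than
#'   `k` eligible faces.
#' @export
select_prototypes <- function(positions, k = 20,
                              mode = c("quadrant", "emotion"),
                              emotion_output = NULL, emotion = NULL,
                              windows = quadrant_windows()) {
  mode <- match.arg(mode)
  stopifnot(nrow(positions) > 0, k >= 1, "gender" %in% names(positions))
  pools <- list(); short <- character(0)
  genders <- sort(unique(positions$gender))
  if (mode == "quadrant") {
    for (q in names(windows$windows)) for (g in genders) {
      el <- positions[positions$quadrant == q & positions$gender == g, ]
      sel <- rank_select(el$face_id, el$E_hat, k, decreasing = TRUE)
      nm <- paste0("Q", q, ".", g)
      pools[[nm]] <- sel
      if (length(sel) < k) short <- c(short, nm)
    }
  } else {
    if (is.null(emotion_output) || is.null(emotion))
      stop("emotion mode needs emotion_output and an emotion name")
    stopifnot(emotion %in% colnames(emotion_output))
    p <- emotion_output[match(positions$face_id, rownames(emotion_output)),
                        emotion]
    for (g in genders) {
      el <- positions$gender == g
      sel <- rank_select(positions$face_id[el], p[el], k, decreasing = TRUE)
      nm <- paste0(emotion, ".", g)
      pools[[nm]] <- sel
      if (length(sel) < k) short <- c(short, nm)
    }
  }
  if (length(short))
    warning("pools smaller than k: ", paste(short, collapse = ", "))
  attr(pools, "short") <- short
  pools
}

#' Select close-to-origin base faces
#'
#' Per gender, the `n_per_gender` faces with the smallest distance from
#' the face-space origin (ascending, ties broken by face id).
#'
#' @param positions position table with `gender` and `E_hat`.
#' @param n_per_gender bases per gender.
#' @return named list (`female`, `male`, ...) of face-id vectors.
#' @export
select_origin_bases <- function(positions, n_per_gender = 4) {
  stopifnot("gender" %in% names(positions))
  out <- list()
  for (g in sort(unique(positions$gender))) {
    el <- positions[positions$gender == g, ]
    if (nrow(el) < n_per_gender)
      stop("fewer than ", n_per_gender, " faces for gender ", g)
    out[[g]] <- rank_select(el$face_id, el$E_hat, n_per_gender,
                            decreasing = FALSE)
  }
  out
}
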