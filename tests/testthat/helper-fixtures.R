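# Shared fixture builders. Cohorts are generated in code (no stored
# binaries); heavier cohorts are memoized so several tests can share
# one generation pass.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Params with every planted field zeroed: all faces identical by
# construction once the noise SDs are zero too.
zero_params <- function(idiosyncrasy_sd = 0, pixel_noise_sd = 0) {
  zd <- lapply(EMOTIONS, function(e)
    matrix(0, 42, 2, dimnames = list(NULL, c("x", "y"))))
  names(zd) <- EMOTIONS
  zc <- lapply(EMOTIONS, function(e) c(0, 0, 0)); names(zc) <- EMOTIONS
  zt <- stats::setNames(rep(0, 7), EMOTIONS)
  zg <- lapply(EMOTIONS, function(e) c(0, 4, 0)); names(zg) <- EMOTIONS
  face_gen_params(
    emotion_displacements = zd, emotion_color = zc, emotion_texture = zt,
    emotion_grain = zg,
    gender_shape_offset = matrix(0, 42, 2),
    gender_color_offset = c(0, 0, 0), gender_texture_offset = 0,
    texture_base_amp = 0,
    idiosyncrasy_sd = idiosyncrasy_sd, pixel_noise_sd = pixel_noise_sd)
}

# Noise-free cohort with full planted signal: every metric separable.
separable_cohort <- function() memo("separable", {
  make_cohort(face_gen_params(idiosyncrasy_sd = 0, pixel_noise_sd = 0),
              n_per_cell = 4, seed = 101)
})

separable_features <- function() memo("separable_feats", {
  cohort_features(separable_cohort())
})

# Default-noise cohort used by classifier tests.
noisy_cohort <- function() memo("noisy", {
  make_cohort(face_gen_params(), n_per_cell = 10, seed = 202)
})

noisy_features <- function() memo("noisy_feats", {
  cohort_features(noisy_cohort())
})

one_hot <- function(emotion) {
  v <- stats::setNames(rep(0, 7), EMOTIONS)
  v[emotion] <- 1
  v
}

# Attenuated-signal, elevated-noise cohort: every metric partially
# (not perfectly) informative; used for the
# combination-beats-individual property.
acceptance_cohort <- function() memo("acc", {
  p <- face_gen_params(
    emotion_displacements = lapply(facetriad:::default_displacements(128),
                                   function(m) m * 0.4),
    emotion_color = lapply(facetriad:::default_emotion_color(),
                           function(v) v * 0.4),
    emotion_texture = facetriad:::default_emotion_texture() * 0.4,
    emotion_grain = lapply(facetriad:::default_emotion_grain(),
                           function(g) c(g[1], g[2], g[3] * 0.15)),
    idiosyncrasy_sd = 2, pixel_noise_sd = 0.05)
  make_cohort(p, n_per_cell = 24, seed = 303)
})

acceptance_features <- function() memo("acc_feats", {
  cohort_features(acceptance_cohort())
})

# Clean training cohort + confounded application cohort for the
# gender-confound recovery check (male neutrals shifted halfway toward
# anger, female neutrals toward fear).
confound_train_cohort <- function() memo("cf_train", {
  make_cohort(face_gen_params(), n_per_cell = 15, seed = 404)
})

confound_train_features <- function() memo("cf_train_feats", {
  cohort_features(confound_train_cohort())
})

confound_apply_cohort <- function() memo("cf_apply", {
  make_cohort(face_gen_params(), n_per_cell = 29,
              confound_spec = list(male = c(anger = 0.5),
                                   female = c(fear = 0.5)),
              seed = 505)
})

confound_apply_features <- function() memo("cf_apply_feats", {
  cohort_features(confound_apply_cohort())
})

# Random emotion-output simplex vectors (7 classes).
random_simplex <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rexp(n * 7), n, 7, dimnames = list(NULL, EMOTIONS))
  m / rowSums(m)
}
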