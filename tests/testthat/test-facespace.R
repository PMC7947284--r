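test_that("one-hot projections reproduce the circumplex table exactly", {
  K <- knutson_coefficients()
  expected <- list(anger = c(1, -1.5), disgust = c(0.6, -1),
                   happy = c(1, 2), fear = c(-0.5, 0.5),
                   sad = c(-1, 0.1), surprise = c(-0.5, 0.1))
  for (e in names(expected)) {
    p <- project_emotions(one_hot(e), K)
    expect_identical(c(p$D_hat, p$A_hat), expected[[e]])
  }
  # pure neutral projects to the origin
  p0 <- project_emotions(one_hot("neutral"), K)
  expect_identical(c(p0$D_hat, p0$A_hat), c(0, 0))
  # half anger, half sad: hand dot product
  mix <- stats::setNames(c(0.5, 0, 0, 0, 0.5, 0, 0), EMOTIONS)
  pm <- project_emotions(mix, K)
  expect_equal(c(pm$D_hat, pm$A_hat), c(0, -0.7), tolerance = 1e-12)
  expect_error(project_emotions(c(anger = 1)), "missing classes")
  expect_error(knutson_coefficients(dominance = c(anger = 1)),
               "six expressive emotions")
})

test_that("projection is linear in the emotion output", {
  V <- random_simplex(50, seed = 41)
  K <- knutson_coefficients()
  for (i in seq_len(25)) {
    a <- runif(1)
    mixed <- a * V[2 * i - 1, ] + (1 - a) * V[2 * i, ]
    lhs <- project_emotions(mixed, K)
    p1 <- project_emotions(V[2 * i - 1, ], K)
    p2 <- project_emotions(V[2 * i, ], K)
    expect_equal(lhs$D_hat, a * p1$D_hat + (1 - a) * p2$D_hat,
                 tolerance = 1e-9)
    expect_equal(lhs$A_hat, a * p1$A_hat + (1 - a) * p2$A_hat,
                 tolerance = 1e-9)
  }
})

test_that("polar conversion handles the axes and the worked anger case", {
  expect_equal(unlist(polar_position(0, 1)), c(E_hat = 1, theta_deg = 0))
  expect_equal(unlist(polar_position(1, 0)), c(E_hat = 1, theta_deg = 90))
  p <- polar_position(1, -1.5)   # one-hot anger coordinates
  expect_equal(p$E_hat, sqrt(3.25), tolerance = 1e-9)
  expect_equal(p$theta_deg, 180 - atan2(1, 1.5) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(round(p$theta_deg, 2), 146.31)
  expect_equal(unlist(polar_position(0, 0)), c(E_hat = 0, theta_deg = 0))
  expect_error(polar_position(NaN, 1), "non-finite")
})

test_that("polar round-trip recovers coordinates to 1e-9", {
  V <- random_simplex(200, seed = 42)
  pr <- project_emotions(V)
  pol <- polar_position(pr$D_hat, pr$A_hat)
  A_back <- pol$E_hat * cos(pol$theta_deg * pi / 180)
  D_back <- pol$E_hat * sin(pol$theta_deg * pi / 180)
  expect_lt(max(abs(A_back - pr$A_hat)), 1e-9)
  expect_lt(max(abs(D_back - pr$D_hat)), 1e-9)
})

test_that("quadrant assignment matches windows, distance rule, and signs", {
  w <- quadrant_windows()
  expect_equal(assign_quadrant(45, 0.5, w), "I")
  expect_equal(assign_quadrant(45, 0.10, w), "none")  # <= 0.15 fails
  expect_equal(assign_quadrant(45, 0.15, w), "none")  # strict inequality
  expect_equal(assign_quadrant(90, 5, w), "none")     # gap between 80 and 100
  expect_equal(assign_quadrant(c(135, 225, 315), c(1, 1, 1), w),
               c("II", "III", "IV"))
  # inclusive bounds
  expect_equal(assign_quadrant(c(10, 80), c(1, 1), w), c("I", "I"))
  expect_error(quadrant_windows(list(I = c(10, 100), II = c(90, 170))),
               "overlapping")

  # sign-based oracle on random positions
  set.seed(7)
  D <- runif(500, -2, 2); A <- runif(500, -2, 2)
  pol <- polar_position(D, A)
  q <- assign_quadrant(pol$theta_deg, pol$E_hat, w)
  signs <- list(I = c(1, 1), II = c(1, -1), III = c(-1, -1), IV = c(-1, 1))
  for (i in which(q != "none")) {
    expect_equal(sign(c(D[i], A[i])), signs[[q[i]]])
    expect_gt(pol$E_hat[i], 0.15)
  }
})

make_positions <- function(n, seed) {
  set.seed(seed)
  pos <- data.frame(face_id = sprintf("s%04d", seq_len(n)),
                    gender = sample(c("female", "male"), n, replace = TRUE),
                    D_hat = runif(n, -2, 2), A_hat = runif(n, -2, 2))
  pol <- polar_position(pos$D_hat, pos$A_hat)
  pos <- cbind(pos, pol)
  pos$quadrant <- assign_quadrant(pos$theta_deg, pos$E_hat)
  pos
}

test_that("prototype selection matches an exhaustive sort oracle", {
  pos <- make_positions(500, seed = 13)
  pools <- select_prototypes(pos, k = 20)
  for (q in c("I", "II", "III", "IV")) for (g in c("female", "male")) {
    el <- pos[pos$quadrant == q & pos$gender == g, ]
    oracle <- el$face_id[order(-el$E_hat, el$face_id)]
    oracle <- oracle[seq_len(min(20, length(oracle)))]
    expect_identical(pools[[paste0("Q", q, ".", g)]], oracle)
  }
})

test_that("emotion-mode pools rank by class probability", {
  pos <- make_positions(60, seed = 14)
  eo <- random_simplex(60, seed = 15)
  rownames(eo) <- pos$face_id
  pools <- select_prototypes(pos, k = 5, mode = "emotion",
                             emotion_output = eo, emotion = "anger")
  for (g in c("female", "male")) {
    el <- pos$gender == g
    oracle <- pos$face_id[el][order(-eo[el, "anger"], pos$face_id[el])][1:5]
    expect_identical(pools[[paste0("anger.", g)]], oracle)
  }
})

test_that("small pools are returned whole with a warning flag", {
  pos <- make_positions(30, seed = 16)
  expect_warning(pools <- select_prototypes(pos, k = 20), "smaller than k")
  short <- attr(pools, "short")
  expect_true(length(short) > 0)
  for (nm in short)
    expect_lt(length(pools[[nm]]), 20)
})

test_that("origin bases are the closest faces, origin itself first", {
  pos <- make_positions(40, seed = 17)
  pos$E_hat[5] <- 0; pos$theta_deg[5] <- 0; pos$quadrant[5] <- "none"
  g5 <- pos$gender[5]
  bases <- select_origin_bases(pos, 4)
  expect_equal(bases[[g5]][1], pos$face_id[5])
  for (g in c("female", "male")) {
    el <- pos[pos$gender == g, ]
    oracle <- el$face_id[order(el$E_hat, el$face_id)][1:4]
    expect_identical(bases[[g]], oracle)
  }
  expect_error(select_origin_bases(pos[1:3, ], 4), "fewer than")
})
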