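test_that("landmark normalization fixes the eye frame exactly", {
  lm <- face_template()$points
  n <- normalize_landmarks(lm)
  ec <- eye_centers(n$points)
  expect_lt(abs(sqrt(sum((ec["right", ] - ec["left", ])^2)) - 1), 1e-9)
  expect_lt(max(abs(colMeans(ec))), 1e-9)
  # idempotent: normalizing a normalized set is (numerically) a no-op
  n2 <- normalize_landmarks(n$points * 100 + 50)  # rescale into "pixels"
  expect_lt(max(abs(n2$points - n$points)), 1e-9)
})

test_that("normalization is invariant to similarity transforms", {
  lm <- separable_cohort()$records[[1]]$landmarks
  n <- normalize_landmarks(lm)
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  lm2 <- (lm %*% t(R)) * 2 + 7
  expect_lt(max(abs(normalize_landmarks(lm2)$points - n$points)), 1e-6)
  # degenerate: coincident eye centers
  bad <- lm; bad[11:18, ] <- 3
  expect_error(normalize_landmarks(bad), "degenerate")
})

test_that("planted brow raise appears as offset / interocular distance", {
  lm <- face_template()$points
  d <- 4
  raised <- lm; raised[1:10, 2] <- raised[1:10, 2] - d
  iod <- sqrt(sum(diff(eye_centers(lm))^2))
  f0 <- extract_structure(normalize_landmarks(lm))
  f1 <- extract_structure(normalize_landmarks(raised))
  expect_equal(unname(f1["brow_eye_gap_l"] - f0["brow_eye_gap_l"]),
               d / iod, tolerance = 1e-6)
  expect_equal(unname(f1["brow_eye_gap_r"] - f0["brow_eye_gap_r"]),
               d / iod, tolerance = 1e-6)
})

test_that("eye-mouth distance feature tracks the planted manipulation", {
  lm <- face_template()$points
  shorter <- lm; shorter[24:35, 2] <- shorter[24:35, 2] - 6
  f0 <- extract_structure(normalize_landmarks(lm))
  f1 <- extract_structure(normalize_landmarks(shorter))
  expect_lt(f1["eye_mouth_dist"], f0["eye_mouth_dist"])
})

test_that("structure features are identical across similarity transforms", {
  lm <- separable_cohort()$records[[8]]$landmarks
  th <- -0.4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  lm2 <- lm %*% t(R) * 1.7 + 20
  f1 <- extract_structure(normalize_landmarks(lm))
  f2 <- extract_structure(normalize_landmarks(lm2))
  expect_equal(unclass(f1), unclass(f2), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("interior mask is the filled hull, checked against a shoelace oracle", {
  r <- separable_cohort()$records[[1]]
  reg <- interior_region(r$landmarks, dim(r$image)[1:2])
  hull <- reg$hull
  oracle_area <- abs(pracma::polyarea(hull[, 1], hull[, 2]))
  expect_lt(abs(sum(reg$mask) - oracle_area) / oracle_area, 0.02)
  expect_lt(sum(reg$mask), prod(dim(r$image)[1:2]))
  for (m in reg$regions) expect_true(all(!m | reg$mask))
  # collinear landmarks have no interior
  flat <- cbind(seq(5, 100, length.out = 42), 50)
  expect_error(interior_region(flat, c(128, 128)), "degenerate")
})

test_that("color features behave on constructed images", {
  r <- separable_cohort()$records[[1]]
  reg <- interior_region(r$landmarks, dim(r$image)[1:2])
  gray <- array(0.5, dim(r$image))
  fc <- extract_color(gray, reg$regions)
  means <- fc[grep("L_mean$", names(fc))]
  expect_lt(max(means) - min(means), 1e-9)
  expect_true(all(fc[grep("_sd$", names(fc))] == 0))
  expect_true(all(fc[grep("contrast$", names(fc))] == 0))

  red <- gray
  ch <- red[, , 1]; ch[reg$regions$cheeks] <- 1; red[, , 1] <- ch
  fr <- extract_color(red, reg$regions)
  px <- cbind(red[, , 1][reg$regions$cheeks],
              red[, , 2][reg$regions$cheeks],
              red[, , 3][reg$regions$cheeks])
  expect_equal(unname(fr["cheeks_L_mean"]),
               mean(grDevices::convertColor(px, "sRGB", "Lab")[, 1]),
               tolerance = 1e-9)
  expect_equal(unname(fr["eyes_L_mean"]), unname(fc["eyes_L_mean"]))

  empty <- reg$regions; empty$mouth[] <- FALSE
  expect_error(extract_color(gray, empty), "mouth")
})

test_that("planted eye darkening is recovered by the contrast feature", {
  r <- separable_cohort()$records[[1]]
  reg <- interior_region(r$landmarks, dim(r$image)[1:2])
  img <- array(0.6, dim(r$image))
  for (c3 in 1:3) {
    ch <- img[, , c3]; ch[reg$regions$eyes] <- 0.4; img[, , c3] <- ch
  }
  fc <- extract_color(img, reg$regions)
  # oracle: direct average of painted pixels
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  oracle <- mean(lum[reg$regions$cheeks]) - mean(lum[reg$regions$eyes])
  expect_equal(unname(fc["eye_cheek_contrast"]), oracle, tolerance = 1e-12)
  expect_equal(unname(fc["eye_cheek_contrast"]), 0.2, tolerance = 0.02)
})

test_that("texture energies are zero on constant images and grow with noise", {
  mask <- matrix(TRUE, 96, 96)
  flat <- array(0.5, c(96, 96, 3))
  f0 <- extract_texture(flat, mask)
  expect_lt(max(abs(f0)), 1e-10)
  set.seed(31)
  noise <- array(stats::rnorm(96 * 96, 0, 0.05), c(96, 96))
  noisy <- flat + array(rep(noise, 3), c(96, 96, 3))
  f1 <- extract_texture(noisy, mask)
  expect_true(all(f1[grep("_mean$", names(f1))] >
                    f0[grep("_mean$", names(f0))]))
  # mask smaller than the largest filter support is rejected
  tiny <- matrix(FALSE, 96, 96); tiny[40:48, 40:48] <- TRUE
  expect_error(extract_texture(flat, tiny), "filter support")
})

test_that("a grating at a bank frequency peaks at the matching filter", {
  # oracle: direct spatial convolution of every kernel at interior pixels
  n <- 72
  lam <- 8
  Y <- matrix(rep(0:(n - 1), times = n), n)
  img1 <- 0.5 + 0.3 * sin(2 * pi * Y / lam)
  img <- array(rep(img1, 3), c(n, n, 3))
  mask <- matrix(TRUE, n, n)
  bank <- gabor_bank()
  ft <- extract_texture(img, mask, bank)
  means <- ft[grep("_mean$", names(ft))]
  expect_equal(names(which.max(means)), "o90_w8_mean")

  direct_energy <- function(f) {
    hs <- (nrow(f$even) - 1) / 2
    pts <- as.matrix(expand.grid(y = seq(hs + 1, n - hs, by = 7),
                                 x = seq(hs + 1, n - hs, by = 7)))
    resp <- apply(pts, 1, function(p) {
      patch <- img1[(p[1] - hs):(p[1] + hs), (p[2] - hs):(p[2] + hs)]
      # convolution flips the kernel; Gabor kernels are (anti)symmetric
      sqrt(sum(patch * f$even[nrow(f$even):1, ncol(f$even):1])^2 +
             sum(patch * f$odd[nrow(f$odd):1, ncol(f$odd):1])^2)
    })
    mean(resp)
  }
  oracle <- vapply(bank, direct_energy, 0)
  expect_equal(names(which.max(oracle)), "o90_w8")
})

test_that("feature matrices are aligned and finite across a cohort", {
  fs <- separable_features()
  co <- separable_cohort()
  for (m in names(fs)) {
    expect_equal(rownames(fs[[m]]), co$metadata$face_id)
    expect_true(all(is.finite(fs[[m]])))
  }
  # color/texture ignore face identity relabeling; structure ignores image
  r <- co$records[[2]]
  reg <- interior_region(r$landmarks, dim(r$image)[1:2])
  a <- extract_color(r$image, reg$regions)
  r2 <- r; r2$face_id <- "renamed"
  b <- extract_color(r2$image, reg$regions)
  expect_identical(unclass(a), unclass(b))
})

test_that("feature CSV round-trip preserves the matrices", {
  fs <- separable_features()
  dir <- withr::local_tempdir()
  write_features(fs, dir)
  back <- read_features(dir)
  for (m in names(fs))
    expect_equal(back[[m]], fs[[m]], tolerance = 1e-9)
})
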