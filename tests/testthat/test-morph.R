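test_that("shape blending is exact, symmetric at 0.5, and guarded", {
  a <- face_template()$points
  b <- a + 3
  expect_identical(average_shape(a, b, 0), a)
  expect_equal(average_shape(matrix(c(0, 0), 1), matrix(c(10, 4), 1), 0.5),
               matrix(c(5, 2), 1))
  expect_equal(average_shape(a, b, 0.5), average_shape(b, a, 0.5))
  expect_error(average_shape(a, b[1:10, ], 0.5), "match")
  expect_error(average_shape(a, b, 1.5), "alpha")
})

test_that("template triangulation is a valid Delaunay-style cover", {
  tris <- template_triangles(128)
  expect_true(nrow(tris) > 40)
  expect_setequal(sort(unique(as.vector(tris))), 1:42)
  pts <- face_template()$points
  areas <- apply(tris, 1, function(tr) {
    abs(pracma::polyarea(pts[tr, 1], pts[tr, 2]))
  })
  expect_true(all(areas > 1e-6))
  # total area equals hull area (triangles tile the hull)
  hull <- pts[grDevices::chull(pts), ]
  expect_equal(sum(areas), abs(pracma::polyarea(hull[, 1], hull[, 2])),
               tolerance = 1e-6)
})

test_that("identity warp reproduces the image within one gray level", {
  r <- separable_cohort()$records[[1]]
  w <- warp_image(r$image, r$landmarks, r$landmarks)
  expect_lt(max(abs(w - r$image)), 1 / 255)
  # uniform image stays uniform under any warp
  flat <- array(0.4, dim(r$image))
  w2 <- warp_image(flat, r$landmarks, r$landmarks + 2)
  expect_lt(max(abs(w2 - 0.4)), 1e-9)
})

test_that("a global landmark translation shifts interior content", {
  r <- separable_cohort()$records[[3]]
  t_px <- 5
  dst <- r$landmarks + cbind(rep(t_px, 42), 0)
  w <- warp_image(r$image, r$landmarks, dst)
  # oracle: shift the source image directly by t_px
  reg <- interior_region(dst, dim(r$image)[1:2])
  inner <- reg$mask
  inner[, 1:(t_px + 1)] <- FALSE
  diffs <- abs(w[, , 1][inner] -
                 r$image[, , 1][cbind(row(inner)[inner],
                                      col(inner)[inner] - t_px)])
  expect_lt(stats::quantile(diffs, 0.99), 1 / 255)
  expect_error(warp_image(r$image, r$landmarks, r$landmarks * 0),
               "degenerate")
})

test_that("blend endpoints recover base and donor", {
  co <- separable_cohort()
  base <- co$records[[which(co$metadata$emotion == "neutral" &
                              co$metadata$gender == "female")[1]]]
  donor <- co$records[[which(co$metadata$emotion == "happy" &
                              co$metadata$gender == "female")[1]]]
  b0 <- blend_transform(base, donor, 0)
  expect_identical(b0$landmarks, base$landmarks)
  reg <- interior_region(base$landmarks, dim(base$image)[1:2])
  expect_lt(mean(abs(b0$image - base$image)[reg$mask]), 2 / 255)
  b1 <- blend_transform(base, donor, 1)
  expect_identical(b1$landmarks, donor$landmarks)
  # self-blend is the identity
  bs <- blend_transform(base, base, 0.5)
  expect_lt(max(abs(bs$image - base$image)), 1 / 255)
  male <- co$records[[which(co$metadata$gender == "male")[1]]]
  expect_error(blend_transform(base, male), "gender")
})

test_that("blend luminance equals the average of the warped faces", {
  co <- separable_cohort()
  ids <- which(co$metadata$gender == "male")
  base <- co$records[[ids[1]]]; donor <- co$records[[ids[8]]]
  lm <- average_shape(base$landmarks, donor$landmarks, 0.5)
  wb <- warp_image(base$image, base$landmarks, lm)
  wd <- warp_image(donor$image, donor$landmarks, lm)
  blend <- blend_transform(base, donor, 0.5)
  reg <- interior_region(lm, dim(base$image)[1:2])
  lum <- function(img) mean(((img[, , 1] + img[, , 2] + img[, , 3]) / 3)[reg$mask])
  expect_equal(lum(blend$image), (lum(wb) + lum(wd)) / 2, tolerance = 0.01)
})

test_that("stimulus-set construction follows the sampling design", {
  co <- make_cohort(face_gen_params(image_size = 64), 6, seed = 33)
  ids <- co$metadata$face_id
  recs <- co$records; names(recs) <- ids
  fem <- ids[co$metadata$gender == "female"]
  mal <- ids[co$metadata$gender == "male"]
  bases <- list(female = fem[1:2], male = mal[1:2])
  pools <- list(QI.female = fem[3:8], QI.male = mal[3:8],
                QII.female = fem[9:14], QII.male = mal[9:14])
  set <- build_stimulus_set(recs, bases, pools, reps_per_category = 2,
                            seed = 12)
  # |bases| x |categories| x reps
  expect_equal(nrow(set$manifest), 4 * 2 * 2)
  expect_length(set$records, nrow(set$manifest))
  # no donor repeats within a base x category (pool is large enough)
  reps <- tapply(set$manifest$donor_id,
                 paste(set$manifest$base_id, set$manifest$category),
                 function(v) any(duplicated(v)))
  expect_false(any(reps))
  expect_false(any(set$manifest$with_replacement))
  # gender matching throughout
  g_of <- stats::setNames(co$metadata$gender, ids)
  expect_true(all(g_of[set$manifest$base_id] == g_of[set$manifest$donor_id]))
  # same seed reproduces the manifest
  set2 <- build_stimulus_set(recs, bases, pools, reps_per_category = 2,
                             seed = 12)
  expect_identical(set$manifest, set2$manifest)
  expect_error(build_stimulus_set(recs, bases, list(QI.female = fem[3:4]),
                                  reps_per_category = 2, seed = 1),
               "empty gender-matched pool")
})
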