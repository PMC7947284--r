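test_that("masculinity composite is masc minus fem", {
  expect_equal(masculinity_composite(5, 2), 3)
  expect_equal(masculinity_composite(c(4, 4), c(4, 4)), c(0, 0))
  expect_error(masculinity_composite(1:3, 1:2), "length")
  set.seed(5)
  masc <- rnorm(200)
  fem <- -masc + rnorm(200, 0, 0.1)
  comp <- masculinity_composite(masc, fem)
  expect_gt(stats::cor(comp, masc), 0.99)
})

test_that("correlation matrix matches cor.test and handles degeneracy", {
  set.seed(8)
  n <- 200
  machine <- cbind(anger = rnorm(n), happy = rnorm(n))
  ratings <- cbind(dominant = machine[, "anger"] + rnorm(n, 0, 0.5),
                   trustworthy = rnorm(n), flat = rep(1, n))
  out <- correlate_traits(machine, ratings)
  expect_equal(out$r["anger", "dominant"],
               unname(stats::cor(machine[, "anger"], ratings[, "dominant"])),
               tolerance = 1e-12)
  expect_true(out$sig["anger", "dominant"])
  expect_gt(out$r["anger", "dominant"], 0)
  expect_true(is.na(out$r["anger", "flat"]))
  expect_false(out$sig["anger", "flat"])
  # self-correlation is exactly 1
  self <- correlate_traits(machine, machine[, "anger", drop = FALSE])
  expect_equal(self$r["anger", "anger"], 1)
  expect_error(correlate_traits(machine[1:2, ], ratings[1:2, ]),
               "at least 3")
})

test_that("independent noise yields near-null correlations at ~5% flags", {
  set.seed(10)
  n <- 200
  machine <- matrix(rnorm(n * 6), n, dimnames = list(NULL, EMOTIONS6))
  ratings <- matrix(rnorm(n * 8), n, dimnames = list(NULL, TRAITS))
  out <- correlate_traits(machine, ratings)
  expect_lt(max(abs(out$r)), 0.25)
  expect_lt(mean(out$sig), 0.15)
})

test_that("mediation paths match an independent lm() oracle", {
  set.seed(20)
  n <- 120
  x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.4 * m + 0.2 * x + rnorm(n)
  res <- mediate(x, m, y, n_boot = 200, seed = 1)
  zx <- as.vector(scale(x)); zm <- as.vector(scale(m)); zy <- as.vector(scale(y))
  fit_a <- stats::lm(zm ~ zx)
  fit_y <- stats::lm(zy ~ zx + zm)
  fit_c <- stats::lm(zy ~ zx)
  expect_equal(res$a, unname(coef(fit_a)["zx"]), tolerance = 1e-10)
  expect_equal(res$b, unname(coef(fit_y)["zm"]), tolerance = 1e-10)
  expect_equal(res$c_prime, unname(coef(fit_y)["zx"]), tolerance = 1e-10)
  expect_equal(res$c, unname(coef(fit_c)["zx"]), tolerance = 1e-10)
  expect_equal(unname(res$se["a"]),
               unname(summary(fit_a)$coefficients["zx", 2]),
               tolerance = 1e-6)
  expect_equal(unname(res$se["b"]),
               unname(summary(fit_y)$coefficients["zm", 2]),
               tolerance = 1e-6)
  # the decomposition identity, to numerical precision
  expect_lt(abs(res$c - (res$c_prime + res$ab)), 1e-10)
})

test_that("a perfect causal chain gives a = b = 1 and c' = 0", {
  x <- rep(c(-1, 1), 10)
  m <- x
  y <- m
  res <- mediate(x, m, y, n_boot = 50, seed = 2)
  expect_equal(res$a, 1, tolerance = 1e-10)
  expect_equal(res$b, 1, tolerance = 1e-10)
  expect_equal(res$c_prime, 0, tolerance = 1e-10)
  expect_equal(res$ab, 1, tolerance = 1e-10)
  expect_error(mediate(rep(1, 20), rnorm(20), rnorm(20)), "constant")
  expect_error(mediate(rnorm(5), rnorm(5), rnorm(5)), "n >= 10")
})

test_that("mediation is reproducible and row-order invariant", {
  set.seed(30)
  n <- 80
  x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.4 * m + rnorm(n)
  r1 <- mediate(x, m, y, n_boot = 300, seed = 9)
  r2 <- mediate(x, m, y, n_boot = 300, seed = 9)
  expect_identical(r1$ci, r2$ci)
  perm <- sample(n)
  r3 <- mediate(x[perm], m[perm], y[perm], n_boot = 300, seed = 9)
  expect_equal(r3$ab, r1$ab, tolerance = 1e-12)
  expect_true(r1$ci["lower"] <= r1$ci["upper"])
})

test_that("bootstrap CI width shrinks with sample size", {
  gen <- function(n, seed) {
    set.seed(seed)
    x <- rnorm(n); m <- 0.4 * x + rnorm(n); y <- 0.4 * m + rnorm(n)
    mediate(x, m, y, n_boot = 500, seed = seed)
  }
  w50 <- mean(sapply(1:5, function(s) diff(gen(50, s)$ci)))
  w500 <- mean(sapply(1:5, function(s) diff(gen(500, s)$ci)))
  expect_lt(w500, w50)
})

test_that("trial preprocessing reproduces the planted manifest", {
  md <- data.frame(face_id = sprintf("f%03d", 1:30))
  ratings <- make_ratings(md, seed = 2)
  trials <- make_trials(ratings, n_participants = 14, n_faces_each = 10,
                        contamination = list(n_low_sd = 2, n_fast = 50,
                                             n_slow = 10), seed = 44)
  mf <- trial_manifest(trials)
  pp <- preprocess_trials(trials)
  expect_equal(pp$report$participants_dropped, 2)
  expect_setequal(pp$report$dropped_participant_ids, mf$low_sd_participants)
  expect_equal(pp$report$trials_dropped_fast, 50)
  expect_equal(pp$report$trials_dropped_slow, 10)
  expect_true(all(pp$trials$response >= 0 & pp$trials$response <= 6))
  expect_equal(pp$report$rows_retained, nrow(pp$trials))
  # accounting: retained + dropped = rows of retained participants
  kept_rows <- sum(!trials$participant_id %in% mf$low_sd_participants)
  expect_equal(pp$report$rows_retained + 50 + 10, kept_rows)
})

test_that("preprocessing is idempotent and clean tables pass untouched", {
  md <- data.frame(face_id = sprintf("f%03d", 1:20))
  ratings <- make_ratings(md, seed = 3)
  trials <- make_trials(ratings, n_participants = 8, n_faces_each = 8,
                        seed = 11)
  trials$response[1] <- 1L   # ensure the 1-7 scale's floor is occupied
  p1 <- preprocess_trials(trials)
  expect_equal(p1$report$participants_dropped, 0)
  expect_equal(p1$report$trials_dropped_fast +
                 p1$report$trials_dropped_slow, 0)
  expect_equal(nrow(p1$trials), nrow(trials))
  p2 <- preprocess_trials(p1$trials)
  expect_equal(p2$trials$response, p1$trials$response)
  expect_equal(nrow(p2$trials), nrow(p1$trials))
  expect_error(preprocess_trials(trials[0, ]), "empty")
})
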