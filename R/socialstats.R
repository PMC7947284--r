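# Statistics linking machine outputs to human impressions: the
# masculinity-femininity composite, trait correlation matrices,
# percentile-bootstrap mediation, and psychophysics trial
# preprocessing.

#' Masculinity-femininity composite
#'
#' `masculinity + (-1) * femininity`: higher scores = more masculine
#' appearance.
#'
#' @param masculinity,femininity aligned rating vectors.
#' @return numeric composite.
#' @export
masculinity_composite <- function(masculinity, femininity) {
  if (length(masculinity) != length(femininity))
    stop("masculinity and femininity vectors differ in length")
  masculinity - femininity
}

#' Correlation matrix between machine outputs and ratings
#'
#' Pearson correlations of every machine-output column with every
#' rating column, with two-sided p-values and a significance mask at
#' `alpha` (no multiple-testing correction). Zero-variance columns
#' yield NA cells rather than errors.
#'
#' @param machine numeric matrix/data.frame (rows = faces).
#' @param ratings numeric matrix/data.frame aligned to the same rows.
#' @param alpha significance level for the mask.
#' @return list: `r`, `p`, `sig` (logical), `n`.
#' @export
correlate_traits <- function(machine, ratings, alpha = 0.05) {
  machine <- as.matrix(machine); ratings <- as.matrix(ratings)
  if (nrow(machine) != nrow(ratings)) stop("row counts differ")
  if (nrow(machine) < 3) stop("need at least 3 paired observations")
  r <- matrix(NA_real_, ncol(machine), ncol(ratings),
              dimnames = list(colnames(machine), colnames(ratings)))
  p <- r
  for (i in seq_len(ncol(machine))) for (j in seq_len(ncol(ratings))) {
    x <- machine[, i]; y <- ratings[, j]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok])
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  list(r = r, p = p, sig = !is.na(p) & p < alpha, n = nrow(machine))
}

# Closed-form standardized simple + two-predictor OLS paths.
# All inputs are z-standardized first; returns a, b, c, c_prime and
# their OLS standard errors.
std_paths <- function(x, m, y) {
  n <- length(x)
  zx <- (x - mean(x)) / stats::sd(x)
  zm <- (m - mean(m)) / stats::sd(m)
  zy <- (y - mean(y)) / stats::sd(y)
  r_xm <- sum(zx * zm) / (n - 1)
  r_xy <- sum(zx * zy) / (n - 1)
  r_my <- sum(zm * zy) / (n - 1)
  a <- r_xm
  se_a <- sqrt(max(0, 1 - r_xm^2) / (n - 2))
  c_tot <- r_xy
  se_c <- sqrt(max(0, 1 - r_xy^2) / (n - 2))
  den <- 1 - r_xm^2
  if (den < 1e-10) {
    # x and m are collinear (perfect chain): the two-predictor fit is
    # rank deficient. Convention: attribute the shared variance to the
    # mediator (b from y ~ m alone, c' by the decomposition identity).
    b <- r_my
    c_p <- r_xy - a * b
    se_b <- sqrt(max(0, 1 - r_my^2) / (n - 2))
    return(list(a = a, b = b, c = r_xy, c_prime = c_p,
                se = c(a = se_a, b = se_b, c = se_c, c_prime = se_b)))
  }
  b <- (r_my - r_xm * r_xy) / den
  c_p <- (r_xy - r_xm * r_my) / den
  # residual variance of y ~ x + m (standardized scale)
  r2 <- c_p * r_xy + b * r_my
  sigma2 <- max(0, (1 - r2)) * (n - 1) / (n - 3)
  se_b <- sqrt(sigma2 / ((n - 1) * den))
  se_cp <- se_b
  list(a = a, b = b, c = c_tot, c_prime = c_p,
       se = c(a = se_a, b = se_b, c = se_c, c_prime = se_cp))
}

#' Percentile-bootstrap mediation
#'
#' Standardized simple-mediation model: path `a` from `m ~ x`, paths
#' `b` and `c_prime` from `y ~ x + m`, total effect `c` from `y ~ x`,
#' all variables z-standardized (a binary predictor is standardized
#' like any column). The indirect effect `ab = a * b` gets a percentile
#' confidence interval over `n_boot` case-resampled replicates
#' (variables re-standardized within each replicate). On standardized
#' OLS the identity `c = c_prime + ab` holds exactly and is asserted on
#' every call.
#'
#' @param x,m,y aligned predictor, mediator, outcome vectors (n >= 10).
#' @param n_boot bootstrap replicates (default 10000).
#' @param conf confidence level for the percentile interval.
#' @param seed integer seed.
#' @return object of class `mediation_result`: `a`, `b`, `c`,
#'   `c_prime`, `se`, `ab`, `ci` (lower, upper), `n`, `n_boot`, `seed`.
#' @export
mediate <- function(x, m, y, n_boot = 10000, conf = 0.95, seed = 1L) {
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y must be aligned")
  if (n < 10) stop("need n >= 10")
  if (stats::sd(x) == 0 || stats::sd(m) == 0 || stats::sd(y) == 0)
    stop("constant column")
  est <- std_paths(x, m, y)
  if (abs(est$c - (est$c_prime + est$a * est$b)) > 1e-8)
    stop("internal error: mediation identity c = c' + ab violated")
  set.seed(as.integer(seed))
  ab_boot <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; mb <- m[idx]; yb <- y[idx]
    sx <- stats::sd(xb); sm <- stats::sd(mb); sy <- stats::sd(yb)
    if (sx == 0 || sm == 0 || sy == 0) { ab_boot[i] <- NA; next }
    zx <- (xb - mean(xb)) / sx; zm <- (mb - mean(mb)) / sm
    zy <- (yb - mean(yb)) / sy
    r_xm <- sum(zx * zm) / (n - 1)
    r_xy <- sum(zx * zy) / (n - 1)
    r_my <- sum(zm * zy) / (n - 1)
    ab_boot[i] <- r_xm * (r_my - r_xm * r_xy) / (1 - r_xm^2)
  }
  qs <- stats::quantile(ab_boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  structure(list(a = est$a, b = est$b, c = est$c, c_prime = est$c_prime,
                 se = est$se, ab = est$a * est$b,
                 ci = c(lower = qs[1], upper = qs[2]),
                 conf = conf, n = n, n_boot = n_boot,
                 seed = as.integer(seed)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation: a=%.3f b=%.3f c=%.3f c'=%.3f ab=%.3f, %d%% CI [%.3f, %.3f], n=%d, %d boots>\n",
    x$a, x$b, x$c, x$c_prime, x$ab, round(100 * x$conf),
    x$ci[1], x$ci[2], x$n, x$n_boot))
  invisible(x)
}

#' Table of mediation results in the standard layout
#'
#' @param results named list of `mediation_result`s.
#' @return data.frame: model, a, se_a, b, se_b, c, se_c, c_prime,
#'   se_c_prime, ab, ci_lower, ci_upper.
#' @export
mediation_table <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(model = nm, a = r$a, se_a = r$se["a"], b = r$b,
               se_b = r$se["b"], c = r$c, se_c = r$se["c"],
               c_prime = r$c_prime, se_c_prime = r$se["c_prime"],
               ab = r$ab, ci_lower = r$ci[1], ci_upper = r$ci[2],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Preprocess a psychophysics trial table
#'
#' Applies the attention/reliability filters: (1) participants whose
#' response SD across all their trials is below `sd_min` are removed
#' entirely; (2) remaining trials with reaction time below `rt_min_ms`
#' or above `rt_max_ms` are removed; (3) responses are shifted by -1 so
#' they range 0-6. The shift is guarded by a range check (applied only
#' when responses are still on the 1-7 scale), which makes the whole
#' step idempotent.
#'
#' @param trials trial table (participant_id, face_id, trait, response,
#'   rt_ms).
#' @param sd_min participant response-SD threshold.
#' @param rt_min_ms,rt_max_ms reaction-time bounds.
#' @return list: `trials` (filtered, shifted), `report`
#'   (`participants_dropped`, `trials_dropped_fast`,
#'   `trials_dropped_slow`, `rows_retained`, `dropped_participant_ids`).
#' @export
preprocess_trials <- function(trials, sd_min = 0.4, rt_min_ms = 50,
                              rt_max_ms = 10000) {
  stopifnot(is.data.frame(trials),
            all(c("participant_id", "response", "rt_ms") %in% names(trials)))
  if (!nrow(trials)) stop("empty trial table")
  sds <- tapply(trials$response, trials$participant_id, stats::sd)
  sds[is.na(sds)] <- 0
  dropped_p <- names(sds)[sds < sd_min]
  kept <- trials[!trials$participant_id %in% dropped_p, , drop = FALSE]
  fast <- kept$rt_ms < rt_min_ms
  slow <- kept$rt_ms > rt_max_ms
  out <- kept[!(fast | slow), , drop = FALSE]
  if (nrow(out) && min(out$response) >= 1 && max(out$response) <= 7)
    out$response <- out$response - 1L
  report <- list(participants_dropped = length(dropped_p),
                 trials_dropped_fast = sum(fast),
                 trials_dropped_slow = sum(slow),
                 rows_retained = nrow(out),
                 dropped_participant_ids = dropped_p)
  attr(out, "manifest") <- attr(trials, "manifest")
  list(trials = out, report = report)
}

#' Thin mixed-model runner for rating contrasts
#'
#' Fits `response ~ face_type * trait + gender + attractiveness +
#' (1 | participant_id)` with standard mixed-model machinery (lmerTest
#' when available, otherwise lme4). Plumbing around the preprocessing
#' filters, not a re-implementation of mixed-model inference.
#'
#' @param data preprocessed trial data with columns `response`,
#'   `face_type`, `trait`, `gender`, `attractiveness`,
#'   `participant_id`.
#' @return fitted merMod object.
#' @export
trait_contrast_model <- function(data) {
  pkg <- if (requireNamespace("lmerTest", quietly = TRUE)) "lmerTest"
         else if (requireNamespace("lme4", quietly = TRUE)) "lme4"
         else stop("mixed-model fitting needs lme4 (or lmerTest)")
  fml <- stats::as.formula(
    "response ~ face_type * trait + gender + attractiveness + (1 | participant_id)")
  getExportedValue(pkg, "lmer")(fml, data = data)
}
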