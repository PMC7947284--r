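# Per-metric emotion classifiers and the accuracy-weighted combination.
#
# The base learner is decay-regularized multinomial logistic regression
# (nnet::multinom); a config hook switches to gradient-boosted trees
# (xgboost) when calibrated nonlinear boundaries are wanted. Downstream
# face-space math only needs calibrated class probabilities, so the
# linear learner is the default.

#' Stratified train/test split
#'
#' Splits face ids stratified by emotion x gender when every cell has
#' at least two members; otherwise falls back to emotion-only strata.
#' Every stratum contributes at least one face to each side, so every
#' emotion class is represented in both train and test.
#'
#' @param metadata data.frame with `face_id`, `emotion` and optionally
#'   `gender`.
#' @param test_fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` character vectors of face ids
#'   (disjoint, union = all ids).
#' @export
split_train_test <- function(metadata, test_fraction = 0.25, seed = 1L) {
  stopifnot(is.data.frame(metadata), "face_id" %in% names(metadata),
            "emotion" %in% names(metadata))
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  strata <- metadata$emotion
  if ("gender" %in% names(metadata)) {
    full <- interaction(metadata$emotion, metadata$gender, drop = TRUE)
    if (min(table(full)) >= 2) strata <- as.character(full)
  }
  tab <- table(strata)
  if (min(tab) < 2)
    stop("stratum smaller than 2: ", names(tab)[which.min(tab)])
  set.seed(as.integer(seed))
  test <- character(0)
  for (s in names(tab)) {
    ids <- metadata$face_id[strata == s]
    n_test <- min(max(round(test_fraction * length(ids)), 1), length(ids) - 1)
    test <- c(test, sample(ids, n_test))
  }
  list(train = sort(setdiff(metadata$face_id, test)), test = sort(test))
}

#' Train a single-metric emotion classifier
#'
#' Fits the configured learner on the training rows and measures test
#' accuracy on a disjoint held-out set (either given explicitly through
#' `split`, or drawn internally with [split_train_test()]).
#'
#' @param features numeric matrix, one row per face (rownames = ids).
#' @param labels factor/character emotion labels aligned to rows.
#' @param metric tag: `"structure"`, `"color"`, `"texture"` or other.
#' @param config list: `learner` (`"multinom"` or `"xgboost"`),
#'   `decay` (multinom weight decay), `nrounds`, `max_depth`, `eta`
#'   (xgboost).
#' @param split optional list(train, test) of face ids.
#' @param test_fraction used when `split` is NULL.
#' @param gender optional vector aligned to rows, for stratification.
#' @param seed integer seed.
#' @return object of class `metric_model` with the fitted state,
#'   `test_accuracy`, `classes`, and the split used.
#' @export
train_metric_model <- function(features, labels, metric = "structure",
                               config = list(learner = "multinom"),
                               split = NULL, test_fraction = 0.25,
                               gender = NULL, seed = 1L) {
  stopifnot(is.matrix(features))
  if (nrow(features) != length(labels))
    stop("feature rows and labels have different lengths")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("r%05d", seq_len(nrow(features)))
  ids <- rownames(features)
  if (is.null(split)) {
    md <- data.frame(face_id = ids, emotion = labels,
                     stringsAsFactors = FALSE)
    if (!is.null(gender)) md$gender <- gender
    split <- split_train_test(md, test_fraction, seed)
  }
  if (length(intersect(split$train, split$test)) > 0)
    stop("train and test ids overlap")
  tr <- ids %in% split$train; te <- ids %in% split$test
  classes <- sort(unique(labels[tr]))
  fit <- fit_learner(features[tr, , drop = FALSE],
                     factor(labels[tr], levels = classes), config, seed)
  model <- structure(list(metric = metric, fit = fit, classes = classes,
                          config = config, split = split,
                          feature_names = colnames(features),
                          center = fit$center, scale = fit$scale),
                     class = "metric_model")
  ev <- evaluate_accuracy(model, features[te, , drop = FALSE], labels[te])
  model$test_accuracy <- ev$accuracy
  model
}

fit_learner <- function(x, y, config, seed) {
  learner <- if (is.null(config$learner)) "multinom" else config$learner
  # drop zero-variance columns and z-scale (helps multinom converge)
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd)
  keep <- which(scl > 1e-12)
  if (!length(keep)) stop("all features are constant")
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep]), 2, scl[keep], "/")
  set.seed(as.integer(seed))
  if (learner == "multinom") {
    decay <- if (is.null(config$decay)) 0.01 else config$decay
    cap <- utils::capture.output(
      fit <- nnet::multinom(y ~ ., data = data.frame(y = y, xs),
                            decay = decay, maxit = 300, trace = FALSE,
                            MaxNWts = 20000))
    list(learner = "multinom", fit = fit, center = ctr[keep],
         scale = scl[keep], keep = keep)
  } else if (learner == "xgboost") {
    if (!requireNamespace("xgboost", quietly = TRUE))
      stop("xgboost learner requested but package not available")
    nrounds <- if (is.null(config$nrounds)) 60 else config$nrounds
    fit <- xgboost::xgboost(
      data = xs, label = as.integer(y) - 1L,
      params = list(objective = "multi:softprob", num_class = nlevels(y),
                    max_depth = config$max_depth %||% 3,
                    eta = config$eta %||% 0.3, nthread = 1),
      nrounds = nrounds, verbose = 0)
    list(learner = "xgboost", fit = fit, nclass = nlevels(y),
         center = ctr[keep], scale = scl[keep], keep = keep)
  } else stop("unknown learner: ", learner)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict per-class emotion probabilities
#'
#' @param object a `metric_model`.
#' @param features numeric matrix with the training columns.
#' @param ... unused.
#' @return matrix (rows = faces, columns = model classes), rows on the
#'   probability simplex.
#' @export
predict.metric_model <- function(object, features, ...) {
  stopifnot(is.matrix(features))
  if (!identical(colnames(features), object$feature_names) &&
      ncol(features) != length(object$feature_names))
    stop("feature dimensionality does not match the training features")
  f <- object$fit
  xs <- sweep(sweep(features[, f$keep, drop = FALSE], 2, f$center),
              2, f$scale, "/")
  if (f$learner == "multinom") {
    pr <- stats::predict(f$fit, newdata = data.frame(xs), type = "probs")
    if (is.null(dim(pr))) {
      pr <- if (nrow(xs) == 1) matrix(pr, 1,
                                      dimnames = list(NULL, names(pr)))
            else cbind(1 - pr, pr)  # 2-class: multinom returns P(class 2)
      if (ncol(pr) == 2 && is.null(colnames(pr)))
        colnames(pr) <- object$classes
    }
  } else {
    raw <- stats::predict(f$fit, xs)
    pr <- matrix(raw, ncol = f$nclass, byrow = TRUE,
                 dimnames = list(NULL, object$classes))
  }
  pr <- pr[, object$classes, drop = FALSE]
  pr <- pr / rowSums(pr)
  rownames(pr) <- rownames(features)
  pr
}

#' Accuracy-weighted combination of per-metric emotion outputs
#'
#' The combined output for class j is `sum_m w_m * I_mj / sum_m w_m`:
#' each model's emotion output weighted by its test accuracy and
#' renormalized to the simplex.
#'
#' @param outputs list of probability matrices (aligned rows/columns).
#' @param weights nonnegative weights, one per output; not all zero.
#' @return probability matrix on the simplex.
#' @export
combine_weighted <- function(outputs, weights) {
  stopifnot(length(outputs) == length(weights))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) <= 0) stop("weights must not be all zero")
  cls <- colnames(outputs[[1]])
  for (o in outputs)
    if (!identical(colnames(o), cls)) stop("class orders are not aligned")
  acc <- 0
  for (i in seq_along(outputs)) acc <- acc + weights[i] * outputs[[i]]
  acc / sum(weights)
}

#' Accuracy, per-class accuracy, and confusion table
#'
#' @param model a `metric_model` (or any object with a
#'   [predict.metric_model()]-compatible method).
#' @param features test feature matrix.
#' @param labels true labels aligned to rows.
#' @return list: `accuracy`, `per_class` (named), `confusion`
#'   (true x predicted counts), `n`.
#' @export
evaluate_accuracy <- function(model, features, labels) {
  labels <- as.character(labels)
  if (!nrow(features)) stop("empty test set")
  unseen <- setdiff(labels, model$classes)
  if (length(unseen))
    stop("unseen class label in test set: ", paste(unseen, collapse = ", "))
  pr <- stats::predict(model, features)
  pred <- model$classes[max.col(pr, ties.method = "first")]
  conf <- table(factor(labels, levels = model$classes),
                factor(pred, levels = model$classes))
  per_class <- diag(conf) / pmax(rowSums(conf), 1)
  list(accuracy = mean(pred == labels), per_class = per_class,
       confusion = conf, n = length(labels))
}

#' Train the three metric models and the accuracy-weighted combination
#'
#' All three models share one stratified split, so the combination
#' weights (test accuracies) are measured on the same held-out faces.
#'
#' @param features list of matrices from [cohort_features()].
#' @param metadata cohort metadata (face_id, emotion, gender).
#' @param config learner config (see [train_metric_model()]).
#' @param test_fraction held-out fraction.
#' @param seed integer seed.
#' @return object of class `combined_model`: `models` (named list),
#'   `weights`, `split`, `classes`.
#' @export
train_combined_model <- function(features, metadata,
                                 config = list(learner = "multinom"),
                                 test_fraction = 0.25, seed = 1L) {
  stopifnot(is.list(features), length(features) >= 1)
  split <- split_train_test(metadata, test_fraction, seed)
  labels <- metadata$emotion[match(rownames(features[[1]]), metadata$face_id)]
  models <- list()
  for (m in names(features)) {
    models[[m]] <- train_metric_model(features[[m]], labels, metric = m,
                                      config = config, split = split,
                                      seed = seed)
  }
  w <- vapply(models, `[[`, 0, "test_accuracy")
  if (sum(w) <= 0) w <- rep(1, length(models))  # degenerate: fall back to mean
  structure(list(models = models, weights = w, split = split,
                 classes = models[[1]]$classes),
            class = "combined_model")
}

#' @rdname train_combined_model
#' @param object a `combined_model`.
#' @param features list of per-metric feature matrices.
#' @param ... unused.
#' @export
predict.combined_model <- function(object, features, ...) {
  outs <- lapply(names(object$models), function(m)
    stats::predict(object$models[[m]], features[[m]]))
  combine_weighted(outs, unname(object$weights))
}

#' @export
print.metric_model <- function(x, ...) {
  cat(sprintf("<metric_model %s (%s): test accuracy %.3f, %d classes>\n",
              x$metric, x$fit$learner, x$test_accuracy, length(x$classes)))
  invisible(x)
}

#' @export
print.combined_model <- function(x, ...) {
  cat("<combined_model> weights:\n")
  print(round(x$weights, 3))
  invisible(x)
}
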