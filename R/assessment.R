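# Impairment-level classifiers over the 25 motor indicators: MLP and SVM
# via nnet/libsvm, an RBF network fitted directly (K-means centres,
# Gaussian units, ridge least-squares output weights), stratified
# cross-validated accuracy and MAPE reporting.

#' Classifier specification
#'
#' @param model_kind `"mlp"`, `"rbfn"` or `"svm"`.
#' @param hidden_neurons Hidden-layer size (MLP) / number of RBF centres.
#' @param rbf_width Gaussian width of the RBF units; `NULL` = median
#'   pairwise distance of the (standardized) training features.
#' @param svm_cost,svm_gamma Soft-margin cost and RBF-kernel gamma
#'   (`NULL` = 1/d); one-vs-one multi-class aggregation.
#' @param feature_subset `"all"` or a character vector of indicator
#'   names to train on.
#' @param folds Number of stratified cross-validation folds.
#' @param grouped If `TRUE`, folds are grouped by subject so a subject's
#'   pre and post sessions never straddle a train/test split (recommended
#'   to avoid leakage; default `FALSE` pools all sessions as independent
#'   points).
#' @param seed Integer seed controlling fold assignment and training.
#' @return An object of class `vr_model_spec`.
#' @export
model_spec <- function(model_kind = c("mlp", "rbfn", "svm"),
                       hidden_neurons = 2L, rbf_width = NULL,
                       svm_cost = 1, svm_gamma = NULL,
                       feature_subset = "all", folds = 5L,
                       grouped = FALSE, seed = 1L) {
  model_kind <- match.arg(model_kind)
  hidden_neurons <- as.integer(hidden_neurons)
  if (is.na(hidden_neurons) || hidden_neurons < 1L) {
    abort("`hidden_neurons` must be >= 1")
  }
  structure(
    list(model_kind = model_kind, hidden_neurons = hidden_neurons,
         rbf_width = rbf_width, svm_cost = svm_cost, svm_gamma = svm_gamma,
         feature_subset = feature_subset, folds = as.integer(folds),
         grouped = isTRUE(grouped), seed = as.integer(seed)),
    class = "vr_model_spec"
  )
}

# training-fold preprocessing: median imputation with missingness flags,
# then zero-mean/unit-variance standardization (constant columns get
# scale 1 so they pass through as zeros)
fit_preproc <- function(X) {
  X <- as.matrix(X)
  med <- apply(X, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  flag_cols <- colnames(X)[colSums(is.na(X)) > 0L]
  imp <- X
  for (j in seq_len(ncol(imp))) {
    imp[is.na(imp[, j]), j] <- med[j]
  }
  flags <- matrix(as.numeric(is.na(X[, flag_cols, drop = FALSE])),
                  nrow = nrow(X))
  full <- cbind(imp, flags)
  ctr <- colMeans(full)
  scl <- apply(full, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(median = med, flag_cols = flag_cols, center = ctr, scale = scl)
}

apply_preproc <- function(pp, X) {
  X <- as.matrix(X)
  flags <- matrix(as.numeric(is.na(X[, pp$flag_cols, drop = FALSE])),
                  nrow = nrow(X))
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- pp$median[j]
  }
  scale(cbind(X, flags), center = pp$center, scale = pp$scale)
}

check_training_input <- function(X, labels) {
  if (length(unique(labels)) < 2L) {
    abort("training labels contain a single class")
  }
  if (any(!is.finite(as.matrix(X)) & !is.na(as.matrix(X)))) {
    abort("non-finite feature values")
  }
}

one_hot <- function(labels, levels) {
  Y <- matrix(0, length(labels), length(levels))
  Y[cbind(seq_along(labels), match(labels, levels))] <- 1
  colnames(Y) <- levels
  Y
}

#' Train an impairment-level classifier
#'
#' Three model families behind one interface, all deterministic under
#' `spec$seed`:
#'
#' * **MLP** — single hidden layer of `hidden_neurons` logistic units
#'   with a softmax output over the K levels ([nnet::nnet], BFGS,
#'   `maxit = 2000`, weight decay `1e-4`);
#' * **RBFN** — Gaussian radial-basis units centred by K-means on the
#'   training features (`k = hidden_neurons`), width `rbf_width`, output
#'   weights by ridge least squares on one-hot targets, prediction by
#'   argmax;
#' * **SVM** — soft-margin RBF-kernel SVM with one-vs-one multi-class
#'   aggregation ([e1071::svm]/libsvm).
#'
#' Features are median-imputed (with missingness-flag columns) and
#' standardized using statistics of the data passed here, so
#' cross-validation in [evaluate_assessment()] never leaks test-fold
#' statistics into training.
#'
#' @param features Data frame / matrix of indicator values (may contain
#'   `NA`).
#' @param labels Integer impairment levels (1-based).
#' @param spec A [model_spec()].
#' @return An object of class `vr_assessor` with a [predict] method
#'   returning integer levels.
#' @export
train_assessor <- function(features, labels, spec = model_spec()) {
  check_training_input(features, labels)
  labels <- as.integer(labels)
  lvls <- sort(unique(labels))
  pp <- fit_preproc(features)
  Xs <- apply_preproc(pp, features)
  fit <- withr::with_seed(spec$seed, switch(
    spec$model_kind,
    mlp = nnet::nnet(x = Xs, y = one_hot(labels, lvls),
                     size = spec$hidden_neurons, softmax = TRUE,
                     maxit = 2000, decay = 1e-4, trace = FALSE,
                     MaxNWts = 10000),
    rbfn = {
      k <- spec$hidden_neurons
      if (k > nrow(Xs)) abort("more RBF centres than training samples")
      centers <- if (k == nrow(Xs)) Xs else lloyd_kmeans(Xs, k)$centers
      width <- spec$rbf_width %||% max(median(stats::dist(Xs)), 1e-6)
      P <- rbf_design(Xs, centers, width)
      Y <- one_hot(labels, lvls)
      W <- solve(crossprod(P) + 1e-6 * diag(ncol(P)), crossprod(P, Y))
      list(centers = centers, width = width, W = W)
    },
    svm = e1071::svm(x = Xs, y = factor(labels, levels = lvls),
                     kernel = "radial", cost = spec$svm_cost,
                     gamma = spec$svm_gamma %||% (1 / ncol(Xs)),
                     scale = FALSE)
  ))
  structure(list(kind = spec$model_kind, fit = fit, preproc = pp,
                 levels = lvls, spec = spec),
            class = "vr_assessor")
}

rbf_design <- function(X, centers, width) {
  D2 <- sapply(seq_len(nrow(centers)), function(j) {
    colSums((t(X) - centers[j, ])^2)
  })
  if (nrow(X) == 1L) D2 <- matrix(D2, nrow = 1L)
  cbind(1, exp(-D2 / (2 * width^2)))
}

#' Shorthand trainers for the three model families
#'
#' Convenience wrappers around [train_assessor()] with the matching
#' `model_kind`.
#'
#' @inheritParams train_assessor
#' @return A `vr_assessor`.
#' @export
train_mlp <- function(features, labels, spec = model_spec("mlp")) {
  spec$model_kind <- "mlp"
  train_assessor(features, labels, spec)
}

#' @rdname train_mlp
#' @export
train_rbfn <- function(features, labels, spec = model_spec("rbfn")) {
  spec$model_kind <- "rbfn"
  train_assessor(features, labels, spec)
}

#' @rdname train_mlp
#' @export
train_svm <- function(features, labels, spec = model_spec("svm")) {
  spec$model_kind <- "svm"
  train_assessor(features, labels, spec)
}

#' @export
predict.vr_assessor <- function(object, newdata, ...) {
  Xs <- apply_preproc(object$preproc, newdata)
  switch(object$kind,
    mlp = {
      pr <- predict(object$fit, Xs)
      object$levels[max.col(pr, ties.method = "first")]
    },
    rbfn = {
      P <- rbf_design(Xs, object$fit$centers, object$fit$width)
      object$levels[max.col(P %*% object$fit$W, ties.method = "first")]
    },
    svm = as.integer(as.character(predict(object$fit, Xs)))
  )
}

#' Mean absolute percentage error between impairment levels
#'
#' `MAPE = (1/T) * sum(|d_k - y_k| / d_k) * 100` over the T samples,
#' where `d_k` is the actual and `y_k` the predicted level. Levels are
#' 1-based so the denominator is never zero. The attached band grades
#' the prediction effect: MAPE < 10 is accurate and MAPE >= 50 is
#' inaccurate (10-20 "good" and 20-50 "reasonable" fill the gap).
#'
#' @param actual,predicted Equal-length integer level vectors (>= 1).
#' @return One-row tibble `mape, band`.
#' @examples
#' mape(c(2, 2), c(1, 3))      # 50, the inaccurate boundary
#' mape(c(1, 2, 3), c(3, 2, 1))  # 88.89
#' @export
mape <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length")
  }
  if (any(actual == 0)) {
    abort("actual levels must be 1-based (division by d_k)")
  }
  m <- mean(abs(actual - predicted) / actual) * 100
  band <- if (m < 10) "accurate" else if (m < 20) "good" else
    if (m < 50) "reasonable" else "inaccurate"
  tibble(mape = m, band = band)
}

# stratified fold assignment; grouped mode keeps a subject's rows together
make_folds <- function(labels, folds, groups = NULL) {
  n <- length(labels)
  fold <- integer(n)
  if (is.null(groups)) {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
  } else {
    # assign groups to folds, stratifying by the group's modal label
    glab <- vapply(split(labels, groups), function(l) {
      as.integer(names(sort(-table(l)))[1])
    }, integer(1))
    gfold <- integer(length(glab))
    for (cl in unique(glab)) {
      idx <- sample(which(glab == cl))
      gfold[idx] <- rep(seq_len(folds), length.out = length(idx))
    }
    fold <- gfold[match(groups, names(glab))]
  }
  fold
}

#' Cross-validated evaluation of an impairment-level classifier
#'
#' Stratified `spec$folds`-fold cross-validation: for each fold the
#' classifier is trained on the remaining folds (imputation and
#' standardization statistics computed on the training folds only) and
#' the held-out fold is predicted; out-of-fold predictions are pooled
#' into per-class accuracy, overall accuracy (%), the confusion table
#' and MAPE. If a random fold split leaves a training fold without some
#' class, the split is re-drawn with a new derived seed (logged).
#'
#' @param features Feature data frame (indicator columns; extra id
#'   columns `subject`/`timepoint` are ignored for training but used for
#'   `grouped` folds).
#' @param labels Integer impairment levels (1-based), one per row.
#' @param spec A [model_spec()].
#' @return An object of class `vr_assessment`: `predictions` (tibble
#'   `row, fold, actual, predicted`), `confusion` (actual x predicted
#'   matrix), `per_class_accuracy`, `overall_accuracy` (%), `mape`,
#'   `mape_band`, `spec`. Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
evaluate_assessment <- function(features, labels, spec = model_spec()) {
  labels <- as.integer(labels)
  cnt <- table(labels)
  if (any(cnt < 2L)) abort("need at least 2 samples per class")
  groups <- if (spec$grouped && "subject" %in% names(features)) {
    features$subject
  } else {
    NULL
  }
  feat_cols <- if (identical(spec$feature_subset, "all")) {
    intersect(indicator_names(), names(as.data.frame(features)))
  } else {
    spec$feature_subset
  }
  if (length(feat_cols) == 0L) {
    feat_cols <- setdiff(colnames(features), c("subject", "timepoint",
                                               "n_attempts_used"))
  }
  X <- as.data.frame(features)[, feat_cols, drop = FALSE]

  fold <- withr::with_seed(spec$seed, {
    f <- make_folds(labels, spec$folds, groups)
    tries <- 0L
    while (tries < 20L) {
      ok <- all(vapply(seq_len(spec$folds), function(j) {
        length(unique(labels[f != j])) == length(unique(labels))
      }, logical(1)))
      if (ok) break
      tries <- tries + 1L
      inform(sprintf("fold re-draw %d: a training fold lost a class", tries))
      f <- make_folds(labels, spec$folds, groups)
    }
    f
  })

  pred <- integer(length(labels))
  for (j in sort(unique(fold))) {
    tr <- fold != j
    sp <- spec
    sp$seed <- spec$seed + 1000L * j
    model <- train_assessor(X[tr, , drop = FALSE], labels[tr], sp)
    pred[!tr] <- predict(model, X[!tr, , drop = FALSE])
  }

  lvls <- sort(unique(labels))
  conf <- table(factor(labels, lvls), factor(pred, lvls))
  dimnames(conf) <- list(actual = lvls, predicted = lvls)
  per_class <- diag(as.matrix(conf)) / rowSums(conf) * 100
  mp <- mape(labels, pred)
  structure(
    list(predictions = tibble(row = seq_along(labels), fold = fold,
                              actual = labels, predicted = pred),
         confusion = conf,
         per_class_accuracy = setNames(as.numeric(per_class),
                                       paste0("level", lvls)),
         overall_accuracy = mean(pred == labels) * 100,
         mape = mp$mape, mape_band = mp$band, spec = spec),
    class = "vr_assessment"
  )
}

#' @export
print.vr_assessment <- function(x, ...) {
  cat(sprintf(
    "<vr_assessment> %s (%d folds): overall accuracy %.1f%%, MAPE %.2f%% (%s)\n",
    x$spec$model_kind, x$spec$folds, x$overall_accuracy, x$mape,
    x$mape_band))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.vr_assessment <- function(x, ...) {
  x$predictions
}

#' @export
glance.vr_assessment <- function(x, ...) {
  tibble(model = x$spec$model_kind,
         hidden_neurons = x$spec$hidden_neurons,
         folds = x$spec$folds, n = nrow(x$predictions),
         overall_accuracy = x$overall_accuracy, mape = x$mape,
         mape_band = x$mape_band)
}

#' @export
autoplot.vr_assessment <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$actual,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::labs(title = sprintf(
      "Confusion (%s): accuracy %.1f%%, MAPE %.2f%%",
      object$spec$model_kind, object$overall_accuracy, object$mape),
      x = "Predicted level", y = "Actual level", fill = "Count") +
    ggplot2::theme_minimal()
}

#' Sweep classifiers over hidden-layer sizes and feature subsets
#'
#' Reproduces the grid experimental design: every combination of model
#' kind, hidden-neuron count and named feature subset is cross-validated
#' with [evaluate_assessment()].
#'
#' @param features,labels As in [evaluate_assessment()].
#' @param model_kinds Character subset of `c("mlp", "rbfn", "svm")`.
#' @param hidden_grid Integer vector of hidden-neuron counts (ignored by
#'   the SVM).
#' @param subsets Named list of feature subsets (`"all"` or character
#'   vectors of indicator names).
#' @param seed,folds Passed to [model_spec()].
#' @return Tibble of [glance()] rows with `subset` identifying the
#'   feature set.
#' @export
assess_grid <- function(features, labels, model_kinds = c("mlp", "rbfn"),
                        hidden_grid = 2:4, subsets = list(all = "all"),
                        seed = 1L, folds = 5L) {
  rows <- list()
  for (mk in model_kinds) {
    hseq <- if (mk == "svm") 1L else hidden_grid
    for (h in hseq) {
      for (sn in names(subsets)) {
        sp <- model_spec(mk, hidden_neurons = h,
                         feature_subset = subsets[[sn]], folds = folds,
                         seed = seed)
        g <- glance(evaluate_assessment(features, labels, sp))
        g$subset <- sn
        rows[[length(rows) + 1L]] <- g
      }
    }
  }
  bind_rows(rows)
}
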