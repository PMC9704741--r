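# MLP / RBFN / SVM classifiers, MAPE and cross-validated evaluation.

blobs_3class <- function(n_per = 15, sep = 6, sd = 0.5) {
  X <- data.frame(
    f1 = c(rnorm(n_per, 0, sd), rnorm(n_per, sep, sd),
           rnorm(n_per, 0, sd)),
    f2 = c(rnorm(n_per, 0, sd), rnorm(n_per, sep, sd),
           rnorm(n_per, sep, sd))
  )
  list(X = X, y = rep(1:3, each = n_per))
}

test_that("MAPE follows its definition, bands and guards", {
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3))$mape, 0)
  expect_equal(mape(c(1, 2, 3), c(1, 2, 3))$band, "accurate")
  b <- mape(c(2, 2), c(1, 3))
  expect_equal(b$mape, 50)
  expect_equal(b$band, "inaccurate")
  expect_equal(mape(c(1, 2, 3), c(3, 2, 1))$mape, (2 / 1 + 0 + 2 / 3) / 3 * 100,
               tolerance = 1e-12)
  expect_error(mape(c(0, 1), c(1, 1)), "1-based")
  expect_error(mape(1:3, 1:2), "equal length")
  # brute-force check on random label pairs
  set.seed(51)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    a <- sample(1:3, n, replace = TRUE)
    p <- sample(1:3, n, replace = TRUE)
    manual <- sum(abs(a - p) / a) / n * 100
    expect_equal(mape(a, p)$mape, manual, tolerance = 1e-12)
  }
})

test_that("all three model families separate tight blobs perfectly", {
  set.seed(52)
  d <- blobs_3class()
  for (kind in c("mlp", "rbfn", "svm")) {
    spec <- model_spec(kind, hidden_neurons = 3, seed = 7)
    fit <- train_assessor(d$X, d$y, spec)
    expect_equal(predict(fit, d$X), d$y, label = kind)
  }
})

test_that("training is deterministic under a fixed seed", {
  set.seed(53)
  d <- blobs_3class(sd = 2)
  for (kind in c("mlp", "rbfn", "svm")) {
    f1 <- train_assessor(d$X, d$y, model_spec(kind, hidden_neurons = 3,
                                              seed = 11))
    f2 <- train_assessor(d$X, d$y, model_spec(kind, hidden_neurons = 3,
                                              seed = 11))
    expect_identical(predict(f1, d$X), predict(f2, d$X), label = kind)
    if (kind == "mlp") expect_identical(f1$fit$wts, f2$fit$wts)
  }
})

test_that("an infinitely wide RBFN degenerates to the majority class", {
  set.seed(54)
  d <- blobs_3class(n_per = 10)
  y <- c(d$y, 3, 3, 3, 3)  # majority = class 3
  X <- rbind(d$X, d$X[1:4, ])
  wide <- train_rbfn(X, y, model_spec("rbfn", hidden_neurons = 3,
                                      rbf_width = 1e9, seed = 1))
  expect_true(all(predict(wide, d$X) == 3))
})

test_that("relabelling classes permutes SVM predictions consistently", {
  set.seed(55)
  d <- blobs_3class()
  perm <- c(2, 3, 1)
  f1 <- train_svm(d$X, d$y, model_spec("svm", seed = 3))
  f2 <- train_svm(d$X, perm[d$y], model_spec("svm", seed = 3))
  expect_equal(perm[predict(f1, d$X)], predict(f2, d$X))
})

test_that("training rejects degenerate inputs", {
  d <- blobs_3class(n_per = 5)
  expect_error(train_assessor(d$X, rep(1, nrow(d$X))), "single class")
  bad <- d$X
  bad$f1[1] <- Inf
  expect_error(train_assessor(bad, d$y), "non-finite")
  expect_error(train_rbfn(d$X[1:3, ], d$y[c(1, 6, 11)],
                          model_spec("rbfn", hidden_neurons = 10)),
               "centres")
})

test_that("cross-validated evaluation is conservative, complete and deterministic", {
  set.seed(56)
  d <- blobs_3class(n_per = 12, sd = 1)
  spec <- model_spec("mlp", hidden_neurons = 2, folds = 4, seed = 21)
  r1 <- evaluate_assessment(d$X, d$y, spec)
  r2 <- evaluate_assessment(d$X, d$y, spec)
  expect_identical(r1$predictions, r2$predictions)
  # confusion rows sum to the class counts
  expect_equal(as.numeric(rowSums(r1$confusion)),
               as.numeric(table(d$y)))
  expect_equal(nrow(r1$predictions), length(d$y))
  expect_true(all(r1$per_class_accuracy >= 0 &
                    r1$per_class_accuracy <= 100))
  expect_gte(r1$mape, 0)
  # every fold held out once, stratified
  expect_setequal(unique(r1$predictions$fold), 1:4)
  g <- glance(r1)
  expect_equal(g$overall_accuracy, r1$overall_accuracy)
  expect_s3_class(autoplot(r1), "ggplot")
  expect_error(evaluate_assessment(d$X, c(rep(1, 35), 2), spec),
               "2 samples")
})

test_that("a perfectly separable problem cross-validates to 100% / MAPE 0", {
  set.seed(57)
  d <- blobs_3class(n_per = 10, sep = 20, sd = 0.1)
  r <- evaluate_assessment(d$X, d$y,
                           model_spec("svm", svm_cost = 10, folds = 5,
                                      seed = 2))
  expect_equal(r$overall_accuracy, 100)
  expect_equal(r$mape, 0)
  expect_equal(r$mape_band, "accurate")
})

test_that("the assessment grid sweeps models, sizes and subsets", {
  set.seed(58)
  d <- blobs_3class(n_per = 8, sd = 1)
  g <- assess_grid(d$X, d$y, model_kinds = c("rbfn", "svm"),
                   hidden_grid = c(3, 4),
                   subsets = list(all = "all", one = "f1"),
                   folds = 4, seed = 5)
  expect_equal(nrow(g), 2 * 2 + 2)  # rbfn x {3,4} x subsets + svm x subsets
  expect_true(all(g$overall_accuracy >= 0 & g$overall_accuracy <= 100))
})
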