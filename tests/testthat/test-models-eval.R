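test_that("stratified split keeps per-class 70/30 proportions and is seeded", {
  tab <- blob_table(n_per_class = 10)
  sp <- stratified_split(tab, 0.7, seed = 5)
  expect_equal(as.integer(table(sp$train$label)), c(7L, 7L))
  expect_equal(as.integer(table(sp$test$label)), c(3L, 3L))
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(tab))

  # reproducibility and sensitivity to the seed
  sp2 <- stratified_split(tab, 0.7, seed = 5)
  expect_identical(sp, sp2)
  big <- blob_table(n_per_class = 30)
  spA <- stratified_split(big, 0.7, seed = 5)
  spB <- stratified_split(big, 0.7, seed = 6)
  expect_false(identical(spA$train$window_start, spB$train$window_start))

  # degenerate fractions and classes are rejected
  expect_error(stratified_split(tab, 1.0), "between 0 and 1")
  expect_error(stratified_split(tab, 0), "between 0 and 1")
  expect_error(stratified_split(rbind(tab[1:10, ], tab[11, ])), "fewer than 2")

  # proportions preserved within one row per class on odd counts
  tab2 <- blob_table(n_per_class = 7)
  sp <- stratified_split(tab2, 0.7, seed = 1)
  expect_equal(as.integer(table(sp$train$label)), c(5L, 5L)) # round(4.9) = 5
})

test_that("all five classifiers separate blob data perfectly", {
  tab <- blob_table(n_per_class = 30, gap = 10)
  sp <- stratified_split(tab, 0.7, seed = 2)
  for (algo in c("svm", "knn", "dt", "nb", "rf")) {
    pred <- fit_predict(classifier_spec(algo, seed = 2), sp$train, sp$test)
    expect_identical(pred$labels, sp$test$label)
    expect_equal(dim(pred$scores), c(nrow(sp$test), 2))
    expect_identical(colnames(pred$scores), c("lying", "walking"))
  }
})

test_that("label-free noise yields chance-level accuracy under the permutation null", {
  accs <- vapply(1:20, function(seed) {
    tab <- noise_table(n = 80, f = 5, seed = seed)
    sp <- stratified_split(tab, 0.7, seed = seed)
    pred <- fit_predict(classifier_spec("rf", seed = seed), sp$train, sp$test)
    mean(pred$labels == sp$test$label)
  }, 0)
  expect_gt(mean(accs), 0.5 - 0.12)
  expect_lt(mean(accs), 0.5 + 0.12)
})

test_that("stochastic learners are reproducible under a fixed seed", {
  tab <- noise_table(n = 60, f = 8, seed = 3, plant = 1)
  sp <- stratified_split(tab, 0.7, seed = 3)
  p1 <- fit_predict(classifier_spec("rf", seed = 9), sp$train, sp$test)
  p2 <- fit_predict(classifier_spec("rf", seed = 9), sp$train, sp$test)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$scores, p2$scores)
  expect_error(fit_classifier(classifier_spec("rf"), sp$train[sp$train$label == "lying", ]),
               "2 classes")
})

test_that("confusion metrics reproduce the printed formulas", {
  # TP=8, FP=2, FN=4 for class A
  y_true <- c(rep("A", 12), rep("B", 8))
  y_pred <- c(rep("A", 8), rep("B", 4), rep("A", 2), rep("B", 6))
  m <- confusion_and_metrics(y_true, y_pred)
  a <- m[m$class == "A", ]
  expect_equal(a$precision, 0.800, tolerance = 1e-3)
  expect_equal(a$recall, 0.667, tolerance = 1e-3)
  expect_equal(a$f1, 0.727, tolerance = 1e-3)
  expect_equal(a$support, 12)

  # perfect predictions
  m <- confusion_and_metrics(y_true, y_true)
  expect_true(all(m$precision == 1 & m$recall == 1 & m$f1 == 1))

  # zero denominators produce 0 with a warning
  expect_warning(m <- confusion_and_metrics(c("A", "A"), c("B", "B")), "zero denominator")
  expect_true(all(m$f1 == 0))
  expect_error(confusion_and_metrics("A", c("A", "B")), "equal length")
})

test_that("micro-averaged precision equals recall equals accuracy; F1 bounded by P and R", {
  set.seed(17)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(10:60, 1)
    y_true <- sample(LETTERS[1:k], n, replace = TRUE)
    y_pred <- sample(LETTERS[1:k], n, replace = TRUE)
    m <- suppressWarnings(confusion_and_metrics(y_true, y_pred))
    cm <- attr(m, "confusion")
    tp <- diag(cm)
    micro_p <- sum(tp) / sum(colSums(cm))
    micro_r <- sum(tp) / sum(rowSums(cm))
    expect_equal(micro_p, micro_r)
    expect_equal(micro_p, attr(m, "accuracy"))
    # bounds
    expect_true(all(m$precision >= 0 & m$precision <= 1))
    expect_true(all(m$f1 >= pmin(m$precision, m$recall) - 1e-12))
    expect_true(all(m$f1 <= pmax(m$precision, m$recall) + 1e-12))
    # F1 is zero exactly when TP is zero
    expect_identical(unname(m$f1 == 0), unname(tp == 0))
  }
})

test_that("recursive elimination reaches exactly the keep target", {
  tab <- noise_table(n = 40, f = 16, seed = 2, plant = 2)
  sel <- rfe_select(tab, keep_frac = 0.25, seed = 2, ntree = 30)
  expect_length(sel, 4) # ceiling(0.25 * 16)
  expect_equal(as.character(sel), intersect(sprintf("feat%03d", 1:16), sel)) # original order

  # identity selection when the target equals the feature count
  sel <- rfe_select(tab, keep_frac = 0.99, seed = 2, ntree = 30)
  expect_length(sel, 16)
  expect_equal(attr(sel, "trace"), 16)

  # a planted signal survives
  sel <- rfe_select(noise_table(n = 80, f = 20, seed = 4, plant = 3),
                    keep_frac = 0.25, seed = 4, ntree = 50)
  expect_length(sel, 5)
  expect_true(all(sprintf("feat%03d", 1:3) %in% sel))

  expect_error(rfe_select(tab, keep_frac = 1.2), "between 0 and 1")
})

test_that("stratified k-fold cross-validation pools out-of-fold predictions", {
  tab <- blob_table(n_per_class = 20, gap = 10)
  m <- cv_evaluate(classifier_spec("rf", seed = 4), tab, folds = 4, seed = 4)
  expect_s3_class(m, "class_metrics")
  expect_equal(sum(m$support), nrow(tab)) # every row scored exactly once
  expect_true(all(m$f1 == 1)) # separable blobs stay separable across folds
  m2 <- cv_evaluate(classifier_spec("rf", seed = 4), tab, folds = 4, seed = 4)
  expect_identical(as.data.frame(m), as.data.frame(m2))
  expect_error(cv_evaluate(classifier_spec("rf"), blob_table(n_per_class = 3),
                           folds = 5), "fewer than 5")
})
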