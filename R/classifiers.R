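# The five reference classifiers (SVM, KNN, DT, NB, RF) behind a uniform
# fit/predict surface returning per-class confidence scores, stratified
# hold-out splitting, confusion-matrix metrics, and recursive feature
# elimination driven by random-forest importance.

.classifier_names <- c("svm", "knn", "dt", "nb", "rf")

.default_hyper <- function(name) {
  switch(name,
    svm = list(kernel = "linear", cost = 1),
    knn = list(k = 8),
    dt = list(split = "gini", cp = 0, minsplit = 2, minbucket = 1,
              maxdepth = 30),
    nb = list(sd_floor = 1e-6),
    rf = list(ntree = 100)
  )
}

#' Classifier specification
#'
#' Defaults follow the reference configuration: linear-kernel SVM in
#' one-vs-all form predicting by highest confidence score; KNN with k = 8;
#' a Gini-impurity decision tree with effectively unlimited depth (cp = 0,
#' minsplit = 2); Gaussian naive Bayes; and a 100-tree random forest.
#'
#' @param name one of `"svm", "knn", "dt", "nb", "rf"`.
#' @param hyper named list overriding the defaults for that algorithm.
#' @param seed integer seed for the stochastic learners (rf); derived seeds
#'   keep fits reproducible.
#' @export
classifier_spec <- function(name = .classifier_names, hyper = list(), seed = 1L) {
  name <- match.arg(name)
  h <- utils::modifyList(.default_hyper(name), hyper)
  structure(list(name = name, hyper = h, seed = as.integer(seed)),
            class = "classifier_spec")
}

.subset_table <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(table, "provenance"),
            class = c("feature_table", "data.frame"))
}

#' Stratified train/test split
#'
#' Per class, `round(train_frac * n_c)` rows (clamped so both sides keep at
#' least one row per class) are sampled without replacement into the training
#' set; the remainder is the test set. Reproducible under `seed`.
#'
#' @param table a `feature_table`; every class needs >= 2 rows.
#' @param train_frac training fraction in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
stratified_split <- function(table, train_frac = 0.7, seed = 1L) {
  if (!is.numeric(train_frac) || train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must lie strictly between 0 and 1")
  }
  y <- table$label
  tab <- table(y)
  if (any(tab < 2)) {
    stop(sprintf("stratified_split: class(es) with fewer than 2 rows: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  train_idx <- with_seed(derive_seed(seed, "split"), {
    unlist(lapply(sort(names(tab)), function(cl) {
      rows <- which(y == cl)
      n_tr <- min(max(round(train_frac * length(rows)), 1L), length(rows) - 1L)
      sample(rows, n_tr)
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = .subset_table(table, train_idx),
       test = .subset_table(table, setdiff(seq_len(nrow(table)), train_idx)))
}

#' Fit a classifier on a feature table
#'
#' @param spec a [classifier_spec()].
#' @param train a `feature_table` containing at least two classes.
#' @return an `adawin_model` usable with `predict(..., type = "class"|"prob")`.
#' @export
fit_classifier <- function(spec, train) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- feature_matrix(train)
  y <- factor(train$label, levels = sort(unique(train$label)))
  if (nlevels(y) < 2L) {
    stop("degenerate training set: need at least 2 classes")
  }
  # Constant columns carry no information and break the Gaussian NB densities
  # and the SVM dual; they are dropped here and on prediction.
  keep <- which(apply(X, 2, function(v) diff(range(v)) > 0))
  if (length(keep) == 0L) stop("all feature columns are constant")
  X <- X[, keep, drop = FALSE]
  h <- spec$hyper
  fit <- switch(spec$name,
    svm = {
      # one binary linear SVM per class; positive decision value = that class
      lapply(stats::setNames(levels(y), levels(y)), function(cl) {
        yb <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
        with_seed(derive_seed(spec$seed, "svm", cl),
                  e1071::svm(X, yb, kernel = h$kernel, cost = h$cost,
                             scale = FALSE))
      })
    },
    knn = {
      k_eff <- min(h$k, nrow(X))
      list(model = caret::knn3(X, y, k = k_eff), k = k_eff)
    },
    dt = {
      df <- data.frame(.label = y, X, check.names = FALSE)
      rpart::rpart(.label ~ ., data = df, method = "class",
                   parms = list(split = h$split),
                   control = rpart::rpart.control(
                     cp = h$cp, minsplit = h$minsplit,
                     minbucket = h$minbucket, maxdepth = h$maxdepth,
                     xval = 0))
    },
    nb = {
      m <- e1071::naiveBayes(X, y)
      # floor per-class sds so zero-variance features yield finite densities
      m$tables <- lapply(m$tables, function(t) {
        t[, 2] <- pmax(t[, 2], h$sd_floor); t
      })
      m
    },
    rf = with_seed(derive_seed(spec$seed, "rf"),
                   randomForest::randomForest(X, y, ntree = h$ntree))
  )
  structure(list(spec = spec, fit = fit, levels = levels(y),
                 columns = colnames(X),
                 train_freq = table(y)[levels(y)]),
            class = "adawin_model")
}

#' Predict from a fitted classifier
#'
#' @param object an `adawin_model`.
#' @param newdata a `feature_table` (or data.frame with the training columns).
#' @param type `"class"` for labels (argmax of the per-class confidence,
#'   ties toward the class more frequent in training, then lexicographic) or
#'   `"prob"` for the score matrix.
#' @param ... unused.
#' @export
predict.adawin_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata)[, object$columns, drop = FALSE]
  lev <- object$levels
  scores <- switch(object$spec$name,
    svm = {
      s <- vapply(lev, function(cl) {
        p <- stats::predict(object$fit[[cl]], X, decision.values = TRUE)
        dv <- attr(p, "decision.values")
        # orient so positive always means "pos" regardless of libsvm ordering
        if (startsWith(colnames(dv)[1], "pos")) dv[, 1] else -dv[, 1]
      }, numeric(nrow(X)))
      matrix(s, nrow = nrow(X), dimnames = list(NULL, lev))
    },
    knn = stats::predict(object$fit$model, X, type = "prob"),
    dt = stats::predict(object$fit,
                        data.frame(X, check.names = FALSE), type = "prob"),
    nb = {
      # score in log space: the stock raw-probability output underflows to
      # 0/0 with hundreds of features, so apply the class-conditional
      # Gaussian log densities and a shifted softmax instead
      m <- object$fit
      logp <- matrix(rep(log(as.numeric(m$apriori[lev]) / sum(m$apriori)),
                         each = nrow(X)), nrow(X), length(lev),
                     dimnames = list(NULL, lev))
      for (col in object$columns) {
        t <- m$tables[[col]]
        for (cl in lev) {
          logp[, cl] <- logp[, cl] +
            stats::dnorm(X[, col], t[cl, 1], t[cl, 2], log = TRUE)
        }
      }
      shift <- apply(logp, 1, max)
      p <- exp(logp - shift)
      p / rowSums(p)
    },
    rf = stats::predict(object$fit, X, type = "prob")
  )
  scores <- scores[, lev, drop = FALSE]
  if (type == "prob") return(scores)
  # ties toward the more frequent training class, then lexicographic
  pref <- order(-as.numeric(object$train_freq), lev)
  pick <- max.col(scores[, pref, drop = FALSE], ties.method = "first")
  lev[pref][pick]
}

#' Fit a classifier and predict the test set
#'
#' @inheritParams fit_classifier
#' @param test a `feature_table` with the same columns as `train`.
#' @return list with `labels` (predicted), `scores` (per-class confidence
#'   matrix) and `model`.
#' @export
fit_predict <- function(spec, train, test) {
  model <- fit_classifier(spec, train)
  list(labels = predict(model, test, type = "class"),
       scores = predict(model, test, type = "prob"),
       model = model)
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Alternative to the single stratified holdout: rows are dealt into `folds`
#' stratified folds, each fold serves once as the test set, and the pooled
#' out-of-fold predictions are scored. Offered because a single holdout is
#' noisy on small tables; the holdout remains the default everywhere else.
#'
#' @inheritParams fit_classifier
#' @param table a `feature_table`; every class needs at least `folds` rows.
#' @param folds number of folds (>= 2), default 5.
#' @param seed integer seed for the fold assignment.
#' @return a `class_metrics` object scored on the pooled out-of-fold
#'   predictions.
#' @export
cv_evaluate <- function(spec, table, folds = 5, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"), folds >= 2)
  y <- table$label
  tab <- table(y)
  if (any(tab < folds)) {
    stop(sprintf("cv_evaluate: class(es) with fewer than %d rows: %s",
                 folds, paste(names(tab)[tab < folds], collapse = ", ")))
  }
  fold_of <- integer(nrow(table))
  with_seed(derive_seed(seed, "cv"), {
    for (cl in sort(names(tab))) {
      rows <- sample(which(y == cl))
      fold_of[rows] <- rep_len(seq_len(folds), length(rows))
    }
  })
  pred <- character(nrow(table))
  for (k in seq_len(folds)) {
    train <- .subset_table(table, which(fold_of != k))
    test_idx <- which(fold_of == k)
    model <- fit_classifier(spec, train)
    pred[test_idx] <- predict(model, .subset_table(table, test_idx),
                              type = "class")
  }
  confusion_and_metrics(y, pred)
}

#' Confusion matrix and per-class precision/recall/F1
#'
#' Per class (one-vs-rest): precision = TP/(TP+FP), recall = TP/(TP+FN) and
#' F1 their harmonic mean; a zero denominator yields 0 with a warning. Macro
#' averages and overall accuracy are attached as attributes.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @return a `class_metrics` data.frame (class, precision, recall, f1,
#'   support) with attributes `confusion`, `macro`, `accuracy`.
#' @export
confusion_and_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (length(y_true) < 1L) stop("need at least one observation")
  classes <- sort(union(unique(y_true), unique(y_pred)))
  cm <- table(true = factor(y_true, classes), pred = factor(y_pred, classes))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  div0 <- FALSE
  safe_div <- function(a, b) {
    z <- b == 0
    if (any(z)) div0 <<- TRUE
    out <- numeric(length(a)); out[!z] <- a[!z] / b[!z]
    out
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  if (div0) warning("zero denominator in precision/recall/F1; reported as 0")
  out <- data.frame(class = classes, precision = precision, recall = recall,
                    f1 = f1, support = as.integer(rowSums(cm)),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out,
            confusion = cm,
            macro = list(precision = mean(precision), recall = mean(recall),
                         f1 = mean(f1)),
            accuracy = sum(tp) / length(y_true),
            class = c("class_metrics", "data.frame"))
}

#' @export
print.class_metrics <- function(x, digits = 3, ...) {
  cat("<class_metrics>\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  m <- attr(x, "macro")
  cat(sprintf("macro P/R/F1: %.3f / %.3f / %.3f; accuracy %.3f\n",
              m$precision, m$recall, m$f1, attr(x, "accuracy")))
  invisible(x)
}

#' Recursive feature elimination by random-forest importance
#'
#' Repeatedly fits a random forest, scores features by mean decrease in Gini
#' impurity, and drops the lowest-scoring `floor(drop_frac_per_iter * F_cur)`
#' features (at least one, never past the target) until
#' `ceiling(keep_frac * F)` features remain.
#'
#' @param table a `feature_table` with >= 4 features and a class label column.
#' @param keep_frac fraction of features to keep, in (0, 1); default 0.25.
#' @param drop_frac_per_iter fraction of the current features dropped per
#'   iteration, default 0.10.
#' @param seed integer seed.
#' @param ntree trees per scoring forest, default 100.
#' @return character vector of surviving feature names, in original column
#'   order, with the per-iteration feature counts attached as attribute
#'   `"trace"`.
#' @export
rfe_select <- function(table, keep_frac = 0.25, drop_frac_per_iter = 0.10,
                       seed = 1L, ntree = 100) {
  if (!is.numeric(keep_frac) || keep_frac <= 0 || keep_frac >= 1) {
    stop("keep_frac must lie strictly between 0 and 1")
  }
  all_features <- setdiff(names(table), c("window_start", "window_end", "label"))
  F_total <- length(all_features)
  if (F_total < 4L) stop("rfe_select needs at least 4 features")
  target <- as.integer(ceiling(keep_frac * F_total))
  if (target < 1L) stop("keep target is below one feature")
  y <- factor(table$label)
  if (nlevels(y) < 2L) stop("rfe_select needs at least 2 classes")
  X_all <- feature_matrix(table)
  current <- all_features
  trace <- length(current)
  iter <- 0L
  while (length(current) > target) {
    iter <- iter + 1L
    rf <- with_seed(derive_seed(seed, "rfe", iter),
                    randomForest::randomForest(
                      X_all[, current, drop = FALSE], y,
                      ntree = ntree, importance = FALSE))
    imp <- randomForest::importance(rf)[, "MeanDecreaseGini"]
    n_drop <- max(1L, as.integer(floor(drop_frac_per_iter * length(current))))
    n_drop <- min(n_drop, length(current) - target)
    drop <- names(sort(imp))[seq_len(n_drop)]
    current <- setdiff(current, drop)
    trace <- c(trace, length(current))
  }
  structure(all_features[all_features %in% current], trace = trace)
}
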