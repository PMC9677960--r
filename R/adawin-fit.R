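# Top-level fitting interface: run the full adaptive-window analysis on one
# labeled stream and return a classed object carrying the grid, the sliding
# optimum, the per-behavior plan, its evaluation, and fusion-ready models.

#' Fit an adaptive-window behavior classifier
#'
#' Runs the complete analysis on a preprocessed labeled stream: a WS/SS grid
#' search with the requested classifiers, selection of the global sliding
#' optimum (highest mean F1) and of the per-behavior adaptive optima for
#' `algorithm`, per-class evaluation at those optima, and training of the
#' multiclass models needed to predict a fused label timeline on new streams.
#'
#' @inheritParams grid_search
#' @param algorithm the classifier the adaptive plan is selected and evaluated
#'   for (must be among `algorithms`), default the first of `algorithms`.
#' @return an object of class `adawin` with components `grid`,
#'   `sliding_optimum`, `plan`, `adaptive_metrics`, `models`, `registry`,
#'   `seed`, `call`.
#' @seealso [grid_search()], [select_adaptive_optima()], [adaptive_evaluate()],
#'   [fuse_predict()]
#' @export
adawin <- function(stream, track, ws_s = default_ws_axis(),
                   ss_s = adaptive_ss_axis(), algorithms = "rf",
                   algorithm = algorithms[1], seed = 1L,
                   classes = default_classes(), purity_threshold = 0.8,
                   registry = feature_registry(), train_frac = 0.7,
                   max_windows = 2000) {
  if (!algorithm %in% algorithms) {
    stop("`algorithm` must be one of `algorithms`")
  }
  grid <- grid_search(stream, track, ws_s, ss_s, algorithms, seed, classes,
                      purity_threshold, registry, train_frac, max_windows)
  sliding <- select_sliding_optimum(grid)
  plan <- select_adaptive_optima(grid, algorithm)
  adaptive <- adaptive_evaluate(stream, track, plan, seed, classes,
                                purity_threshold, registry, train_frac,
                                max_windows)
  # train one multiclass model per distinct plan window, on all labeled
  # windows at that configuration, for fusion-time prediction
  models <- list()
  rate <- stream$sample_rate
  for (i in seq_len(nrow(plan))) {
    sp <- window_spec_seconds(plan$ws_s[i], plan$ss_s[i], rate)
    key <- sprintf("%dx%d", sp$ws, sp$ss)
    if (!is.null(models[[key]])) next
    segs <- segment_stream(stream, track, sp, classes, purity_threshold)
    feats <- featurize(segs, stream, registry)
    models[[key]] <- fit_classifier(
      classifier_spec(algorithm, seed = derive_seed(seed, "fuse", key)), feats)
  }
  structure(list(grid = grid, sliding_optimum = sliding, plan = plan,
                 adaptive_metrics = adaptive, models = models,
                 algorithm = algorithm, registry = registry, seed = seed,
                 classes = classes, call = match.call()),
            class = "adawin")
}

#' @export
print.adawin <- function(x, ...) {
  cat("Adaptive-window behavior classifier\n")
  cat(sprintf("  algorithm: %s; seed: %d\n", x$algorithm, x$seed))
  cat(sprintf("  sliding optimum: ws %g s, ss %g s (mean F1 %.3f)\n",
              x$sliding_optimum$ws_s, x$sliding_optimum$ss_s,
              x$sliding_optimum$mean_f1))
  cat("  adaptive plan:\n")
  for (i in seq_len(nrow(x$plan))) {
    cat(sprintf("    %-9s ws %g s, ss %g s (F1 %.3f)\n", x$plan$class[i],
                x$plan$ws_s[i], x$plan$ss_s[i], x$plan$f1[i]))
  }
  invisible(x)
}

#' @export
summary.adawin <- function(object, ...) {
  print(object)
  cat("\nPer-class metrics at the adaptive optima:\n")
  print.data.frame(object$adaptive_metrics, row.names = FALSE, digits = 3)
  u <- attr(object$grid, "unevaluable")
  if (nrow(u)) {
    cat(sprintf("\n%d unevaluable grid point(s):\n", nrow(u)))
    print.data.frame(u, row.names = FALSE)
  }
  invisible(object)
}

#' Per-class window parameters of a fitted adaptive-window model
#' @param object an `adawin` fit.
#' @param ... unused.
#' @return numeric matrix, one row per class, columns `ws_s` and `ss_s`.
#' @export
coef.adawin <- function(object, ...) {
  m <- as.matrix(object$plan[, c("ws_s", "ss_s")])
  rownames(m) <- object$plan$class
  m
}

#' Predict a behavior timeline for a new stream
#'
#' Applies the fused per-class adaptive models ([fuse_predict()]) to a new
#' preprocessed stream, producing one behavior label per sample.
#'
#' @param object an `adawin` fit.
#' @param stream a preprocessed `sensor_stream`.
#' @param ... unused.
#' @return character vector of per-sample labels (`"unknown"` where no window
#'   covers the sample).
#' @export
predict.adawin <- function(object, stream, ...) {
  fuse_predict(stream, object$plan, object$models, object$registry)
}

#' Plot the F1 surface of a fitted adaptive-window model
#'
#' F1 versus step size, one line per window size, for a given class (or the
#' mean over classes).
#'
#' @param x an `adawin` fit.
#' @param class behavior to plot; `NULL` (default) plots the mean F1 over
#'   classes.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.adawin <- function(x, class = NULL, ...) {
  d <- x$grid[x$grid$algorithm == x$algorithm, , drop = FALSE]
  if (!is.null(class)) d <- d[d$class == class, , drop = FALSE]
  if (nrow(d) == 0L) stop("nothing to plot for that class/algorithm")
  agg <- stats::aggregate(f1 ~ ws_s + ss_s, data = d, FUN = mean)
  ws_axis <- sort(unique(agg$ws_s)); ss_axis <- sort(unique(agg$ss_s))
  M <- matrix(NA_real_, length(ss_axis), length(ws_axis),
              dimnames = list(ss_axis, ws_axis))
  M[cbind(match(agg$ss_s, ss_axis), match(agg$ws_s, ws_axis))] <- agg$f1
  graphics::matplot(ss_axis, M, type = "b", pch = 19, lty = 1,
                    xlab = "step size (s)", ylab = "F1",
                    main = sprintf("%s F1 vs window/step size (%s)",
                                   class %||% "mean", x$algorithm), ...)
  graphics::legend("bottomleft", legend = paste("ws", ws_axis, "s"),
                   col = seq_along(ws_axis), lty = 1, pch = 19, bty = "n")
  invisible(M)
}
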