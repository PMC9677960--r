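# Window-size/step-size optimization: evaluate the full segmentation ->
# features -> split -> classify -> metrics pipeline over a WS x SS grid,
# select the global sliding optimum and the per-behavior adaptive optima, and
# fuse per-class models into a single predicted label timeline.

#' Default WS/SS grid axes (seconds)
#'
#' The sliding-window sweep uses WS of 2, 3, 5 and 7 s with SS from 0.5 to
#' 6.5 s in 0.5-s increments. The adaptive phase extends the SS axis below
#' 0.5 s (0.1-0.5 s) because per-behavior optima tend to sit at fine step
#' sizes.
#'
#' @name grid_axes
#' @export
default_ws_axis <- function() c(2, 3, 5, 7)

#' @rdname grid_axes
#' @export
default_ss_axis <- function() seq(0.5, 6.5, by = 0.5)

#' @rdname grid_axes
#' @export
adaptive_ss_axis <- function() c(0.1, 0.3, 0.5, 1, 1.5, 2, 3, 5)

# Evaluate one (ws, ss) grid point: segment, (optionally subsample), featurize,
# split, fit every algorithm, compute per-class metrics. The point seed is
# derived only from (seed, ws, ss) so adaptive_evaluate reproduces grid_search
# numbers exactly.
.evaluate_point <- function(stream, track, ws_s, ss_s, algorithms, seed,
                            classes, purity_threshold, registry, train_frac,
                            max_windows, n_splits = 1) {
  rate <- stream$sample_rate
  spec <- window_spec_seconds(ws_s, ss_s, rate)
  pt_seed <- derive_seed(seed, "grid", spec$ws, spec$ss)
  segs <- segment_stream(stream, track, spec, classes, purity_threshold)
  tab0 <- table(segs$label)
  usable <- names(tab0)[tab0 >= 2]
  if (length(usable) < 2L) {
    return(list(ok = FALSE, reason = sprintf(
      "only %d class(es) with >= 2 windows", length(usable))))
  }
  keep <- segs$label %in% usable
  segs <- structure(segs[keep, , drop = FALSE],
                    spec = spec, sample_rate = rate,
                    class = c("segment_set", "data.frame"))
  if (is.finite(max_windows) && nrow(segs) > max_windows) {
    # stratified thinning: cap the row count, keep >= 2 rows per class
    idx <- with_seed(derive_seed(pt_seed, "thin"), {
      unlist(lapply(usable, function(cl) {
        rows <- which(segs$label == cl)
        n_keep <- max(2L, round(max_windows * length(rows) / nrow(segs)))
        if (length(rows) > n_keep) sample(rows, n_keep) else rows
      }), use.names = FALSE)
    })
    segs <- structure(segs[sort(idx), , drop = FALSE],
                      spec = spec, sample_rate = rate,
                      class = c("segment_set", "data.frame"))
  }
  feats <- featurize(segs, stream, registry)
  rows <- list()
  for (algo in algorithms) {
    reps <- list()
    for (r in seq_len(n_splits)) {
      # the first replicate uses the bare point seed so that single-split
      # runs (the default) are exactly reproducible by adaptive_evaluate
      rep_seed <- if (r == 1) pt_seed else derive_seed(pt_seed, "rep", r)
      split <- stratified_split(feats, train_frac, rep_seed)
      pred <- fit_predict(classifier_spec(algo, seed = rep_seed),
                          split$train, split$test)
      met <- confusion_and_metrics(split$test$label, pred$labels)
      reps[[r]] <- met[met$class %in% usable, , drop = FALSE]
    }
    met <- reps[[1]]
    if (n_splits > 1) {
      for (col in c("precision", "recall", "f1", "support")) {
        met[[col]] <- rowMeans(vapply(reps, function(m) {
          m[[col]][match(met$class, m$class)]
        }, numeric(nrow(met))))
      }
    }
    rows[[algo]] <- data.frame(ws_s = ws_s, ss_s = ss_s, algorithm = algo,
                               met, stringsAsFactors = FALSE)
  }
  list(ok = TRUE, rows = do.call(rbind, rows))
}

#' Grid search over window and step sizes
#'
#' For every (WS, SS) pair, runs segmentation, feature extraction, a
#' stratified 70/30 split and each classifier, recording per-class precision,
#' recall and F1. Grid points whose segmentation yields fewer than two
#' trainable classes are recorded as unevaluable rather than silently
#' dropped. Deterministic under `seed`.
#'
#' @param stream a preprocessed `sensor_stream`.
#' @param track a `label_track`.
#' @param ws_s,ss_s grid axes in seconds; defaults [default_ws_axis()] and
#'   [default_ss_axis()].
#' @param algorithms classifier names to evaluate, default `"rf"`.
#' @param seed integer top-level seed.
#' @param classes behaviors to classify, default [default_classes()].
#' @param purity_threshold window purity gate, default 0.8.
#' @param registry a [feature_registry()].
#' @param train_frac training fraction, default 0.7.
#' @param max_windows cap on labeled windows per grid point (stratified
#'   thinning keeps class shares); `Inf` disables. Default 2000.
#' @param n_splits number of repeated stratified splits averaged per grid
#'   point (damps selection noise); the default 1 is the single-holdout
#'   procedure.
#' @return a `grid_result`: data.frame with columns ws_s, ss_s, algorithm,
#'   class, precision, recall, f1, support; unevaluable points, axes and the
#'   seed are attached as attributes.
#' @export
grid_search <- function(stream, track, ws_s = default_ws_axis(),
                        ss_s = default_ss_axis(), algorithms = "rf",
                        seed = 1L, classes = default_classes(),
                        purity_threshold = 0.8,
                        registry = feature_registry(), train_frac = 0.7,
                        max_windows = 2000, n_splits = 1) {
  stopifnot(length(ws_s) > 0, length(ss_s) > 0, length(algorithms) > 0)
  algorithms <- match.arg(algorithms, .classifier_names, several.ok = TRUE)
  rows <- list()
  unev <- list()
  for (w in ws_s) {
    for (s in ss_s) {
      r <- .evaluate_point(stream, track, w, s, algorithms, seed, classes,
                           purity_threshold, registry, train_frac, max_windows,
                           n_splits)
      if (r$ok) {
        rows[[sprintf("%g_%g", w, s)]] <- r$rows
      } else {
        unev[[sprintf("%g_%g", w, s)]] <-
          data.frame(ws_s = w, ss_s = s, reason = r$reason)
      }
    }
  }
  if (length(rows) == 0L) {
    stop("grid_search: every grid point was unevaluable")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            unevaluable = if (length(unev)) {
              u <- do.call(rbind, unev); rownames(u) <- NULL; u
            } else data.frame(ws_s = numeric(0), ss_s = numeric(0),
                              reason = character(0)),
            ws_axis = ws_s, ss_axis = ss_s, algorithms = algorithms,
            seed = seed, train_frac = train_frac,
            purity_threshold = purity_threshold, max_windows = max_windows,
            n_splits = n_splits,
            class = c("grid_result", "data.frame"))
}

#' @export
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d rows; ws {%s} s x ss {%s} s; algorithms: %s\n",
              nrow(x), paste(attr(x, "ws_axis"), collapse = ","),
              paste(attr(x, "ss_axis"), collapse = ","),
              paste(attr(x, "algorithms"), collapse = ", ")))
  u <- attr(x, "unevaluable")
  if (nrow(u)) cat(sprintf("  %d unevaluable grid point(s)\n", nrow(u)))
  invisible(x)
}

# Pick the (ws, ss) row with maximal `value`; ties toward larger ws (stabler
# features over more samples), then smaller ss (finer resolution).
.argmax_ws_ss <- function(df, value) {
  best <- df[df[[value]] >= max(df[[value]]) - 1e-12, , drop = FALSE]
  best <- best[order(-best$ws_s, best$ss_s), , drop = FALSE]
  best[1, , drop = FALSE]
}

#' Select the sliding-window optimum
#'
#' The default criterion is the mean F1 over all algorithms and classes at
#' each grid point; ties are broken toward the larger window size (features
#' computed over more samples are stabler) and then the smaller step size.
#'
#' @param grid a `grid_result`.
#' @param criterion `"mean_f1"` (one global optimum) or `"per_algorithm"`
#'   (one optimum per algorithm).
#' @return for `"mean_f1"`, a list with `ws_s`, `ss_s`, `mean_f1`; for
#'   `"per_algorithm"`, a data.frame with one row per algorithm.
#' @export
select_sliding_optimum <- function(grid, criterion = c("mean_f1", "per_algorithm")) {
  stopifnot(inherits(grid, "grid_result"), nrow(grid) > 0)
  criterion <- match.arg(criterion)
  if (criterion == "mean_f1") {
    agg <- stats::aggregate(f1 ~ ws_s + ss_s, data = grid, FUN = mean)
    b <- .argmax_ws_ss(agg, "f1")
    list(ws_s = b$ws_s, ss_s = b$ss_s, mean_f1 = b$f1)
  } else {
    res <- lapply(split(grid, grid$algorithm), function(d) {
      agg <- stats::aggregate(f1 ~ ws_s + ss_s, data = d, FUN = mean)
      b <- .argmax_ws_ss(agg, "f1")
      data.frame(algorithm = d$algorithm[1], ws_s = b$ws_s, ss_s = b$ss_s,
                 mean_f1 = b$f1)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  }
}

#' Select the per-behavior adaptive window optima
#'
#' For one algorithm, returns the (WS, SS) maximizing each class's F1, with
#' ties broken toward larger WS then smaller SS. Longer-duration behaviors are
#' expected to select larger windows than short-bout behaviors.
#'
#' @param grid a `grid_result`.
#' @param algorithm classifier name, default `"rf"`.
#' @return an `adaptive_plan`: data.frame with columns class, ws_s, ss_s, f1.
#' @export
select_adaptive_optima <- function(grid, algorithm = "rf") {
  stopifnot(inherits(grid, "grid_result"))
  d <- grid[grid$algorithm == algorithm, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop(sprintf("algorithm '%s' not present in the grid", algorithm))
  }
  res <- lapply(split(d, d$class), function(dd) {
    b <- .argmax_ws_ss(dd, "f1")
    data.frame(class = dd$class[1], ws_s = b$ws_s, ss_s = b$ss_s, f1 = b$f1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$class), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, algorithm = algorithm,
            class = c("adaptive_plan", "data.frame"))
}

#' @export
print.adaptive_plan <- function(x, ...) {
  cat(sprintf("<adaptive_plan> algorithm: %s\n", attr(x, "algorithm")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Evaluate an adaptive plan
#'
#' For each behavior class, re-runs the full pipeline at that class's (WS, SS)
#' and reports the class's own precision/recall/F1 from that run. Seeds are
#' derived from (seed, ws, ss) exactly as in [grid_search()], so evaluating a
#' plan selected from a grid with the same seed reproduces the grid's numbers.
#'
#' @param stream a preprocessed `sensor_stream`.
#' @param track a `label_track`.
#' @param plan an `adaptive_plan`.
#' @param seed integer top-level seed.
#' @inheritParams grid_search
#' @return data.frame with one row per class: class, ws_s, ss_s, precision,
#'   recall, f1, support.
#' @export
adaptive_evaluate <- function(stream, track, plan, seed = 1L,
                              classes = default_classes(),
                              purity_threshold = 0.8,
                              registry = feature_registry(),
                              train_frac = 0.7, max_windows = 2000,
                              n_splits = 1) {
  stopifnot(inherits(plan, "adaptive_plan"))
  algorithm <- attr(plan, "algorithm")
  cfg_key <- sprintf("%g_%g", plan$ws_s, plan$ss_s)
  evals <- list()
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    key <- cfg_key[i]
    if (is.null(evals[[key]])) {
      r <- .evaluate_point(stream, track, plan$ws_s[i], plan$ss_s[i],
                           algorithm, seed, classes, purity_threshold,
                           registry, train_frac, max_windows, n_splits)
      if (!r$ok) {
        stop(sprintf("adaptive point (ws=%g, ss=%g) unevaluable: %s",
                     plan$ws_s[i], plan$ss_s[i], r$reason))
      }
      evals[[key]] <- r$rows
    }
    rows <- evals[[key]]
    row <- rows[rows$class == plan$class[i], , drop = FALSE]
    if (nrow(row) == 0L) {
      stop(sprintf("class '%s' absent at its adaptive point (ws=%g, ss=%g)",
                   plan$class[i], plan$ws_s[i], plan$ss_s[i]))
    }
    out[[i]] <- data.frame(class = plan$class[i], ws_s = plan$ws_s[i],
                           ss_s = plan$ss_s[i],
                           precision = row$precision, recall = row$recall,
                           f1 = row$f1, support = row$support,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fuse per-class adaptive models into a label timeline
#'
#' Inference-time combination of per-behavior windows: for each time step t,
#' class c's confidence is taken from the most recent window covering t under
#' class c's (WS, SS), scored by the multiclass model trained at that window
#' configuration; the predicted label is the argmax, with ties broken toward
#' the behavior more frequent in training, then lexicographically. Samples
#' covered by no window (before the first full window or in step gaps) are
#' labeled `"unknown"`. This fusion is an extension beyond per-class
#' reporting: the adaptive results of [adaptive_evaluate()] are per class at
#' its own window, not fused.
#'
#' @param stream a preprocessed `sensor_stream`.
#' @param plan an `adaptive_plan`.
#' @param models named list of `adawin_model` objects, one per distinct
#'   window configuration in the plan, named `"<ws_samples>x<ss_samples>"`.
#' @param registry the [feature_registry()] the models were trained with.
#' @return character vector of length `n_samples(stream)`: the predicted
#'   behavior per sample.
#' @export
fuse_predict <- function(stream, plan, models, registry = feature_registry()) {
  stopifnot(inherits(stream, "sensor_stream"), inherits(plan, "adaptive_plan"))
  n <- n_samples(stream)
  rate <- stream$sample_rate
  specs <- lapply(seq_len(nrow(plan)), function(i) {
    window_spec_seconds(plan$ws_s[i], plan$ss_s[i], rate)
  })
  keys <- vapply(specs, function(sp) sprintf("%dx%d", sp$ws, sp$ss), "")
  missing_models <- setdiff(unique(keys), names(models))
  if (length(missing_models)) {
    stop(sprintf("missing model(s) for window configuration(s): %s",
                 paste(missing_models, collapse = ", ")))
  }
  t0 <- seq_len(n) - 1L
  score <- matrix(-Inf, nrow = n, ncol = nrow(plan),
                  dimnames = list(NULL, plan$class))
  freq <- numeric(nrow(plan))
  for (key in unique(keys)) {
    sp <- specs[[match(key, keys)]]
    wins <- enumerate_windows(n, sp)
    if (nrow(wins) == 0L) next
    segs <- structure(data.frame(start = wins$start, end = wins$end,
                                 label = NA_character_, purity = NA_real_),
                      spec = sp, sample_rate = rate,
                      class = c("segment_set", "data.frame"))
    feats <- featurize(segs, stream, registry)
    sc <- predict(models[[key]], feats, type = "prob")
    # most recent window covering t: index floor(t/ss), clamped to the last
    widx <- pmin(t0 %/% sp$ss, nrow(wins) - 1L) + 1L
    covered <- t0 >= wins$start[widx] & t0 < wins$end[widx]
    for (i in which(keys == key)) {
      cl <- plan$class[i]
      if (!cl %in% colnames(sc)) next
      score[covered, i] <- sc[widx[covered], cl]
      ft <- models[[key]]$train_freq
      freq[i] <- if (cl %in% names(ft)) as.numeric(ft[[cl]]) else 0
    }
  }
  pref <- order(-freq, plan$class)
  any_cov <- apply(score, 1, function(r) any(is.finite(r)))
  out <- rep("unknown", n)
  if (any(any_cov)) {
    pick <- apply(score[any_cov, pref, drop = FALSE], 1, which.max)
    out[any_cov] <- plan$class[pref][pick]
  }
  out
}
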