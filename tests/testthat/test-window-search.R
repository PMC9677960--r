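# Small simulated stream reused across the search tests (built once).
search_fixture <- local({
  sim <- simulate_stream(sim_config(duration_s = 1200), seed = 31)
  list(stream = preprocess_stream(sim$stream), track = sim$track)
})

test_that("a one-point grid on separable data reaches F1 = 1 for every class", {
  # balanced, near-noiseless mix: every class has ample support and the
  # classes are cleanly separable
  cfg <- sim_config(duration_s = 1200,
                    class_mix = c(eating = 0.3, lying = 0.3,
                                  walking = 0.2, standing = 0.2),
                    noise_sd = 0.05, gyro_noise_sd = 1)
  sim <- simulate_stream(cfg, seed = 41)
  g <- grid_search(preprocess_stream(sim$stream), sim$track,
                   ws_s = 3, ss_s = 0.5, algorithms = "rf", seed = 7,
                   max_windows = 400)
  expect_s3_class(g, "grid_result")
  expect_true(all(g$f1 == 1))
  expect_setequal(unique(g$class), c("eating", "lying", "walking", "standing"))
})

test_that("grid search is exhaustive and deterministic under a seed", {
  run <- function() {
    grid_search(search_fixture$stream, search_fixture$track,
                ws_s = c(2, 3), ss_s = c(0.5, 1), algorithms = c("rf", "dt"),
                seed = 11, max_windows = 300)
  }
  g1 <- run(); g2 <- run()
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  # |entries| = |ws| * |ss| * |algorithms| * |classes| minus unevaluable points
  n_classes <- length(unique(g1$class))
  expect_equal(nrow(g1) + nrow(attr(g1, "unevaluable")) * 2 * n_classes,
               2 * 2 * 2 * n_classes)
})

test_that("the sliding optimum maximizes mean F1 with the documented tie-break", {
  base <- expand.grid(ws_s = c(3, 5), ss_s = c(0.3, 0.5),
                      algorithm = "rf", class = c("eating", "walking"),
                      stringsAsFactors = FALSE)
  base$precision <- base$recall <- 0.9
  base$support <- 10
  # one strictly dominating point
  base$f1 <- ifelse(base$ws_s == 3 & base$ss_s == 0.5, 0.9, 0.5)
  opt <- select_sliding_optimum(manual_grid(base))
  expect_equal(c(opt$ws_s, opt$ss_s), c(3, 0.5))
  expect_equal(opt$mean_f1, 0.9)
  # equal mean F1 at ws 3 and ws 5 -> the ws-5 point wins
  base$f1 <- ifelse(base$ss_s == 0.5, 0.8, 0.2)
  opt <- select_sliding_optimum(manual_grid(base))
  expect_equal(c(opt$ws_s, opt$ss_s), c(5, 0.5))
  # equal F1 at two step sizes -> the smaller ss wins
  base$f1 <- 0.7
  opt <- select_sliding_optimum(manual_grid(base))
  expect_equal(c(opt$ws_s, opt$ss_s), c(5, 0.3))
  # per-algorithm criterion returns one row per algorithm
  two <- rbind(base, transform(base, algorithm = "svm", f1 = ifelse(ws_s == 3, 1, 0)))
  per <- select_sliding_optimum(manual_grid(two), criterion = "per_algorithm")
  expect_equal(nrow(per), 2)
  expect_equal(per$ws_s[per$algorithm == "svm"], 3)
})

test_that("adaptive optima pick each class's argmax, invariant to row order", {
  base <- expand.grid(ws_s = c(2, 7), ss_s = c(0.1, 0.5),
                      algorithm = "rf", class = c("eating", "walking"),
                      stringsAsFactors = FALSE)
  base$precision <- base$recall <- 0.9
  base$support <- 10
  base$f1 <- with(base, ifelse(class == "eating" & ws_s == 7 & ss_s == 0.1, 0.95,
                        ifelse(class == "walking" & ws_s == 2 & ss_s == 0.5, 0.9, 0.4)))
  plan <- select_adaptive_optima(manual_grid(base), "rf")
  expect_equal(plan$ws_s[plan$class == "eating"], 7)
  expect_equal(plan$ss_s[plan$class == "eating"], 0.1)
  expect_equal(plan$ws_s[plan$class == "walking"], 2)
  set.seed(1)
  shuffled <- manual_grid(base[sample(nrow(base)), ])
  expect_identical(as.data.frame(select_adaptive_optima(shuffled, "rf")),
                   as.data.frame(plan))
  expect_error(select_adaptive_optima(manual_grid(base), "nb"), "not present")
})

test_that("adaptive evaluation reproduces grid numbers (sliding reduction)", {
  g <- grid_search(search_fixture$stream, search_fixture$track,
                   ws_s = 3, ss_s = c(0.5, 1), algorithms = "rf", seed = 5,
                   max_windows = 300)
  # a plan putting every class at one grid point is just that sliding run
  classes <- sort(unique(g$class))
  plan <- structure(data.frame(class = classes, ws_s = 3, ss_s = 1,
                               f1 = NA_real_, stringsAsFactors = FALSE),
                    algorithm = "rf", class = c("adaptive_plan", "data.frame"))
  ae <- adaptive_evaluate(search_fixture$stream, search_fixture$track, plan,
                          seed = 5, max_windows = 300)
  ref <- g[g$ss_s == 1, ]
  ref <- ref[order(ref$class), ]
  expect_equal(ae$f1, ref$f1)
  expect_equal(ae$precision, ref$precision)
  expect_equal(ae$support, ref$support)
})

test_that("argmax dominance: grid maximum is at least the sliding-optimum F1", {
  g <- grid_search(search_fixture$stream, search_fixture$track,
                   ws_s = c(2, 5), ss_s = c(0.3, 1), algorithms = "rf",
                   seed = 13, max_windows = 300)
  opt <- select_sliding_optimum(g)
  plan <- select_adaptive_optima(g, "rf")
  at_opt <- g[g$ws_s == opt$ws_s & g$ss_s == opt$ss_s, ]
  for (cl in plan$class) {
    expect_gte(plan$f1[plan$class == cl], at_opt$f1[at_opt$class == cl])
  }
})

test_that("fusion produces a sensible per-sample timeline", {
  st <- search_fixture$stream
  tr <- search_fixture$track
  sp <- window_spec_seconds(3, 0.5, 10)
  segs <- segment_stream(st, tr, sp)
  feats <- featurize(segs, st)
  model <- fit_classifier(classifier_spec("rf", seed = 3), feats)
  classes <- sort(unique(segs$label))
  plan <- structure(data.frame(class = classes, ws_s = 3, ss_s = 0.5,
                               f1 = NA_real_, stringsAsFactors = FALSE),
                    algorithm = "rf", class = c("adaptive_plan", "data.frame"))
  timeline <- fuse_predict(st, plan, list(`30x5` = model))
  expect_length(timeline, n_samples(st))
  expect_true(all(timeline %in% c(classes, "unknown")))
  # single-(ws,ss) plans reduce to ordinary windowed prediction: each sample
  # inherits the label of its most recent covering window
  win_pred <- predict(model, feats, type = "class")
  # timeline accuracy should track per-window accuracy closely
  truth <- adawin:::sample_labels(tr, n_samples(st), 10)
  ok <- !is.na(truth) & truth %in% classes & timeline != "unknown"
  timeline_acc <- mean(timeline[ok] == truth[ok])
  window_acc <- mean(win_pred == segs$label)
  expect_gte(timeline_acc, window_acc - 0.05)
  # missing model is reported
  expect_error(fuse_predict(st, plan, list()), "missing model")
})

test_that("the adawin() fit object exposes plan, coefficients and predictions", {
  fit <- adawin(search_fixture$stream, search_fixture$track,
                ws_s = c(2, 3), ss_s = c(0.5, 1.5), seed = 21,
                max_windows = 300)
  expect_s3_class(fit, "adawin")
  expect_output(print(fit), "sliding optimum")
  cf <- coef(fit)
  expect_identical(colnames(cf), c("ws_s", "ss_s"))
  expect_setequal(rownames(cf), unique(fit$grid$class))
  expect_true(all(cf[, "ws_s"] %in% c(2, 3)))
  tl <- predict(fit, search_fixture$stream)
  expect_length(tl, n_samples(search_fixture$stream))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("repeated-split averaging is deterministic and defaults to one holdout", {
  g1 <- grid_search(search_fixture$stream, search_fixture$track,
                    ws_s = 3, ss_s = 1, algorithms = "rf", seed = 9,
                    max_windows = 300)
  g2 <- grid_search(search_fixture$stream, search_fixture$track,
                    ws_s = 3, ss_s = 1, algorithms = "rf", seed = 9,
                    max_windows = 300, n_splits = 3)
  g3 <- grid_search(search_fixture$stream, search_fixture$track,
                    ws_s = 3, ss_s = 1, algorithms = "rf", seed = 9,
                    max_windows = 300, n_splits = 3)
  expect_identical(as.data.frame(g2), as.data.frame(g3))
  # averaged support is the mean across replicate test sets, close to the
  # single-holdout support
  expect_equal(g2$class, g1$class)
  expect_true(all(abs(g2$support - g1$support) <= pmax(2, 0.2 * g1$support)))
})
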