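test_that("channel statistics agree with the brute-force oracle", {
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(sample(2:200, 1), sd = runif(1, 0.1, 10))
    expect_equal(channel_statistics(x), oracle_stats(x), tolerance = 1e-9)
  }
  # signals with exact zeros and ties exercise the sign-carry rule
  x <- c(1, 0, 0, -1, 0, 1, 1, 0, -1)
  expect_equal(channel_statistics(x), oracle_stats(x), tolerance = 1e-9)
  expect_error(channel_statistics(5), "2 samples")
})

test_that("hand-worked statistic examples hold", {
  s <- channel_statistics(c(1, 3, 2))
  expect_equal(unname(s["abs_sum_changes"]), 3) # |3-1| + |2-3|
  s <- channel_statistics(c(1, -1, 1, -1))
  expect_equal(unname(s["zero_cross"]), 3)
  expect_equal(unname(s["mean"]), 0)
})

test_that("statistics scale as documented under x -> a*x", {
  set.seed(3)
  x <- rnorm(50)
  a <- 3.7
  s1 <- channel_statistics(x)
  s2 <- channel_statistics(a * x)
  linear <- c("mean", "sd", "max", "min", "iqr", "range", "abs_sum_changes", "l2norm")
  expect_equal(s2[linear], a * s1[linear], tolerance = 1e-9)
  expect_equal(unname(s2["sse"]), unname(a^2 * s1["sse"]), tolerance = 1e-9)
  invariant <- c("pos_count", "neg_count", "skewness", "kurtosis", "zero_cross")
  expect_equal(s2[invariant], s1[invariant], tolerance = 1e-9)
})

test_that("magnitude spectrum matches a direct DFT and Parseval's identity", {
  set.seed(8)
  for (n in c(2, 3, 17, 64)) {
    x <- rnorm(n)
    expect_equal(magnitude_spectrum(x), oracle_spectrum(x), tolerance = 1e-8)
  }
  # pure cosine at bin k peaks at bin k
  n <- 64; k <- 5
  x <- cos(2 * pi * k * (0:(n - 1)) / n)
  spec <- magnitude_spectrum(x)
  expect_equal(which.max(spec), k)
  expect_length(spec, 32)
  # constant input has an all-zero spectrum (mean removal)
  expect_equal(magnitude_spectrum(rep(4, 10)), rep(0, 5))
  # Parseval under the documented scaling (interior bins doubled)
  for (n in c(11, 12)) {
    x <- rnorm(n)
    spec <- magnitude_spectrum(x)
    total <- 2 * sum(spec^2) - (n %% 2 == 0) * spec[length(spec)]^2
    expect_equal(total, n * sum((x - mean(x))^2), tolerance = 1e-6)
  }
})

test_that("pitch and roll recover known orientations", {
  g <- 9.81
  expect_equal(pitch_roll(matrix(c(0, 0, g), 1)), c(pitch = 0, roll = 0))
  expect_equal(pitch_roll(matrix(c(g, 0, 0), 1)), c(pitch = 90, roll = 0))
  expect_equal(pitch_roll(matrix(c(0, g, 0), 1)), c(pitch = 0, roll = 90))
  # 30-degree tilt
  expect_equal(pitch_roll(matrix(c(g / 2, 0, g * sqrt(3) / 2), 1))["pitch"],
               c(pitch = 30), tolerance = 1e-9)
  # zero samples are skipped; all-zero input warns and returns 0
  acc <- rbind(c(0, 0, 0), c(0, 0, g))
  expect_equal(pitch_roll(acc), c(pitch = 0, roll = 0))
  expect_warning(out <- pitch_roll(matrix(0, 2, 3)), "all-zero")
  expect_equal(out, c(pitch = 0, roll = 0))
  # agrees with the oracle on random windows
  set.seed(5)
  a <- matrix(rnorm(60), 20, 3)
  expect_equal(pitch_roll(a), oracle_pitch_roll(a), tolerance = 1e-9)
})

test_that("the default registry yields 226 columns, halved core without freq", {
  reg <- feature_registry()
  expect_length(feature_names(reg), 226)
  reg_t <- feature_registry(domains = "time")
  expect_length(feature_names(reg_t), 112 + 2)
  reg_bare <- feature_registry(domains = "time", include_orientation = FALSE)
  expect_length(feature_names(reg_bare), 112)
  expect_false(anyDuplicated(feature_names(reg)) > 0)
})

test_that("featurize computes registry statistics per window and channel", {
  st <- random_stream(n = 100, seed = 13)
  segs <- manual_segments(c(0, 20, 40), ws = 20, ss = 20,
                          labels = c("eating", "lying", "eating"))
  tab <- featurize(segs, st)
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 3)
  expect_equal(ncol(tab), 3 + 226)
  expect_identical(names(tab)[1:3], c("window_start", "window_end", "label"))
  expect_false(anyNA(tab[, -3]))
  expect_equal(attr(tab, "provenance")$n_features, 226)

  # spot-check one window against the public per-vector operations
  w2 <- 21:40
  expect_equal(unlist(tab[2, paste0("ax_time_", names(oracle_stats(1:3)))]),
               oracle_stats(st$acc[w2, 1]),
               tolerance = 1e-9, ignore_attr = TRUE)
  gmag <- sqrt(rowSums(st$gyro[w2, ]^2))
  expect_equal(unlist(tab[2, paste0("gyro_mag_freq_", names(oracle_stats(1:3)))]),
               oracle_stats(oracle_spectrum(gmag)),
               tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(c(tab$pitch[2], tab$roll[2]),
               unname(oracle_pitch_roll(st$acc[w2, ])), tolerance = 1e-9)

  # determinism: two identical windows give identical rows
  segs2 <- manual_segments(c(10, 10), ws = 20, ss = 20,
                           labels = c("eating", "eating"))
  tab2 <- featurize(segs2, st)
  expect_identical(unlist(tab2[1, -(1:3)]), unlist(tab2[2, -(1:3)]))

  # a preprocessed stream is required
  expect_error(featurize(segs, random_stream(na_frac = 0.2)), "gap-free")
})

test_that("spectrum statistics of a 2-sample window degrade gracefully", {
  st <- random_stream(n = 10, seed = 2)
  segs <- manual_segments(c(0, 2), ws = 2, ss = 2, labels = c("eating", "lying"))
  tab <- featurize(segs, st)
  expect_false(anyNA(tab[, -3]))
  expect_equal(tab$ax_freq_sd, c(0, 0)) # single-bin spectrum has no spread
})
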