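# In-code fixtures shared across test files.

random_stream <- function(n = 50, seed = 1, na_frac = 0) {
  set.seed(seed)
  acc <- matrix(rnorm(3 * n, sd = 5), n, 3)
  gyro <- matrix(rnorm(3 * n, sd = 100), n, 3)
  if (na_frac > 0) {
    acc[sample(length(acc), round(na_frac * length(acc)))] <- NA
    gyro[sample(length(gyro), round(na_frac * length(gyro)))] <- NA
  }
  sensor_stream(acc, gyro, sample_rate = 10,
                animal_id = "pigA", session_id = "s1")
}

# a stream whose six channels are the given vector (handy for channel-level
# expectations)
channel_stream <- function(x, sample_rate = 10) {
  sensor_stream(acc = cbind(x, x, x), gyro = cbind(x, x, x),
                sample_rate = sample_rate)
}

# a segment_set over explicit windows, bypassing segment_stream
manual_segments <- function(starts, ws, ss, labels, sample_rate = 10) {
  structure(data.frame(start = starts, end = starts + ws, label = labels,
                       purity = 1, stringsAsFactors = FALSE),
            spec = window_spec(ws, ss), sample_rate = sample_rate,
            class = c("segment_set", "data.frame"))
}

# linearly separable two-class feature table
blob_table <- function(n_per_class = 30, seed = 1, gap = 10) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * 3), ncol = 3),
             matrix(rnorm(n_per_class * 3, mean = gap), ncol = 3))
  out <- cbind(data.frame(window_start = seq_len(2 * n_per_class) - 1,
                          window_end = seq_len(2 * n_per_class),
                          label = rep(c("lying", "walking"), each = n_per_class),
                          stringsAsFactors = FALSE),
               as.data.frame(X))
  names(out)[4:6] <- c("f1", "f2", "f3")
  structure(out, class = c("feature_table", "data.frame"))
}

# random feature table with `f` noise features and an optional planted signal
noise_table <- function(n = 60, f = 20, seed = 1, plant = 0) {
  set.seed(seed)
  y <- rep(c("lying", "walking"), length.out = n)
  X <- matrix(rnorm(n * f), n, f)
  if (plant > 0) {
    for (j in seq_len(plant)) X[, j] <- X[, j] + ifelse(y == "lying", 3, -3)
  }
  colnames(X) <- sprintf("feat%03d", seq_len(f))
  out <- cbind(data.frame(window_start = seq_len(n) - 1, window_end = seq_len(n),
                          label = y, stringsAsFactors = FALSE),
               as.data.frame(X))
  structure(out, class = c("feature_table", "data.frame"))
}

# hand-built grid_result for the selector tests
manual_grid <- function(df) {
  structure(df,
            unevaluable = data.frame(ws_s = numeric(0), ss_s = numeric(0),
                                     reason = character(0)),
            ws_axis = sort(unique(df$ws_s)), ss_axis = sort(unique(df$ss_s)),
            algorithms = unique(df$algorithm), seed = 1L,
            class = c("grid_result", "data.frame"))
}
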