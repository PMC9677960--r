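# Core containers: sensor_stream (6-channel inertial record) and label_track
# (non-overlapping behavior intervals). Both are plain S3 over base types.

#' Behavior vocabulary
#'
#' The eight behavior classes observed in the source ethogram, ordered from
#' rarest to most frequent recorded time share (sitting 0.24%, playing 0.48%,
#' drinking 0.49%, standing 1.76%, walking 7.87%, lying 33.33%, eating 49.40%),
#' with the catch-all "unknown" last. The order doubles as the tie-break
#' priority when a window's majority label is ambiguous: ties go to the rarer
#' class, protecting minority behaviors.
#'
#' @export
behavior_vocabulary <- function() {
  c("sitting", "playing", "drinking", "standing",
    "walking", "lying", "eating", "unknown")
}

#' Default analysis classes
#'
#' The four behaviors retained for classification; sitting, drinking, playing
#' and unknown are excluded as too infrequent to train on.
#'
#' @export
default_classes <- function() c("eating", "lying", "walking", "standing")

#' Construct a sensor stream
#'
#' A time-ordered 6-channel inertial record for one animal and session:
#' 3-axis acceleration (m/s^2), 3-axis angular velocity (deg/s), a per-sample
#' timestamp (seconds) and a hardware counter. Missing values are `NA`.
#'
#' @param acc numeric n x 3 matrix of acceleration (columns x, y, z), m/s^2.
#' @param gyro numeric n x 3 matrix of angular velocity (columns x, y, z), deg/s.
#' @param timestamps numeric vector of length n, seconds, non-decreasing where
#'   finite. Default `(0:(n-1))/sample_rate`.
#' @param counters non-negative integer vector of length n. Default `0:(n-1)`.
#' @param sample_rate samples per second (> 0), default 10.
#' @param animal_id,session_id identifiers.
#' @return an object of class `sensor_stream`.
#' @export
sensor_stream <- function(acc, gyro, timestamps = NULL, counters = NULL,
                          sample_rate = 10, animal_id = "animal1",
                          session_id = "session1") {
  acc <- as.matrix(acc)
  gyro <- as.matrix(gyro)
  if (ncol(acc) != 3L || ncol(gyro) != 3L) {
    stop("acc and gyro must each have 3 columns (x, y, z)")
  }
  n <- nrow(acc)
  if (nrow(gyro) != n) stop("acc and gyro must have the same number of rows")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar")
  }
  if (is.null(timestamps)) timestamps <- seq_len(n) / sample_rate - 1 / sample_rate
  if (is.null(counters)) counters <- seq_len(n) - 1
  timestamps <- as.numeric(timestamps)
  counters <- as.numeric(counters)
  if (length(timestamps) != n || length(counters) != n) {
    stop("timestamps and counters must have length n = nrow(acc)")
  }
  ft <- timestamps[is.finite(timestamps)]
  if (length(ft) > 1 && any(diff(ft) < 0)) {
    warning("timestamps are not non-decreasing; see validate_stream()")
  }
  colnames(acc) <- c("x", "y", "z")
  colnames(gyro) <- c("x", "y", "z")
  structure(
    list(animal_id = animal_id, session_id = session_id,
         sample_rate = sample_rate, timestamps = timestamps,
         counters = counters, acc = acc, gyro = gyro),
    class = "sensor_stream"
  )
}

#' Number of samples in a sensor stream
#' @param stream a `sensor_stream`.
#' @export
n_samples <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  nrow(stream$acc)
}

#' @export
print.sensor_stream <- function(x, ...) {
  n <- n_samples(x)
  cat(sprintf("<sensor_stream> %s/%s: %d samples @ %g Hz (%.1f s)\n",
              x$animal_id, x$session_id, n, x$sample_rate, n / x$sample_rate))
  na_acc <- sum(is.na(x$acc)); na_gyro <- sum(is.na(x$gyro))
  cat(sprintf("  acc  [m/s^2]: range [%s]; %d missing cells\n",
              paste(signif(range(x$acc, na.rm = TRUE), 4), collapse = ", "), na_acc))
  cat(sprintf("  gyro [deg/s]: range [%s]; %d missing cells\n",
              paste(signif(range(x$gyro, na.rm = TRUE), 4), collapse = ", "), na_gyro))
  invisible(x)
}

#' Construct a label track
#'
#' Half-open behavior intervals `[start_s, end_s)` over a stream's time axis.
#' Intervals must not overlap and labels must come from
#' [behavior_vocabulary()].
#'
#' @param start_s,end_s numeric vectors, seconds.
#' @param label character vector of behavior labels.
#' @return a `label_track`, a data.frame sorted by `start_s`.
#' @export
label_track <- function(start_s, end_s, label) {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  label <- as.character(label)
  n <- length(start_s)
  if (length(end_s) != n || length(label) != n) {
    stop("start_s, end_s and label must have equal length")
  }
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    stop("interval bounds must be finite")
  }
  if (any(end_s <= start_s)) {
    bad <- which(end_s <= start_s)[1]
    stop(sprintf("interval %d has end_s <= start_s (%g <= %g)",
                 bad, end_s[bad], start_s[bad]))
  }
  unknown <- setdiff(unique(label), behavior_vocabulary())
  if (length(unknown)) {
    stop(sprintf("label(s) not in the behavior vocabulary: %s",
                 paste(unknown, collapse = ", ")))
  }
  o <- order(start_s, end_s)
  start_s <- start_s[o]; end_s <- end_s[o]; label <- label[o]
  if (n > 1) {
    ov <- which(start_s[-1] < end_s[-n])
    if (length(ov)) {
      i <- ov[1]
      stop(sprintf(
        "intervals %d and %d overlap: [%g, %g) '%s' vs [%g, %g) '%s'",
        i, i + 1, start_s[i], end_s[i], label[i],
        start_s[i + 1], end_s[i + 1], label[i + 1]))
    }
  }
  structure(data.frame(start_s = start_s, end_s = end_s, label = label,
                       stringsAsFactors = FALSE),
            class = c("label_track", "data.frame"))
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track> %d intervals over [%g, %g) s\n",
              nrow(x), min(x$start_s), max(x$end_s)))
  tab <- tapply(x$end_s - x$start_s, x$label, sum)
  tot <- sum(tab)
  for (lab in names(sort(tab, decreasing = TRUE))) {
    cat(sprintf("  %-9s %8.1f s (%.1f%%)\n", lab, tab[[lab]], 100 * tab[[lab]] / tot))
  }
  invisible(x)
}

# Per-sample behavior labels for samples 0..n-1; sample i is assigned the
# interval containing time i/rate, NA where uncovered.
sample_labels <- function(track, n, rate) {
  times <- (seq_len(n) - 1) / rate
  idx <- findInterval(times, track$start_s)
  lab <- rep(NA_character_, n)
  hit <- idx >= 1L
  hit[hit] <- times[hit] < track$end_s[idx[hit]]
  lab[hit] <- track$label[idx[hit]]
  lab
}
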