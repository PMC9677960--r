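# Segmentation: fixed sliding windows over the sample axis and majority-label
# assignment with a purity gate. Window indices are 0-based half-open
# [start, end) sample ranges, matching the convention that with WS 50 and
# SS 25 the first two windows are [0, 50) and [25, 75).

#' Window specification
#'
#' @param ws window size in samples (>= 2).
#' @param ss step size in samples (>= 1); `ss < ws` gives overlapping windows,
#'   `ss > ws` leaves gaps.
#' @export
window_spec <- function(ws, ss) {
  ws <- as.integer(round(ws)); ss <- as.integer(round(ss))
  if (ws < 2L) stop("window size ws must be >= 2 samples")
  if (ss < 1L) stop("step size ss must be >= 1 sample")
  structure(list(ws = ws, ss = ss), class = "window_spec")
}

#' Convert a window specification from seconds to samples
#'
#' @param ws_s,ss_s window and step size in seconds.
#' @param sample_rate samples per second.
#' @export
window_spec_seconds <- function(ws_s, ss_s, sample_rate = 10) {
  window_spec(round(ws_s * sample_rate), round(ss_s * sample_rate))
}

#' Enumerate sliding windows
#'
#' Windows are `[start, start + ws)` for `start = 0, ss, 2*ss, ...` while the
#' window fits inside the stream, giving `floor((n - ws)/ss) + 1` windows when
#' `n >= ws` and none otherwise.
#'
#' @param n number of samples (>= 1).
#' @param spec a [window_spec()].
#' @return a data.frame with 0-based columns `start`, `end` (half-open).
#' @export
enumerate_windows <- function(n, spec) {
  stopifnot(inherits(spec, "window_spec"), n >= 1)
  if (n < spec$ws) return(data.frame(start = integer(0), end = integer(0)))
  start <- seq.int(0L, n - spec$ws, by = spec$ss)
  data.frame(start = start, end = start + spec$ws)
}

# Tie-break priority: rarer behavior wins (behavior_vocabulary order), then
# lexicographic for labels outside the vocabulary.
.label_priority <- function(labels) {
  pri <- match(labels, behavior_vocabulary())
  pri[is.na(pri)] <- length(behavior_vocabulary()) + rank(labels[is.na(pri)])
  pri
}

#' Label one window from a label track
#'
#' The window takes the behavior covering the largest number of its samples;
#' purity is that coverage fraction (uncovered samples count against purity).
#' Ties are broken toward the rarer behavior, then lexicographically. Windows
#' below the purity threshold get label `NA`.
#'
#' @param start,end 0-based half-open sample range of the window.
#' @param track a `label_track`.
#' @param sample_rate samples per second.
#' @param purity_threshold minimum coverage fraction, default 0.8.
#' @param n optional stream length for bounds checking.
#' @return list with `label` (character or `NA`) and `purity`.
#' @export
label_window <- function(start, end, track, sample_rate = 10,
                         purity_threshold = 0.8, n = NULL) {
  if (start < 0 || end <= start) stop("invalid window bounds")
  if (!is.null(n) && end > n) {
    stop(sprintf("window [%d, %d) outside stream extent n=%d", start, end, n))
  }
  labs <- sample_labels(track, end, sample_rate)[(start + 1):end]
  labs <- labs[!is.na(labs)]
  ws <- end - start
  if (length(labs) == 0L) return(list(label = NA_character_, purity = 0))
  counts <- table(labs)
  top <- names(counts)[counts == max(counts)]
  winner <- top[order(.label_priority(top))][1]
  purity <- as.numeric(max(counts)) / ws
  if (purity < purity_threshold) {
    list(label = NA_character_, purity = purity)
  } else {
    list(label = winner, purity = purity)
  }
}

#' Segment a stream into labeled windows
#'
#' Enumerates sliding windows, assigns each a majority label with a purity
#' gate, and retains windows whose label is in `classes`. Deterministic for
#' fixed inputs.
#'
#' @param stream a preprocessed `sensor_stream`.
#' @param track a `label_track`.
#' @param spec a [window_spec()] (samples).
#' @param classes behaviors to keep; default [default_classes()] (the four
#'   analysis behaviors; sitting, drinking, playing, unknown are excluded).
#' @param purity_threshold minimum majority-coverage fraction, default 0.8.
#' @return a `segment_set`: data.frame with 0-based `start`, `end`, `label`,
#'   `purity`, carrying the spec and stream identifiers as attributes. May
#'   have zero rows.
#' @export
segment_stream <- function(stream, track, spec,
                           classes = default_classes(),
                           purity_threshold = 0.8) {
  stopifnot(inherits(stream, "sensor_stream"), inherits(track, "label_track"),
            inherits(spec, "window_spec"))
  n <- n_samples(stream)
  wins <- enumerate_windows(n, spec)
  out <- data.frame(start = integer(0), end = integer(0),
                    label = character(0), purity = numeric(0))
  if (nrow(wins) > 0L) {
    labs <- sample_labels(track, n, stream$sample_rate)
    seen <- unique(labs[!is.na(labs)])
    if (length(seen) > 0L) {
      # cumulative per-class coverage -> O(1) window counts per class
      seen <- seen[order(.label_priority(seen))] # priority order for max.col ties
      cum <- vapply(seen, function(lab) cumsum(!is.na(labs) & labs == lab),
                    numeric(n))
      cum <- rbind(0, cum) # cum[i + 1, c] = count of class c in samples 1..i
      cover <- cum[wins$end + 1L, , drop = FALSE] -
        cum[wins$start + 1L, , drop = FALSE]
      best <- max.col(cover, ties.method = "first") # first = rarest by ordering
      best_count <- cover[cbind(seq_len(nrow(cover)), best)]
      purity <- best_count / spec$ws
      label <- seen[best]
      keep <- best_count > 0 & purity >= purity_threshold & label %in% classes
      out <- data.frame(start = wins$start[keep], end = wins$end[keep],
                        label = label[keep], purity = purity[keep])
    }
  }
  structure(out,
            spec = spec, sample_rate = stream$sample_rate,
            animal_id = stream$animal_id, session_id = stream$session_id,
            classes = classes, purity_threshold = purity_threshold,
            class = c("segment_set", "data.frame"))
}

#' @export
print.segment_set <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<segment_set> %d windows (ws=%d, ss=%d samples)\n",
              nrow(x), spec$ws, spec$ss))
  if (nrow(x)) print(table(x$label))
  invisible(x)
}
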