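# Feature extraction: 14 statistics per channel per domain over 8 channels
# (6 axes + acceleration/gyro magnitudes), in the time domain and on the
# one-sided magnitude spectrum, plus accelerometer pitch and roll. The default
# registry has 14 x 8 x 2 = 224 core features + 2 orientation angles.

.stat_names <- c("mean", "sd", "max", "min", "iqr", "range", "pos_count",
                 "neg_count", "skewness", "kurtosis", "zero_cross", "sse",
                 "abs_sum_changes", "l2norm")
.channel_names <- c("ax", "ay", "az", "gx", "gy", "gz", "acc_mag", "gyro_mag")

#' Feature registry
#'
#' Declares which statistics, channels and domains make up the feature vector.
#' The defaults reproduce the 224-feature layout (14 statistics x 8 channels
#' x time/frequency) plus the pitch and roll orientation angles, for 226
#' columns per window.
#'
#' @param statistics ordered subset of the 14 statistic names.
#' @param channels ordered subset of
#'   `ax, ay, az, gx, gy, gz, acc_mag, gyro_mag`.
#' @param domains subset of `c("time", "freq")`.
#' @param include_orientation add accelerometer `pitch` and `roll`, default
#'   TRUE.
#' @return a `feature_registry`.
#' @export
feature_registry <- function(statistics = .stat_names,
                             channels = .channel_names,
                             domains = c("time", "freq"),
                             include_orientation = TRUE) {
  statistics <- match.arg(statistics, .stat_names, several.ok = TRUE)
  channels <- match.arg(channels, .channel_names, several.ok = TRUE)
  domains <- match.arg(domains, c("time", "freq"), several.ok = TRUE)
  if (anyDuplicated(statistics) || anyDuplicated(channels) || anyDuplicated(domains)) {
    stop("registry entries must be unique")
  }
  structure(list(statistics = statistics, channels = channels,
                 domains = domains, include_orientation = include_orientation),
            class = "feature_registry")
}

#' Feature names of a registry, in column order
#'
#' Channel-major, then domain, then statistic (`ax_time_mean`, ...), with
#' `pitch` and `roll` last when orientation is enabled.
#'
#' @param registry a [feature_registry()].
#' @export
feature_names <- function(registry) {
  stopifnot(inherits(registry, "feature_registry"))
  core <- as.vector(vapply(
    registry$channels,
    function(ch) as.vector(vapply(
      registry$domains,
      function(dom) paste(ch, dom, registry$statistics, sep = "_"),
      character(length(registry$statistics)))),
    character(length(registry$statistics) * length(registry$domains))))
  if (registry$include_orientation) c(core, "pitch", "roll") else core
}

#' @export
print.feature_registry <- function(x, ...) {
  cat(sprintf("<feature_registry> %d features: %d statistics x %d channels x %d domains%s\n",
              length(feature_names(x)), length(x$statistics), length(x$channels),
              length(x$domains),
              if (x$include_orientation) " + pitch/roll" else ""))
  invisible(x)
}

# All 14 statistics column-wise over a windows-in-columns matrix. Returns a
# 14 x ncol matrix (rownames = statistic names). Degenerate single-row input
# (e.g. the 1-bin spectrum of a 2-sample window) yields 0 for the spread,
# shape and change statistics.
stat_matrix <- function(M) {
  m <- nrow(M); k <- ncol(M)
  mu <- colMeans(M)
  Mc <- M - rep(mu, each = m)
  sse <- colSums(Mc^2)
  m2 <- sse / m
  sdv <- if (m > 1) sqrt(sse / (m - 1)) else rep(0, k)
  mx <- apply(M, 2, max)
  mn <- apply(M, 2, min)
  # type-7 quartiles from column-sorted order statistics
  S <- matrix(apply(M, 2, sort), nrow = m)
  q_at <- function(p) {
    pos <- (m - 1) * p + 1
    lo <- floor(pos); fr <- pos - lo
    v <- S[lo, ]
    if (fr > 0) v <- v + fr * (S[lo + 1, ] - v)
    v
  }
  iqr <- q_at(0.75) - q_at(0.25)
  pos_count <- colSums(Mc > 0)
  neg_count <- colSums(Mc < 0)
  safe_m2 <- ifelse(m2 > 0, m2, 1)
  skewness <- ifelse(m2 > 0, colMeans(Mc^3) / safe_m2^1.5, 0)
  kurtosis <- ifelse(m2 > 0, colMeans(Mc^4) / safe_m2^2 - 3, 0)
  zero_cross <- apply(Mc, 2, function(v) {
    s <- sign(v); s <- s[s != 0]
    if (length(s) < 2) 0L else sum(diff(s) != 0)
  })
  abs_sum_changes <- if (m > 1) {
    colSums(abs(M[-1, , drop = FALSE] - M[-m, , drop = FALSE]))
  } else rep(0, k)
  l2norm <- sqrt(colSums(M^2))
  out <- rbind(mean = mu, sd = sdv, max = mx, min = mn, iqr = iqr,
               range = mx - mn, pos_count = pos_count, neg_count = neg_count,
               skewness = skewness, kurtosis = kurtosis,
               zero_cross = zero_cross, sse = sse,
               abs_sum_changes = abs_sum_changes, l2norm = l2norm)
  out
}

#' The 14 per-channel statistics of a signal
#'
#' Conventions: `sd` uses denominator n-1; `iqr` uses linear interpolation at
#' position `(n-1)q` (quantile type 7); `pos_count`/`neg_count` count
#' mean-centered samples strictly above/below zero (raw signs are degenerate
#' after min-max normalization); skewness is the bias-uncorrected standardized
#' third moment and kurtosis the excess fourth moment (0 for a normal);
#' `zero_cross` counts sign changes of the mean-centered signal, with zeros
#' inheriting the previous nonzero sign; `sse` is the total squared deviation
#' from the mean; `abs_sum_changes` is `sum(|x[i+1] - x[i]|)`; `l2norm` is the
#' Euclidean norm of the raw signal.
#'
#' @param x numeric vector, length >= 2, no missing values.
#' @return named numeric vector of the 14 statistics.
#' @export
channel_statistics <- function(x) {
  if (length(x) < 2L) stop("channel_statistics needs at least 2 samples")
  if (anyNA(x)) stop("channel_statistics requires a gap-free signal")
  stat_matrix(matrix(x, ncol = 1))[, 1]
}

#' One-sided magnitude spectrum of a window
#'
#' The discrete Fourier transform of the mean-removed signal; the DC bin is
#' excluded (it is zero after mean removal) and bins 2..floor(n/2)+1 are
#' returned, i.e. `floor(n/2)` magnitudes up to and including the Nyquist bin
#' for even n. No 1/n scaling is applied, so Parseval's identity reads
#' `2 * sum(spec^2) - (n even) * spec_Nyquist^2 = n * sum((x - mean(x))^2)`.
#'
#' @param x numeric vector, length >= 2, no missing values.
#' @return numeric vector of length `floor(length(x)/2)`.
#' @export
magnitude_spectrum <- function(x) {
  n <- length(x)
  if (n < 2L) stop("magnitude_spectrum needs at least 2 samples")
  if (anyNA(x)) stop("magnitude_spectrum requires a gap-free signal")
  Mod(stats::fft(x - mean(x)))[2:(floor(n / 2) + 1)]
}

#' Accelerometer pitch and roll of a window
#'
#' Per sample, pitch is the inclination of the x axis against the gravity
#' plane, `atan2(ax, sqrt(ay^2 + az^2))`, and roll the inclination of the y
#' axis, `atan2(ay, sqrt(ax^2 + az^2))`; the window value is the mean over
#' samples, in degrees. The per-sample angles live in (-90, 90] degrees so a
#' plain mean is circular-safe. All-zero acceleration samples are skipped; an
#' all-zero window yields 0 with a warning.
#'
#' @param acc numeric n x 3 acceleration matrix.
#' @return named numeric vector `c(pitch = , roll = )`, degrees.
#' @export
pitch_roll <- function(acc) {
  acc <- as.matrix(acc)
  stopifnot(ncol(acc) == 3)
  nz <- rowSums(acc != 0) > 0
  if (!any(nz)) {
    warning("all-zero acceleration; pitch/roll set to 0")
    return(c(pitch = 0, roll = 0))
  }
  a <- acc[nz, , drop = FALSE]
  deg <- 180 / pi
  p <- atan2(a[, 1], sqrt(a[, 2]^2 + a[, 3]^2)) * deg
  r <- atan2(a[, 2], sqrt(a[, 1]^2 + a[, 3]^2)) * deg
  c(pitch = mean(p), roll = mean(r))
}

#' Extract the feature table of a segment set
#'
#' For each window and channel (six axes plus the acceleration and gyro
#' magnitude vectors), computes the registry's statistics on the time signal
#' and on its one-sided magnitude spectrum, plus mean pitch/roll when
#' orientation is enabled. Rows follow the segment order; the row label is the
#' window's behavior label.
#'
#' @param segments a `segment_set` (windows of one common size).
#' @param stream the preprocessed `sensor_stream` the segments index into.
#' @param registry a [feature_registry()].
#' @return a `feature_table`: data.frame with columns `window_start`,
#'   `window_end`, `label`, then one column per registry feature; provenance
#'   (ws, ss, registry hash, feature count) attached as an attribute.
#' @export
featurize <- function(segments, stream, registry = feature_registry()) {
  stopifnot(inherits(segments, "segment_set"), inherits(stream, "sensor_stream"),
            inherits(registry, "feature_registry"))
  spec <- attr(segments, "spec")
  ws <- spec$ws
  if (ws < 2L) stop("windows must span at least 2 samples")
  if (anyNA(stream$acc) || anyNA(stream$gyro)) {
    stop("featurize requires a gap-free (preprocessed) stream")
  }
  fnames <- feature_names(registry)
  nw <- nrow(segments)
  prov <- list(ws = ws, ss = spec$ss, sample_rate = attr(segments, "sample_rate"),
               registry_hash = fnv1a_hash(paste(fnames, collapse = ",")),
               n_features = length(fnames))
  if (nw == 0L) {
    empty <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = length(fnames),
                                  dimnames = list(NULL, fnames)))
    out <- cbind(data.frame(window_start = integer(0), window_end = integer(0),
                            label = character(0)), empty)
    return(structure(out, provenance = prov,
                     class = c("feature_table", "data.frame")))
  }
  chan <- list(
    ax = stream$acc[, 1], ay = stream$acc[, 2], az = stream$acc[, 3],
    gx = stream$gyro[, 1], gy = stream$gyro[, 2], gz = stream$gyro[, 3]
  )
  chan$acc_mag <- sqrt(chan$ax^2 + chan$ay^2 + chan$az^2)
  chan$gyro_mag <- sqrt(chan$gx^2 + chan$gy^2 + chan$gz^2)
  idx <- outer(seq_len(ws), segments$start, "+") # ws x nw sample indices
  blocks <- list()
  for (ch in registry$channels) {
    M <- matrix(chan[[ch]][idx], nrow = ws)
    for (dom in registry$domains) {
      D <- if (dom == "time") M else {
        Mc <- M - rep(colMeans(M), each = ws)
        Mod(stats::mvfft(Mc))[2:(floor(ws / 2) + 1), , drop = FALSE]
      }
      S <- stat_matrix(D)[registry$statistics, , drop = FALSE]
      rownames(S) <- paste(ch, dom, registry$statistics, sep = "_")
      blocks[[paste(ch, dom, sep = "_")]] <- S
    }
  }
  feat <- t(do.call(rbind, blocks))
  if (registry$include_orientation) {
    px <- matrix(stream$acc[, 1][idx], nrow = ws)
    py <- matrix(stream$acc[, 2][idx], nrow = ws)
    pz <- matrix(stream$acc[, 3][idx], nrow = ws)
    nz <- (px != 0) | (py != 0) | (pz != 0)
    deg <- 180 / pi
    pit <- atan2(px, sqrt(py^2 + pz^2)) * deg
    rol <- atan2(py, sqrt(px^2 + pz^2)) * deg
    pit[!nz] <- NA; rol[!nz] <- NA
    denom <- colSums(nz)
    pitch <- ifelse(denom > 0, colSums(pit, na.rm = TRUE) / denom, 0)
    roll <- ifelse(denom > 0, colSums(rol, na.rm = TRUE) / denom, 0)
    feat <- cbind(feat, pitch = pitch, roll = roll)
  }
  feat <- feat[, fnames, drop = FALSE]
  if (anyNA(feat)) stop("internal error: missing cells in feature table")
  out <- cbind(data.frame(window_start = segments$start,
                          window_end = segments$end,
                          label = segments$label,
                          stringsAsFactors = FALSE),
               as.data.frame(feat))
  rownames(out) <- NULL
  structure(out, provenance = prov, class = c("feature_table", "data.frame"))
}

# Feature-only numeric matrix of a feature table.
feature_matrix <- function(table) {
  cols <- setdiff(names(table), c("window_start", "window_end", "label"))
  as.matrix(as.data.frame(table)[, cols, drop = FALSE])
}
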