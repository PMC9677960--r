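# Preprocessing: interquartile-fence outlier censoring combined with the
# sensors' physical range limits, linear-interpolation gap filling, and
# min-max normalization to [0, 1].

#' Physical sensor ranges
#'
#' Hard measurement limits of the accelerometer (+/- 16 g = 156.96 m/s^2) and
#' the gyroscope (+/- 2000 deg/s); values beyond them are physically
#' impossible readings.
#'
#' @param acc_abs_max accelerometer absolute limit, m/s^2. Default 16 * 9.81.
#' @param gyro_abs_max gyroscope absolute limit, deg/s. Default 2000.
#' @export
physical_ranges <- function(acc_abs_max = 16 * 9.81, gyro_abs_max = 2000) {
  stopifnot(acc_abs_max > 0, gyro_abs_max > 0)
  structure(list(acc_abs_max = acc_abs_max, gyro_abs_max = gyro_abs_max),
            class = "physical_ranges")
}

#' Tukey fences of a channel
#'
#' Quartiles are computed by linear interpolation between closest order
#' statistics at position `(m - 1) * q` over the m finite values
#' (`stats::quantile` type 7); the fences are `Q1 - multiplier * IQR` and
#' `Q3 + multiplier * IQR`.
#'
#' @param x numeric vector; missing values are ignored.
#' @param multiplier fence multiplier, default 1.5 (Tukey's rule).
#' @return a `fences` object with `lower`, `upper`, `q1`, `q3`, `multiplier`.
#' @export
iqr_fences <- function(x, multiplier = 1.5) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) stop("iqr_fences needs at least 4 finite values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  structure(list(lower = q[1] - multiplier * iqr, upper = q[2] + multiplier * iqr,
                 q1 = q[1], q3 = q[2], multiplier = multiplier),
            class = "fences")
}

#' Censor outliers in a sensor stream
#'
#' A sample is an outlier when it lies outside its channel's interquartile
#' fences AND beyond the sensor's physical range (rule `"and"`, the default),
#' or when either condition holds (rule `"or"`). Flagged samples are
#' replaced by `NA`; all other samples pass through bit-identical. Fences are
#' computed per channel over the stream (i.e. per recording session).
#'
#' @param stream a `sensor_stream`.
#' @param ranges a [physical_ranges()] object.
#' @param multiplier fence multiplier, default 1.5.
#' @param rule `"and"` (fence AND range violation required) or `"or"` (either
#'   suffices), for sensitivity analysis.
#' @return the stream with outliers replaced by `NA`; the number of censored
#'   cells per channel is attached as attribute `"n_censored"`.
#' @export
censor_outliers <- function(stream, ranges = physical_ranges(),
                            multiplier = 1.5, rule = c("and", "or")) {
  stopifnot(inherits(stream, "sensor_stream"))
  rule <- match.arg(rule)
  censor_channel <- function(x, abs_max) {
    fin <- is.finite(x)
    flag_range <- fin & abs(x) > abs_max
    if (sum(fin) >= 4L) {
      f <- iqr_fences(x, multiplier)
      flag_fence <- fin & (x < f$lower | x > f$upper)
    } else {
      flag_fence <- rep(FALSE, length(x))
    }
    flag <- if (rule == "and") flag_fence & flag_range else flag_fence | flag_range
    x[flag] <- NA_real_
    list(x = x, n = sum(flag))
  }
  n_censored <- integer(6)
  names(n_censored) <- c("ax", "ay", "az", "gx", "gy", "gz")
  for (j in 1:3) {
    r <- censor_channel(stream$acc[, j], ranges$acc_abs_max)
    stream$acc[, j] <- r$x; n_censored[j] <- r$n
    r <- censor_channel(stream$gyro[, j], ranges$gyro_abs_max)
    stream$gyro[, j] <- r$x; n_censored[3 + j] <- r$n
  }
  attr(stream, "n_censored") <- n_censored
  stream
}

#' Fill missing values by linear interpolation
#'
#' Interior runs of missing values are linearly interpolated between the
#' flanking finite values; leading/trailing missing values are filled by
#' holding the nearest finite value (interpolation is undefined beyond the
#' first/last observation).
#'
#' @param x numeric vector with at least one finite value.
#' @return `x` with no missing values, same length.
#' @export
fill_missing <- function(x) {
  fin <- which(is.finite(x))
  if (length(fin) == 0L) stop("fill_missing: input has no finite values")
  if (length(fin) == length(x)) return(x)
  if (length(fin) == 1L) return(rep(x[fin], length(x)))
  stats::approx(fin, x[fin], xout = seq_along(x), method = "linear", rule = 2)$y
}

#' Min-max normalize sensor channels to [0, 1]
#'
#' Each channel is mapped by `(x - min) / (max - min)` within its group so
#' that animals of different size and sensor mounting become comparable before
#' pooling. With `grouping = "per-animal"` the min/max are taken over all
#' streams of the same animal; with `"global"` over all streams together.
#' Constant channels map to 0.
#'
#' @param streams a `sensor_stream` or a list of them, with no missing values
#'   (run [fill_missing()] first, see [preprocess_stream()]).
#' @param grouping `"per-animal"` (default) or `"global"`.
#' @return the same shape as the input (single stream or list), normalized.
#' @export
normalize_minmax <- function(streams, grouping = c("per-animal", "global")) {
  grouping <- match.arg(grouping)
  single <- inherits(streams, "sensor_stream")
  if (single) streams <- list(streams)
  stopifnot(all(vapply(streams, inherits, TRUE, "sensor_stream")))
  if (any(vapply(streams, function(s) anyNA(s$acc) || anyNA(s$gyro), TRUE))) {
    stop("normalize_minmax requires gap-free streams; run fill_missing first")
  }
  group_of <- if (grouping == "per-animal") {
    vapply(streams, function(s) as.character(s$animal_id), "")
  } else {
    rep("all", length(streams))
  }
  scale01 <- function(x, lo, hi) if (hi > lo) (x - lo) / (hi - lo) else x * 0
  for (g in unique(group_of)) {
    idx <- which(group_of == g)
    for (field in c("acc", "gyro")) {
      for (j in 1:3) {
        vals <- unlist(lapply(streams[idx], function(s) s[[field]][, j]))
        lo <- min(vals); hi <- max(vals)
        for (i in idx) {
          streams[[i]][[field]][, j] <- scale01(streams[[i]][[field]][, j], lo, hi)
        }
      }
    }
  }
  if (single) streams[[1]] else streams
}

#' Preprocess a sensor stream
#'
#' Runs the cleaning chain: outlier censoring, gap filling and (optionally)
#' min-max normalization, preserving the sample count exactly.
#'
#' @inheritParams censor_outliers
#' @param normalize normalize channels to `[0, 1]` after filling, default TRUE.
#' @return a cleaned `sensor_stream`.
#' @export
preprocess_stream <- function(stream, ranges = physical_ranges(),
                              multiplier = 1.5, rule = c("and", "or"),
                              normalize = TRUE) {
  rule <- match.arg(rule)
  stream <- censor_outliers(stream, ranges, multiplier, rule)
  for (field in c("acc", "gyro")) {
    for (j in 1:3) stream[[field]][, j] <- fill_missing(stream[[field]][, j])
  }
  if (normalize) stream <- normalize_minmax(stream) else stream
}
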