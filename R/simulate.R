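# Labeled synthetic inertial streams. The generator emulates the structural
# properties of body-mounted pig recordings that matter for windowing
# experiments -- 10 Hz, two 3-axis sensors, a heavily imbalanced four-class
# ethogram, and the long/short bout-duration contrast (eating and lying last
# minutes; walking and standing seconds) -- not biomechanical realism. Each
# behavior is a gravity orientation plus a sinusoidal oscillation plus noise.

# Per-class signal models. Orientations are unit vectors (multiplied by g) --
# small tilts around vertical; the movement signature is a three-axis
# oscillation (relative axis amplitudes 1/0.8/0.5 on acceleration and
# 1/0.7/0.4 on the gyro, with fixed phase offsets) whose *frequency* is the
# primary class signature. Keeping oscillation magnitudes comparable across
# classes makes each channel's interquartile fences robustly wider than any
# class's (bounded) extremes, whatever class mix a particular stream realizes,
# so artifact-free synthetic data never trips the outlier censor.
.default_class_models <- function() {
  list(
    eating = list(orientation = c(0.1045, 0, 0.9945), freq = 1.2,
                  acc_amp = 1.4, gyro_amp = 25),
    lying = list(orientation = c(0, 0.0349, 0.9994), freq = 0.25,
                 acc_amp = 1.2, gyro_amp = 20),
    walking = list(orientation = c(0, 0, 1), freq = 2.5,
                   acc_amp = 1.5, gyro_amp = 28),
    standing = list(orientation = c(0, 0, 1), freq = 0.6,
                    acc_amp = 1.25, gyro_amp = 22),
    playing = list(orientation = c(0.0872, 0.0872, 0.99238), freq = 1.8,
                   acc_amp = 1.4, gyro_amp = 26),
    drinking = list(orientation = c(0.1392, 0, 0.9903), freq = 1.0,
                    acc_amp = 1.3, gyro_amp = 24),
    sitting = list(orientation = c(-0.1392, 0, 0.9903), freq = 0.4,
                   acc_amp = 1.2, gyro_amp = 21),
    unknown = list(orientation = c(0, 0, 1), freq = 1.5,
                   acc_amp = 1.3, gyro_amp = 23)
  )
}

.acc_axis_amp <- c(1, 0.8, 0.7)
.gyro_axis_amp <- c(1, 0.7, 0.55)
.axis_phase <- c(0, pi / 2, pi / 4)

#' Simulator configuration
#'
#' Defaults encode the study conditions: 10 Hz sampling; class time shares
#' proportional to the recorded ethogram composition (eating 49.40, lying
#' 33.33, walking 7.87, standing 1.76); log-normal bout durations with
#' long-bout majors (eating median 120 s, lying 300 s) and short-bout minors
#' (walking 8 s, standing 6 s). Acceleration noise is Gaussian truncated at
#' `noise_bound_sd` standard deviations, mimicking the bounded dynamic range
#' of a real MEMS sensor and keeping artifact-free synthetic streams inside
#' their interquartile fences so preprocessing tests have exact ground truth.
#'
#' @param sample_rate samples per second, default 10.
#' @param duration_s total stream duration in seconds.
#' @param class_mix named nonnegative weights over behaviors; normalized to
#'   time shares. Default the four analysis classes in ethogram proportion.
#' @param bout_duration named list of `c(median_s, sigma)` log-normal bout
#'   parameters per class.
#' @param class_models named list of per-class signal models (`orientation`
#'   unit vector, oscillation `freq` in Hz, `acc_amp` in m/s^2, `gyro_amp` in
#'   deg/s); defaults provided for all eight vocabulary behaviors. Classes are
#'   distinguished chiefly by oscillation frequency and small orientation
#'   tilts, so the value of a window depends on how many cycles it spans.
#' @param noise_sd accelerometer noise standard deviation, m/s^2. Default 0.3.
#' @param gyro_noise_sd gyroscope noise standard deviation, deg/s. Default 8.
#' @param noise_bound_sd truncation bound for the noise, in standard
#'   deviations. Default 2.5.
#' @param outlier_rate,missing_rate artifact rates in `[0, 1]` for
#'   [inject_artifacts()], default 0.
#' @param seed default seed used by [simulate_stream()] when none is given.
#' @return a `sim_config`.
#' @export
sim_config <- function(sample_rate = 10, duration_s = 600,
                       class_mix = c(eating = 49.40, lying = 33.33,
                                     walking = 7.87, standing = 1.76),
                       bout_duration = list(eating = c(120, 0.5),
                                            lying = c(300, 0.5),
                                            walking = c(8, 0.4),
                                            standing = c(6, 0.4),
                                            playing = c(10, 0.4),
                                            drinking = c(15, 0.4),
                                            sitting = c(12, 0.4),
                                            unknown = c(30, 0.5)),
                       class_models = .default_class_models(),
                       noise_sd = 0.3, gyro_noise_sd = 6,
                       noise_bound_sd = 2.5,
                       outlier_rate = 0, missing_rate = 0, seed = 1L) {
  stopifnot(sample_rate > 0, duration_s > 0,
            all(class_mix >= 0), sum(class_mix) > 0,
            outlier_rate >= 0, outlier_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            noise_sd >= 0, gyro_noise_sd >= 0, noise_bound_sd > 0)
  classes <- names(class_mix)
  if (is.null(classes) || !all(classes %in% behavior_vocabulary())) {
    stop("class_mix must be named with behaviors from the vocabulary")
  }
  missing_spec <- setdiff(classes, names(bout_duration))
  if (length(missing_spec)) {
    stop(sprintf("bout_duration missing for: %s", paste(missing_spec, collapse = ", ")))
  }
  if (any(vapply(bout_duration[classes], function(b) b[1] <= 0, TRUE))) {
    stop("bout duration medians must be positive")
  }
  structure(list(sample_rate = sample_rate, duration_s = duration_s,
                 class_mix = class_mix / sum(class_mix),
                 bout_duration = bout_duration, class_models = class_models,
                 noise_sd = noise_sd, gyro_noise_sd = gyro_noise_sd,
                 noise_bound_sd = noise_bound_sd,
                 outlier_rate = outlier_rate, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Gaussian noise truncated at +/- bound*sd by rejection-free inverse CDF.
.rnorm_trunc <- function(n, sd, bound) {
  if (sd == 0 || n == 0) return(numeric(n))
  p <- stats::pnorm(bound)
  stats::qnorm(stats::runif(n, 1 - p, p)) * sd
}

#' Simulate a labeled inertial stream
#'
#' Draws behavior bouts with log-normal lengths; the next bout's label is
#' sampled proportionally to each class's current time-share deficit
#' (target share times elapsed time minus realized time), a negative-feedback
#' scheme that keeps realized shares concentrated around the configured mix
#' while leaving bout order random. Within each bout the acceleration is
#' gravity along the class orientation plus the class's three-axis oscillation
#' plus truncated Gaussian noise; the gyro carries the matching rotational
#' oscillation plus noise. Bit-identical under the same seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; defaults to the config's seed.
#' @return list with elements `stream` (a `sensor_stream`) and `track`
#'   (a `label_track` covering `[0, duration_s)` exactly).
#' @export
simulate_stream <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  rate <- config$sample_rate
  n <- as.integer(round(config$duration_s * rate))
  if (n < 1L) stop("duration too short for a single sample")
  classes <- names(config$class_mix)
  target <- config$class_mix
  with_seed(derive_seed(seed, "sim"), {
    # --- bout sequence covering the duration (deficit-weighted labels)
    starts <- numeric(0); ends <- numeric(0); labs <- character(0)
    realized <- stats::setNames(numeric(length(classes)), classes)
    t <- 0
    while (t < config$duration_s) {
      deficit <- pmax(target * t - realized, 0)
      w <- if (sum(deficit) > 0) deficit else target
      cl <- sample(classes, 1, prob = w)
      b <- config$bout_duration[[cl]]
      len <- stats::rlnorm(1, meanlog = log(b[1]), sdlog = b[2])
      len <- max(len, 2 / rate) # a bout spans at least two samples
      end <- min(t + len, config$duration_s)
      realized[cl] <- realized[cl] + (end - t)
      if (length(labs) && labs[length(labs)] == cl) {
        ends[length(ends)] <- end
      } else {
        starts <- c(starts, t); ends <- c(ends, end)
        labs <- c(labs, cl)
      }
      t <- end
    }
    track <- label_track(starts, ends, labs)
    # --- per-sample signal
    times <- (seq_len(n) - 1) / rate
    acc <- matrix(0, n, 3); gyro <- matrix(0, n, 3)
    bout_of <- findInterval(times, track$start_s)
    for (b in seq_len(nrow(track))) {
      idx <- which(bout_of == b)
      if (!length(idx)) next
      m <- config$class_models[[track$label[b]]]
      if (is.null(m)) stop(sprintf("no signal model for class '%s'", track$label[b]))
      tt <- times[idx]
      phase <- stats::runif(1, 0, 2 * pi)
      ang <- 2 * pi * m$freq * tt + phase
      for (j in 1:3) {
        acc[idx, j] <- 9.81 * m$orientation[j] +
          m$acc_amp * .acc_axis_amp[j] * sin(ang + .axis_phase[j])
        gyro[idx, j] <- m$gyro_amp * .gyro_axis_amp[j] * cos(ang + .axis_phase[j])
      }
    }
    acc <- acc + matrix(.rnorm_trunc(3 * n, config$noise_sd,
                                     config$noise_bound_sd), n, 3)
    gyro <- gyro + matrix(.rnorm_trunc(3 * n, config$gyro_noise_sd,
                                       config$noise_bound_sd), n, 3)
    stream <- sensor_stream(acc, gyro, timestamps = times,
                            counters = (seq_len(n) - 1) %% 2^16,
                            sample_rate = rate,
                            animal_id = "sim1", session_id = "sim_session1")
    list(stream = stream, track = track)
  })
}

#' Inject outlier and missing-value artifacts
#'
#' Replaces randomly chosen sample/channel cells with range-violating spikes
#' (beyond 16 g for acceleration, beyond 2000 deg/s for the gyro) or missing
#' markers, emulating sensor failures and transmission errors. The injection
#' log is attached as attribute `"injection_log"` so tests can verify that
#' preprocessing recovers exactly the injected cells.
#'
#' @param stream a `sensor_stream`.
#' @param outlier_rate fraction of samples receiving a range-violating spike.
#' @param missing_rate fraction of samples receiving a missing marker.
#' @param seed integer seed.
#' @param ranges [physical_ranges()] the spikes must violate.
#' @return the modified stream; `attr(, "injection_log")` is a list of two
#'   data.frames (`outliers`, `missing`) with columns `index` (sample row),
#'   `field` ("acc"/"gyro") and `axis` (1-3).
#' @export
inject_artifacts <- function(stream, outlier_rate = 0.001,
                             missing_rate = 0.001, seed = 1L,
                             ranges = physical_ranges()) {
  stopifnot(inherits(stream, "sensor_stream"),
            outlier_rate >= 0, outlier_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  n <- n_samples(stream)
  n_out <- round(outlier_rate * n)
  n_mis <- round(missing_rate * n)
  log <- list(
    outliers = data.frame(index = integer(0), field = character(0), axis = integer(0)),
    missing = data.frame(index = integer(0), field = character(0), axis = integer(0))
  )
  if (n_out + n_mis > 0) {
    if (n_out + n_mis > n) stop("artifact rates too high for stream length")
    picks <- with_seed(derive_seed(seed, "artifacts"), {
      rows <- sample(n, n_out + n_mis)
      list(rows = rows,
           field = sample(c("acc", "gyro"), n_out + n_mis, replace = TRUE),
           axis = sample(3L, n_out + n_mis, replace = TRUE),
           sign = sample(c(-1, 1), n_out + n_mis, replace = TRUE),
           mag = stats::runif(n_out + n_mis, 1.2, 2.0))
    })
    for (i in seq_len(n_out + n_mis)) {
      f <- picks$field[i]; ax <- picks$axis[i]; r <- picks$rows[i]
      if (i <= n_out) {
        lim <- if (f == "acc") ranges$acc_abs_max else ranges$gyro_abs_max
        stream[[f]][r, ax] <- picks$sign[i] * picks$mag[i] * lim
        log$outliers <- rbind(log$outliers,
                              data.frame(index = r, field = f, axis = ax))
      } else {
        stream[[f]][r, ax] <- NA_real_
        log$missing <- rbind(log$missing,
                             data.frame(index = r, field = f, axis = ax))
      }
    }
  }
  attr(stream, "injection_log") <- log
  stream
}
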