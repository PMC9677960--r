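# Delimited-text I/O for sensor logs, label tracks and feature tables, plus
# stream validity checking from the timestamp/counter side channels.
#
# File dialect: comma-separated with a header row, "." decimal point, missing
# cells encoded as empty fields. Lines starting with "#" carry provenance and
# are skipped on read.

.sensor_cols <- c("ts", "counter", "ax", "ay", "az", "gx", "gy", "gz")

.read_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = ""),
    error = function(e) stop(sprintf("cannot read '%s': %s", path, conditionMessage(e)))
  )
  df
}

.as_num <- function(v) suppressWarnings(as.numeric(as.character(v)))

# Write a data.frame as CSV, optionally preceded by "#" provenance lines.
# Written atomically (temp file + rename) so failures never leave partial output.
.write_csv <- function(df, path, provenance = NULL) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wt")
  ok <- FALSE
  tryCatch({
    if (!is.null(provenance)) {
      writeLines(paste0("# ", names(provenance), ": ",
                        vapply(provenance, as.character, "")), con)
    }
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok) unlink(tmp)
  })
  file.rename(tmp, path)
  invisible(path)
}

#' Read a sensor log
#'
#' Reads a delimited sensor log (one row per sample) into a [sensor_stream()].
#' Cells that fail numeric parsing become missing values; row order is
#' preserved.
#'
#' @param path file path.
#' @param schema named character vector mapping the canonical column names
#'   `ts, counter, ax, ay, az, gx, gy, gz` to the file's column names.
#'   Defaults to the identity mapping.
#' @param sample_rate samples per second, default 10.
#' @return a `sensor_stream`.
#' @export
read_sensor_stream <- function(path, schema = NULL, sample_rate = 10) {
  if (is.null(schema)) schema <- stats::setNames(.sensor_cols, .sensor_cols)
  missing_keys <- setdiff(.sensor_cols, names(schema))
  if (length(missing_keys)) {
    stop(sprintf("schema must map columns: %s", paste(missing_keys, collapse = ", ")))
  }
  df <- .read_csv(path)
  if (nrow(df) == 0L) stop(sprintf("empty sensor log: %s", path))
  absent <- setdiff(unname(schema[.sensor_cols]), names(df))
  if (length(absent)) {
    stop(sprintf("missing required column(s) in %s: %s",
                 path, paste(absent, collapse = ", ")))
  }
  g <- function(key) .as_num(df[[schema[[key]]]])
  acc <- cbind(g("ax"), g("ay"), g("az"))
  gyro <- cbind(g("gx"), g("gy"), g("gz"))
  sensor_stream(
    acc = acc, gyro = gyro, timestamps = g("ts"), counters = g("counter"),
    sample_rate = sample_rate,
    animal_id = if ("animal_id" %in% names(df)) df$animal_id[1] else "animal1",
    session_id = if ("session_id" %in% names(df)) df$session_id[1] else "session1"
  )
}

#' Write a sensor stream as a CSV log
#'
#' @param stream a `sensor_stream`.
#' @param path output file path.
#' @param provenance optional named list written as `#`-prefixed header lines.
#' @return the path, invisibly.
#' @export
write_sensor_stream <- function(stream, path, provenance = NULL) {
  stopifnot(inherits(stream, "sensor_stream"))
  df <- data.frame(
    ts = stream$timestamps, counter = stream$counters,
    ax = stream$acc[, 1], ay = stream$acc[, 2], az = stream$acc[, 3],
    gx = stream$gyro[, 1], gy = stream$gyro[, 2], gz = stream$gyro[, 3],
    animal_id = stream$animal_id, session_id = stream$session_id
  )
  .write_csv(df, path, provenance)
}

#' Read a label track
#'
#' Expects columns `start_s, end_s, label`; intervals are sorted and checked
#' for overlap and vocabulary membership.
#'
#' @param path file path.
#' @return a `label_track`.
#' @export
read_label_track <- function(path) {
  df <- .read_csv(path)
  need <- c("start_s", "end_s", "label")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop(sprintf("missing required column(s) in %s: %s",
                 path, paste(absent, collapse = ", ")))
  }
  label_track(df$start_s, df$end_s, df$label)
}

#' Write a label track
#' @param track a `label_track`.
#' @param path output file path.
#' @param provenance optional named list written as header comments.
#' @export
write_label_track <- function(track, path, provenance = NULL) {
  stopifnot(inherits(track, "label_track"))
  .write_csv(as.data.frame(track), path, provenance)
}

#' Read a feature table
#'
#' Expects columns `window_start, window_end, label` followed by one column
#' per feature.
#'
#' @param path file path.
#' @return a `feature_table` data.frame.
#' @export
read_feature_table <- function(path) {
  df <- .read_csv(path)
  need <- c("window_start", "window_end", "label")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop(sprintf("missing required column(s) in %s: %s",
                 path, paste(absent, collapse = ", ")))
  }
  df$label <- as.character(df$label)
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Write a feature table
#' @param table a `feature_table`.
#' @param path output file path.
#' @param provenance optional named list written as header comments; defaults
#'   to the table's provenance attribute.
#' @export
write_feature_table <- function(table, path, provenance = NULL) {
  if (is.null(provenance)) {
    prov <- attr(table, "provenance")
    if (!is.null(prov)) provenance <- prov[vapply(prov, length, 1L) == 1L]
  }
  .write_csv(as.data.frame(table), path, provenance)
}

#' Check stream validity from counters and timestamps
#'
#' The logger stamps every sample with a timestamp and a rolling counter;
#' dropped or duplicated records show up as counter increments different from
#' one (modulo the counter width) and as timestamp regressions.
#'
#' @param stream a `sensor_stream` with at least 2 samples.
#' @param counter_width counter width in bits; increments are computed modulo
#'   `2^counter_width` so hardware wraparound is not flagged as a gap.
#'   Default 16.
#' @return a `validity_report` with counts and 1-based locations (index of the
#'   first sample of each offending adjacent pair).
#' @export
validate_stream <- function(stream, counter_width = 16) {
  stopifnot(inherits(stream, "sensor_stream"))
  n <- n_samples(stream)
  if (n < 2L) stop("validate_stream needs at least 2 samples")
  modulus <- 2^counter_width
  inc <- diff(stream$counters) %% modulus
  gap_locations <- which(is.na(inc) | inc != 1)
  duplicate_locations <- which(!is.na(inc) & inc == 0)
  dts <- diff(stream$timestamps)
  regression_locations <- which(!is.na(dts) & dts < 0)
  structure(
    list(n_counter_gaps = length(gap_locations),
         n_timestamp_regressions = length(regression_locations),
         n_duplicate_counters = length(duplicate_locations),
         gap_locations = gap_locations,
         regression_locations = regression_locations,
         duplicate_locations = duplicate_locations,
         counter_width = counter_width),
    class = "validity_report"
  )
}

#' @export
print.validity_report <- function(x, ...) {
  cat("<validity_report>\n")
  cat(sprintf("  counter gaps:          %d\n", x$n_counter_gaps))
  cat(sprintf("  duplicate counters:    %d\n", x$n_duplicate_counters))
  cat(sprintf("  timestamp regressions: %d\n", x$n_timestamp_regressions))
  invisible(x)
}
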