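#' @name recording-io
#' @title Read and write synchronized six-sensor gyroscope recordings
#'
#' @description
#' A recording holds the synchronized triaxial gyroscope streams of the six
#' sensors worn on the wrists, thumbs and index fingers of both hands, in
#' degrees per second, plus optional triaxial accelerometer streams in g.
#' On disk a recording is a wide CSV with one row per synchronized sample:
#' header `t_s,LW_gx,LW_gy,LW_gz,LT_gx,...,RI_gz` (optionally `*_ax,*_ay,
#' *_az` accelerometer columns), decimal point, comma separator, UTF-8.
#'
#' Timestamps must be strictly increasing and uniform at the declared sample
#' rate (relative tolerance 1e-6 on each sampling interval), which catches
#' corrupt or truncated files without forbidding resampled data.
NULL

.gyro_axes  <- c("gx", "gy", "gz")
.accel_axes <- c("ax", "ay", "az")

.gyro_columns <- function() {
  as.vector(t(outer(imu_placements(), .gyro_axes, paste, sep = "_")))
}
.accel_columns <- function() {
  as.vector(t(outer(imu_placements(), .accel_axes, paste, sep = "_")))
}

#' Construct a recording object
#'
#' @param participant_id Single string identifying the participant.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param data Data frame with column `t_s` (seconds) and the 18 gyroscope
#'   columns `LW_gx ... RI_gz` in deg/s; optional accelerometer columns.
#' @return An object of class `imu_recording`.
#' @export
new_recording <- function(participant_id, sample_rate_hz, data) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("sample_rate_hz must be a single positive number", call. = FALSE)
  }
  required <- c("t_s", .gyro_columns())
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop("recording is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- intersect(c(required, .accel_columns()), names(data))
  for (cl in num_cols) {
    v <- data[[cl]]
    if (!is.numeric(v)) {
      stop("column ", cl, " is not numeric", call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("column ", cl, " contains NA or non-finite values", call. = FALSE)
    }
  }
  t <- data$t_s
  n <- length(t)
  if (n >= 2L) {
    if (any(diff(t) <= 0)) {
      stop("timestamps are not strictly increasing", call. = FALSE)
    }
    dt <- 1 / sample_rate_hz
    dev <- abs(t - (t[1L] + (seq_len(n) - 1L) * dt))
    if (max(dev) > 1e-6 * dt * max(1, n)) {
      stop("timestamps deviate from the declared sample rate of ",
           sample_rate_hz, " Hz", call. = FALSE)
    }
  }
  structure(list(participant_id = participant_id,
                 sample_rate_hz = sample_rate_hz,
                 data = data[, num_cols, drop = FALSE]),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  dur <- if (nrow(x$data) > 0L) nrow(x$data) / x$sample_rate_hz else 0
  cat(sprintf(
    "<imu_recording> participant %s: %d samples @ %g Hz (%.2f s), %s\n",
    x$participant_id, nrow(x$data), x$sample_rate_hz, dur,
    if (any(.accel_columns() %in% names(x$data)))
      "gyro + accel" else "gyro only"))
  invisible(x)
}

#' @rdname recording-io
#' @param path Path to a wide-format recording CSV.
#' @param sample_rate_hz Declared sampling rate in Hz; if `NULL`, inferred
#'   from the median timestamp interval.
#' @param participant_id Participant identifier to attach; defaults to the
#'   file name without extension.
#' @return `read_recording()` returns a validated `imu_recording`.
#' @export
read_recording <- function(path, sample_rate_hz = NULL,
                           participant_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("t_s", .gyro_columns())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("recording CSV ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.null(sample_rate_hz)) {
    if (nrow(df) < 2L) {
      stop("cannot infer sample rate from fewer than 2 samples; ",
           "pass sample_rate_hz", call. = FALSE)
    }
    sample_rate_hz <- 1 / stats::median(diff(df$t_s))
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
    participant_id <- sub("^recording_", "", participant_id)
  }
  new_recording(participant_id, sample_rate_hz, df)
}

#' @rdname recording-io
#' @param recording An `imu_recording`.
#' @param digits Number of decimal places used for the signal columns
#'   (timestamps always get 9). Values already rounded to `digits` decimals
#'   round-trip bit-identically through `read_recording()`.
#' @export
write_recording <- function(recording, path, digits = 6L) {
  stopifnot(inherits(recording, "imu_recording"))
  df <- recording$data
  out <- df
  out$t_s <- formatC(df$t_s, format = "f", digits = 9L)
  for (cl in setdiff(names(df), "t_s")) {
    out[[cl]] <- formatC(df[[cl]], format = "f", digits = digits)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Duration of a recording in seconds
#' @param recording An `imu_recording`.
#' @return Duration `n / sample_rate_hz` in seconds.
#' @export
recording_duration <- function(recording) {
  nrow(recording$data) / recording$sample_rate_hz
}

#' Read and write activity-segment annotations
#'
#' A segment annotates one repetition of one activity: who performed it,
#' what the activity was, the repetition index, the half-open time window
#' `[t_start_s, t_end_s)` within the participant's recording, the
#' experimenter-assigned true category and, where known, the performing
#' hand. Repetitions are capped at `max_duration_s` (default 25 s).
#'
#' On disk: CSV with header
#' `participant_id,activity,repetition,t_start_s,t_end_s,true_category,performed_hand`.
#'
#' @param path Path to the segments CSV.
#' @param max_duration_s Maximum allowed repetition duration in seconds.
#' @return Data frame of validated segments sorted by
#'   (participant_id, activity, repetition).
#' @export
read_segments <- function(path, max_duration_s = 25) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(participant_id = "character"))
  required <- c("participant_id", "activity", "repetition",
                "t_start_s", "t_end_s", "true_category")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("segments CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"performed_hand" %in% names(df)) df$performed_hand <- "unknown"
  validate_segments(df, max_duration_s = max_duration_s)
}

#' @rdname read_segments
#' @param segments Data frame of segments.
#' @export
write_segments <- function(segments, path) {
  utils::write.csv(segments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_segments
#' @export
validate_segments <- function(segments, max_duration_s = 25) {
  .assert_category(segments$true_category)
  if (any(!segments$repetition == as.integer(segments$repetition)) ||
      any(segments$repetition < 1L)) {
    stop("repetition must be a positive integer", call. = FALSE)
  }
  bad_win <- segments$t_end_s <= segments$t_start_s
  if (any(bad_win)) {
    stop("segment window with t_end_s <= t_start_s for ",
         paste(segments$participant_id[bad_win], segments$activity[bad_win],
               sep = "/", collapse = ", "), call. = FALSE)
  }
  too_long <- (segments$t_end_s - segments$t_start_s) > max_duration_s
  if (any(too_long)) {
    stop("segment longer than the ", max_duration_s, " s maximum: ",
         paste(segments$participant_id[too_long], segments$activity[too_long],
               sep = "/", collapse = ", "), call. = FALSE)
  }
  bad_hand <- !segments$performed_hand %in% c("left", "right", "both",
                                              "unknown")
  if (any(bad_hand)) {
    stop("performed_hand must be left/right/both/unknown", call. = FALSE)
  }
  ord <- order(segments$participant_id, segments$activity,
               segments$repetition)
  out <- segments[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
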