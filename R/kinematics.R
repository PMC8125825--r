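#' Euclidean norm of a triaxial gyroscope series
#'
#' Combines the x, y and z angular-velocity components into the scalar
#' angular speed `sqrt(x^2 + y^2 + z^2)` per sample. No filtering is
#' applied to the raw signal.
#'
#' @param gyro_xyz A 3-column numeric matrix or data frame (columns x, y, z
#'   in deg/s), or a list of three equal-length numeric vectors.
#' @return Nonnegative numeric vector of per-sample angular speeds (deg/s),
#'   same length as the input series.
#' @export
#' @examples
#' norm_series(cbind(3, 4, 0))  # 5
norm_series <- function(gyro_xyz) {
  if (is.list(gyro_xyz) && !is.data.frame(gyro_xyz)) {
    lens <- lengths(gyro_xyz)
    if (length(gyro_xyz) != 3L || length(unique(lens)) != 1L) {
      stop("gyro_xyz must have exactly 3 equal-length components",
           call. = FALSE)
    }
    gyro_xyz <- do.call(cbind, gyro_xyz)
  }
  m <- as.matrix(gyro_xyz)
  if (ncol(m) != 3L) {
    stop("gyro_xyz must have exactly 3 columns (x, y, z)", call. = FALSE)
  }
  if (!is.numeric(m)) stop("gyro_xyz must be numeric", call. = FALSE)
  sqrt(rowSums(m * m))
}

# internal: row indices of a recording inside the half-open window
# [t_start, t_end) of a segment
.segment_rows <- function(recording, segment) {
  t <- recording$data$t_s
  which(t >= segment$t_start_s & t < segment$t_end_s)
}

#' Mean angular speeds of a repetition at sensor, fingers, wrist and hand level
#'
#' For one annotated repetition, computes the time-average of the per-sample
#' angular-speed norm of each of the six sensors over the half-open window
#' `[t_start_s, t_end_s)`, then aggregates per hand: the hand signal is the
#' arithmetic mean of that hand's three sensors (wrist, thumb, index), the
#' fingers signal the mean of thumb and index, and the wrist level the wrist
#' sensor alone. The mean of a sensor over the segment is the average of its
#' norm series (not the norm of the averaged vector, which would cancel
#' oscillatory motion); with synchronized uniform sampling, averaging the
#' per-sensor means equals averaging the aggregated norm series.
#'
#' @param recording An `imu_recording` containing the segment window.
#' @param segment A one-row data frame (or list) with `t_start_s` and
#'   `t_end_s` in seconds.
#' @return An object of class `mean_speeds`: list with elements `sensor`
#'   (named length-6 vector, deg/s), `hand`, `fingers`, `wrist` (each a
#'   named length-2 vector, `left`/`right`), and `n_samples`.
#' @export
mean_speeds <- function(recording, segment) {
  stopifnot(inherits(recording, "imu_recording"))
  if (segment$t_start_s < recording$data$t_s[1L] - 1e-9 ||
      segment$t_end_s > recording_duration(recording) +
        recording$data$t_s[1L] + 1e-9) {
    stop("segment window [", segment$t_start_s, ", ", segment$t_end_s,
         ") extends beyond the recording", call. = FALSE)
  }
  rows <- .segment_rows(recording, segment)
  if (length(rows) == 0L) {
    stop("empty segment: no samples in [", segment$t_start_s, ", ",
         segment$t_end_s, ")", call. = FALSE)
  }
  sensor <- vapply(imu_placements(), function(p) {
    cols <- paste(p, .gyro_axes, sep = "_")
    mean(norm_series(recording$data[rows, cols]))
  }, numeric(1L))
  agg <- function(places) {
    vapply(c(left = "left", right = "right"), function(h) {
      mean(sensor[places(h)])
    }, numeric(1L))
  }
  structure(list(sensor = sensor,
                 hand = agg(.hand_placements),
                 fingers = agg(.finger_placements),
                 wrist = agg(.wrist_placement),
                 n_samples = length(rows)),
            class = "mean_speeds")
}

#' @export
print.mean_speeds <- function(x, ...) {
  cat("<mean_speeds> (deg/s over", x$n_samples, "samples)\n")
  print(round(x$sensor, 3))
  cat(sprintf("hand    L %.3f  R %.3f\n", x$hand["left"], x$hand["right"]))
  cat(sprintf("fingers L %.3f  R %.3f\n", x$fingers["left"],
              x$fingers["right"]))
  cat(sprintf("wrist   L %.3f  R %.3f\n", x$wrist["left"],
              x$wrist["right"]))
  invisible(x)
}
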