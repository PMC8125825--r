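#' Fit linear calibration coefficients from reference readings
#'
#' Each sensor axis is modelled as a linear transducer:
#' `raw = value / gain + offset`, where `raw` is the sensor's raw count,
#' `value` the physical reference (deg/s for gyroscopes, g for
#' accelerometers), `gain` the physical unit per raw count and `offset` the
#' raw count at zero input. Coefficients are estimated per axis by ordinary
#' least squares over reference/raw pairs, e.g. the 0 g, +1 g and -1 g
#' orientations for an accelerometer axis, or a set of reference angular
#' speeds from a rate table for a gyroscope axis.
#'
#' @param readings Data frame with columns `sensor`, `axis`, `reference`
#'   (physical units) and `raw` (raw counts), with at least two distinct
#'   reference values per (sensor, axis).
#' @return Data frame with columns `sensor`, `axis`, `gain`, `offset`
#'   (one row per calibrated axis).
#' @export
#' @examples
#' readings <- data.frame(sensor = "LW", axis = "gx",
#'                        reference = c(-1, 0, 1),
#'                        raw = c(-1000, 0, 1000))
#' fit_calibration(readings)  # gain 0.001, offset 0
fit_calibration <- function(readings) {
  required <- c("sensor", "axis", "reference", "raw")
  missing <- setdiff(required, names(readings))
  if (length(missing) > 0L) {
    stop("readings missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(readings,
                  list(readings$sensor, readings$axis), drop = TRUE)
  rows <- lapply(groups, function(g) {
    if (length(unique(g$reference)) < 2L) {
      stop("singular calibration fit for ", g$sensor[1L], "/", g$axis[1L],
           ": need >= 2 distinct reference values", call. = FALSE)
    }
    fit <- stats::lm(raw ~ reference, data = g)
    slope <- unname(stats::coef(fit)[2L])
    if (!is.finite(slope) || slope == 0) {
      stop("singular calibration fit for ", g$sensor[1L], "/", g$axis[1L],
           ": raw counts do not vary with the reference", call. = FALSE)
    }
    data.frame(sensor = g$sensor[1L], axis = g$axis[1L],
               gain = 1 / slope, offset = unname(stats::coef(fit)[1L]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sensor, out$axis), , drop = FALSE]
}

#' Apply calibration coefficients to a raw series
#'
#' Converts raw counts to physical units with
#' `value = (raw - offset) * gain`, elementwise.
#'
#' @param raw Numeric vector of raw counts.
#' @param coeffs Either a coefficient table from [fit_calibration()]
#'   (requires `sensor` and `axis`) or a list/row with elements `gain` and
#'   `offset`.
#' @param sensor,axis Placement and axis to look up when `coeffs` is a
#'   table.
#' @return Numeric vector in physical units, same length as `raw`.
#' @export
apply_calibration <- function(raw, coeffs, sensor = NULL, axis = NULL) {
  if (is.data.frame(coeffs)) {
    if (is.null(sensor) || is.null(axis)) {
      stop("sensor and axis are required with a coefficient table",
           call. = FALSE)
    }
    hit <- coeffs$sensor == sensor & coeffs$axis == axis
    if (sum(hit) != 1L) {
      stop("no calibration coefficients for ", sensor, "/", axis,
           call. = FALSE)
    }
    gain <- coeffs$gain[hit]
    offset <- coeffs$offset[hit]
  } else {
    gain <- coeffs$gain
    offset <- coeffs$offset
  }
  if (is.null(gain) || is.null(offset) || !is.finite(gain) || gain == 0) {
    stop("invalid calibration coefficients (gain must be nonzero)",
         call. = FALSE)
  }
  (raw - offset) * gain
}

#' Read or write a calibration coefficient table
#'
#' CSV dialect: header `sensor,axis,gain,offset`, one row per axis.
#'
#' @param path Path to the calibration CSV.
#' @return `read_calibration()` returns the coefficient data frame.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("sensor", "axis", "gain", "offset")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("calibration CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$gain)) || any(df$gain == 0)) {
    stop("calibration gains must be finite and nonzero", call. = FALSE)
  }
  df
}

#' @rdname read_calibration
#' @param coeffs Coefficient table as returned by [fit_calibration()].
#' @export
write_calibration <- function(coeffs, path) {
  utils::write.csv(coeffs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
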