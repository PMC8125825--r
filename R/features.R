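#' Hands ratio (HR)
#'
#' Ratio of the mean angular speed of the most active hand to that of the
#' least active hand. Values close to 1 indicate both hands equally active;
#' large values indicate a unimanual performance or a near-still stabilizing
#' hand. When the least active hand's mean speed is below `eps`, `Inf` is
#' returned as a sentinel, interpreted downstream as unimanual.
#'
#' @param mean_hand_a,mean_hand_b Nonnegative mean hand-signal speeds
#'   (deg/s), in either order.
#' @param eps Zero-denominator guard in deg/s.
#' @return HR, a dimensionless value `>= 1` (possibly `Inf`).
#' @export
#' @examples
#' hands_ratio(10, 2)  # 5
hands_ratio <- function(mean_hand_a, mean_hand_b, eps = 1e-9) {
  if (mean_hand_a < 0 || mean_hand_b < 0) {
    stop("hand mean speeds must be nonnegative", call. = FALSE)
  }
  lo <- min(mean_hand_a, mean_hand_b)
  hi <- max(mean_hand_a, mean_hand_b)
  if (lo < eps) return(Inf)
  hi / lo
}

#' Fingers-to-wrist ratio (FWR)
#'
#' Ratio of the mean angular speed of a hand's fingers signal (mean of
#' thumb and index sensors) to that of its wrist sensor. Values close to 1
#' indicate the hand moving as a whole (global hand activity, e.g. tool
#' manipulation); higher values indicate finger movement independent of the
#' wrist (e.g. writing, typing). When the wrist mean is below `eps`, `Inf`
#' is returned as a sentinel.
#'
#' @param fingers_mean,wrist_mean Nonnegative mean speeds (deg/s).
#' @param eps Zero-denominator guard in deg/s.
#' @return FWR, a dimensionless positive value (possibly `Inf`).
#' @export
#' @examples
#' fingers_wrist_ratio(2, 1)  # 2
fingers_wrist_ratio <- function(fingers_mean, wrist_mean, eps = 1e-9) {
  if (fingers_mean < 0 || wrist_mean < 0) {
    stop("mean speeds must be nonnegative", call. = FALSE)
  }
  if (wrist_mean < eps) return(Inf)
  fingers_mean / wrist_mean
}

#' Extract the classification features of one repetition
#'
#' Computes the segment's [mean_speeds()] and derives the feature vector the
#' decision tree consumes: HR from the two hand-signal means; the FWR of
#' each hand; `fwr_active`, the FWR of the most active hand (the label-free
#' proxy for the dominant hand in stabilizing-hand activities); and
#' `fwr_mean`, the average of the two hands' FWRs (used for activities with
#' both hands active). A tie in hand activity is broken toward the right
#' hand, so the result is deterministic.
#'
#' @param recording An `imu_recording`.
#' @param segment One-row segment annotation (see [read_segments()]).
#' @param eps Zero-denominator guard in deg/s.
#' @return One-row data frame with columns `participant_id`, `activity`,
#'   `repetition`, `true_category`, `hr`, `fwr_active`, `fwr_mean`,
#'   `most_active_hand`, plus audit columns `hand_mean_left`,
#'   `hand_mean_right`, `fwr_left`, `fwr_right`.
#' @export
extract_features <- function(recording, segment, eps = 1e-9) {
  ms <- mean_speeds(recording, segment)
  hand_l <- unname(ms$hand["left"])
  hand_r <- unname(ms$hand["right"])
  hr <- hands_ratio(hand_l, hand_r, eps = eps)
  fwr_l <- fingers_wrist_ratio(unname(ms$fingers["left"]),
                               unname(ms$wrist["left"]), eps = eps)
  fwr_r <- fingers_wrist_ratio(unname(ms$fingers["right"]),
                               unname(ms$wrist["right"]), eps = eps)
  most_active <- if (hand_r >= hand_l) "right" else "left"
  fwr_active <- if (most_active == "right") fwr_r else fwr_l
  data.frame(
    participant_id = as.character(segment$participant_id),
    activity = as.character(segment$activity),
    repetition = as.integer(segment$repetition),
    true_category = as.character(segment$true_category),
    hr = hr,
    fwr_active = fwr_active,
    fwr_mean = (fwr_l + fwr_r) / 2,
    most_active_hand = most_active,
    hand_mean_left = hand_l,
    hand_mean_right = hand_r,
    fwr_left = fwr_l,
    fwr_right = fwr_r,
    stringsAsFactors = FALSE)
}

#' Extract the feature table of a whole dataset
#'
#' Applies [extract_features()] to every annotated segment, matching each
#' segment to its participant's recording.
#'
#' @param recordings A single `imu_recording` or a list of them; a list may
#'   be named by participant id (unnamed lists are matched through each
#'   recording's own `participant_id`).
#' @param segments Segment data frame as from [read_segments()].
#' @param eps Zero-denominator guard in deg/s.
#' @return Feature data frame, one row per repetition (see
#'   [extract_features()] for columns).
#' @export
extract_feature_table <- function(recordings, segments, eps = 1e-9) {
  if (inherits(recordings, "imu_recording")) recordings <- list(recordings)
  ids <- vapply(recordings, function(r) r$participant_id, character(1L))
  names(recordings) <- ids
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, , drop = FALSE]
    rec <- recordings[[as.character(seg$participant_id)]]
    if (is.null(rec)) {
      stop("no recording for participant ", seg$participant_id,
           call. = FALSE)
    }
    extract_features(rec, seg, eps = eps)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read or write a feature table CSV
#'
#' Dialect: header `participant_id,activity,repetition,true_category,hr,
#' fwr_active,fwr_mean,most_active_hand` (audit columns optional).
#'
#' @param path Path to the feature CSV.
#' @return `read_feature_table()` returns the feature data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(participant_id = "character"))
  required <- c("participant_id", "activity", "repetition",
                "true_category", "hr", "fwr_active", "fwr_mean")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("feature CSV missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  .assert_category(df$true_category)
  df
}

#' @rdname read_feature_table
#' @param features Feature data frame.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
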