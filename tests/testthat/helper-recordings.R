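# Builders and independent oracles shared across test files.

# A recording in which every sensor's norm series is constant: placement p
# gets the triaxial series (v_p, 0, 0), so its norm is exactly v_p.
constant_recording <- function(norms, n = 50L, rate = 100,
                               participant_id = "T1") {
  stopifnot(all(imu_placements() %in% names(norms)))
  df <- data.frame(t_s = (seq_len(n) - 1L) / rate)
  for (p in imu_placements()) {
    df[[paste0(p, "_gx")]] <- rep(norms[[p]], n)
    df[[paste0(p, "_gy")]] <- rep(0, n)
    df[[paste0(p, "_gz")]] <- rep(0, n)
  }
  new_recording(participant_id, rate, df)
}

# A recording with iid normal gyro components on every axis.
random_recording <- function(n = 100L, rate = 100, sd = 30,
                             participant_id = "T1") {
  df <- data.frame(t_s = (seq_len(n) - 1L) / rate)
  for (p in imu_placements()) {
    for (ax in c("gx", "gy", "gz")) {
      df[[paste0(p, "_", ax)]] <- rnorm(n, sd = sd)
    }
  }
  new_recording(participant_id, rate, df)
}

segment_row <- function(t_start, t_end, participant_id = "T1",
                        activity = "toy", repetition = 1L,
                        category = "unimanual") {
  data.frame(participant_id = participant_id, activity = activity,
             repetition = as.integer(repetition), t_start_s = t_start,
             t_end_s = t_end, true_category = category,
             performed_hand = "unknown", stringsAsFactors = FALSE)
}

# Brute-force mean speeds: loop over in-window samples and sensors.
mean_speeds_oracle <- function(recording, t_start, t_end) {
  d <- recording$data
  rows <- which(d$t_s >= t_start & d$t_s < t_end)
  out <- numeric(0)
  for (p in imu_placements()) {
    acc <- 0
    for (i in rows) {
      acc <- acc + sqrt(d[[paste0(p, "_gx")]][i]^2 +
                        d[[paste0(p, "_gy")]][i]^2 +
                        d[[paste0(p, "_gz")]][i]^2)
    }
    out[p] <- acc / length(rows)
  }
  out
}

# Exhaustive ROC oracle: sweep a dense grid of candidate thresholds and
# count rates directly; returns the max Youden J and the sens/spec pairs
# attainable.
roc_oracle_sweep <- function(scores, labels) {
  cand <- sort(unique(c(-Inf, Inf, scores,
                        scores - 1e-9, scores + 1e-9)))
  sens <- vapply(cand, function(t) mean(scores[labels == 1] > t),
                 numeric(1))
  spec <- vapply(cand, function(t) mean(scores[labels == 0] <= t),
                 numeric(1))
  list(threshold = cand, sens = sens, spec = spec, j = sens + spec - 1)
}

# O(n^2) Mann-Whitney AUC oracle: probability a random positive outscores a
# random negative, ties counted one half.
auc_oracle_mw <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# A random 3D rotation matrix via QR decomposition.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
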