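#' Parameters for the synthetic six-sensor dataset generator
#'
#' The generator emulates the statistical structure the classifier relies
#' on: per-category hand asymmetry (HR) and finger independence (FWR),
#' subject-level multiplicative random effects, repetition-to-repetition
#' variation, and short repetitions of synchronized six-sensor gyroscope
#' streams. Per-repetition targets are drawn uniformly from per-category
#' ranges:
#' \itemize{
#'   \item HR: unimanual `[30, 90]`, stabilizing-hand `[6, 18]`,
#'     both-hands `[1, 3]` (`well_separated` preset);
#'   \item FWR: finger-activity branch `[2.6, 6]`, global-hand branch
#'     `[1.2, 2.1]`.
#' }
#' Under `well_separated` the category ranges leave clean gaps (HR gaps
#' (18, 30) and (3, 6); FWR gap (2.1, 2.6)) so learned cutoffs must land
#' between classes and the pipeline can be held to near-perfect recovery.
#' The `realistic` preset widens the ranges until neighbouring categories
#' overlap and adds subject- and repetition-level ratio noise, producing
#' imperfect, subject-dependent accuracy; it is intended for illustration,
#' not for pass/fail testing.
#'
#' @param preset `"well_separated"` (default) or `"realistic"`.
#' @param sample_rate_hz Sampling rate of the synthesized streams (Hz).
#'   Default 100 keeps generated datasets small; the hardware the pipeline
#'   targets samples at 500.
#' @param duration_range_s Range (s) repetition durations are drawn from;
#'   must stay within `max_duration_s`.
#' @param max_duration_s Maximum repetition duration (s), default 25.
#' @param wrist_speed_range Range (deg/s) of the active hand's wrist mean
#'   speed.
#' @param sigma_subject_speed Lognormal sigma of the subject-level
#'   multiplier on speeds (dimensionless; speeds cancel in the ratios).
#' @param sigma_subject_ratio Lognormal sigma of the subject-level
#'   multiplier applied to HR/FWR targets.
#' @param sigma_rep_ratio Lognormal sigma of the repetition-level
#'   multiplier applied to HR/FWR targets.
#' @param hr_range_unimanual,hr_range_stab,hr_range_both Per-category HR
#'   target ranges.
#' @param fwr_range_finger,fwr_range_global FWR target ranges for the
#'   finger-activity and global-hand branches.
#' @return List of class `synth_params`.
#' @export
synth_params <- function(preset = c("well_separated", "realistic"),
                         sample_rate_hz = 100,
                         duration_range_s = c(3, 6),
                         max_duration_s = 25,
                         wrist_speed_range = c(30, 90),
                         sigma_subject_speed = 0.2,
                         sigma_subject_ratio = NULL,
                         sigma_rep_ratio = NULL,
                         hr_range_unimanual = NULL,
                         hr_range_stab = NULL,
                         hr_range_both = NULL,
                         fwr_range_finger = NULL,
                         fwr_range_global = NULL) {
  preset <- match.arg(preset)
  defaults <- if (preset == "well_separated") {
    list(sigma_subject_ratio = 0, sigma_rep_ratio = 0,
         hr_range_unimanual = c(30, 90), hr_range_stab = c(6, 18),
         hr_range_both = c(1, 3), fwr_range_finger = c(2.6, 6),
         fwr_range_global = c(1.2, 2.1))
  } else {
    list(sigma_subject_ratio = 0.12, sigma_rep_ratio = 0.10,
         hr_range_unimanual = c(15, 90), hr_range_stab = c(3.5, 25),
         hr_range_both = c(1, 5.5), fwr_range_finger = c(2.2, 6),
         fwr_range_global = c(1.3, 2.8))
  }
  pick <- function(x, d) if (is.null(x)) d else x
  p <- list(preset = preset,
            sample_rate_hz = sample_rate_hz,
            duration_range_s = duration_range_s,
            max_duration_s = max_duration_s,
            wrist_speed_range = wrist_speed_range,
            sigma_subject_speed = sigma_subject_speed,
            sigma_subject_ratio = pick(sigma_subject_ratio,
                                       defaults$sigma_subject_ratio),
            sigma_rep_ratio = pick(sigma_rep_ratio,
                                   defaults$sigma_rep_ratio),
            hr_range_unimanual = pick(hr_range_unimanual,
                                      defaults$hr_range_unimanual),
            hr_range_stab = pick(hr_range_stab, defaults$hr_range_stab),
            hr_range_both = pick(hr_range_both, defaults$hr_range_both),
            fwr_range_finger = pick(fwr_range_finger,
                                    defaults$fwr_range_finger),
            fwr_range_global = pick(fwr_range_global,
                                    defaults$fwr_range_global))
  ranges <- p[grep("_range", names(p))]
  if (any(vapply(ranges, function(r) any(r <= 0) || r[2] < r[1],
                 logical(1L)))) {
    stop("all parameter ranges must be positive and increasing",
         call. = FALSE)
  }
  if (p$duration_range_s[2] > p$max_duration_s) {
    stop("duration_range_s exceeds max_duration_s", call. = FALSE)
  }
  class(p) <- "synth_params"
  p
}

# internal: draw a per-repetition target set (HR, per-hand FWR, wrist
# speed of the active hand) for a category, applying subject- and
# repetition-level multiplicative effects
.draw_targets <- function(category, params, effects) {
  runif1 <- function(r) stats::runif(1L, r[1L], r[2L])
  jitter_ratio <- function(x) {
    x * effects$ratio * exp(stats::rnorm(1L, 0, params$sigma_rep_ratio))
  }
  hr <- jitter_ratio(switch(category,
    unimanual = runif1(params$hr_range_unimanual),
    bimanual_stab_finger = ,
    bimanual_stab_global = runif1(params$hr_range_stab),
    bimanual_both_finger = ,
    bimanual_both_global = runif1(params$hr_range_both)))
  hr <- max(hr, 1)
  fwr_active <- jitter_ratio(switch(category,
    bimanual_stab_finger = ,
    bimanual_both_finger = runif1(params$fwr_range_finger),
    runif1(params$fwr_range_global)))
  # the less active hand: in the both-hands categories it shares the active
  # hand's branch (its fingers behave alike); elsewhere it is a stabilizer
  # or rest hand moving as a whole
  fwr_other <- jitter_ratio(
    if (category %in% .both_categories()) {
      runif1(if (category == "bimanual_both_finger")
               params$fwr_range_finger else params$fwr_range_global)
    } else {
      runif1(params$fwr_range_global)
    })
  wrist_active <- runif1(params$wrist_speed_range) * effects$speed
  active_hand <- sample(c("left", "right"), 1L)
  list(category = category, hr = hr, fwr_active = fwr_active,
       fwr_other = fwr_other, fwr_mean = (fwr_active + fwr_other) / 2,
       wrist_active = wrist_active, active_hand = active_hand)
}

# internal: a nonnegative burst-like norm series rescaled so its mean is
# exactly `target`
.norm_burst <- function(n, target) {
  envelope <- 0.25 + sin(pi * seq_len(n) / (n + 1))^2
  s <- envelope * (0.2 + abs(stats::rnorm(n)))
  s * target / mean(s)
}

# internal: distribute a norm series over x/y/z with per-sample random
# directions (isotropic); the per-sample Euclidean norm equals `norms`
.isotropic_xyz <- function(norms) {
  n <- length(norms)
  dir <- matrix(stats::rnorm(3L * n), ncol = 3L)
  dir <- dir / sqrt(rowSums(dir * dir))
  dir * norms
}

#' Simulate one annotated repetition
#'
#' Draws per-repetition targets (HR, per-hand FWR, active-hand wrist speed)
#' for the requested category, converts them to the six per-sensor target
#' mean speeds, and synthesizes each sensor's triaxial series as a random
#' burst in the norm domain, distributed isotropically over x/y/z and
#' rescaled so the empirical time-averaged norm hits its target to within
#' floating-point error. The pipeline only consumes norms, so the axis
#' decomposition is deliberately simple. Randomness comes from R's global
#' RNG; seed upstream with `set.seed()`.
#'
#' Per-sensor targets follow from the targets and the hand-signal algebra:
#' the active hand's thumb and index means are `fwr * wrist`, so its hand
#' mean is `wrist * (1 + 2 fwr) / 3`; the other hand's hand mean is the
#' active hand mean divided by HR, and its wrist mean follows from its own
#' FWR.
#'
#' @param category One of [categories()].
#' @param params A [synth_params()] object.
#' @param effects Subject-level effects, list with multipliers `speed` and
#'   `ratio` (default none).
#' @param participant_id,activity,repetition Annotation fields; `activity`
#'   defaults to `synthetic_<category>`.
#' @param t0_s Start time of the repetition in the recording (s); must be a
#'   multiple of the sampling interval.
#' @return List with `data` (wide data frame: `t_s` + 18 gyro columns),
#'   `segment` (one-row annotation) and `targets` (the drawn target set).
#' @export
simulate_segment <- function(category, params,
                             effects = list(speed = 1, ratio = 1),
                             participant_id = "S01", activity = NULL,
                             repetition = 1L, t0_s = 0) {
  .assert_category(category)
  stopifnot(inherits(params, "synth_params"))
  if (is.null(activity)) activity <- paste0("synthetic_", category)
  tg <- .draw_targets(category, params, effects)
  dur <- stats::runif(1L, params$duration_range_s[1L],
                      params$duration_range_s[2L])
  n <- max(2L, round(dur * params$sample_rate_hz))
  # per-sensor target means
  other_hand <- setdiff(c("left", "right"), tg$active_hand)
  hand_mean_active <- tg$wrist_active * (1 + 2 * tg$fwr_active) / 3
  hand_mean_other <- hand_mean_active / tg$hr
  wrist_other <- 3 * hand_mean_other / (1 + 2 * tg$fwr_other)
  target_of <- function(hand) {
    w <- if (hand == tg$active_hand) tg$wrist_active else wrist_other
    f <- if (hand == tg$active_hand) tg$fwr_active else tg$fwr_other
    stats::setNames(c(w, f * w, f * w),
                    c(.wrist_placement(hand), .finger_placements(hand)))
  }
  targets <- c(target_of("left"), target_of("right"))
  if (any(!is.finite(targets)) || any(targets < 0)) {
    stop("unreachable synthesis targets for category ", category,
         call. = FALSE)
  }
  dt <- 1 / params$sample_rate_hz
  df <- data.frame(t_s = t0_s + (seq_len(n) - 1L) * dt)
  for (p in imu_placements()) {
    xyz <- .isotropic_xyz(.norm_burst(n, targets[[p]]))
    df[paste(p, .gyro_axes, sep = "_")] <- xyz
  }
  segment <- data.frame(
    participant_id = participant_id, activity = activity,
    repetition = as.integer(repetition),
    t_start_s = t0_s, t_end_s = t0_s + n * dt,
    true_category = category,
    performed_hand = tg$active_hand,
    stringsAsFactors = FALSE)
  list(data = df, segment = segment, targets = tg)
}

#' Simulate a multi-participant study in memory
#'
#' Builds, for each synthetic participant, one continuous recording made of
#' back-to-back repetitions (`reps_per_category` of each of the five
#' categories, in category order) plus the ground-truth segment
#' annotations, and a manifest of every repetition's drawn targets for
#' checking learned cutoffs against the generator's inter-class gaps.
#'
#' @param n_subjects Number of participants (>= 2).
#' @param reps_per_category Repetitions of each category per participant.
#' @param params A [synth_params()] object.
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return List with `recordings` (named list of `imu_recording`),
#'   `segments` (annotation data frame) and `manifest` (one row of drawn
#'   targets per repetition).
#' @export
simulate_study <- function(n_subjects, reps_per_category, params,
                           seed = 1L) {
  stopifnot(inherits(params, "synth_params"))
  if (n_subjects < 2L) stop("n_subjects must be >= 2", call. = FALSE)
  set.seed(seed)
  recordings <- list()
  segments <- list()
  manifest <- list()
  for (i in seq_len(n_subjects)) {
    pid <- sprintf("S%02d", i)
    effects <- list(
      speed = exp(stats::rnorm(1L, 0, params$sigma_subject_speed)),
      ratio = exp(stats::rnorm(1L, 0, params$sigma_subject_ratio)))
    chunks <- list()
    t0 <- 0
    for (category in categories()) {
      for (rep_i in seq_len(reps_per_category)) {
        sim <- simulate_segment(category, params, effects = effects,
                                participant_id = pid, repetition = rep_i,
                                t0_s = t0)
        chunks[[length(chunks) + 1L]] <- sim$data
        segments[[length(segments) + 1L]] <- sim$segment
        manifest[[length(manifest) + 1L]] <- data.frame(
          participant_id = pid, activity = sim$segment$activity,
          repetition = rep_i, true_category = category,
          hr_target = sim$targets$hr,
          fwr_active_target = sim$targets$fwr_active,
          fwr_mean_target = sim$targets$fwr_mean,
          wrist_active_target = sim$targets$wrist_active,
          stringsAsFactors = FALSE)
        t0 <- sim$segment$t_end_s
      }
    }
    recordings[[pid]] <- new_recording(pid, params$sample_rate_hz,
                                       do.call(rbind, chunks))
  }
  segs <- validate_segments(do.call(rbind, segments),
                            max_duration_s = params$max_duration_s)
  list(recordings = recordings, segments = segs,
       manifest = do.call(rbind, manifest))
}

#' Write a simulated study to disk in the package CSV dialects
#'
#' Calls [simulate_study()] and writes one `recording_<participant>.csv`
#' per participant, a `segments.csv`, and a `manifest.json` recording the
#' preset, seed and per-repetition drawn targets. Output is byte-identical
#' across runs with the same arguments.
#'
#' @inheritParams simulate_study
#' @param dir Output directory (created if needed).
#' @return Invisibly, the [simulate_study()] result with a `paths` element
#'   appended.
#' @export
simulate_dataset <- function(dir, n_subjects, reps_per_category, params,
                             seed = 1L) {
  study <- simulate_study(n_subjects, reps_per_category, params,
                          seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0L)
  for (pid in names(study$recordings)) {
    p <- file.path(dir, paste0("recording_", pid, ".csv"))
    write_recording(study$recordings[[pid]], p)
    paths <- c(paths, p)
  }
  seg_path <- file.path(dir, "segments.csv")
  write_segments(study$segments, seg_path)
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(preset = params$preset, seed = seed,
         sample_rate_hz = params$sample_rate_hz,
         targets = study$manifest),
    man_path, dataframe = "rows", digits = NA)
  study$paths <- c(paths, seg_path, man_path)
  invisible(study)
}

#' Inter-class target gaps of a simulated study
#'
#' From a generator manifest, computes for each decision boundary the gap
#' between the highest drawn target of the lower class and the lowest drawn
#' target of the upper class. Under the `well_separated` preset every gap
#' is nonempty and any correctly learned cutoff must fall inside it.
#'
#' @param manifest Manifest data frame from [simulate_study()].
#' @return Data frame with columns `boundary`, `lower_max`, `upper_min`.
#' @export
cutoff_gaps <- function(manifest) {
  cat_ <- manifest$true_category
  data.frame(
    boundary = c("hr_unimanual", "hr_stabilizing", "fwr_stab", "fwr_both"),
    lower_max = c(
      max(manifest$hr_target[cat_ != "unimanual"]),
      max(manifest$hr_target[cat_ %in% .both_categories()]),
      max(manifest$fwr_active_target[cat_ == "bimanual_stab_global"]),
      max(manifest$fwr_mean_target[cat_ == "bimanual_both_global"])),
    upper_min = c(
      min(manifest$hr_target[cat_ == "unimanual"]),
      min(manifest$hr_target[cat_ %in% .stab_categories()]),
      min(manifest$fwr_active_target[cat_ == "bimanual_stab_finger"]),
      min(manifest$fwr_mean_target[cat_ == "bimanual_both_finger"])))
}
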