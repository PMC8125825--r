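#' Three-step decision-tree classification of a repetition
#'
#' Routes a repetition's (HR, FWR) features through the threshold tree:
#' \enumerate{
#'   \item `hr > hr_unimanual` -> `unimanual` (stop);
#'   \item otherwise, `hr > hr_stabilizing` selects the stabilizing-hand
#'     branch, else the both-hands branch;
#'   \item stabilizing branch: `fwr_active > fwr_stab` ->
#'     `bimanual_stab_finger`, else `bimanual_stab_global`; both-hands
#'     branch: `fwr_mean > fwr_both` -> `bimanual_both_finger`, else
#'     `bimanual_both_global`.
#' }
#' All inequalities are strict; equality falls to the lower branch. `Inf`
#' feature values (zero-denominator sentinels) compare greater than any
#' finite cutoff. FWR values not consulted by the path taken may be `NA`.
#'
#' @param hr,fwr_active,fwr_mean Numeric vectors of features, recycled to a
#'   common length.
#' @param cutoffs A `cutoff_set`.
#' @return Character vector of category codes (see [categories()]).
#' @export
#' @examples
#' cs <- cutoff_set(20.96, 4.67, 2.61, 2.26)
#' classify(56.73, NA, NA, cs)            # unimanual
#' classify(1.51, NA, 1.70, cs)           # bimanual_both_global
classify <- function(hr, fwr_active, fwr_mean, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  n <- max(length(hr), length(fwr_active), length(fwr_mean))
  hr <- rep_len(hr, n)
  fwr_active <- rep_len(fwr_active, n)
  fwr_mean <- rep_len(fwr_mean, n)
  vapply(seq_len(n), function(i) {
    if (is.na(hr[i])) stop("hr must not be NA", call. = FALSE)
    if (hr[i] > cutoffs$hr_unimanual) return("unimanual")
    if (hr[i] > cutoffs$hr_stabilizing) {
      if (is.na(fwr_active[i])) {
        stop("fwr_active needed for the stabilizing branch but is NA",
             call. = FALSE)
      }
      if (fwr_active[i] > cutoffs$fwr_stab) "bimanual_stab_finger"
      else "bimanual_stab_global"
    } else {
      if (is.na(fwr_mean[i])) {
        stop("fwr_mean needed for the both-hands branch but is NA",
             call. = FALSE)
      }
      if (fwr_mean[i] > cutoffs$fwr_both) "bimanual_both_finger"
      else "bimanual_both_global"
    }
  }, character(1L))
}

#' @rdname classify
#' @param features Feature data frame with columns `hr`, `fwr_active`,
#'   `fwr_mean`.
#' @return `classify_features()` returns `features` with a `predicted`
#'   column appended.
#' @export
classify_features <- function(features, cutoffs) {
  features$predicted <- classify(features$hr, features$fwr_active,
                                 features$fwr_mean, cutoffs)
  features
}

# internal: per-repetition criterion checks against the TRUE category's
# expected ranges (the green/red accounting). Returns logical columns
# step1/step2/step3 with NA where a step does not apply to the category.
.criterion_checks <- function(features, cutoffs) {
  cat_ <- features$true_category
  hr <- features$hr
  fa <- features$fwr_active
  fm <- features$fwr_mean
  is_uni <- cat_ == "unimanual"
  is_stab <- cat_ %in% .stab_categories()
  is_both <- cat_ %in% .both_categories()
  step1 <- ifelse(is_uni, hr > cutoffs$hr_unimanual,
                  hr <= cutoffs$hr_unimanual)
  step2 <- rep(NA, length(cat_))
  step2[is_stab] <- hr[is_stab] > cutoffs$hr_stabilizing
  step2[is_both] <- hr[is_both] <= cutoffs$hr_stabilizing
  step3 <- rep(NA, length(cat_))
  sel <- cat_ == "bimanual_stab_finger"
  step3[sel] <- fa[sel] > cutoffs$fwr_stab
  sel <- cat_ == "bimanual_stab_global"
  step3[sel] <- fa[sel] <= cutoffs$fwr_stab
  sel <- cat_ == "bimanual_both_finger"
  step3[sel] <- fm[sel] > cutoffs$fwr_both
  sel <- cat_ == "bimanual_both_global"
  step3[sel] <- fm[sel] <= cutoffs$fwr_both
  data.frame(step1 = step1, step2 = step2, step3 = step3)
}

# internal: accuracy summaries from a per-repetition outcome table
.summarize_outcomes <- function(per_rep) {
  acc <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  summarize_by <- function(keys) {
    groups <- split(per_rep, per_rep[keys], drop = TRUE)
    rows <- lapply(groups, function(g) {
      cbind(g[1L, keys, drop = FALSE],
            data.frame(n = nrow(g),
                       step1 = acc(g$step1), step2 = acc(g$step2),
                       step3 = acc(g$step3),
                       overall = mean(g$overall_correct)))
    })
    out <- do.call(rbind, rows)
    ord <- if ("activity" %in% keys) {
      order(match(out$true_category, categories()), out$activity)
    } else {
      order(match(out$true_category, categories()))
    }
    out <- out[ord, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  lev <- categories()
  confusion <- table(true = factor(per_rep$true_category, levels = lev),
                     predicted = factor(per_rep$predicted, levels = lev))
  list(activity_accuracy = summarize_by(c("activity", "true_category")),
       category_accuracy = summarize_by("true_category"),
       confusion = confusion,
       overall_accuracy = mean(per_rep$overall_correct))
}

#' Evaluate classification criteria against labeled features
#'
#' For every repetition, checks whether its HR and FWR values fall in the
#' ranges its true category requires at each applicable step of the
#' algorithm (step 2 and 3 never apply to unimanual repetitions). A
#' repetition is overall-correct only if every applicable criterion passes.
#' This per-criterion accounting is the primary view; because a mis-branched
#' repetition can still be checked against later criteria of its true
#' category, it differs from plain hierarchical routing, which is reported
#' alongside as a 5x5 confusion matrix of [classify()] predictions.
#'
#' @param features Labeled feature data frame (columns `participant_id`,
#'   `activity`, `repetition`, `true_category`, `hr`, `fwr_active`,
#'   `fwr_mean`).
#' @param cutoffs A `cutoff_set`.
#' @return Object of class `manuclass_eval`: list with `per_repetition`
#'   (features plus logical `step1`, `step2`, `step3`, `overall_correct`,
#'   and `predicted`), `activity_accuracy` and `category_accuracy` data
#'   frames (fractions in `[0, 1]`; `NA` where a step never applies),
#'   `confusion`, and `overall_accuracy`.
#' @export
evaluate <- function(features, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  if (anyNA(features$true_category)) {
    stop("every repetition must carry a true category", call. = FALSE)
  }
  .assert_category(features$true_category)
  checks <- .criterion_checks(features, cutoffs)
  overall <- apply(checks, 1L, function(r) all(r[!is.na(r)]))
  per_rep <- cbind(features, checks,
                   data.frame(overall_correct = as.logical(overall)))
  per_rep$predicted <- classify(features$hr, features$fwr_active,
                                features$fwr_mean, cutoffs)
  out <- c(list(per_repetition = per_rep, cutoffs = cutoffs),
           .summarize_outcomes(per_rep))
  class(out) <- "manuclass_eval"
  out
}

#' @export
print.manuclass_eval <- function(x, ...) {
  cat(sprintf("<manuclass_eval> %d repetitions, overall accuracy %.1f%%\n",
              nrow(x$per_repetition), 100 * x$overall_accuracy))
  df <- x$category_accuracy
  df[c("step1", "step2", "step3", "overall")] <-
    lapply(df[c("step1", "step2", "step3", "overall")],
           function(v) ifelse(is.na(v), NA, round(100 * v)))
  print(df)
  invisible(x)
}

#' Leave-one-subject-out cross-validation of the full pipeline
#'
#' For each participant in turn, learns the cutoff set on all remaining
#' participants' repetitions ([learn_cutoffs()]) and evaluates the held-out
#' participant against those cutoffs ([evaluate()]). Per-repetition
#' outcomes are pooled across folds into overall step-wise and per-category
#' accuracies, so every repetition is tested exactly once.
#'
#' @param features Labeled feature table covering at least two
#'   participants, with every category present in every training split.
#' @param convention Threshold convention passed to [learn_cutoffs()].
#' @return Object of class `manuclass_cv`: list with `folds` (per held-out
#'   participant: `participant_id`, learned `cutoffs`, fold `eval`),
#'   `per_repetition` (pooled), `activity_accuracy`, `category_accuracy`,
#'   `confusion`, `overall_accuracy`.
#' @export
loso_cv <- function(features, convention = c("midpoint", "observed")) {
  convention <- match.arg(convention)
  pids <- unique(features$participant_id)
  if (length(pids) < 2L) {
    stop("leave-one-subject-out requires >= 2 participants", call. = FALSE)
  }
  folds <- lapply(pids, function(p) {
    train <- features[features$participant_id != p, , drop = FALSE]
    test <- features[features$participant_id == p, , drop = FALSE]
    cuts <- tryCatch(
      learn_cutoffs(train, convention = convention),
      error = function(e) {
        stop("degenerate fold holding out participant ", p, ": ",
             conditionMessage(e), call. = FALSE)
      })
    list(participant_id = p, cutoffs = cuts, eval = evaluate(test, cuts))
  })
  per_rep <- do.call(rbind, lapply(folds, function(f) f$eval$per_repetition))
  rownames(per_rep) <- NULL
  out <- c(list(folds = folds, per_repetition = per_rep),
           .summarize_outcomes(per_rep))
  class(out) <- "manuclass_cv"
  out
}

#' @export
print.manuclass_cv <- function(x, ...) {
  cat(sprintf(
    "<manuclass_cv> %d folds, %d repetitions, overall accuracy %.1f%%\n",
    length(x$folds), nrow(x$per_repetition), 100 * x$overall_accuracy))
  for (f in x$folds) {
    cat(sprintf("  held out %-6s cutoffs %.4g / %.4g / %.4g / %.4g\n",
                f$participant_id, f$cutoffs$hr_unimanual,
                f$cutoffs$hr_stabilizing, f$cutoffs$fwr_stab,
                f$cutoffs$fwr_both))
  }
  invisible(x)
}

#' End-to-end evaluation of a recorded dataset on disk
#'
#' Runs the complete pipeline on a dataset laid out in the package's CSV
#' dialects: one `recording_<participant>.csv` per participant plus a
#' `segments.csv` (see [read_recording()] and [read_segments()]). Features
#' are extracted, and leave-one-subject-out cross-validation is run. Use
#' this to score a real multi-participant study export; the learned cutoff
#' sets and accuracy tables can then be compared against published values.
#'
#' @param dir Directory containing `segments.csv` and the recording CSVs.
#' @param sample_rate_hz Declared sampling rate; `NULL` to infer per file.
#' @param convention Threshold convention for [learn_cutoffs()].
#' @return A list with `features`, whole-sample `cutoffs`, and the
#'   [loso_cv()] result `cv`.
#' @export
evaluate_external_dataset <- function(dir, sample_rate_hz = NULL,
                                      convention = "midpoint") {
  seg_path <- file.path(dir, "segments.csv")
  if (!dir.exists(dir) || !file.exists(seg_path)) {
    stop("no dataset found at ", dir,
         ": expected segments.csv plus recording_<participant>.csv files",
         call. = FALSE)
  }
  segments <- read_segments(seg_path)
  pids <- unique(segments$participant_id)
  recordings <- lapply(pids, function(p) {
    path <- file.path(dir, paste0("recording_", p, ".csv"))
    read_recording(path, sample_rate_hz = sample_rate_hz,
                   participant_id = p)
  })
  features <- extract_feature_table(recordings, segments)
  list(features = features,
       cutoffs = learn_cutoffs(features, convention = convention),
       cv = loso_cv(features, convention = convention))
}
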