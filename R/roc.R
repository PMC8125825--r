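#' ROC curve by exact counting
#'
#' Builds the receiver operating characteristic of a scalar score against
#' binary labels, under the convention that `score > threshold` predicts the
#' positive class (label 1). Candidate thresholds are, by default, the
#' midpoints between adjacent distinct sorted scores, bracketed by `-Inf`
#' and `+Inf` sentinels; the `observed` convention uses the distinct scores
#' themselves instead of midpoints. Sensitivity (true-positive rate) and
#' 1 - specificity (false-positive rate) are computed by exact counting at
#' every candidate threshold.
#'
#' @param scores Numeric vector of scores (`Inf` allowed).
#' @param labels Vector of 0/1 labels (or logicals), positive class = 1,
#'   expected to score higher.
#' @param convention `"midpoint"` (default) or `"observed"`. A midpoint
#'   with an infinite neighbour is replaced by the finite score + 1: any
#'   threshold in that open interval yields identical rates.
#' @return Data frame of class `roc_points` with columns `threshold`,
#'   `sensitivity`, `one_minus_specificity`, sorted by increasing
#'   threshold (sensitivity is then non-increasing).
#' @export
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1))
roc_curve <- function(scores, labels,
                      convention = c("midpoint", "observed")) {
  convention <- match.arg(convention)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: both classes must be present", call. = FALSE)
  }
  if (anyNA(scores)) stop("scores must not contain NA", call. = FALSE)
  s <- sort(unique(scores))
  if (convention == "midpoint") {
    if (length(s) >= 2L) {
      lo <- s[-length(s)]
      hi <- s[-1L]
      mids <- (lo + hi) / 2
      inf_pair <- !is.finite(lo) | !is.finite(hi)
      mids[inf_pair] <- ifelse(is.finite(lo[inf_pair]),
                               lo[inf_pair] + 1,
                               hi[inf_pair] - 1)
    } else {
      mids <- numeric(0L)
    }
    thr <- c(-Inf, mids, Inf)
  } else {
    thr <- c(-Inf, s)
  }
  thr <- unique(thr)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1L))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1L))
  out <- data.frame(threshold = thr, sensitivity = sens,
                    one_minus_specificity = fpr)
  out <- out[order(out$threshold), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("roc_points", "data.frame")
  out
}

#' Area under the ROC curve
#'
#' Trapezoidal area over (1 - specificity, sensitivity). With exact-count
#' rates and all distinct-score thresholds represented, this equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative, ties counted 1/2.
#'
#' @param roc An `roc_points` data frame from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  if (!all(c("sensitivity", "one_minus_specificity") %in% names(roc))) {
    stop("roc must have sensitivity and one_minus_specificity columns",
         call. = FALSE)
  }
  ord <- order(roc$one_minus_specificity, roc$sensitivity)
  x <- roc$one_minus_specificity[ord]
  y <- roc$sensitivity[ord]
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' ROC-optimal cutoff (Youden)
#'
#' Selects the threshold that jointly maximizes sensitivity and specificity,
#' i.e. maximizes Youden's J = sensitivity + specificity - 1, which
#' minimizes the total number of misclassifications at equal class weights.
#' Ties are broken toward the larger threshold (the more specific rule).
#'
#' @param roc An `roc_points` data frame from [roc_curve()].
#' @return The selected threshold. If only the infinite sentinel thresholds
#'   attain the maximum (e.g. all scores equal), the sentinel is returned
#'   with a warning.
#' @export
optimal_cutoff <- function(roc) {
  j <- roc$sensitivity + (1 - roc$one_minus_specificity) - 1
  best <- which(j == max(j))
  thr <- max(roc$threshold[best])
  if (!is.finite(thr)) {
    warning("degenerate ROC: no finite threshold improves on chance; ",
            "returning sentinel ", thr, call. = FALSE)
  }
  thr
}

#' Construct a cutoff set for the three-step classifier
#'
#' The four learned thresholds of the decision tree: `hr_unimanual`
#' separates uni- from bimanual repetitions (step 1), `hr_stabilizing`
#' separates stabilizing-hand from both-hands bimanual repetitions
#' (step 2), `fwr_stab` detects finger activity within the stabilizing-hand
#' branch (on the active hand's FWR), and `fwr_both` detects finger
#' activity within the both-hands branch (on the mean FWR). The step-2 HR
#' cutoff is expected to be smaller than the step-1 cutoff, since a
#' stabilizing hand still performs low-amplitude movements.
#'
#' @param hr_unimanual,hr_stabilizing,fwr_stab,fwr_both Positive
#'   thresholds.
#' @param auc Optional named list of the four AUCs (for learned sets).
#' @param convention Threshold convention the set was learned under.
#' @return An object of class `cutoff_set`.
#' @export
cutoff_set <- function(hr_unimanual, hr_stabilizing, fwr_stab, fwr_both,
                       auc = NULL, convention = "midpoint") {
  vals <- c(hr_unimanual = hr_unimanual, hr_stabilizing = hr_stabilizing,
            fwr_stab = fwr_stab, fwr_both = fwr_both)
  if (any(!is.numeric(vals)) || any(vals <= 0)) {
    stop("all cutoffs must be positive numbers", call. = FALSE)
  }
  if (hr_unimanual <= hr_stabilizing) {
    warning("hr_unimanual <= hr_stabilizing: the step-1 HR cutoff is ",
            "expected to exceed the step-2 cutoff", call. = FALSE)
  }
  structure(list(hr_unimanual = hr_unimanual,
                 hr_stabilizing = hr_stabilizing,
                 fwr_stab = fwr_stab, fwr_both = fwr_both,
                 auc = auc, convention = convention),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("<cutoff_set>\n")
  cat(sprintf("  step 1  HR  uni vs bimanual        > %.4g\n",
              x$hr_unimanual))
  cat(sprintf("  step 2  HR  stabilizing vs both    > %.4g\n",
              x$hr_stabilizing))
  cat(sprintf("  step 3  FWR finger (stabilizing)   > %.4g\n", x$fwr_stab))
  cat(sprintf("  step 3  FWR finger (both hands)    > %.4g\n", x$fwr_both))
  if (!is.null(x$auc)) {
    cat("  AUC:", paste(sprintf("%s=%.3f", names(x$auc), unlist(x$auc)),
                        collapse = ", "), "\n")
  }
  invisible(x)
}

#' Learn the full cutoff set from a labeled feature table
#'
#' Runs the four nested ROC analyses and picks each ROC-optimal cutoff:
#' (A) all repetitions, HR, positive = unimanual;
#' (B) bimanual repetitions only, HR, positive = stabilizing-hand;
#' (C) stabilizing-hand repetitions only, active-hand FWR, positive =
#' finger activity; (D) both-hands repetitions only, mean FWR, positive =
#' finger activity.
#'
#' @param features Labeled feature table (see [extract_feature_table()]);
#'   must contain all five categories.
#' @param convention Threshold convention passed to [roc_curve()].
#' @return A `cutoff_set` with the four thresholds and their AUCs.
#' @export
learn_cutoffs <- function(features,
                          convention = c("midpoint", "observed")) {
  convention <- match.arg(convention)
  .assert_category(features$true_category)
  cat_ <- features$true_category
  branch <- function(name, rows, scores, positive) {
    if (length(unique(positive[rows])) < 2L) {
      stop("degenerate labels in ROC branch '", name,
           "': a category is missing from the subset", call. = FALSE)
    }
    roc <- roc_curve(scores[rows], positive[rows], convention = convention)
    list(cutoff = optimal_cutoff(roc), auc = auc(roc))
  }
  a <- branch("hr_unimanual", seq_along(cat_), features$hr,
              as.integer(cat_ == "unimanual"))
  bim <- which(cat_ != "unimanual")
  b <- branch("hr_stabilizing", bim, features$hr,
              as.integer(cat_ %in% .stab_categories()))
  stab <- which(cat_ %in% .stab_categories())
  c_ <- branch("fwr_stab", stab, features$fwr_active,
               as.integer(cat_ == "bimanual_stab_finger"))
  both <- which(cat_ %in% .both_categories())
  d <- branch("fwr_both", both, features$fwr_mean,
              as.integer(cat_ == "bimanual_both_finger"))
  cutoff_set(a$cutoff, b$cutoff, c_$cutoff, d$cutoff,
             auc = list(hr_unimanual = a$auc, hr_stabilizing = b$auc,
                        fwr_stab = c_$auc, fwr_both = d$auc),
             convention = convention)
}

#' Read or write a cutoff set as JSON
#'
#' JSON form:
#' `{"hr_unimanual": ..., "hr_stabilizing": ..., "fwr_stab": ...,
#'   "fwr_both": ..., "auc": {...}, "convention": "..."}`.
#'
#' @param path Path to the JSON file.
#' @return `read_cutoffs()` returns a `cutoff_set`.
#' @export
read_cutoffs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutoff_set(x$hr_unimanual, x$hr_stabilizing, x$fwr_stab, x$fwr_both,
             auc = x$auc,
             convention = if (is.null(x$convention)) "midpoint"
                          else x$convention)
}

#' @rdname read_cutoffs
#' @param cutoffs A `cutoff_set`.
#' @export
write_cutoffs <- function(cutoffs, path) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  jsonlite::write_json(unclass(cutoffs), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
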