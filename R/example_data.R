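#' Bundled worked example: one held-out participant's feature table
#'
#' A small worked example used throughout the documentation and tests: the
#' HR/FWR feature table of one participant's session (14 activities of
#' daily living, 5 repetitions each) together with the cutoff set learned
#' with that participant excluded from training
#' (HR 20.96 / 4.67, FWR 2.61 / 2.26). Feeding the features through
#' [evaluate()] with these cutoffs reproduces the per-repetition green/red
#' criterion grid and the per-activity accuracies of the validation
#' example, e.g. "Using a spoon" passing 5/5 at step 1 and "Opening a
#' screw-topped jar" repetition 5 failing the step-3 FWR < 2.26 criterion
#' with FWR 2.43.
#'
#' FWR values are stored in the column the true category consumes
#' (`fwr_active` for stabilizing-hand activities, `fwr_mean` for
#' both-hands activities); the unused column is `NA`, which [classify()]
#' only tolerates on branches it does not take.
#'
#' @return `example_features()`: the feature data frame (70 repetitions).
#' @export
example_features <- function() {
  read_feature_table(system.file("extdata", "example_features_p3.csv",
                                 package = "manuclass", mustWork = TRUE))
}

#' @rdname example_features
#' @return `example_cutoffs()`: the matching `cutoff_set`.
#' @export
example_cutoffs <- function() {
  cutoff_set(hr_unimanual = 20.96, hr_stabilizing = 4.67,
             fwr_stab = 2.61, fwr_both = 2.26)
}
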