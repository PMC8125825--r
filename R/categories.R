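#' Canonical activity categories
#'
#' The five categories a repetition of a manual activity can belong to,
#' ordered as they fall out of the three-step decision tree: unimanual
#' first, then the two stabilizing-hand bimanual categories, then the two
#' both-hands bimanual categories.
#'
#' @return Character vector of the five canonical category codes.
#' @seealso [category_labels()] for the long, human-readable forms.
#' @export
#' @examples
#' categories()
categories <- function() {
  c("unimanual",
    "bimanual_stab_finger",
    "bimanual_stab_global",
    "bimanual_both_finger",
    "bimanual_both_global")
}

#' Human-readable category labels
#'
#' Long descriptive names for the five category codes, as used in reports.
#'
#' @return Named character vector mapping category code to display label.
#' @export
category_labels <- function() {
  c(unimanual = "Unimanual",
    bimanual_stab_finger =
      "Bimanual with a stabilizing hand and finger activity of the active hand",
    bimanual_stab_global =
      "Bimanual with a stabilizing hand and global activity of the active hand",
    bimanual_both_finger = "Bimanual with finger activity of both hands",
    bimanual_both_global = "Bimanual with a global activity of both hands")
}

#' Sensor placements
#'
#' The six sensor placements: wrist (W), thumb (T) and index finger (I) of
#' the left (L) and right (R) hand.
#'
#' @return Character vector `c("LW","LT","LI","RW","RT","RI")`.
#' @export
imu_placements <- function() {
  c("LW", "LT", "LI", "RW", "RT", "RI")
}

# internal: placements per hand / role
.hand_placements <- function(hand) {
  switch(hand,
         left  = c("LW", "LT", "LI"),
         right = c("RW", "RT", "RI"),
         stop("unknown hand: ", hand))
}
.finger_placements <- function(hand) {
  switch(hand, left = c("LT", "LI"), right = c("RT", "RI"))
}
.wrist_placement <- function(hand) {
  switch(hand, left = "LW", right = "RW")
}

.assert_category <- function(x) {
  bad <- setdiff(unique(as.character(x)), categories())
  if (length(bad) > 0L) {
    stop("unknown category label(s): ", paste(bad, collapse = ", "),
         "; must be one of: ", paste(categories(), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

# bimanual sub-families, used when subsetting for the nested ROC analyses
.stab_categories <- function() c("bimanual_stab_finger", "bimanual_stab_global")
.both_categories <- function() c("bimanual_both_finger", "bimanual_both_global")
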