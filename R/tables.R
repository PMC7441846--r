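#' Construct a response table
#'
#' Bundles a participant table (one row per participant: id, geographic unit,
#' optional demographics) with a long, sparse response table (one row per
#' observed participant x item cell). Under planned missingness most cells
#' are unobserved and simply absent.
#'
#' @param participants data frame with at least `participant_id` and `unit`.
#' @param responses data frame with `participant_id`, `item_id`, `response`.
#' @param likert_min,likert_max admissible response bounds.
#' @param sample_id label for the sample.
#' @return object of class `response_table`.
#' @export
response_table <- function(participants, responses,
                           likert_min = 1L, likert_max = 6L,
                           sample_id = "sample") {
  stopifnot(
    all(c("participant_id", "unit") %in% names(participants)),
    all(c("participant_id", "item_id", "response") %in% names(responses))
  )
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant_id in participants table")
  }
  bad <- responses$response < likert_min | responses$response > likert_max
  if (any(bad, na.rm = TRUE)) {
    stop(sum(bad), " responses outside [", likert_min, ", ", likert_max, "]")
  }
  structure(
    list(participants = participants, responses = responses,
         likert_min = as.integer(likert_min),
         likert_max = as.integer(likert_max),
         sample_id = sample_id),
    class = "response_table"
  )
}

#' @export
print.response_table <- function(x, ...) {
  cat("<response_table> sample:", x$sample_id, "\n",
      nrow(x$participants), "participants,",
      nrow(x$responses), "observed responses,",
      length(unique(x$participants$unit)), "units\n")
  invisible(x)
}

#' Construct a state score table
#'
#' Unit-level mean scores: one row per geographic unit, one column per trait,
#' plus the per-unit participant count `n`. `k`, the average number of
#' participants per unit, is stored as an attribute along with the sample and
#' inventory labels.
#'
#' @param df data frame with column `unit`, one numeric column per trait, and
#'   `n`.
#' @param traits trait column names (default: every column except `unit` and
#'   `n`).
#' @param sample_id,inventory labels.
#' @return object of class `state_scores` (a data frame).
#' @export
state_scores <- function(df, traits = NULL, sample_id = "sample",
                         inventory = NA_character_) {
  stopifnot("unit" %in% names(df), "n" %in% names(df))
  if (anyDuplicated(df$unit)) stop("duplicate unit labels in state score table")
  if (is.null(traits)) traits <- setdiff(names(df), c("unit", "n"))
  for (tr in traits) {
    if (!is.numeric(df[[tr]])) stop("trait column '", tr, "' is not numeric")
  }
  structure(
    df,
    traits = traits,
    k = sum(df$n) / nrow(df),
    sample_id = sample_id,
    inventory = inventory,
    class = c("state_scores", "data.frame")
  )
}

#' Trait names of a state score table
#' @param x a `state_scores` object.
#' @return character vector.
#' @export
score_traits <- function(x) attr(x, "traits")

#' Restrict a unit-indexed table to a unit subset
#'
#' @param x data frame with a `unit` column (e.g. `state_scores`,
#'   `sociodemo_table`).
#' @param subset character vector of unit labels, or a universe name accepted
#'   by [us_units()].
#' @return the filtered table (class and attributes preserved).
#' @export
filter_units <- function(x, subset) {
  if (length(subset) == 1 && subset %in% c("all51", "contiguous49", "contiguous48")) {
    subset <- us_units(subset)
  }
  keep <- x$unit %in% subset
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in setdiff(names(attributes(x)), c("names", "row.names", "class"))) {
    attr(out, a) <- attr(x, a)
  }
  if (inherits(x, "state_scores")) attr(out, "k") <- sum(out$n) / nrow(out)
  class(out) <- class(x)
  out
}
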