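#' Write / read a state score table as CSV
#'
#' Column layout mirrors published supplementary state-score tables: `unit`,
#' one numeric column per trait, `n`. The reader validates the schema and
#' refuses duplicate unit labels or non-numeric score cells.
#'
#' @param x a [state_scores()] table.
#' @param path CSV path.
#' @return `write_state_scores`: the path, invisibly. `read_state_scores`:
#'   a [state_scores()] table.
#' @export
write_state_scores <- function(x, path) {
  stopifnot(inherits(x, "state_scores"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_state_scores
#' @param traits expected trait columns; `NULL` accepts every column besides
#'   `unit` and `n`.
#' @param sample_id,inventory labels to attach to the table.
#' @export
read_state_scores <- function(path, traits = NULL, sample_id = "sample",
                              inventory = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("unit", "n")) {
    if (!col %in% names(df)) stop("schema error: missing column '", col, "'")
  }
  if (anyDuplicated(df$unit)) {
    stop("duplicate unit labels: ",
         paste(unique(df$unit[duplicated(df$unit)]), collapse = ", "))
  }
  if (!is.null(traits)) {
    miss <- setdiff(traits, names(df))
    if (length(miss)) {
      stop("schema error: missing trait column(s): ",
           paste(miss, collapse = ", "))
    }
  } else {
    traits <- setdiff(names(df), c("unit", "n"))
  }
  for (tr in traits) {
    if (!is.numeric(df[[tr]])) {
      stop("non-numeric score cells in column '", tr, "'")
    }
  }
  state_scores(df[, c("unit", traits, "n")], traits = traits,
               sample_id = sample_id, inventory = inventory)
}

#' Write / read an item bank as CSV
#' @param bank item bank data frame.
#' @param path CSV path.
#' @export
write_item_bank <- function(bank, path) {
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_item_bank
#' @export
read_item_bank <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("item_id", "inventory", "trait", "keying", "sampling_rate")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!all(df$keying %in% c(-1L, 1L))) stop("keying must be +1 or -1")
  class(df) <- c("item_bank", class(df))
  df
}

#' Write / read a response table as a pair of CSVs
#'
#' The participant table goes to `<stem>_participants.csv`, the long response
#' table to `<stem>_responses.csv`.
#'
#' @param x a [response_table()].
#' @param stem path stem (no extension).
#' @export
write_response_table <- function(x, stem) {
  stopifnot(inherits(x, "response_table"))
  utils::write.csv(x$participants, paste0(stem, "_participants.csv"),
                   row.names = FALSE)
  utils::write.csv(x$responses, paste0(stem, "_responses.csv"),
                   row.names = FALSE)
  invisible(stem)
}

#' @rdname write_response_table
#' @param likert_min,likert_max,sample_id passed to [response_table()].
#' @export
read_response_table <- function(stem, likert_min = 1L, likert_max = 6L,
                                sample_id = "sample") {
  parts <- utils::read.csv(paste0(stem, "_participants.csv"),
                           stringsAsFactors = FALSE)
  resp <- utils::read.csv(paste0(stem, "_responses.csv"),
                          stringsAsFactors = FALSE)
  if (!is.numeric(resp$response)) stop("non-numeric response cells")
  response_table(parts, resp, likert_min = likert_min,
                 likert_max = likert_max, sample_id = sample_id)
}

#' Write a machine-readable run manifest
#'
#' Records the seed, iteration counts, parameters and input paths of a
#' stochastic stage so the run can be reproduced exactly.
#'
#' @param path output JSON path.
#' @param stage stage name.
#' @param seed integer seed used.
#' @param ... further named parameters to record.
#' @return the path, invisibly.
#' @export
write_run_manifest <- function(path, stage, seed, ...) {
  manifest <- c(
    list(
      stage = stage,
      seed = seed,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("stateagg"))
    ),
    list(...)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
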