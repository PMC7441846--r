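#' Score scales as the simple mean of observed items
#'
#' Computes per-participant trait scores for one inventory: reverse-keyed
#' items are reflected as `likert_min + likert_max - response`, and the score
#' is the plain mean over the participant's observed items for that trait.
#' Under planned missingness different participants average different item
#' subsets; participants observing fewer than `min_items` items for a trait
#' get a missing score for it.
#'
#' @param responses a [response_table()].
#' @param bank an item bank data frame (`item_id`, `inventory`, `trait`,
#'   `keying`).
#' @param inventory which inventory to score.
#' @param min_items minimum observed items per trait for a score (default 1).
#' @return long data frame with `participant_id`, `unit`, `trait`, `score`,
#'   `n_items`, carrying attributes `sample_id`, `inventory`, `likert_min`,
#'   `likert_max`.
#' @export
score_scales <- function(responses, bank, inventory, min_items = 1L) {
  stopifnot(inherits(responses, "response_table"), min_items >= 1)
  b <- bank[bank$inventory == inventory, , drop = FALSE]
  if (nrow(b) == 0) stop("inventory '", inventory, "' not present in item bank")

  r <- responses$responses
  known <- r$item_id %in% bank$item_id
  if (!all(known)) {
    warning(sum(!known), " responses to unknown item ids skipped")
    r <- r[known, , drop = FALSE]
  }
  idx <- match(r$item_id, b$item_id)
  r <- r[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]

  lmin <- responses$likert_min
  lmax <- responses$likert_max
  keyed <- ifelse(b$keying[idx] == 1L, r$response,
                  lmin + lmax - r$response)

  key <- paste(r$participant_id, b$trait[idx], sep = "\r")
  sums <- rowsum(keyed, key)
  counts <- rowsum(rep(1L, length(keyed)), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(
    participant_id = vapply(parts, `[`, "", 1L),
    trait = vapply(parts, `[`, "", 2L),
    score = as.numeric(sums) / as.numeric(counts),
    n_items = as.integer(counts),
    stringsAsFactors = FALSE
  )
  out$score[out$n_items < min_items] <- NA_real_
  out$unit <- responses$participants$unit[
    match(out$participant_id, responses$participants$participant_id)
  ]
  out <- out[order(out$participant_id, out$trait),
             c("participant_id", "unit", "trait", "score", "n_items")]
  rownames(out) <- NULL
  structure(out,
            sample_id = responses$sample_id, inventory = inventory,
            likert_min = lmin, likert_max = lmax,
            class = c("scale_scores", "data.frame"))
}

#' Aggregate individual scores to unit-level state scores
#'
#' Unit trait mean = unweighted mean over participants with a non-missing
#' trait score (each participant counts once; no post-stratification). Units
#' outside `unit_subset` or with fewer than `min_n` scored participants are
#' excluded.
#'
#' @param scores a `scale_scores` long data frame from [score_scales()].
#' @param min_n minimum scored participants per included unit.
#' @param unit_subset unit labels (or a universe name for [us_units()]);
#'   `NULL` keeps every unit present.
#' @param sample_id,inventory labels for the output; default from `scores`.
#' @return a [state_scores()] table.
#' @export
aggregate_states <- function(scores, min_n = 1L, unit_subset = NULL,
                             sample_id = NULL, inventory = NULL) {
  if (is.null(sample_id)) sample_id <- attr(scores, "sample_id")
  if (is.null(inventory)) inventory <- attr(scores, "inventory")
  s <- scores[!is.na(scores$score), , drop = FALSE]
  if (!is.null(unit_subset)) {
    if (length(unit_subset) == 1 &&
        unit_subset %in% c("all51", "contiguous49", "contiguous48")) {
      unit_subset <- us_units(unit_subset)
    }
    s <- s[s$unit %in% unit_subset, , drop = FALSE]
  }
  if (nrow(s) == 0) stop("no scored participants after filtering")

  traits <- sort(unique(s$trait))
  units <- sort(unique(s$unit))
  wide <- matrix(NA_real_, length(units), length(traits),
                 dimnames = list(units, traits))
  for (tr in traits) {
    st <- s[s$trait == tr, ]
    m <- tapply(st$score, st$unit, mean)
    wide[names(m), tr] <- m
  }
  n_by_unit <- tapply(s$participant_id, s$unit,
                      function(p) length(unique(p)))
  n_by_unit <- as.integer(n_by_unit[units])

  drop <- n_by_unit < min_n
  if (any(drop)) {
    warning("excluding ", sum(drop), " unit(s) with fewer than ", min_n,
            " scored participants: ", paste(units[drop], collapse = ", "))
  }
  df <- data.frame(unit = units, wide, n = n_by_unit,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[!drop, , drop = FALSE]
  rownames(df) <- NULL
  state_scores(df, traits = traits, sample_id = sample_id,
               inventory = inventory)
}

#' Individual- and unit-level dispersion of trait scores
#'
#' For each trait: the SD and range of individual scores, and the SD and
#' range (max - min, with the units attaining them) of the unit-level means.
#' With a single unit the unit-level SD is undefined and reported missing.
#'
#' @param scores a `scale_scores` data frame (individual level).
#' @param table a [state_scores()] table aggregated from them.
#' @return data frame with one row per trait: `mean`, `indiv_sd`,
#'   `indiv_range`, `unit_sd`, `unit_range`, `unit_min`, `unit_max`,
#'   `min_unit`, `max_unit`.
#' @export
state_dispersion <- function(scores, table) {
  stopifnot(inherits(table, "state_scores"), nrow(table) >= 1)
  traits <- score_traits(table)
  out <- lapply(traits, function(tr) {
    ind <- scores$score[scores$trait == tr & !is.na(scores$score)]
    um <- table[[tr]]
    ok <- !is.na(um)
    um <- um[ok]; un <- table$unit[ok]
    i_min <- which.min(um); i_max <- which.max(um)
    data.frame(
      trait = tr,
      mean = mean(ind),
      indiv_sd = stats::sd(ind),
      indiv_range = max(ind) - min(ind),
      unit_sd = if (length(um) > 1) stats::sd(um) else NA_real_,
      unit_range = max(um) - min(um),
      unit_min = um[i_min], unit_max = um[i_max],
      min_unit = un[i_min], max_unit = un[i_max],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
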