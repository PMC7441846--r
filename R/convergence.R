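#' Population-weighted Pearson correlation
#'
#' Pearson correlation computed from weighted means, variances and
#' covariance, with weights normalized to sum to one (frequency weights).
#' Used to weight unit-level correlations by census population so that small
#' units do not dominate.
#'
#' @param x,y numeric vectors over units.
#' @param w non-negative weights (e.g. population counts); `NULL` or equal
#'   weights reduce to the ordinary Pearson correlation. Pairs with missing
#'   `x`, `y` or `w` are dropped.
#' @return correlation in \[-1, 1\].
#' @export
weighted_pearson <- function(x, y, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(x) == length(y), length(w) == length(x))
  ok <- is.finite(x) & is.finite(y) & is.finite(w)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < 3) stop("need at least 3 complete (x, y, w) triples")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative, sum > 0")
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx == 0 || vy == 0) stop("zero weighted variance; correlation undefined")
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

# weighted correlation matrix of the columns of X (weights normalized)
weighted_cor_matrix <- function(X, w = NULL) {
  X <- as.matrix(X)
  if (is.null(w)) w <- rep(1, nrow(X))
  w <- w / sum(w)
  mu <- colSums(w * X)
  Xc <- sweep(X, 2, mu)
  V <- crossprod(Xc, w * Xc)
  if (any(diag(V) == 0)) {
    stop("zero weighted variance in column(s): ",
         paste(colnames(X)[diag(V) == 0], collapse = ", "))
  }
  stats::cov2cor(V)
}

#' Fisher-z pooled mean of correlations
#'
#' Converts correlations to z-scores (`atanh`), averages, and transforms the
#' mean back (`tanh`) -- the variance-stabilized way to average correlations.
#' Inputs with |r| = 1 are clipped to +/-(1 - 1e-12) with a warning, since
#' `atanh(1)` is infinite.
#'
#' @param rs numeric vector of correlations.
#' @param na.rm drop missing values first.
#' @return pooled correlation.
#' @examples
#' fisher_mean(c(0.72, 0.76, 0.80, 0.85, 0.70))  # ~0.77
#' @export
fisher_mean <- function(rs, na.rm = FALSE) {
  if (na.rm) rs <- rs[!is.na(rs)]
  if (length(rs) == 0) stop("cannot pool an empty set of correlations")
  if (any(abs(rs) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(abs(rs) == 1)) {
    warning("|r| = 1 clipped to 1 - 1e-12 before Fisher transform")
    rs <- sign(rs) * pmin(abs(rs), 1 - 1e-12)
  }
  tanh(mean(atanh(rs)))
}

#' Classify a sample pair by design similarity
#'
#' Two samples can differ in personality inventory, research project, and
#' collection period. Periods overlapping by more than a boundary year are
#' "Same" (`"S"`); periods that only touch at a boundary year (a sequential
#' hand-off) or are disjoint with a gap shorter than `gap_years` are
#' "Adjacent" (`"A"`); larger gaps are "Non-adjacent" (`"N"`). Inventory and
#' project are `"S"` or `"D"` by label equality.
#'
#' @param a,b rows of a sample-metadata table with `inventory`, `project`,
#'   `period_start`, `period_end`.
#' @param gap_years adjacency threshold in years (default 5).
#' @return list with `inventory`, `project`, `time` (single characters).
#' @export
classify_pair_design <- function(a, b, gap_years = 5) {
  stopifnot(a$period_start <= a$period_end, b$period_start <= b$period_end)
  gap <- max(a$period_start, b$period_start) -
    min(a$period_end, b$period_end)
  time <- if (gap < 0) "S" else if (gap < gap_years) "A" else "N"
  list(
    inventory = if (identical(a$inventory, b$inventory)) "S" else "D",
    project = if (identical(a$project, b$project)) "S" else "D",
    time = time
  )
}

#' Pairwise same-trait convergence panel
#'
#' For every unordered pair of state score tables and every shared trait,
#' computes the population-weighted correlation of unit scores over the
#' common unit subset, and attaches the pair's design class from the sample
#' metadata.
#'
#' @param tables list of [state_scores()] tables.
#' @param meta data frame with one row per table: `sample_id`, `inventory`,
#'   `project`, `period_start`, `period_end` (matched to tables by
#'   `sample_id`).
#' @param w named weight vector over units (e.g. census populations), or
#'   `NULL` for unweighted.
#' @param unit_subset units to correlate over (labels or a universe name);
#'   `NULL` uses the units common to each pair.
#' @param gap_years passed to [classify_pair_design()].
#' @return long data frame of class `convergence_panel`: `sample_a`,
#'   `sample_b`, `inv`, `proj`, `time`, `trait`, `r`, `n_units`.
#' @export
pairwise_convergence <- function(tables, meta, w = NULL, unit_subset = NULL,
                                 gap_years = 5) {
  stopifnot(length(tables) >= 2)
  ids <- vapply(tables, function(t) attr(t, "sample_id"), "")
  if (!all(ids %in% meta$sample_id)) {
    stop("meta is missing sample_id(s): ",
         paste(setdiff(ids, meta$sample_id), collapse = ", "))
  }
  if (!is.null(unit_subset) && length(unit_subset) == 1 &&
      unit_subset %in% c("all51", "contiguous49", "contiguous48")) {
    unit_subset <- us_units(unit_subset)
  }
  rows <- list()
  n <- length(tables)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      ta <- tables[[i]]; tb <- tables[[j]]
      ma <- meta[meta$sample_id == ids[i], ][1, ]
      mb <- meta[meta$sample_id == ids[j], ][1, ]
      cls <- classify_pair_design(ma, mb, gap_years)
      units <- intersect(ta$unit, tb$unit)
      if (!is.null(unit_subset)) units <- intersect(units, unit_subset)
      traits <- union(score_traits(ta), score_traits(tb))
      for (tr in traits) {
        if (!(tr %in% score_traits(ta)) || !(tr %in% score_traits(tb))) {
          warning("trait '", tr, "' missing for pair ", ids[i], "-", ids[j])
          r <- NA_real_
        } else {
          wi <- if (is.null(w)) NULL else unname(w[units])
          r <- weighted_pearson(ta[[tr]][match(units, ta$unit)],
                                tb[[tr]][match(units, tb$unit)], wi)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample_a = ids[i], sample_b = ids[j],
          inv = cls$inventory, proj = cls$project, time = cls$time,
          trait = tr, r = r, n_units = length(units),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("convergence_panel", "data.frame")
  out
}

#' Fisher-pooled means of a convergence panel
#'
#' Pools the panel's same-trait correlations with [fisher_mean()] at four
#' levels: per (design class, trait) cell, per design class over traits, per
#' trait over all pairs, and the grand mean over every (pair, trait) cell.
#'
#' @param panel a `convergence_panel` from [pairwise_convergence()].
#' @return data frame with columns `scope` (`"class_trait"`, `"class"`,
#'   `"trait"`, `"grand"`), `inv`, `proj`, `time`, `trait`, `r`, `n`.
#' @export
group_means <- function(panel) {
  stopifnot(nrow(panel) > 0)
  p <- panel[!is.na(panel$r), , drop = FALSE]
  if (nrow(p) == 0) stop("panel has no non-missing correlations")
  cls <- paste(p$inv, p$proj, p$time, sep = "/")
  rows <- list()
  for (cl in unique(cls)) {
    sub <- p[cls == cl, ]
    parts <- strsplit(cl, "/")[[1]]
    for (tr in unique(sub$trait)) {
      ri <- sub$r[sub$trait == tr]
      rows[[length(rows) + 1L]] <- data.frame(
        scope = "class_trait", inv = parts[1], proj = parts[2],
        time = parts[3], trait = tr, r = fisher_mean(ri), n = length(ri),
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "class", inv = parts[1], proj = parts[2], time = parts[3],
      trait = NA_character_, r = fisher_mean(sub$r), n = nrow(sub),
      stringsAsFactors = FALSE)
  }
  for (tr in unique(p$trait)) {
    ri <- p$r[p$trait == tr]
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "trait", inv = NA_character_, proj = NA_character_,
      time = NA_character_, trait = tr, r = fisher_mean(ri), n = length(ri),
      stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    scope = "grand", inv = NA_character_, proj = NA_character_,
    time = NA_character_, trait = NA_character_, r = fisher_mean(p$r),
    n = nrow(p), stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correct a correlation for attenuation due to unreliability
#'
#' Divides an observed correlation by the square root of the product of the
#' two variables' reliabilities to estimate the correlation between the
#' underlying true scores. Values may exceed 1 (sampling error, or
#' reliability underestimates) and are reported unclipped.
#'
#' @param r observed correlation.
#' @param rel_a,rel_b reliabilities in (0, 1\].
#' @return adjusted correlation. Vectorized.
#' @examples
#' disattenuate(0.81, 0.83, 0.84)  # ~0.97
#' @export
disattenuate <- function(r, rel_a, rel_b) {
  if (any(rel_a <= 0) || any(rel_b <= 0)) {
    stop("reliabilities must be positive")
  }
  r / sqrt(rel_a * rel_b)
}

#' Split-half bootstrap of cross-inventory convergence
#'
#' Repeatedly splits the participants into two random halves; within each
#' half, scores each inventory and aggregates to unit-level state scores;
#' then correlates (population-weighted) inventory A's unit scores from one
#' half with inventory B's from the other, averaging the two orderings.
#' Same-inventory cross-half correlations estimate the reliability of the
#' aggregated scores; cross-inventory cells are additionally reported
#' adjusted for those reliabilities ([disattenuate()]). Cell summaries across
#' iterations are Fisher-pooled by default. Splitting the sample breaks the
#' dependence that shared items induce between inventories scored on the
#' same participants.
#'
#' @param responses a [response_table()].
#' @param bank item bank covering `inventories`.
#' @param inventories character vector (>= 2) of inventory labels to compare.
#' @param iterations number of random splits.
#' @param seed integer seed.
#' @param w named unit weight vector, or `NULL`.
#' @param unit_subset unit labels or universe name; `NULL` = all.
#' @param min_items passed to [score_scales()].
#' @param pool `"fisher"` or `"raw"` averaging of per-iteration cells.
#' @param split `"bootstrap"` for random halves; `"duplicate"` places the
#'   full sample in both halves (degenerate split: cells reduce to the
#'   full-sample cross-inventory correlations; used for validation).
#' @return object of class `split_half_result`: `raw`, `reliability`,
#'   `adjusted` (inventory x inventory x trait arrays; `reliability` holds
#'   the diagonal per trait), `iterations`, `seed`, `dropped_units` count.
#' @export
split_half_bootstrap <- function(responses, bank, inventories,
                                 iterations = 1000, seed = 1, w = NULL,
                                 unit_subset = NULL, min_items = 1L,
                                 pool = c("fisher", "raw"),
                                 split = c("bootstrap", "duplicate")) {
  pool <- match.arg(pool)
  split <- match.arg(split)
  stopifnot(length(inventories) >= 2)
  if (split == "duplicate") iterations <- 1L
  if (!is.null(unit_subset) && length(unit_subset) == 1 &&
      unit_subset %in% c("all51", "contiguous49", "contiguous48")) {
    unit_subset <- us_units(unit_subset)
  }

  pid <- responses$participants$participant_id
  n <- length(pid)
  n_inv <- length(inventories)
  set.seed(seed)

  half_tables <- function(ids) {
    keep <- responses$participants$participant_id %in% ids
    rt <- response_table(
      responses$participants[keep, , drop = FALSE],
      responses$responses[responses$responses$participant_id %in% ids, ,
                          drop = FALSE],
      likert_min = responses$likert_min, likert_max = responses$likert_max,
      sample_id = responses$sample_id
    )
    lapply(inventories, function(inv) {
      aggregate_states(score_scales(rt, bank, inv, min_items),
                       unit_subset = unit_subset)
    })
  }

  traits <- NULL
  acc <- NULL      # iterations x n_inv x n_inv x n_traits accumulation list
  dropped <- 0L
  draws <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    if (split == "duplicate") {
      h1 <- pid; h2 <- pid
    } else {
      perm <- sample.int(n)
      h1 <- pid[perm[seq_len(n %/% 2)]]
      h2 <- pid[perm[(n %/% 2 + 1):n]]
    }
    t1 <- half_tables(h1)
    t2 <- half_tables(h2)
    if (is.null(traits)) {
      traits <- Reduce(intersect, lapply(c(t1, t2), score_traits))
      acc <- array(NA_real_, c(iterations, n_inv, n_inv, length(traits)),
                   dimnames = list(NULL, inventories, inventories, traits))
    }
    for (a in seq_len(n_inv)) for (b in seq_len(n_inv)) {
      for (ti in seq_along(traits)) {
        tr <- traits[ti]
        c1 <- cross_half_cor(t1[[a]], t2[[b]], tr, w)
        cors <- c1$r
        dropped <- dropped + c1$dropped
        if (a != b) {
          c2 <- cross_half_cor(t1[[b]], t2[[a]], tr, w)
          cors <- c(cors, c2$r)
          dropped <- dropped + c2$dropped
        }
        acc[it, a, b, ti] <- mean(atanh(clip_r(cors)))
      }
    }
  }

  pool_fun <- if (pool == "fisher") function(z) tanh(mean(z)) else
    function(z) mean(tanh(z))
  raw <- apply(acc, c(2, 3, 4), pool_fun)
  reliability <- sapply(traits, function(tr) diag(raw[, , tr]))
  if (is.null(dim(reliability))) {
    reliability <- matrix(reliability, nrow = n_inv,
                          dimnames = list(inventories, traits))
  }
  adjusted <- raw
  for (ti in seq_along(traits)) {
    rel <- diag(raw[, , ti])
    adjusted[, , ti] <- raw[, , ti] / sqrt(outer(rel, rel))
  }

  structure(list(
    raw = raw, reliability = reliability, adjusted = adjusted,
    traits = traits, inventories = inventories,
    iterations = iterations, seed = seed, pool = pool,
    dropped_units = dropped
  ), class = "split_half_result")
}

# correlation of table A's and table B's unit scores for one trait over
# common units; attribute "dropped" counts units present in one half only
cross_half_cor <- function(ta, tb, trait, w) {
  units <- intersect(ta$unit, tb$unit)
  dropped <- length(union(ta$unit, tb$unit)) - length(units)
  wi <- if (is.null(w)) NULL else unname(w[units])
  r <- weighted_pearson(ta[[trait]][match(units, ta$unit)],
                        tb[[trait]][match(units, tb$unit)], wi)
  list(r = r, dropped = dropped)
}

clip_r <- function(r, eps = 1e-12) pmin(pmax(r, -1 + eps), 1 - eps)

#' @export
print.split_half_result <- function(x, ...) {
  cat("<split_half_result>", x$iterations, "iterations,",
      length(x$inventories), "inventories,",
      length(x$traits), "traits\n")
  for (tr in x$traits) {
    cat("\n", tr, "(raw below diagonal, reliability on it, adjusted above):\n")
    m <- x$raw[, , tr]
    m[upper.tri(m)] <- x$adjusted[, , tr][upper.tri(m)]
    print(round(m, 2))
  }
  invisible(x)
}
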