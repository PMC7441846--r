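#' Population-weighted partial correlation
#'
#' Partial correlation of `x` and `y` given control variables, computed from
#' the weighted correlation matrix of `(x, y, controls)` via the Schur
#' complement (equivalently, the matrix-inverse formula
#' `r_xy.c = -P[1,2] / sqrt(P[1,1] * P[2,2])`). With no controls this reduces
#' to [weighted_pearson()]. If `x` or `y` is explained exactly by the
#' controls its partial variance vanishes and nothing is left to correlate;
#' the partial correlation is reported as 0.
#'
#' @param x,y numeric vectors over units.
#' @param controls data frame / matrix of control variables (may have zero
#'   columns).
#' @param w non-negative weights or `NULL`.
#' @return partial correlation.
#' @export
weighted_partial_correlation <- function(x, y, controls = NULL, w = NULL) {
  if (is.null(controls) || NCOL(controls) == 0 ||
      (is.data.frame(controls) && ncol(controls) == 0)) {
    return(weighted_pearson(x, y, w))
  }
  C <- as.matrix(controls)
  if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
  X <- cbind(x = x, y = y, C)
  ok <- stats::complete.cases(X) & (if (is.null(w)) TRUE else is.finite(w))
  X <- X[ok, , drop = FALSE]
  wi <- if (is.null(w)) NULL else w[ok]
  if (nrow(X) < ncol(C) + 3) {
    stop("need at least ", ncol(C) + 3, " complete units")
  }
  R <- weighted_cor_matrix(X, wi)
  ci <- seq(3, ncol(R))
  sol <- tryCatch(solve(R[ci, ci, drop = FALSE], R[ci, 1:2, drop = FALSE]),
                  error = function(e) {
    stop("singular correlation matrix among controls (",
         paste(colnames(C), collapse = ", "), "): ", conditionMessage(e))
  })
  P <- R[1:2, 1:2] - R[1:2, ci, drop = FALSE] %*% sol
  if (P[1, 1] < 1e-12 || P[2, 2] < 1e-12) return(0)
  P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

#' Trait x sociodemographic correlation panel
#'
#' For every (sample, trait, variable): the population-weighted correlation
#' between the sample's unit-level trait scores and the sociodemographic
#' variable, partialled for the sample's other traits (or raw). Units are
#' restricted to `unit_subset` and handled pairwise-complete with a warning
#' when sociodemographic rows are missing.
#'
#' @param tables list of [state_scores()] tables.
#' @param sociodemo data frame `unit` + one column per variable.
#' @param w named weight vector over units, or `NULL`.
#' @param unit_subset unit labels or a universe name (e.g. `"contiguous48"`).
#' @param partialled control for the other traits (default `TRUE`).
#' @return long data frame of class `replication_panel`: `sample_id`,
#'   `trait`, `variable`, `r`, `partialled`, `n_units`.
#' @export
build_panel <- function(tables, sociodemo, w = NULL, unit_subset = NULL,
                        partialled = TRUE) {
  if (!is.null(unit_subset) && length(unit_subset) == 1 &&
      unit_subset %in% c("all51", "contiguous49", "contiguous48")) {
    unit_subset <- us_units(unit_subset)
  }
  variables <- setdiff(names(sociodemo), "unit")
  rows <- list()
  for (tab in tables) {
    sid <- attr(tab, "sample_id")
    traits <- score_traits(tab)
    units <- intersect(tab$unit, sociodemo$unit)
    if (!is.null(unit_subset)) units <- intersect(units, unit_subset)
    n_expect <- if (is.null(unit_subset)) length(units) else
      length(unit_subset)
    if (length(units) < n_expect) {
      warning("sample ", sid, ": ", n_expect - length(units),
              " unit(s) missing; proceeding pairwise-complete")
    }
    ti <- match(units, tab$unit)
    si <- match(units, sociodemo$unit)
    wi <- if (is.null(w)) NULL else unname(w[units])
    for (tr in traits) {
      ctrl <- if (partialled) {
        as.data.frame(tab[ti, setdiff(traits, tr), drop = FALSE])
      } else NULL
      for (v in variables) {
        r <- weighted_partial_correlation(tab[[tr]][ti], sociodemo[[v]][si],
                                          ctrl, wi)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, trait = tr, variable = v, r = r,
          partialled = partialled, n_units = length(units),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("replication_panel", "data.frame")
  out
}

#' Replication correlation between two correlation panels
#'
#' Pairs every old-sample correlation with every new-sample correlation for
#' the same (trait, variable) cell -- n_old x n_new x n_variables pairs per
#' trait -- and reports the Pearson correlation over those pairs: the extent
#' to which the new samples reproduce the old samples' pattern of
#' trait-sociodemographic correlations.
#'
#' @param panel_old,panel_new `replication_panel` data frames.
#' @param trait which trait to summarize; `NULL` = all traits.
#' @return data frame: `trait`, `replication_r`, `n_pairs`, `range`
#'   (max - min over the pooled old + new correlation values for the trait).
#' @export
replication_correlation <- function(panel_old, panel_new, trait = NULL) {
  traits <- if (is.null(trait)) {
    intersect(unique(panel_old$trait), unique(panel_new$trait))
  } else trait
  out <- lapply(traits, function(tr) {
    po <- panel_old[panel_old$trait == tr, ]
    pn <- panel_new[panel_new$trait == tr, ]
    vars <- intersect(unique(po$variable), unique(pn$variable))
    if (length(vars) == 0) stop("no shared variables for trait '", tr, "'")
    pairs_old <- numeric(0); pairs_new <- numeric(0)
    for (v in vars) {
      ro <- po$r[po$variable == v]
      rn <- pn$r[pn$variable == v]
      grid <- expand.grid(old = ro, new = rn)
      pairs_old <- c(pairs_old, grid$old)
      pairs_new <- c(pairs_new, grid$new)
    }
    if (length(pairs_old) < 3) stop("fewer than 3 correlation pairs")
    data.frame(
      trait = tr,
      replication_r = stats::cor(pairs_old, pairs_new),
      n_pairs = length(pairs_old),
      range = max(c(po$r, pn$r)) - min(c(po$r, pn$r)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Range of a trait's panel correlations
#'
#' Max minus min of the correlation values for one trait in a panel (pool
#' panels with `rbind` first to get the range over old and new samples
#' together). A restricted range can cap the attainable replication
#' correlation.
#'
#' @param panel a `replication_panel`.
#' @param trait trait label.
#' @return numeric range.
#' @export
correlation_range <- function(panel, trait) {
  r <- panel$r[panel$trait == trait]
  if (length(r) == 0) stop("trait '", trait, "' absent from panel")
  max(r) - min(r)
}

#' Critical correlation for two-sided significance
#'
#' The smallest |r| significant at level `alpha` with `n` observations,
#' via the t transform `r = t / sqrt(t^2 + n - 2)` at the upper
#' `alpha/2` t quantile with `n - 2` degrees of freedom. With aggregated
#' data the effective n is the number of units, so thresholds are large.
#'
#' @param n observation count (>= 3); vectorized.
#' @param alpha two-sided level in (0, 1).
#' @return threshold correlation.
#' @examples
#' critical_r(48)  # ~0.28
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (any(n < 3)) stop("need n >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  t <- stats::qt(1 - alpha / 2, df = n - 2)
  t / sqrt(t^2 + n - 2)
}
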