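#' One-way ANOVA intraclass correlation (ICC1) and group-mean reliability
#'
#' Estimates ICC1 -- the fraction of individual-score variance accounted for
#' by group (unit) membership -- from a one-way random-effects ANOVA on
#' possibly unbalanced groups:
#' `ICC1 = (MSB - MSW) / (MSB + (k - 1) * MSW)`, with `k` the average group
#' size. ICC2, the reliability of group means, follows by the Spearman-Brown
#' relation ([spearman_brown()]). ICC1 can be negative when group means are
#' more similar than chance.
#'
#' @param x numeric scores (rows with missing `x` or `g` are dropped).
#' @param g group labels, same length as `x`.
#' @param k_method `"mean"` uses the arithmetic mean group size (the quantity
#'   conventionally reported as "average participants per unit");
#'   `"effective"` uses the unbalanced-design k0 =
#'   `(N - sum(n_j^2)/N) / (J - 1)`.
#' @return list of class `icc_result`: `icc1`, `icc2`, `k`, `n_units`,
#'   `n_total`, `ms_between`, `ms_within`, `k_method`.
#' @examples
#' x <- c(1, 2, 1, 2); g <- c("a", "a", "b", "b")
#' anova_icc(x, g)$icc1  # MSB = 0 => negative
#' @export
anova_icc <- function(x, g, k_method = c("mean", "effective")) {
  k_method <- match.arg(k_method)
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- as.character(g[ok])
  if (length(x) < 2) stop("need at least 2 observations")
  f <- factor(g)
  if (nlevels(f) < 2) stop("need at least 2 groups")
  if (stats::var(x) == 0) stop("all observations identical; ICC undefined")

  n_j <- tabulate(f)
  N <- length(x)
  J <- nlevels(f)
  sums <- rowsum(x, f)
  grand <- sum(x) / N
  ssb <- sum(sums^2 / n_j) - N * grand^2
  sst <- sum(x^2) - N * grand^2
  ssw <- sst - ssb
  msb <- ssb / (J - 1)
  msw <- ssw / (N - J)

  k <- switch(k_method,
    mean = N / J,
    effective = (N - sum(n_j^2) / N) / (J - 1)
  )
  icc1 <- (msb - msw) / (msb + (k - 1) * msw)
  # deeply negative icc1 can make the Spearman-Brown denominator vanish
  icc2 <- tryCatch(spearman_brown(icc1, k), error = function(e) NA_real_)
  structure(list(
    icc1 = icc1,
    icc2 = icc2,
    k = k, n_units = J, n_total = N,
    ms_between = msb, ms_within = msw,
    k_method = k_method
  ), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC1 = %.4f  ICC2 = %.2f  (k = %.1f, %d units, n = %d)\n",
              x$icc1, x$icc2, x$k, x$n_units, x$n_total))
  invisible(x)
}

#' Per-trait ICCs from long scale scores
#'
#' Applies [anova_icc()] separately to each trait of a `scale_scores` data
#' frame, and summarizes with the arithmetic mean of the per-trait ICC1s and
#' ICC2s (the relation between the two is nonlinear, so the mean ICC2 is not
#' the Spearman-Brown transform of the mean ICC1).
#'
#' @param scores long data frame with `trait`, `score`, `unit`.
#' @param ... passed to [anova_icc()].
#' @return data frame, one row per trait plus a `Mean` row: `trait`, `icc1`,
#'   `icc2`, `k`, `n_units`, `n_total`, `ms_between`, `ms_within`.
#' @export
icc_by_trait <- function(scores, ...) {
  traits <- sort(unique(scores$trait))
  rows <- lapply(traits, function(tr) {
    s <- scores[scores$trait == tr, ]
    r <- anova_icc(s$score, s$unit, ...)
    data.frame(trait = tr, icc1 = r$icc1, icc2 = r$icc2, k = r$k,
               n_units = r$n_units, n_total = r$n_total,
               ms_between = r$ms_between, ms_within = r$ms_within,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(trait = "Mean", icc1 = mean(out$icc1),
                         icc2 = mean(out$icc2), k = mean(out$k),
                         n_units = NA_integer_, n_total = NA_integer_,
                         ms_between = NA_real_, ms_within = NA_real_,
                         stringsAsFactors = FALSE)
  out <- rbind(out, mean_row)
  rownames(out) <- NULL
  out
}

#' Spearman-Brown group-mean reliability
#'
#' Maps a single-observation reliability (ICC1) and average group size `k` to
#' the reliability of a mean of `k` observations:
#' `ICC2 = k * ICC1 / (1 + (k - 1) * ICC1)`. Values are returned unclipped;
#' negative ICC1 gives negative ICC2.
#'
#' @param icc1 numeric reliability (<= 1; may be negative).
#' @param k average group size (>= 1). Vectorized over both arguments.
#' @return ICC2.
#' @examples
#' spearman_brown(0.0137, 459)   # ~0.86
#' spearman_brown(0.0122, 2602)  # ~0.97
#' @export
spearman_brown <- function(icc1, k) {
  if (any(k < 1)) stop("k must be >= 1")
  if (any(icc1 > 1)) stop("icc1 must be <= 1")
  denom <- 1 + (k - 1) * icc1
  if (any(denom <= 0)) {
    stop("degenerate input: 1 + (k - 1) * icc1 <= 0 (icc1 = ",
         paste(signif(icc1[denom <= 0], 4), collapse = ", "),
         ", k = ", paste(signif(k[denom <= 0], 4), collapse = ", "), ")")
  }
  k * icc1 / denom
}

#' Invert the Spearman-Brown relation
#'
#' Recovers the single-observation reliability implied by a group-mean
#' reliability at average group size `k`.
#'
#' @param icc2 group-mean reliability.
#' @param k average group size (> 0).
#' @return ICC1 such that `spearman_brown(icc1, k) == icc2`.
#' @export
spearman_brown_inverse <- function(icc2, k) {
  icc2 / (k - (k - 1) * icc2)
}

#' Permutation null distribution for group aggregation
#'
#' Randomly reassigns participants to units without replacement -- i.e.
#' permutes unit labels, keeping the number of participants per unit exactly
#' constant -- and recomputes ICC1 and ICC2 each iteration, per trait. The
#' mean permuted ICC1 shows how much apparent between-unit variance pure
#' sampling error produces at the same group sizes; the mean permuted ICC2 is
#' slightly negative (Jensen's inequality applied to the Spearman-Brown
#' transform of a null-centered ICC1).
#'
#' Labels are permuted within each trait's complete cases so group sizes are
#' identical across iterations even under planned missingness.
#'
#' @param scores long `scale_scores` data frame (`trait`, `score`, `unit`).
#' @param iterations number of permutations (>= 1).
#' @param seed integer seed for the shuffles.
#' @param k_method passed to [anova_icc()].
#' @return list of class `permutation_null`: `draws` (data frame `iteration`,
#'   `trait`, `icc1`, `icc2`), `mean_icc1`, `mean_icc2`, `iterations`,
#'   `seed`.
#' @export
permutation_null <- function(scores, iterations = 1000, seed = 1,
                             k_method = "mean") {
  stopifnot(iterations >= 1)
  traits <- sort(unique(scores$trait))
  # precompute per-trait complete-case vectors and fixed group structure
  prep <- lapply(traits, function(tr) {
    s <- scores[scores$trait == tr & !is.na(scores$score), ]
    f <- factor(s$unit)
    n_j <- tabulate(f)
    N <- nrow(s); J <- nlevels(f)
    k <- if (k_method == "mean") N / J else (N - sum(n_j^2) / N) / (J - 1)
    list(x = s$score, f = f, n_j = n_j, N = N, J = J, k = k,
         sst = sum(s$score^2) - sum(s$score)^2 / N)
  })
  names(prep) <- traits

  set.seed(seed)
  draws <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    res <- lapply(prep, function(p) {
      perm <- p$f[sample.int(p$N)]
      sums <- rowsum(p$x, perm)
      ssb <- sum(sums^2 / p$n_j) - sum(p$x)^2 / p$N
      msb <- ssb / (p$J - 1)
      msw <- (p$sst - ssb) / (p$N - p$J)
      icc1 <- (msb - msw) / (msb + (p$k - 1) * msw)
      c(icc1 = icc1, icc2 = spearman_brown(icc1, p$k))
    })
    draws[[it]] <- data.frame(
      iteration = it, trait = traits,
      icc1 = vapply(res, `[[`, 0, "icc1"),
      icc2 = vapply(res, `[[`, 0, "icc2"),
      stringsAsFactors = FALSE
    )
  }
  draws <- do.call(rbind, draws)
  rownames(draws) <- NULL
  structure(list(
    draws = draws,
    mean_icc1 = mean(draws$icc1),
    mean_icc2 = mean(draws$icc2),
    iterations = iterations,
    seed = seed
  ), class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "Permutation null (%d iterations): mean ICC1 = %.4f, mean ICC2 = %.2f\n",
    x$iterations, x$mean_icc1, x$mean_icc2))
  invisible(x)
}
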