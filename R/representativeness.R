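#' Representativeness of per-unit participant counts
#'
#' Correlates each unit's participant count with its census population
#' (unweighted Pearson). A sample recruited proportionally to population
#' correlates near 1; the statistic is invariant to rescaling the census
#' counts.
#'
#' @param responses a [response_table()].
#' @param census a `census` object from [generate_census()], or a named
#'   numeric vector of unit populations.
#' @return list: `r`, `n_units`, and the `counts` data frame.
#' @export
count_representativeness <- function(responses, census) {
  pop <- if (inherits(census, "census")) census$populations else census
  counts <- table(responses$participants$unit)
  units <- intersect(names(pop), names(counts))
  if (length(units) < 3) stop("need at least 3 units common to sample and census")
  x <- as.numeric(counts[units]); y <- as.numeric(pop[units])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate variance in counts or populations")
  }
  list(
    r = stats::cor(x, y),
    n_units = length(units),
    counts = data.frame(unit = units, sample_n = x, census_population = y,
                        stringsAsFactors = FALSE)
  )
}

#' Representativeness of within-unit demographic composition
#'
#' For one demographic dimension (e.g. ethnicity), correlates -- across
#' units, per category -- the sample's percentage of participants in that
#' category with the census margin. Categories with zero variance in either
#' vector are flagged `NA` rather than dropped silently; categories in the
#' margins but absent from the sample produce a warning.
#'
#' @param responses a [response_table()]; the participants table must carry a
#'   column named like `dimension` (`ethnicity`, `age_band`/`age`,
#'   `education`).
#' @param margins census margins data frame (`unit`, `dimension`, `category`,
#'   `proportion`), or a `census` object.
#' @param dimension which dimension to check.
#' @param age_breaks used to band a numeric `age` column when
#'   `dimension = "age_band"`.
#' @return data frame: `category`, `r`, `n_units`.
#' @export
composition_representativeness <- function(responses, margins,
                                           dimension = "ethnicity",
                                           age_breaks = c(18, 25, 45, 65, Inf)) {
  if (inherits(margins, "census")) margins <- margins$margins
  m <- margins[margins$dimension == dimension, , drop = FALSE]
  if (nrow(m) == 0) stop("dimension '", dimension, "' absent from margins")

  p <- responses$participants
  val <- if (dimension %in% names(p)) {
    p[[dimension]]
  } else if (dimension == "age_band" && "age" %in% names(p)) {
    as.character(cut(p$age, age_breaks, right = FALSE,
                     labels = c("18-24", "25-44", "45-64", "65+")))
  } else {
    stop("dimension '", dimension, "' absent from sample demographics")
  }

  tab <- table(p$unit, val)
  shares <- prop.table(tab, 1)
  units <- intersect(rownames(shares), unique(m$unit))
  out <- lapply(unique(m$category), function(cat) {
    if (!cat %in% colnames(shares)) {
      warning("category '", cat, "' absent from sample; reported NA")
      return(data.frame(category = cat, r = NA_real_,
                        n_units = length(units), stringsAsFactors = FALSE))
    }
    x <- as.numeric(shares[units, cat])
    y <- m$proportion[match(paste(units, cat), paste(m$unit, m$category))]
    r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
      stats::cor(x, y)
    data.frame(category = cat, r = r, n_units = length(units),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Descriptive summary of a sample
#'
#' Participant counts plus, where demographics are present, percentage
#' breakdowns by sex, ethnicity and education, and the median age with its
#' median absolute deviation (reported both raw and with the 1.4826
#' normal-consistency scaling).
#'
#' @param responses a [response_table()].
#' @return list of class `sample_summary`.
#' @export
summarize_sample <- function(responses) {
  p <- responses$participants
  out <- list(
    sample_id = responses$sample_id,
    n_participants = nrow(p),
    n_units = length(unique(p$unit)),
    n_responses = nrow(responses$responses)
  )
  pct <- function(x) round(100 * prop.table(table(x)), 1)
  if ("sex" %in% names(p)) out$sex_pct <- pct(p$sex)
  if ("ethnicity" %in% names(p)) out$ethnicity_pct <- pct(p$ethnicity)
  if ("education" %in% names(p)) out$education_pct <- pct(p$education)
  if ("age" %in% names(p)) {
    a <- p$age[!is.na(p$age)]
    out$median_age <- stats::median(a)
    out$age_mad_raw <- stats::mad(a, constant = 1)
    out$age_mad_scaled <- stats::mad(a)
  }
  class(out) <- "sample_summary"
  out
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("<sample_summary>", x$sample_id, "-", x$n_participants,
      "participants in", x$n_units, "units\n")
  if (!is.null(x$median_age)) {
    cat(sprintf("median age %.0f (MAD %.1f raw / %.1f scaled)\n",
                x$median_age, x$age_mad_raw, x$age_mad_scaled))
  }
  invisible(x)
}
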