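#' Configuration for the synthetic study generator
#'
#' Builds and validates the configuration that drives every synthetic-data
#' generator in the package. The defaults emulate a large online assessment
#' with planned item missingness: ~51 geographic units with very unequal
#' populations, small between-unit trait variance (implied ICC1 about 0.003),
#' a 100-item inventory (20 items per Big Five trait) sampled at 30% per
#' participant, and 1-6 Likert responses.
#'
#' The implied intraclass correlation for each trait,
#' `between_unit_sd^2 / (between_unit_sd^2 + within_unit_sd^2)`, is recorded
#' in the returned object as `true_icc1` and is the ground truth that
#' downstream reliability estimates are checked against.
#'
#' @param n_units number of geographic units. When 51, units are labelled
#'   with US postal codes (see [us_units()]); otherwise `U01`, `U02`, ...
#' @param unit_weights relative population weights (non-negative, sum 1).
#'   Default: a fixed right-skewed profile with max/min ratio ~66, comparable
#'   to US state populations. Recycled deterministically; not seed-dependent.
#' @param n_participants total participants to simulate.
#' @param traits character vector of trait names.
#' @param trait_means latent trait means on the Likert scale (scalar or one
#'   per trait).
#' @param between_unit_sd SD of unit-level latent trait means (scalar or per
#'   trait), in trait-score units.
#' @param within_unit_sd SD of individual deviations around the unit mean.
#' @param inventories data frame with columns `name`, `items_per_trait`,
#'   `sampling_rate`, and optionally `share_with` (name of another inventory
#'   whose items are partially reused) and `share_frac` (fraction of items per
#'   trait shared).
#' @param item_loading multiplier mapping the centered latent trait to the
#'   item expectation.
#' @param item_noise_sd residual SD on the item scale. The default 1.0 gives a
#'   single-item reliability near 0.5, typical of short Likert items.
#' @param reverse_key_fraction fraction of items keyed negatively.
#' @param likert_min,likert_max integer response bounds.
#' @param sociodemo_specs data frame with columns `variable`, one numeric
#'   column per trait holding the target correlation between the variable and
#'   the unit-level trait means, and optionally `noise_sd` (NA = calibrate the
#'   noise so the expected realized correlation equals the target).
#' @param assignment `"multinomial"` draws each participant's unit with
#'   probability proportional to `unit_weights`; `"quota"` fixes per-unit
#'   counts at their expectations (largest-remainder rounding), the design
#'   used for permutation-null studies that hold per-unit counts constant.
#' @param seed integer master seed; every generator derives its own
#'   sub-stream from it (see [derive_seed()]).
#' @return an object of class `synth_config`.
#' @examples
#' cfg <- synth_config(n_participants = 500, seed = 7)
#' cfg$true_icc1
#' @export
synth_config <- function(n_units = 51,
                         unit_weights = NULL,
                         n_participants = 10000,
                         traits = big_five(),
                         trait_means = c(4.2, 4.7, 3.6, 4.5, 3.8),
                         between_unit_sd = 0.055,
                         within_unit_sd = 1.0,
                         inventories = data.frame(
                           name = "INV1",
                           items_per_trait = 20,
                           sampling_rate = 0.30
                         ),
                         item_loading = 1.0,
                         item_noise_sd = 1.0,
                         reverse_key_fraction = 0.3,
                         likert_min = 1L,
                         likert_max = 6L,
                         sociodemo_specs = default_sociodemo_specs(traits),
                         assignment = c("multinomial", "quota"),
                         seed = 1L) {
  assignment <- match.arg(assignment)
  stopifnot(n_units >= 2, n_participants >= 1, length(traits) >= 1)
  if (likert_min >= likert_max) {
    stop("likert_min must be strictly less than likert_max")
  }

  units <- if (n_units == 51) us_units("all51") else sprintf("U%02d", seq_len(n_units))
  if (is.null(unit_weights)) {
    # fixed skewed profile (lognormal quantiles); deterministic by design
    unit_weights <- exp(0.9 * stats::qnorm(stats::ppoints(n_units)))
    unit_weights <- unit_weights / sum(unit_weights)
  }
  if (length(unit_weights) != n_units) {
    stop("unit_weights must have length n_units")
  }
  if (any(unit_weights < 0) || abs(sum(unit_weights) - 1) > 1e-9) {
    stop("unit_weights must be non-negative and sum to 1 (within 1e-9)")
  }

  n_traits <- length(traits)
  trait_means <- rep_len(trait_means, n_traits)
  between_unit_sd <- rep_len(between_unit_sd, n_traits)
  within_unit_sd <- rep_len(within_unit_sd, n_traits)
  if (any(between_unit_sd < 0) || any(within_unit_sd <= 0)) {
    stop("between_unit_sd must be >= 0 and within_unit_sd > 0")
  }

  inventories <- as.data.frame(inventories, stringsAsFactors = FALSE)
  req <- c("name", "items_per_trait", "sampling_rate")
  if (!all(req %in% names(inventories))) {
    stop("inventories needs columns: ", paste(req, collapse = ", "))
  }
  if (any(inventories$items_per_trait < 1)) {
    stop("invalid config: every (inventory, trait) cell needs at least one item")
  }
  if (any(inventories$sampling_rate < 0 | inventories$sampling_rate > 1)) {
    stop("sampling_rate must lie in [0, 1]")
  }
  if (anyDuplicated(inventories$name)) stop("inventory names must be unique")
  if (!"share_with" %in% names(inventories)) inventories$share_with <- NA_character_
  if (!"share_frac" %in% names(inventories)) inventories$share_frac <- 0

  if (!is.null(sociodemo_specs)) {
    sociodemo_specs <- as.data.frame(sociodemo_specs, stringsAsFactors = FALSE)
    missing_tr <- setdiff(traits, names(sociodemo_specs))
    for (tr in missing_tr) sociodemo_specs[[tr]] <- 0
    if (!"noise_sd" %in% names(sociodemo_specs)) {
      sociodemo_specs$noise_sd <- NA_real_
    }
    tgt <- as.matrix(sociodemo_specs[, traits, drop = FALSE])
    if (any(abs(tgt) > 1)) {
      stop("invalid config: sociodemographic target |correlation| > 1")
    }
  }

  if (reverse_key_fraction < 0 || reverse_key_fraction > 1) {
    stop("reverse_key_fraction must lie in [0, 1]")
  }

  cfg <- list(
    n_units = n_units, units = units, unit_weights = unit_weights,
    n_participants = as.integer(n_participants),
    traits = traits, trait_means = trait_means,
    between_unit_sd = between_unit_sd, within_unit_sd = within_unit_sd,
    inventories = inventories,
    item_loading = item_loading, item_noise_sd = item_noise_sd,
    reverse_key_fraction = reverse_key_fraction,
    likert_min = as.integer(likert_min), likert_max = as.integer(likert_max),
    sociodemo_specs = sociodemo_specs,
    assignment = assignment,
    seed = as.integer(seed),
    true_icc1 = stats::setNames(
      between_unit_sd^2 / (between_unit_sd^2 + within_unit_sd^2), traits
    )
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Default synthetic sociodemographic variable specification
#'
#' Thirteen unit-level variables (per-capita or percentage style) with target
#' correlations to the unit trait means, concentrated on Conscientiousness,
#' Neuroticism and Openness and weak for Extraversion and Agreeableness --
#' the pattern under which replication-correlation analyses are informative.
#'
#' @param traits trait names; targets are defined for the Big Five and zero
#'   for any other trait.
#' @return data frame usable as `sociodemo_specs` in [synth_config()].
#' @export
default_sociodemo_specs <- function(traits = big_five()) {
  specs <- data.frame(
    variable = c(
      "cancer_deaths", "heart_disease_deaths", "violent_crime",
      "property_crime", "arts_jobs", "business_jobs", "tech_jobs",
      "healthcare_jobs", "patents", "political_liberals", "religiosity",
      "wellbeing_index", "community_recognition"
    ),
    Conscientiousness = c(0, .30, 0, -.30, 0, .35, 0, .25, 0, 0, .25, 0, 0),
    Agreeableness     = c(0, 0, -.25, 0, 0, 0, 0, 0, 0, 0, 0, 0, .20),
    Neuroticism       = c(.35, .25, .30, 0, 0, 0, 0, 0, 0, 0, 0, -.45, 0),
    Openness          = c(0, 0, 0, 0, .45, 0, .40, 0, .45, .55, -.40, 0, 0),
    Extraversion      = c(0, 0, 0, 0, 0, .20, 0, 0, 0, 0, 0, 0, .25),
    noise_sd = NA_real_,
    stringsAsFactors = FALSE
  )
  for (tr in setdiff(traits, names(specs))) specs[[tr]] <- 0
  specs
}

#' Derive a reproducible sub-stream seed
#'
#' Maps the master seed and a stage tag to an integer below 2^31 so that every
#' stochastic stage draws from its own documented stream. Fixing the master
#' seed fixes all generated artifacts bit-for-bit.
#'
#' @param seed integer master seed.
#' @param tag character stage tag (e.g. `"responses"`).
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(as.numeric(seed)) * 1009 + h) %% 2147483647)
}

#' Generate a synthetic item bank
#'
#' Creates `items_per_trait` items for every (inventory, trait) cell, with a
#' deterministic (seed-derived) assignment of keying directions. Inventories
#' may share items: an inventory with `share_with`/`share_frac` set reuses
#' that fraction of each trait's items from the source inventory, mirroring
#' item pools from which several inventories are drawn.
#'
#' @param config a [synth_config()].
#' @return an item bank data frame with columns `item_id`, `inventory`,
#'   `trait`, `keying` (+1/-1), `sampling_rate`.
#' @export
generate_item_bank <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "item_bank"))
  inv <- config$inventories
  rows <- list()
  for (i in seq_len(nrow(inv))) {
    ipt <- inv$items_per_trait[i]
    share_with <- inv$share_with[i]
    n_shared <- if (!is.na(share_with) && inv$share_frac[i] > 0) {
      round(inv$share_frac[i] * ipt)
    } else 0L
    for (tr in config$traits) {
      ids <- sprintf("%s_%s_%02d", inv$name[i], abbreviate(tr, 5), seq_len(ipt))
      key <- ifelse(
        stats::runif(ipt) < config$reverse_key_fraction, -1L, 1L
      )
      if (n_shared > 0) {
        src <- rows[[paste(share_with, tr)]]
        if (is.null(src)) {
          stop("share_with inventory '", share_with,
               "' must be defined before '", inv$name[i], "'")
        }
        take <- seq_len(min(n_shared, nrow(src)))
        ids[take] <- src$item_id[take]
        key[take] <- src$keying[take]
      }
      rows[[paste(inv$name[i], tr)]] <- data.frame(
        item_id = ids, inventory = inv$name[i], trait = tr,
        keying = key, sampling_rate = inv$sampling_rate[i],
        stringsAsFactors = FALSE
      )
    }
  }
  bank <- do.call(rbind, rows)
  rownames(bank) <- NULL
  class(bank) <- c("item_bank", class(bank))
  bank
}

#' Generate synthetic participant responses under planned missingness
#'
#' Assigns participants to units (multinomially by population weight, or by
#' fixed quota), draws latent trait scores as unit mean + individual
#' deviation, and produces Likert item responses: a rounded, range-clipped
#' linear function of the keyed latent trait plus Gaussian item noise. Each
#' participant sees each inventory's items independently at that inventory's
#' sampling rate; unseen cells are simply absent from the long response table.
#' Demographics (sex, age, ethnicity, education) are drawn from the census
#' margins so that composition-representativeness checks have a known target.
#'
#' @param config a [synth_config()].
#' @param bank an item bank from [generate_item_bank()].
#' @param census optional census object from [generate_census()]; generated
#'   from `config` if omitted.
#' @param sample_id label stored on the response table.
#' @param unit_means optional unit x trait matrix (or the
#'   `unit_trait_means` data frame of an earlier `ground_truth`) of latent
#'   unit means to reuse instead of drawing fresh ones. Lets several
#'   independent samples be generated from one population, as when studying
#'   cross-sample convergence.
#' @return list with elements `responses` (a `response_table`: `participants`
#'   and long `responses` data frames) and `truth` (a `ground_truth`:
#'   `unit_trait_means`, `participant_traits`, `true_icc1`).
#' @export
generate_responses <- function(config, bank, census = NULL,
                               sample_id = "synthetic",
                               unit_means = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(census)) census <- generate_census(config)
  set.seed(derive_seed(config$seed, "responses"))

  n <- config$n_participants
  n_units <- config$n_units
  n_traits <- length(config$traits)

  # unit latent means: drawn, or reused from a shared population
  if (is.null(unit_means)) {
    unit_mu <- matrix(
      rep(config$trait_means, each = n_units) +
        stats::rnorm(n_units * n_traits) *
          rep(config$between_unit_sd, each = n_units),
      nrow = n_units,
      dimnames = list(config$units, config$traits)
    )
  } else {
    if (is.data.frame(unit_means)) {
      rownames(unit_means) <- unit_means$unit
      unit_means <- as.matrix(unit_means[, config$traits, drop = FALSE])
    }
    stopifnot(all(config$units %in% rownames(unit_means)))
    unit_mu <- unit_means[config$units, config$traits, drop = FALSE]
  }

  # unit assignment
  if (config$assignment == "multinomial") {
    unit_idx <- sample.int(n_units, n, replace = TRUE, prob = config$unit_weights)
  } else {
    counts <- largest_remainder(config$unit_weights * n)
    unit_idx <- rep(seq_len(n_units), counts)
  }
  unit <- config$units[unit_idx]

  latent <- unit_mu[unit_idx, , drop = FALSE] +
    matrix(stats::rnorm(n * n_traits), nrow = n) %*%
      diag(config$within_unit_sd, n_traits)
  colnames(latent) <- config$traits
  pid <- sprintf("P%06d", seq_len(n))

  demog <- draw_demographics(unit, census)

  participants <- data.frame(
    participant_id = pid, unit = unit, demog,
    stringsAsFactors = FALSE
  )

  # item responses, inventory by inventory
  mid <- (config$likert_min + config$likert_max) / 2
  resp_list <- list()
  for (inv in unique(bank$inventory)) {
    b <- bank[bank$inventory == inv, , drop = FALSE]
    n_items <- nrow(b)
    seen <- which(stats::runif(n * n_items) < b$sampling_rate[1])
    if (length(seen) == 0) next
    p_i <- ((seen - 1L) %% n) + 1L          # participant index
    it_i <- ((seen - 1L) %/% n) + 1L        # item index within inventory
    tr_i <- match(b$trait[it_i], config$traits)
    mu <- mid + b$keying[it_i] * config$item_loading *
      (latent[cbind(p_i, tr_i)] - mid)
    val <- round(mu + stats::rnorm(length(seen)) * config$item_noise_sd)
    val <- pmin(pmax(val, config$likert_min), config$likert_max)
    resp_list[[inv]] <- data.frame(
      participant_id = pid[p_i], item_id = b$item_id[it_i],
      response = as.integer(val), stringsAsFactors = FALSE
    )
  }
  responses <- do.call(rbind, resp_list)
  rownames(responses) <- NULL
  # an item shared between inventories is answered at most once
  dup <- duplicated(responses[c("participant_id", "item_id")])
  if (any(dup)) responses <- responses[!dup, , drop = FALSE]

  rt <- response_table(participants, responses,
                       likert_min = config$likert_min,
                       likert_max = config$likert_max,
                       sample_id = sample_id)

  truth <- structure(list(
    unit_trait_means = data.frame(unit = config$units, unit_mu,
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE),
    participant_traits = data.frame(participant_id = pid, unit = unit,
                                    latent, check.names = FALSE,
                                    stringsAsFactors = FALSE),
    true_icc1 = config$true_icc1,
    sociodemo_true_r = NULL
  ), class = "ground_truth")

  list(responses = rt, truth = truth)
}

# largest-remainder rounding of expected counts to integers with fixed total
largest_remainder <- function(x) {
  base <- floor(x)
  rem <- x - base
  short <- round(sum(x)) - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

draw_demographics <- function(unit, census) {
  n <- length(unit)
  sex <- ifelse(stats::runif(n) < 0.66, "female", "male")
  eth <- character(n); ageband <- character(n); edu <- character(n)
  for (u in unique(unit)) {
    idx <- which(unit == u)
    for (dim in c("ethnicity", "age_band", "education")) {
      m <- census$margins[census$margins$unit == u &
                            census$margins$dimension == dim, ]
      draw <- sample(m$category, length(idx), replace = TRUE,
                     prob = m$proportion)
      if (dim == "ethnicity") eth[idx] <- draw
      if (dim == "age_band") ageband[idx] <- draw
      if (dim == "education") edu[idx] <- draw
    }
  }
  age_lo <- c("18-24" = 18, "25-44" = 25, "45-64" = 45, "65+" = 65)
  age_hi <- c("18-24" = 24, "25-44" = 44, "45-64" = 64, "65+" = 90)
  age <- floor(stats::runif(n, age_lo[ageband], age_hi[ageband] + 1))
  data.frame(sex = sex, age = as.integer(age), ethnicity = eth,
             education = edu, stringsAsFactors = FALSE)
}

#' Generate synthetic census populations and demographic margins
#'
#' Unit population counts are exactly proportional to the configured unit
#' weights; per-unit demographic composition (ethnicity, age band, education
#' tier) is drawn around national base rates with unit-level log-scale
#' perturbations and renormalized to sum to one within each
#' (unit, dimension).
#'
#' @param config a [synth_config()].
#' @param total_population scale for the population counts.
#' @return object of class `census`: list with `populations` (named numeric)
#'   and `margins` (data frame `unit`, `dimension`, `category`,
#'   `proportion`).
#' @export
generate_census <- function(config, total_population = 3.08e8) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, "census"))
  pop <- stats::setNames(config$unit_weights * total_population, config$units)

  base <- list(
    ethnicity = c(white = .64, african_american = .12, hispanic = .16,
                  asian = .05, other = .03),
    age_band = c("18-24" = .13, "25-44" = .35, "45-64" = .33, "65+" = .19),
    education = c(hs_or_less = .40, some_college = .30, bachelor_plus = .30)
  )
  rows <- list()
  for (dim in names(base)) {
    p0 <- base[[dim]]
    for (u in config$units) {
      lp <- log(p0) + stats::rnorm(length(p0), 0, 0.35)
      p <- exp(lp) / sum(exp(lp))
      rows[[paste(dim, u)]] <- data.frame(
        unit = u, dimension = dim, category = names(p0),
        proportion = as.numeric(p), stringsAsFactors = FALSE
      )
    }
  }
  margins <- do.call(rbind, rows)
  rownames(margins) <- NULL
  structure(list(populations = pop, margins = margins), class = "census")
}

#' Generate unit-level sociodemographic variables with known structure
#'
#' Each variable is a linear combination of the standardized unit trait means
#' plus Gaussian noise. With `noise_sd = NA` in the spec row, the noise is
#' calibrated so the expected realized correlation with each trait equals the
#' target; with an explicit `noise_sd`, the trait weights equal the targets
#' and the realized correlations attenuate accordingly. Realized correlations
#' are recorded in the `realized_r` attribute.
#'
#' @param config a [synth_config()] (its `sociodemo_specs` is used).
#' @param truth a `ground_truth` from [generate_responses()].
#' @return a `sociodemo_table` data frame (`unit` plus one column per
#'   variable) with attributes `target_r` and `realized_r` (variable x trait
#'   matrices).
#' @export
generate_sociodemographics <- function(config, truth) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "ground_truth"))
  specs <- config$sociodemo_specs
  if (is.null(specs)) stop("config has no sociodemo_specs")
  set.seed(derive_seed(config$seed, "sociodemo"))

  um <- as.matrix(truth$unit_trait_means[, config$traits, drop = FALSE])
  Z <- scale(um)
  Z[is.nan(Z)] <- 0  # zero between-unit variance => no trait signal
  n_units <- nrow(Z)

  out <- data.frame(unit = truth$unit_trait_means$unit,
                    stringsAsFactors = FALSE)
  tgt <- as.matrix(specs[, config$traits, drop = FALSE])
  rownames(tgt) <- specs$variable
  realized <- tgt * NA_real_
  for (v in seq_len(nrow(specs))) {
    r <- tgt[v, ]
    S <- sum(r^2)
    if (is.na(specs$noise_sd[v])) {
      if (S >= 1) {
        stop("invalid config: squared targets for '", specs$variable[v],
             "' sum to >= 1; cannot calibrate noise")
      }
      val <- as.numeric(Z %*% r) / sqrt(1 - S) + stats::rnorm(n_units)
    } else {
      val <- as.numeric(Z %*% r) + stats::rnorm(n_units, 0, specs$noise_sd[v])
    }
    out[[specs$variable[v]]] <- val
    realized[v, ] <- apply(um, 2, function(col) {
      if (stats::sd(col) == 0 || stats::sd(val) == 0) NA_real_
      else stats::cor(col, val)
    })
  }
  structure(out, target_r = tgt, realized_r = realized,
            class = c("sociodemo_table", "data.frame"))
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper: item bank, census, responses with ground truth, and
#' sociodemographic table from a single configuration.
#'
#' @param config a [synth_config()].
#' @param sample_id label stored on the response table.
#' @return list with `bank`, `census`, `responses`, `truth`, `sociodemo`.
#' @export
simulate_study <- function(config, sample_id = "synthetic") {
  bank <- generate_item_bank(config)
  census <- generate_census(config)
  gen <- generate_responses(config, bank, census, sample_id = sample_id)
  sociodemo <- if (is.null(config$sociodemo_specs)) NULL else
    generate_sociodemographics(config, gen$truth)
  gen$truth$sociodemo_true_r <- if (is.null(sociodemo)) NULL else
    attr(sociodemo, "realized_r")
  list(bank = bank, census = census, responses = gen$responses,
       truth = gen$truth, sociodemo = sociodemo)
}
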