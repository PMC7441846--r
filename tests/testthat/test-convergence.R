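test_that("weighted Pearson reduces, respects affine maps, matches brute force", {
  set.seed(401)
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(weighted_pearson(x, y, rep(2, 20)), stats::cor(x, y),
               tolerance = 1e-12)
  expect_equal(weighted_pearson(x, y, NULL), stats::cor(x, y),
               tolerance = 1e-12)
  w5 <- c(5, 1, 3, 2, 9)
  expect_equal(weighted_pearson(x[1:5], 2 * x[1:5] + 3, w5), 1,
               tolerance = 1e-12)

  # brute-force weighted-moments oracle on 5 units
  x5 <- c(3.2, 4.1, 3.8, 4.6, 3.0); y5 <- c(2.9, 4.4, 3.5, 4.2, 3.3)
  wn <- w5 / sum(w5)
  mx <- sum(wn * x5); my <- sum(wn * y5)
  oracle <- sum(wn * (x5 - mx) * (y5 - my)) /
    sqrt(sum(wn * (x5 - mx)^2) * sum(wn * (y5 - my)^2))
  expect_equal(weighted_pearson(x5, y5, w5), oracle, tolerance = 1e-12)

  expect_error(weighted_pearson(rep(1, 5), y[1:5], w5), "zero weighted variance")
  expect_error(weighted_pearson(x[1:2], y[1:2], c(1, 1)), "at least 3")
})

test_that("Fisher pooling averages on the z scale", {
  expect_equal(fisher_mean(rep(0.4, 7)), 0.4, tolerance = 1e-12)
  set.seed(402)
  rs <- runif(9, -0.8, 0.9)
  pooled <- fisher_mean(rs)
  expect_gte(pooled, min(rs)); expect_lte(pooled, max(rs))
  expect_equal(fisher_mean(sample(rs)), pooled, tolerance = 1e-12)
  expect_warning(out <- fisher_mean(c(1, 0.5)), "clipped")
  expect_lt(out, 1)
  expect_error(fisher_mean(numeric(0)), "empty")
})

test_that("pair design classification follows the period rules", {
  mk <- function(inv, proj, s, e) {
    data.frame(inventory = inv, project = proj, period_start = s,
               period_end = e, stringsAsFactors = FALSE)
  }
  # boundary-year hand-off -> adjacent
  c1 <- classify_pair_design(mk("BFI", "GP", 1999, 2005),
                             mk("BFI", "GP", 2005, 2009))
  expect_equal(c1, list(inventory = "S", project = "S", time = "A"))
  # five-year gap -> non-adjacent
  c2 <- classify_pair_design(mk("BFI", "GP", 1999, 2005),
                             mk("BFFM", "SAPA", 2010, 2015))
  expect_equal(c2$time, "N")
  expect_equal(c2$inventory, "D")
  # identical periods -> same
  c3 <- classify_pair_design(mk("TIPI", "RP", 2002, 2009),
                             mk("TIPI", "CCAP", 2002, 2009))
  expect_equal(c3$time, "S")
  expect_equal(c3$project, "D")
})

test_that("pairwise convergence enumerates pairs and is symmetric", {
  # seven tiny score tables over the same units
  set.seed(403)
  units <- us_units("contiguous49")
  meta <- published_sample_meta()
  tables <- lapply(meta$sample_id, function(sid) {
    df <- data.frame(unit = units, Openness = rnorm(49), Neuroticism = rnorm(49),
                     n = 100L, stringsAsFactors = FALSE)
    state_scores(df, sample_id = sid)
  })
  pan <- pairwise_convergence(tables, meta)
  expect_equal(nrow(pan), choose(7, 2) * 2)
  expect_equal(length(unique(paste(pan$sample_a, pan$sample_b))), 21)

  # self-pair correlates 1 on every trait
  attr2 <- tables[[1]]; attr(attr2, "sample_id") <- "copy"
  self <- pairwise_convergence(list(tables[[1]], attr2),
                               rbind(meta[1, ],
                                     transform(meta[1, ], sample_id = "copy")))
  expect_equal(self$r, c(1, 1), tolerance = 1e-12)

  # symmetry under list order reversal
  pan_rev <- pairwise_convergence(tables[c(2, 1)], meta)
  a <- pan[pan$sample_a == meta$sample_id[1] & pan$sample_b == meta$sample_id[2], ]
  b <- pan_rev[order(pan_rev$trait), ]
  expect_equal(b$r, a[order(a$trait), "r"], tolerance = 1e-12)
})

test_that("group means pool on the published panel structure", {
  pan <- published_pair_panel()
  gm <- group_means(pan)
  # single-pair class mean equals that pair's Fisher mean
  sdn <- gm[gm$scope == "class" & gm$inv == "D" & gm$time == "N", ]
  pair <- pan[pan$sample_a == "Sample1" & pan$sample_b == "SAPA2015", ]
  expect_equal(sdn$r, fisher_mean(pair$r), tolerance = 1e-12)
  # grand mean equals Fisher mean of per-trait means (equal pair counts)
  per_trait <- gm$r[gm$scope == "trait"]
  expect_equal(gm$r[gm$scope == "grand"], fisher_mean(per_trait),
               tolerance = 1e-10)
})

test_that("disattenuation follows the reliability algebra", {
  expect_equal(disattenuate(0.5, 1, 1), 0.5)
  expect_gt(disattenuate(0.5, 0.8, 0.7), 0.5)  # raw <= adjusted
  expect_error(disattenuate(0.5, 0, 0.7), "positive")
  # may exceed 1 and is reported unclipped
  expect_gt(disattenuate(0.9, 0.7, 0.7), 1)
})

test_that("degenerate duplicate split returns full-sample cross correlations", {
  inv2 <- data.frame(name = c("A", "B"), items_per_trait = c(6, 6),
                     sampling_rate = c(0.8, 0.8))
  cfg <- synth_config(n_units = 10, n_participants = 800, inventories = inv2,
                      between_unit_sd = 0.2, seed = 404)
  sim <- simulate_study(cfg)
  w <- sim$census$populations
  sh <- split_half_bootstrap(sim$responses, sim$bank, c("A", "B"),
                             split = "duplicate", w = w)
  # oracle: correlate the full-sample aggregated tables directly
  ta <- aggregate_states(score_scales(sim$responses, sim$bank, "A"))
  tb <- aggregate_states(score_scales(sim$responses, sim$bank, "B"))
  units <- intersect(ta$unit, tb$unit)
  for (tr in cfg$traits) {
    oracle <- weighted_pearson(ta[[tr]][match(units, ta$unit)],
                               tb[[tr]][match(units, tb$unit)],
                               unname(w[units]))
    expect_equal(sh$raw["A", "B", tr], oracle, tolerance = 1e-9)
    expect_equal(sh$raw["B", "A", tr], oracle, tolerance = 1e-9)
  }
  # same-inventory duplicate halves correlate ~1
  expect_true(all(sh$reliability > 1 - 1e-6))
})

test_that("identical inventories converge to 1 under the duplicate split", {
  inv2 <- data.frame(name = c("A", "B"), items_per_trait = c(6, 6),
                     sampling_rate = 1, share_with = c(NA, "A"),
                     share_frac = c(0, 1))
  cfg <- synth_config(n_units = 10, n_participants = 300, inventories = inv2,
                      between_unit_sd = 0.3, item_noise_sd = 0.4, seed = 405)
  sim <- simulate_study(cfg)
  sh <- split_half_bootstrap(sim$responses, sim$bank, c("A", "B"),
                             split = "duplicate")
  expect_true(all(abs(sh$raw - 1) < 1e-6))
  expect_true(all(abs(sh$adjusted - 1) < 1e-6))
})

test_that("split-half bootstrap recovers latent convergence after adjustment", {
  inv2 <- data.frame(name = c("A", "B"), items_per_trait = c(8, 8),
                     sampling_rate = 0.9)
  cfg <- synth_config(n_units = 20, n_participants = 6000, inventories = inv2,
                      between_unit_sd = 0.25, seed = 406)
  sim <- simulate_study(cfg)
  sh <- split_half_bootstrap(sim$responses, sim$bank, c("A", "B"),
                             iterations = 40, seed = 407,
                             w = sim$census$populations)
  for (tr in cfg$traits) {
    # both inventories measure the same latent trait: adjusted ~ 1
    expect_gt(sh$adjusted["A", "B", tr], 0.85)
    expect_lt(sh$adjusted["A", "B", tr], 1.15)
    # raw is attenuated below adjusted for positive r and rel < 1
    expect_lte(sh$raw["A", "B", tr], sh$adjusted["A", "B", tr])
  }
  expect_identical(dim(sh$raw), c(2L, 2L, 5L))
})
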