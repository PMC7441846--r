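test_that("weighted partial correlation nests its special cases", {
  set.seed(601)
  x <- rnorm(12); y <- rnorm(12); w <- runif(12, 0.5, 3)
  expect_equal(weighted_partial_correlation(x, y, NULL, w),
               weighted_pearson(x, y, w), tolerance = 1e-12)

  # y an exact linear function of a control -> nothing left to correlate
  ctrl <- data.frame(c1 = rnorm(12))
  expect_lt(abs(weighted_partial_correlation(x, 2 * ctrl$c1 - 1, ctrl, w)),
            1e-10)

  # collinear controls are named in the error
  bad <- data.frame(c1 = ctrl$c1, c2 = 2 * ctrl$c1)
  expect_error(weighted_partial_correlation(x, y, bad, w), "singular")
})

test_that("matrix-inversion route matches the residualization oracle", {
  set.seed(602)
  for (i in 1:20) {
    n <- 6 + i %% 5
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    ctrl <- data.frame(c1 = rnorm(n) + 0.3 * x, c2 = rnorm(n))
    w <- runif(n, 0.2, 4)
    got <- weighted_partial_correlation(x, y, ctrl, w)
    # oracle: correlate residuals of weighted least-squares fits
    rx <- stats::resid(stats::lm(x ~ c1 + c2, data = ctrl, weights = w))
    ry <- stats::resid(stats::lm(y ~ c1 + c2, data = ctrl, weights = w))
    oracle <- weighted_pearson(rx, ry, w)
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("equal weights agree with the unweighted partial correlation", {
  set.seed(603)
  x <- rnorm(15); y <- rnorm(15)
  ctrl <- data.frame(c1 = rnorm(15), c2 = rnorm(15), c3 = rnorm(15))
  got <- weighted_partial_correlation(x, y, ctrl, rep(1, 15))
  rx <- stats::resid(stats::lm(x ~ ., data = ctrl))
  ry <- stats::resid(stats::lm(y ~ ., data = ctrl))
  expect_equal(got, stats::cor(rx, ry), tolerance = 1e-8)
})

test_that("panel enumerates every sample x trait x variable cell", {
  set.seed(604)
  units <- us_units("contiguous48")
  tables <- lapply(sprintf("S%d", 1:7), function(sid) {
    df <- cbind(data.frame(unit = units),
                as.data.frame(matrix(rnorm(48 * 5), 48,
                                     dimnames = list(NULL, big_five()))),
                data.frame(n = 50L))
    state_scores(df, sample_id = sid)
  })
  socio <- cbind(data.frame(unit = units),
                 as.data.frame(matrix(rnorm(48 * 13), 48,
                                      dimnames = list(NULL, sprintf("v%02d", 1:13)))))
  pnl <- build_panel(tables, socio, unit_subset = "contiguous48")
  expect_equal(nrow(pnl), 7 * 5 * 13)
  expect_true(all(abs(pnl$r) <= 1))

  raw <- build_panel(tables[1], socio, partialled = FALSE)
  t1 <- tables[[1]]
  expect_equal(
    raw$r[raw$trait == "Openness" & raw$variable == "v01"],
    weighted_pearson(t1$Openness, socio$v01, NULL),
    tolerance = 1e-12
  )
})

test_that("replication correlation pairs old and new panels", {
  mk_panel <- function(sid, rs) {
    data.frame(sample_id = sid, trait = "Openness",
               variable = sprintf("v%d", seq_along(rs)), r = rs,
               partialled = TRUE, n_units = 48L, stringsAsFactors = FALSE)
  }
  old <- rbind(mk_panel("o1", c(0.5, -0.2, 0.1)),
               mk_panel("o2", c(0.4, -0.1, 0.0)))
  new1 <- mk_panel("n1", c(0.45, -0.15, 0.05))

  # hand oracle over the 2 x 1 x 3 = 6 pairs
  pairs_old <- c(0.5, 0.4, -0.2, -0.1, 0.1, 0.0)
  pairs_new <- c(0.45, 0.45, -0.15, -0.15, 0.05, 0.05)
  rep1 <- replication_correlation(old, new1, "Openness")
  expect_equal(rep1$n_pairs, 6)
  expect_equal(rep1$replication_r, stats::cor(pairs_old, pairs_new),
               tolerance = 1e-12)

  # a new panel identical to an old one replicates perfectly
  ident <- transform(mk_panel("o1", c(0.5, -0.2, 0.1)), sample_id = "n")
  expect_equal(replication_correlation(old[1:3, ], ident)$replication_r, 1)
  neg <- transform(ident, r = -r)
  expect_equal(replication_correlation(old[1:3, ], neg)$replication_r, -1)

  # invariant to the order of variables and samples
  shuf <- old[sample(nrow(old)), ]
  expect_equal(replication_correlation(shuf, new1, "Openness")$replication_r,
               rep1$replication_r, tolerance = 1e-12)
})

test_that("correlation range scans a trait's panel values", {
  pnl <- data.frame(sample_id = "s", trait = "Openness",
                    variable = c("a", "b", "c"), r = c(-0.5, 0.6, 0.1),
                    partialled = TRUE, n_units = 48L)
  expect_equal(correlation_range(pnl, "Openness"), 1.1)
  pnl$r <- 0.3
  expect_equal(correlation_range(pnl, "Openness"), 0)
  expect_error(correlation_range(pnl, "Neuroticism"), "absent")

  # brute-force scan oracle on a random panel
  set.seed(605)
  pnl2 <- data.frame(sample_id = "s", trait = "T", variable = letters[1:10],
                     r = runif(10, -1, 1), partialled = FALSE, n_units = 48L)
  expect_equal(correlation_range(pnl2, "T"), max(pnl2$r) - min(pnl2$r))
})

test_that("critical r follows the t transform and shrinks with n", {
  # t-quantile oracle at the smallest admissible n (1 df)
  t1 <- stats::qt(0.975, 1)
  expect_equal(critical_r(3), t1 / sqrt(t1^2 + 1), tolerance = 1e-12)
  ns <- c(5, 10, 48, 100, 1000)
  expect_true(all(diff(critical_r(ns)) < 0))
  expect_error(critical_r(2), "n >= 3")
  expect_error(critical_r(48, 1.5), "alpha")
})

test_that("panel cells recover the generator's sociodemographic structure", {
  # score tables built from the latent unit means reproduce realized_r exactly
  truth <- shared_sim$truth$unit_trait_means
  tab <- state_scores(
    cbind(truth, data.frame(n = 1L)),
    traits = shared_cfg$traits, sample_id = "latent"
  )
  pnl <- build_panel(list(tab), shared_sim$sociodemo, partialled = FALSE)
  realized <- attr(shared_sim$sociodemo, "realized_r")
  for (i in seq_len(nrow(pnl))) {
    expect_equal(pnl$r[i], realized[pnl$variable[i], pnl$trait[i]],
                 tolerance = 1e-10)
  }

  # aggregated sample scores recover the same cells up to attenuation noise
  pnl_s <- build_panel(list(shared_table), shared_sim$sociodemo,
                       partialled = FALSE)
  key <- paste(pnl$trait, pnl$variable)
  expect_gt(stats::cor(pnl$r, pnl_s$r[match(key, paste(pnl_s$trait,
                                                       pnl_s$variable))]),
            0.4)
})
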