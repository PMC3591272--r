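test_that("noise statistics match hand arithmetic and exact identities", {
  pop <- structure(data.frame(fsc = c(1, 1), ssc = c(1, 1),
                              yfp = c(10, 20), mcherry = c(1, 2)),
                   strain_id = "s", condition = 0.1,
                   class = c("CellPopulation", "data.frame"))
  ns <- population_noise_stats(pop)
  expect_equal(ns$mean, 15)
  expect_equal(ns$variance, 50)       # unbiased (n - 1)
  expect_equal(ns$noise, 50 / 225)
  expect_equal(ns$noise_strength, 50 / 15)
  # identities hold to machine precision for arbitrary populations
  set.seed(91)
  for (i in 1:20) {
    p <- simulate_cell_population(runif(1, 1, 20), runif(1, 10, 500),
                                  n_cells = 1000, seed = i)
    s <- population_noise_stats(p)
    expect_equal(s$noise_strength, s$noise * s$mean, tolerance = 1e-12)
    expect_equal(s$burst_frequency * s$burst_size, s$mean,
                 tolerance = 1e-12)
  }
})

test_that("noise statistics transform correctly under a gain change", {
  pop <- simulate_cell_population(8, 70, n_cells = 5000, seed = 2)
  s1 <- population_noise_stats(pop)
  pop$yfp <- pop$yfp * 3
  s2 <- population_noise_stats(pop)
  expect_equal(s2$mean, 3 * s1$mean)
  expect_equal(s2$noise, s1$noise)                 # dimensionless
  expect_equal(s2$noise_strength, 3 * s1$noise_strength)
})

test_that("burst parameters are recovered across the (a, b) grid", {
  # moderate grid here; the full 100-replicate sweep runs in the
  # acceptance suite
  for (a in c(2, 10)) {
    for (b in c(10, 1000)) {
      pop <- simulate_cell_population(a, b, n_cells = 1e5,
                                      seed = 1000 * a + b)
      s <- population_noise_stats(pop)
      expect_lt(abs(s$burst_frequency - a) / a, 0.05)
      expect_lt(abs(s$burst_size - b) / b, 0.05)
    }
  }
})

test_that("gating removes planted spores but spares homogeneous scatter", {
  pop <- simulate_cell_population(10, 100, n_cells = 2e4, extrinsic_cv = 0.3,
                                  spore_frac = 0.05, seed = 3)
  g <- gate_cells(pop)
  spore_before <- sum(attr(pop, "spore"))
  spore_after <- sum(attr(g, "spore"))
  expect_gte(1 - spore_after / spore_before, 0.90)
  # homogeneous lognormal population: removal stays near the expected
  # robust-band tail fraction (Monte-Carlo oracle on an independent draw)
  pop0 <- simulate_cell_population(10, 100, n_cells = 2e4, seed = 4)
  g0 <- gate_cells(pop0)
  set.seed(5)
  tail_frac <- local({
    x <- rlnorm(2e5, log(100), 0.25)
    y <- rlnorm(2e5, log(80), 0.30)
    1 - mean(threeprime:::in_robust_band(x, 2.5) &
               threeprime:::in_robust_band(y, 2.5))
  })
  expect_lte(attr(g0, "gate_report")$frac_removed_total, 2 * tail_frac)
})

test_that("gating keeps identical-scatter populations intact and over-gating errors", {
  pop <- structure(data.frame(fsc = rep(5, 600), ssc = rep(7, 600),
                              yfp = rlnorm(600), mcherry = rlnorm(600)),
                   class = c("CellPopulation", "data.frame"))
  g <- gate_cells(pop)
  expect_identical(nrow(g), 600L)
  expect_error(gate_cells(pop[1:100, ]), "min_cells")
  tiny <- gate_spec(k = 0.0001, min_cells = 590L)
  mixed <- simulate_cell_population(5, 50, n_cells = 600, seed = 1)
  expect_error(gate_cells(mixed, tiny), "over-gated")
})

test_that("plate correction rescales means and noise consistently", {
  stats <- data.frame(
    strain_id = c("REF", "s1", "REF", "s1"),
    plate = c("p1", "p1", "p2", "p2"),
    mean = c(120, 40, 80, 40),
    noise = c(0.1, 0.2, 0.1, 0.2))
  stats$noise_strength <- stats$noise * stats$mean
  out <- plate_correct(stats, "REF")
  # grand reference mean 100; plate p2 factor = 100/80 = 1.25
  expect_equal(out$mean[out$plate == "p2" & out$strain_id == "s1"], 50)
  expect_equal(out$noise[out$plate == "p2" & out$strain_id == "s1"],
               0.2 / 1.25)
  # noise_strength' = noise' * mean' preserves noise * mean
  expect_equal(out$noise_strength, out$noise * out$mean)
  expect_equal(out$noise_strength[2], 0.2 * 40)
  # identity correction leaves everything unchanged
  same <- stats
  same$mean[same$strain_id == "REF"] <- 100
  out2 <- plate_correct(same, "REF")
  expect_equal(out2$mean, same$mean)
  expect_equal(out2$noise, same$noise)
  bad <- stats[stats$strain_id != "REF" | stats$plate != "p2", ]
  expect_error(plate_correct(bad, "REF"), "p2")
})

test_that("plate factors planted by simulation are corrected away", {
  set.seed(17)
  base <- simulate_cell_population(10, 100, n_cells = 2e4, seed = 31)
  factor_p2 <- 1.6
  rows <- list()
  for (p in c("p1", "p2")) {
    f <- if (p == "p2") factor_p2 else 1
    for (s in c("REF", "strainA")) {
      pop <- simulate_cell_population(10, if (s == "REF") 80 else 100,
                                      n_cells = 2e4,
                                      seed = 7 * (s == "REF") + 13 * (p == "p2"))
      pop$yfp <- pop$yfp * f
      ns <- population_noise_stats(pop)
      ns$strain_id <- s
      ns$plate <- p
      rows[[length(rows) + 1L]] <- as.data.frame(ns)
    }
  }
  stats <- do.call(rbind, rows)
  out <- plate_correct(stats, "REF")
  means <- out$mean[out$strain_id == "strainA"]
  expect_lt(abs(diff(means)) / mean(means), 0.03)
})

test_that("nested F-test agrees with the brute-force oracle", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    p <- sample(1:3, 1)
    xr <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("r", 1:p)))
    extra <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("e1", "e2")))
    xf <- cbind(xr, extra)
    y <- rnorm(n)
    got <- nested_regression_ftest(y, xr, xf)
    want <- oracle_nested_f(y, xr, xf)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$rss_full, want$rss_f, tolerance = 1e-8)
    expect_lte(got$rss_full, got$rss_reduced + 1e-12)
    expect_gte(got$r2_full, got$r2_reduced - 1e-12)
  }
})

test_that("perfect-fit limit drives the F statistic to infinity", {
  x1 <- c(1, 2, 3, 4, 5)
  x2 <- c(0, 0, 0, 0, 1)
  y <- c(1, 2, 3, 4, 6)     # exactly x1 + x2
  res <- nested_regression_ftest(y, cbind(x1 = x1), cbind(x1 = x1, x2 = x2))
  oracle <- oracle_nested_f(y, cbind(x1), cbind(x1, x2))
  expect_equal(res$rss_reduced, 0.4, tolerance = 1e-10)
  expect_equal(res$rss_reduced, oracle$rss_r, tolerance = 1e-10)
  expect_lt(res$rss_full, 1e-20)
  expect_gt(res$F, 1e10)
  expect_lt(res$p, 1e-10)
})

test_that("nested F-test rejects invalid designs", {
  y <- rnorm(10)
  x <- matrix(rnorm(10), 10, dimnames = list(NULL, "a"))
  expect_error(nested_regression_ftest(y, x, x), "no predictors")
  xf <- cbind(a = x[, 1], b = x[, 1])  # collinear
  expect_error(nested_regression_ftest(y, x, xf), "collinear")
  other <- matrix(rnorm(10), 10, dimnames = list(NULL, "z"))
  expect_error(nested_regression_ftest(y, other, cbind(b = rnorm(10), c = rnorm(10))),
               "subset")
})

test_that("orientation comparison reports maximal p for identical groups", {
  df <- data.frame(
    expression = rep(c(1, 2, 3, 4, 5), 2),
    orientation = rep(c("tandem", "convergent"), each = 5),
    intergenic_length = rep(c(100, 200, 300, 400, 500), 2))
  out <- orientation_group_compare(df)
  expect_gte(out$rank_sum$p.value, 0.99)
  expect_equal(out$ecdf$p.value, 1)
  # covariate equal to expression gives rho exactly 1
  df$cov2 <- df$expression
  out2 <- orientation_group_compare(df, covariates = "cov2")
  expect_equal(out2$by_group$rho, rep(1, nrow(out2$by_group)))
  # constant covariate: undefined marker, not a crash
  df$flat <- 5
  out3 <- orientation_group_compare(df, covariates = "flat")
  expect_true(all(is.na(out3$by_group$rho)))
})

test_that("planted library shows no orientation effect on expression", {
  # the generator ties expression to window A/T only, so tandem and
  # convergent constructs must be statistically indistinguishable
  lib <- generate_construct_library(85, seed = 19)
  out <- orientation_group_compare(lib$constructs)
  expect_gt(out$rank_sum$p.value, 0.01)
  expect_gt(out$ecdf$p.value, 0.01)
})

test_that("strongly shifted orientation groups are detected", {
  set.seed(111)
  df <- data.frame(
    expression = c(rnorm(40, 0, 1), rnorm(40, 5, 1)),
    orientation = rep(c("tandem", "convergent"), each = 40),
    intergenic_length = runif(80, 100, 1000))
  out <- orientation_group_compare(df)
  expect_lt(out$rank_sum$p.value, 1e-6)
  expect_lt(out$ecdf$p.value, 1e-6)
})
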