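test_that("background subtraction uses the right role per channel", {
  t4 <- c(0, 600, 1200, 1800)
  tc <- time_course("w", "s", t4, c(1.1, 1.2, 1.3, 1.4),
                    c(10, 20, 30, 40), c(5, 6, 7, 8))
  blanks <- list(
    media_blank = time_course("m", "media", t4, rep(0.1, 4), rep(0, 4),
                              rep(0, 4)),
    yfp_background_strain = time_course("yb", "b1", t4, rep(0.1, 4),
                                        rep(2, 4), rep(99, 4)),
    mcherry_background_strain = time_course("mb", "b2", t4, rep(0.1, 4),
                                            rep(99, 4), rep(1, 4))
  )
  out <- subtract_background(tc, blanks)
  expect_equal(out$od, c(1.0, 1.1, 1.2, 1.3))
  expect_equal(out$yfp, c(8, 18, 28, 38))
  expect_equal(out$mcherry, c(4, 5, 6, 7))
})

test_that("OD is floored at zero and flagged; fluorescence may go negative", {
  t4 <- c(0, 600, 1200, 1800)
  tc <- time_course("w", "s", t4, c(0.05, 0.2, 0.3, 0.4),
                    c(1, 2, 3, 4), c(1, 2, 3, 4))
  blanks <- list(
    media_blank = time_course("m", "x", t4, c(0.1, 0.1, 0.1, 0.1),
                              rep(0, 4), rep(0, 4)),
    yfp_background_strain = time_course("yb", "x", t4, rep(0, 4),
                                        rep(2, 4), rep(0, 4)),
    mcherry_background_strain = time_course("mb", "x", t4, rep(0, 4),
                                            rep(0, 4), rep(0, 4))
  )
  out <- subtract_background(tc, blanks)
  expect_equal(out$od[1], 0)
  expect_equal(attr(out, "qc")$od_points_floored, 1L)
  expect_equal(out$yfp[1], -1)   # left as-is
  blanks$media_blank <- NULL
  expect_error(subtract_background(tc, blanks), "media_blank")
})

test_that("point outlier rule flags spikes, not trends or constants", {
  expect_identical(which(remove_point_outliers(c(1, 1, 1, 9, 1, 1, 1),
                                               k = 3, w = 3)), 4L)
  expect_identical(which(remove_point_outliers(1:10, k = 3, w = 3)),
                   integer(0))
  expect_identical(which(remove_point_outliers(rep(2, 10), k = 5, w = 5)),
                   integer(0))
  expect_error(remove_point_outliers(1:10, w = 4), "odd")
  expect_error(remove_point_outliers(1:4, w = 5), "length")
})

test_that("spikes on an exponential rise are caught; QC warns on heavy masking", {
  t <- seq_len(60)
  y <- 10 * exp(0.1 * t)
  y[25] <- y[25] * 4
  flags <- remove_point_outliers(y, k = 5, w = 5)
  expect_identical(which(flags), 25L)
  heavy <- rep(1, 20)
  heavy[c(5, 10, 15)] <- 50   # 15% of points are spikes
  f2 <- remove_point_outliers(heavy, k = 3, w = 3)
  expect_false(is.null(attr(f2, "qc_warning")))
})

test_that("simulator-planted spikes are recovered at stated sensitivity and FPR", {
  strains <- data.frame(strain_id = sprintf("s%d", 1:6),
                        production = c(0.5, 1, 2, 3, 4, 6))
  sim <- simulate_plate_timecourses(strains, seed = 42, spike_rate = 0.02)
  spk <- sim$truth$spikes
  # the rule itself, channel by channel on the raw simulated series
  hits <- misses <- fps <- n_clean <- 0
  for (w in names(sim$samples)) {
    for (ch in c("od", "yfp", "mcherry")) {
      truth_idx <- spk$index[spk$well == w & spk$channel == ch]
      flagged <- which(remove_point_outliers(sim$samples[[w]][[ch]]))
      hits <- hits + sum(truth_idx %in% flagged)
      misses <- misses + sum(!truth_idx %in% flagged)
      fps <- fps + length(setdiff(flagged, truth_idx))
      n_clean <- n_clean + length(sim$samples[[w]][[ch]]) - length(truth_idx)
    }
  }
  expect_gte(hits / (hits + misses), 0.95)
  expect_lte(fps / n_clean, 0.01)

  # full pipeline (subtraction + iterated masking) still catches spikes
  blanks <- lapply(sim$backgrounds, threeprime:::clean_background_timecourse)
  hits2 <- misses2 <- 0
  for (w in names(sim$samples)) {
    tc <- mask_timecourse_outliers(subtract_background(sim$samples[[w]], blanks))
    truth_idx <- unique(spk$index[spk$well == w])
    hits2 <- hits2 + sum(truth_idx %in% which(!tc$mask))
    misses2 <- misses2 + sum(!truth_idx %in% which(!tc$mask))
  }
  expect_gte(hits2 / (hits2 + misses2), 0.95)
})

test_that("phase segmentation matches the closed-form logistic oracle", {
  g <- list(K = 1.0, od0 = 0.05, r = log(2) / 6000, lag = 0)
  t <- seq(0, 86400, by = 1200)
  od <- g$K * g$od0 * exp(g$r * t) / (g$K - g$od0 + g$od0 * exp(g$r * t))
  tc <- time_course("w", "s", t, od, od * 10, od * 5)
  ph <- segment_growth_phases(tc)
  # oracle: d log OD/dt = r (1 - OD/K); boundary where it crosses
  # expo_frac * its max over the samples
  slope <- g$r * (1 - od / g$K)
  thr <- 0.55 * max(slope)
  t_true <- t[min(which(slope < thr))]
  expect_lte(abs(ph$exponential[2] - t_true), 2 * 1200)
  expect_equal(ph$exponential[1], 0)
})

test_that("pure exponential growth is classified as exponential nearly everywhere", {
  t <- seq(0, 20000, by = 500)
  od <- 0.05 * exp(2e-4 * t)
  tc <- time_course("w", "s", t, od, od, od)
  ph <- segment_growth_phases(tc)
  expect_gte(diff(ph$exponential) / diff(range(t)), 0.9)
})

test_that("flat OD raises a no-growth error, never a degenerate phase set", {
  t <- seq(0, 10000, by = 1000)
  tc <- time_course("w", "s", t, rep(0.05, length(t)), seq_along(t),
                    seq_along(t))
  expect_error(segment_growth_phases(tc), "no growth")
})

test_that("growth phase container enforces ordering and contiguity", {
  expect_error(growth_phases(c(0, 10), c(10, 10), c(10, 20), c(20, 30)),
               "positive duration")
  expect_error(growth_phases(c(0, 10), c(12, 20), c(20, 25), c(25, 30)),
               "contiguous")
})

test_that("production integrates to the known rate on analytic inputs", {
  # OD = 1 for 10,000 s, YFP rising 0 -> 10,000 linearly: rate exactly 1
  tc <- toy_timecourse(n = 11L, dt = 1000, od = 1, yfp_rate = 1)
  ph <- growth_phases(c(0, 0), c(0, 10000 + 1), c(10001, 10001),
                      c(10001, 10001))
  m <- production_per_cell(tc, ph)
  expect_equal(m$production, 1.0, tolerance = 1e-9)
  # constant YFP: production 0
  tc0 <- time_course("w", "s", tc$times, tc$od, rep(5, 11), tc$mcherry)
  expect_equal(production_per_cell(tc0, ph)$production, 0)
})

test_that("production transforms exactly under gain and time rescaling", {
  tc <- toy_timecourse(n = 20L, dt = 500, od = 2, yfp_rate = 3)
  ph <- growth_phases(c(0, 0), c(0, 9500 + 1), c(9501, 9501), c(9501, 9501))
  p0 <- production_per_cell(tc, ph)$production
  # gain g on fluorescence multiplies production by exactly g
  tc_g <- time_course("w", "s", tc$times, tc$od, tc$yfp * 7, tc$mcherry)
  expect_equal(production_per_cell(tc_g, ph)$production, 7 * p0)
  # uniform time rescaling divides the rate by the same factor
  tc_t <- time_course("w", "s", tc$times * 2, tc$od, tc$yfp, tc$mcherry)
  ph2 <- growth_phases(c(0, 0), c(0, 19001), c(19001, 19001), c(19001, 19001))
  expect_equal(production_per_cell(tc_t, ph2)$production, p0 / 2)
})

test_that("masked points are excluded from the production computation", {
  tc <- toy_timecourse(n = 12L, dt = 1000, od = 1, yfp_rate = 1)
  tc$yfp[6] <- 1e6
  tc$mask[6] <- FALSE
  ph <- growth_phases(c(0, 0), c(0, 11001), c(11001, 11001), c(11001, 11001))
  expect_equal(production_per_cell(tc, ph)$production, 1.0, tolerance = 1e-9)
})

test_that("mCherry control channel is tight across simulated library strains", {
  strains <- data.frame(strain_id = sprintf("s%d", 1:10),
                        production = exp(seq(log(0.5), log(6),
                                             length.out = 10)))
  sim <- simulate_plate_timecourses(strains, seed = 11)
  res <- plate_expression(sim, channel = "mcherry")
  expect_lte(sd(res$production) / mean(res$production),
             2 * sim$truth$noise_cv)
})

test_that("clone concordance filter accepts, rejects and defers correctly", {
  m <- data.frame(
    strain_id = c("a", "a", "a", "b", "b", "c"),
    production = c(1.00, 1.10, 2.0, 1.0, 2.0, 5))
  out <- concordant_clone_filter(m, tol = 0.15)
  a <- out[out$strain_id == "a", ]
  expect_identical(a$status, "accepted")
  expect_equal(a$value, 1.05)
  expect_identical(out$status[out$strain_id == "b"], "rejected")
  expect_identical(out$status[out$strain_id == "c"], "unvalidated")
  ident <- concordant_clone_filter(
    data.frame(strain_id = "d", production = c(1, 1, 1))[c(1, 1, 1), ])
  expect_equal(ident$value, 1)
})
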