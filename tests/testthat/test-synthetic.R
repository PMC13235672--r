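# Ground-truth generator: determinism, defect injection, effect recovery.

test_that("the generator is fully deterministic under the seed", {
  cfg <- small_config(seed = 77)
  s1 <- generate_scene(cfg, extent = c(0, 1100, 0, 1100))
  s2 <- generate_scene(cfg, extent = c(0, 1100, 0, 1100))
  expect_identical(s1, s2)
  t1 <- generate_trips(s1, cfg)
  t2 <- generate_trips(s2, cfg)
  expect_identical(t1, t2)
  # and a different seed changes the draw
  s3 <- generate_scene(small_config(seed = 78), extent = c(0, 1100, 0, 1100))
  expect_false(identical(s1$ndvi, s3$ndvi))
})

test_that("generator calls do not disturb the caller's RNG stream", {
  set.seed(123); a <- runif(3)
  set.seed(123); invisible(generate_scene(small_config(1),
                                          extent = c(0, 1000, 0, 1000)))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("degenerate or undersized extents are rejected", {
  cfg <- small_config()
  expect_error(generate_scene(cfg, extent = c(0, 0, 0, 100)), "degenerate")
  expect_error(generate_scene(cfg, extent = c(0, 500, 0, 500)), "1 km")
})

test_that("a single archetype produces one homogeneous profile", {
  cfg <- small_config(seed = 79, n_archetypes = 1)
  sc <- generate_scene(cfg, extent = c(0, 1100, 0, 1100))
  expect_equal(length(unique(sc$archetype)), 1L)
  # between-cell NDVI spread stays at the within-archetype noise scale
  expect_lt(sd(sc$ndvi), 2 * sqrt(0.05^2 + 0.03^2))
})

test_that("identical archetype profiles remove recoverable structure", {
  prof <- walkscape:::archetype_profiles(4)
  prof[2:4, -1] <- prof[rep(1, 3), -1]
  cfg <- small_config(seed = 80)
  # smooth fields off: they would create real (non-archetype) spatial
  # clusters and the point here is that no profile-driven structure remains
  sc <- generate_scene(cfg, extent = c(0, 1100, 0, 1100), profiles = prof,
                       field_ndvi_sd = 0, field_noise_sd = 0)
  skip_if_not_installed("mclust")
  feat <- scale(scene_cell_features(sc))
  km <- with_seed_test(3, stats::kmeans(feat, 4, nstart = 5))
  expect_lt(abs(mclust::adjustedRandIndex(km$cluster, sc$archetype)), 0.05)
})

test_that("scene invariants: proportions sum to one, NDVI in range", {
  sc <- small_scene(81)
  expect_true(all(sc$ndvi >= -1 & sc$ndvi <= 1))
  props <- as.matrix(sc$images[, image_classes()])
  expect_true(all(abs(rowSums(props) - 1) < 1e-9))
  expect_true(all(props >= 0))
})

test_that("zero defect rates leave every stream intact through cleaning", {
  cfg <- small_config(seed = 82, teleport_rate = 0, dwell_rate = 0)
  sc <- small_scene(82)
  st <- generate_trips(sc, cfg)
  for (s in st) {
    cl <- clean_stream(s)
    expect_equal(nrow(cl), nrow(s))
    expect_equal(attr(cl, "n_dropped_gap"), 0L)
  }
})

test_that("teleport rate 1 injects exactly one >500-m jump per stream", {
  cfg <- small_config(seed = 83, teleport_rate = 1)
  sc <- small_scene(83)
  st <- generate_trips(sc, cfg)
  for (s in st) {
    n <- nrow(s)
    d <- haversine_m(cbind(s$lat[-n], s$lon[-n]), cbind(s$lat[-1], s$lon[-1]))
    expect_equal(sum(d > 500), 2)  # into and out of the displaced fix
    cl <- clean_stream(s)
    expect_equal(attr(cl, "n_dropped_gap"), 1L)
    expect_equal(nrow(cl), n - 1L)
    gt <- attr(s, "ground_truth")
    expect_false(gt$teleport_idx %in%
                   match(cl$time_s, s$time_s))
  }
})

test_that("injected dwells split streams at the stored ground truth", {
  cfg <- small_config(seed = 84, dwell_rate = 1, dwell_s = 300)
  sc <- small_scene(84)
  st <- generate_trips(sc, cfg)
  for (s in st[1:4]) {
    gt <- attr(s, "ground_truth")
    trips <- segment_trips(clean_stream(s))
    expect_equal(length(trips), nrow(gt$segments))
    for (k in seq_along(trips)) {
      expect_lte(abs(trips[[k]]$times[1] - gt$segments$start_s[k]), 120)
      expect_lte(abs(max(trips[[k]]$times) - gt$segments$end_s[k]), 120)
    }
  }
})

test_that("generated walks have plausible speeds at 1 fix per second", {
  cfg <- small_config(seed = 85)
  sc <- small_scene(85)
  s <- generate_trips(sc, cfg)[[1]]
  n <- nrow(s)
  expect_equal(diff(s$time_s), rep(1, n - 1))
  d <- haversine_m(cbind(s$lat[-n], s$lon[-n]), cbind(s$lat[-1], s$lon[-1]))
  expect_gt(mean(d), 0.7)
  expect_lt(mean(d), 2.0)
})

test_that("zero SCR rate gives a flat phasic component and no events", {
  cfg <- small_config(seed = 86, scr_rate = 0, physio_betas = c())
  sc <- small_scene(86)
  tr <- segment_trips(clean_stream(generate_trips(sc, cfg)[[1]]))[[1]]
  ses <- generate_physio(tr, sc, cfg, seed = 1)
  out <- summarize_trip(ses)
  expect_equal(out$scr_count, 0)
  d <- eda_decompose(eda_smooth(ses$eda$uS))
  expect_lt(max(abs(d$phasic)), 0.05)
})

test_that("trips shorter than two minutes are refused by the physio generator", {
  sc <- small_scene(87)
  fake <- structure(list(trip_id = "X", duration_s = 90), class = "walking_trip")
  expect_error(generate_physio(fake, sc, small_config(87)), "2 min")
})

test_that("rating generation respects scales, clipping and the zero case", {
  cfg0 <- small_config(seed = 88, rating_betas = c(),
                       random_intercept_sd = 0, residual_sd = 0)
  tab <- data.frame(participant_id = rep(c("A", "B"), 50),
                    ndvi_mean = rnorm(100))
  out0 <- generate_ratings(tab, cfg0, discretize = FALSE, seed = 1)
  expect_true(all(out0$trip_feeling_env == 2.5))  # grand mean of 0-5
  expect_true(all(out0$unwell_well == 3.5))
  # discretized: every rating collapses to the same integer
  outd <- generate_ratings(tab, cfg0, seed = 1)
  for (oc in rating_outcomes()) expect_length(unique(outd[[oc]]), 1L)
  # massive noise never escapes the scales
  cfgN <- small_config(seed = 89, rating_betas = c(), residual_sd = 50)
  outN <- generate_ratings(tab, cfgN, seed = 2)
  for (oc in rating_outcomes()) {
    rng <- attr(rating_outcomes(), "range")[[oc]]
    expect_true(all(outN[[oc]] >= rng[1] & outN[[oc]] <= rng[2]))
    expect_true(all(outN[[oc]] == round(outN[[oc]])))
  }
})

test_that("unknown predictors in rating_betas are rejected by name", {
  cfg <- small_config(rating_betas = c(not_a_column = 0.1))
  expect_error(generate_ratings(data.frame(participant_id = "A", x = 1), cfg),
               "not_a_column")
})

test_that("rating effects are recovered by the H1 estimator", {
  # moderate scale: one replicate, betas within 2 SE
  cfg <- ground_truth_config(n_participants = 60, trips_per_participant = 20,
                             rating_betas = c(x1 = 0.13, x2 = 0.09), seed = 90)
  tab <- data.frame(participant_id = rep(sprintf("P%02d", 1:60), each = 20))
  set.seed(42)
  tab$x1 <- rnorm(1200); tab$x2 <- rnorm(1200)
  out <- generate_ratings(tab, cfg, seed = 91)
  tabz <- standardize_columns(out, c("x1", "x2"))
  et <- fit_mixed("agitated_calm", c("x1", "x2"), tabz)
  expect_lt(abs(et$beta[et$predictor == "x1"] - 0.13),
            2.5 * et$se[et$predictor == "x1"])
  expect_lt(abs(et$beta[et$predictor == "x2"] - 0.09),
            2.5 * et$se[et$predictor == "x2"])
})

test_that("injected physiological amplitude shifts are recovered", {
  # regression of simulated per-trip SCR amplitude on the standardized
  # exposure recovers the injected effect across many trips
  cfg <- small_config(seed = 92, physio_betas = c(t_max = 0.16))
  sc <- small_scene(92)
  n <- 200
  zt <- with_seed_test(7, rnorm(n))
  t_ref <- mean(sc$weather$t_max) + zt * walkscape:::pop_sd(sc$weather$t_max)
  amp <- numeric(n)
  tr <- segment_trips(clean_stream(generate_trips(sc, cfg)[[1]]))[[1]]
  for (i in seq_len(n)) {
    ex <- data.frame(t_max = t_ref[i])
    ses <- generate_physio(tr, sc, cfg, exposures = ex, seed = 1000 + i)
    amp[i] <- mean(attr(ses, "ground_truth")$events$amplitude_uS)
  }
  fit <- lm(amp ~ zt)
  expect_lt(abs(coef(fit)["zt"] - 0.16), 2 * summary(fit)$coefficients["zt", 2])
})
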