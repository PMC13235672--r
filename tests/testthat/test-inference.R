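# Standardization, correlations, mixed models, blocks, clustering.

test_that("standardization produces exact population z-scores", {
  tab <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5), poi_x = c(NA, NA, 2))
  expect_warning(out <- standardize_columns(tab, c("a", "b")), "zero-variance")
  expect_equal(out$a, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_null(out$b)
  sc <- attr(out, "scaling")
  expect_equal(unname(sc$a["center"]), 2)
  # POI missing -> 0 before standardization
  out2 <- standardize_columns(tab, "poi_x")
  z <- (c(0, 0, 2) - 2 / 3) / walkscape:::pop_sd(c(0, 0, 2))
  expect_equal(out2$poi_x, z, tolerance = 1e-9)
})

test_that("an all-missing POI column becomes constant and is dropped", {
  tab <- data.frame(poi_y = c(NA_real_, NA_real_, NA_real_))
  expect_warning(out <- standardize_columns(tab, "poi_y"), "zero-variance")
  expect_null(out$poi_y)
})

test_that("standardized columns have mean 0 and population SD 1", {
  set.seed(50)
  tab <- data.frame(x = rnorm(100, 5, 3), y = runif(100))
  out <- standardize_columns(tab, c("x", "y"))
  for (cl in c("x", "y")) {
    expect_equal(mean(out[[cl]]), 0, tolerance = 1e-9)
    expect_equal(walkscape:::pop_sd(out[[cl]]), 1, tolerance = 1e-9)
  }
})

test_that("pearson matrix: self, negation, and sampling accuracy", {
  set.seed(51)
  n <- 2000
  x <- rnorm(n)
  y <- 0.25 * x + sqrt(1 - 0.25^2) * rnorm(n)
  r <- pearson_matrix(data.frame(x = x, neg = -x, y = y), c("x", "neg", "y"))
  expect_equal(r["x", "x"], 1)
  expect_equal(r["x", "neg"], -1)
  expect_lt(abs(r["x", "y"] - 0.25), 0.05)
  expect_equal(r, t(r))
})

test_that("fit_mixed recovers jointly injected effects within 2 SE", {
  betas <- c(x1 = 0.3, x2 = 0)
  d <- simulate_mixed_study(betas, 90, 25, 0.5, 1, seed = 60)
  et <- fit_mixed("y", c("x1", "x2"), d)
  expect_true(all(et$converged))
  expect_lt(abs(et$beta[et$predictor == "x1"] - 0.3),
            2 * et$se[et$predictor == "x1"])
  # intercept variance recovered within 30%
  expect_lt(abs(attr(et, "intercept_var") - 0.25), 0.3 * 0.25)
  # residual variance close to 1
  expect_equal(attr(et, "residual_var"), 1, tolerance = 0.1)
})

test_that("fit_mixed reduces to OLS when the intercept variance is forced to zero", {
  d <- simulate_mixed_study(c(x1 = 0.2), 40, 10, intercept_sd = 0,
                            residual_sd = 1, seed = 61)
  ols <- coef(lm(y ~ x1, d))["x1"]
  et0 <- fit_mixed("y", "x1", d, random = "none")
  expect_equal(et0$beta, unname(ols), tolerance = 1e-9)
  expect_equal(attr(et0, "intercept_var"), 0)
  # and the estimated-variance route lands on the same answer when the
  # grouping truly carries no variance (balanced design)
  et <- suppressWarnings(fit_mixed("y", "x1", d))
  expect_equal(et$beta, unname(ols), tolerance = 5e-3)
})

test_that("an intercept-only mixed model attributes participant-constant variance", {
  set.seed(62)
  pid <- rep(sprintf("P%02d", 1:30), each = 8)
  b <- rnorm(30, 0, 1)
  d <- data.frame(participant_id = pid, y = rep(b, each = 8) + rnorm(240, 0, 0.05))
  et <- fit_mixed("y", character(0), d)
  expect_gt(attr(et, "intercept_var") /
              (attr(et, "intercept_var") + attr(et, "residual_var")), 0.95)
})

test_that("fit_mixed validates design prerequisites", {
  d <- simulate_mixed_study(c(x1 = 0.1), 5, 4, seed = 63)
  expect_error(fit_mixed("y", "zz", d), "missing column")
  d1 <- d[d$participant_id == "P001", ]
  expect_error(fit_mixed("y", "x1", d1), "2 participants")
})

test_that("run_h1 output schema: 4 models x predictors, flags at alpha", {
  set.seed(64)
  n <- 200
  tab <- data.frame(participant_id = rep(sprintf("P%02d", 1:20), each = 10))
  for (p in h1_predictors()) tab[[p]] <- rnorm(n)
  for (oc in rating_outcomes()) tab[[oc]] <- rnorm(n, 3.5, 1)
  h1 <- run_h1(tab)
  expect_equal(nrow(h1), 4 * length(h1_predictors()))
  expect_identical(h1$significant, h1$p < 0.05)
  tab$ndvi_mean <- NULL
  expect_error(run_h1(tab), "ndvi_mean")
})

test_that("H2 fits 5 x 27 models and retains on the joint rule", {
  set.seed(65)
  n <- 300
  tab <- data.frame(participant_id = rep(sprintf("P%02d", 1:30), each = 10))
  for (p in unique(unlist(h2_blocks()))) tab[[p]] <- rnorm(n)
  # one outcome with a strong effect of t_max, one with a significant but
  # tiny effect; the rest pure noise
  for (oc in physio_indicator_names()) tab[[oc]] <- rnorm(n)
  zt <- (tab$t_max - mean(tab$t_max)) / walkscape:::pop_sd(tab$t_max)
  tab$scr_amp_mean <- 0.5 * zt + rnorm(n, 0, 0.3)
  tab$hr_mean <- 0.05 * zt + rnorm(n, 0, 0.05)   # tiny beta, tiny noise
  h2 <- run_h2(tab)
  expect_equal(attr(h2, "n_models"), 135)
  d <- as.data.frame(h2)
  strong <- d[d$outcome == "scr_amp_mean" & d$predictor == "t_max", ]
  expect_true(strong$significant && strong$retained)
  tiny <- d[d$outcome == "hr_mean" & d$predictor == "t_max", ]
  expect_true(tiny$significant)      # precise but small
  expect_false(tiny$retained)        # excluded by the effect-size gate
  expect_identical(d$retained, d$significant & abs(d$beta) > 0.1)
})

test_that("elbow selection finds the knee of a clean scree", {
  set.seed(66)
  # four tight, well-separated 3-D blobs
  ctr <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(0, 0, 8))
  x <- ctr[rep(1:4, each = 60), ] + matrix(rnorm(720, 0, 0.6), ncol = 3)
  expect_equal(as.integer(choose_k_elbow(scale(x), seed = 3)), 4L)
})

test_that("Kruskal-Wallis behaviour inside the cluster report", {
  set.seed(67)
  n <- 120
  tab <- data.frame(participant_id = rep(sprintf("P%02d", 1:12), each = 10))
  feats <- c("ndvi_mean", "noise_lden_mean")
  grp <- rep(1:3, length.out = n)
  tab$ndvi_mean <- c(0.1, 0.4, 0.7)[grp] + rnorm(n, 0, 0.02)
  tab$noise_lden_mean <- c(70, 55, 45)[grp] + rnorm(n, 0, 1)
  tab$flat <- rnorm(n)                     # no cluster signal
  tab$shifted <- c(0, 0, 2)[grp] + rnorm(n)
  rep3 <- run_h3(tab, features = feats, outcomes = c("flat", "shifted"),
                 k = 3, seed = 5)
  kw <- rep3$kw
  expect_gt(kw$p[kw$variable == "flat"], 0.05)
  expect_lt(kw$p[kw$variable == "shifted"], 0.05)
  # labels canonically ordered by descending noise mean
  expect_equal(order(rep3$centroids[, "noise_lden_mean"], decreasing = TRUE),
               1:3)
  # KW chi2 invariant under strictly monotone transforms
  tab$mono <- exp(tab$shifted)
  rep4 <- run_h3(tab, features = feats, outcomes = c("shifted", "mono"),
                 k = 3, seed = 5)
  expect_equal(rep4$kw$chi2[rep4$kw$variable == "mono"],
               rep4$kw$chi2[rep4$kw$variable == "shifted"], tolerance = 1e-9)
})

test_that("KW with two groups matches the squared normal approximation", {
  # rank-sum z^2 equals the KW chi-square with k = 2 (no ties)
  set.seed(68)
  y <- c(rnorm(40), rnorm(40, 1))
  g <- rep(1:2, each = 40)
  kw <- kruskal.test(y, g)
  n <- 80; n1 <- 40
  R1 <- sum(rank(y)[g == 1])
  z <- (R1 - n1 * (n + 1) / 2) / sqrt(n1 * n1 * (n + 1) / 12)
  expect_equal(unname(kw$statistic), z^2, tolerance = 1e-6)
})

test_that("an outcome with identical distribution across clusters yields chi2 ~ 0", {
  set.seed(69)
  # three tight feature clusters; the outcome takes the same multiset of
  # values within each cluster, so mean ranks coincide exactly
  tab <- data.frame(participant_id = rep("P", 90),
                    ndvi_mean = rep(c(0, 0.5, 1), each = 30) + rnorm(90, 0, 0.01),
                    same = rep(seq_len(30), times = 3))
  rep0 <- run_h3(tab, features = "ndvi_mean", outcomes = "same", k = 3)
  expect_lt(rep0$kw$chi2, 1e-9)
  expect_gt(rep0$kw$p, 0.95)
})

test_that("run_h3 rejects fewer trips than clusters", {
  tab <- data.frame(participant_id = c("A", "B", "C"),
                    ndvi_mean = c(0.2, 0.5, 0.9),
                    noise_lden_mean = c(50, 60, 70))
  expect_error(run_h3(tab, features = c("ndvi_mean", "noise_lden_mean"),
                      outcomes = character(0), k = 4),
               "fewer trips")
})
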