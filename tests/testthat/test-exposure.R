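# Buffered environmental aggregation.

test_that("raster stats: constant layer, hand-computed pair, empty set", {
  expect_equal(raster_stats(rep(0.5, 7)),
               c(mean = 0.5, min = 0.5, max = 0.5, sd = 0))
  # population SD of {0.2, 0.4} is 0.1
  expect_equal(raster_stats(c(0.2, 0.4)),
               c(mean = 0.3, min = 0.2, max = 0.4, sd = 0.1))
  expect_warning(got <- raster_stats(numeric(0)), "no intersecting")
  expect_true(all(is.na(got)))
})

test_that("min <= mean <= max on random layers", {
  set.seed(40)
  for (i in 1:20) {
    s <- raster_stats(runif(sample(1:30, 1), -1, 1))
    expect_lte(s["min"], s["mean"])
    expect_lte(s["mean"], s["max"])
  }
})

test_that("POI counts: containment, closed boundary, absent categories zero", {
  buf <- buffer_route(cbind(c(0, 100), c(0, 0)), 25)
  poi <- data.frame(x = c(10, 50, 90, 50, 50),
                    y = c(0, 10, -20, 40, 25),  # 40 is outside, 25 on boundary
                    category = c("leisure", "leisure", "leisure", "leisure",
                                 "tourism"))
  got <- poi_counts(buf, poi)
  expect_equal(unname(got["leisure"]), 3L)
  expect_equal(unname(got["tourism"]), 1L)   # boundary point counts
  expect_equal(unname(got["commerce"]), 0L)  # absent -> 0
  # empty POI set: all categories zero
  none <- poi_counts(buf, poi[0, ])
  expect_true(all(none == 0L))
  expect_setequal(names(none), poi_categories())
})

test_that("unknown POI categories go to 'other' with a warning", {
  buf <- buffer_route(cbind(c(0, 100), c(0, 0)), 25)
  poi <- data.frame(x = 50, y = 0, category = "casino")
  expect_warning(got <- poi_counts(buf, poi), "other")
  expect_equal(unname(got["other"]), 1L)
})

test_that("POI counts never decrease when the buffer grows", {
  set.seed(41)
  route <- cbind(cumsum(runif(30, 0, 10)), cumsum(runif(30, -5, 5)))
  poi <- data.frame(x = runif(200, -50, 350), y = runif(200, -80, 80),
                    category = sample(poi_categories(), 200, TRUE))
  small <- poi_counts(buffer_route(route, 25), poi)
  big <- poi_counts(buffer_route(route, 60), poi)
  expect_true(all(big[names(small)] >= small))
})

test_that("exposure is invariant under row reordering", {
  set.seed(42)
  buf <- buffer_route(cbind(c(0, 200), c(0, 0)), 25)
  poi <- data.frame(x = runif(100, -20, 220), y = runif(100, -40, 40),
                    category = sample(poi_categories(), 100, TRUE))
  expect_identical(poi_counts(buf, poi), poi_counts(buf, poi[sample(100), ]))
})

test_that("image class means: single image, hand mean, and no-image flag", {
  buf <- buffer_route(cbind(c(0, 100), c(0, 0)), 25)
  mk_img <- function(x, veg) {
    img <- data.frame(image_id = paste0("i", x), x = x, y = 0)
    rest <- (1 - veg) / 7
    for (cl in image_classes()) img[[cl]] <- ifelse(cl == "vegetation", veg, rest)
    img
  }
  one <- image_class_means(buf, mk_img(50, 0.4))
  expect_equal(unname(one["vegetation"]), 0.4)
  two <- image_class_means(buf, rbind(mk_img(30, 0.2), mk_img(60, 0.6)))
  expect_equal(unname(two["vegetation"]), 0.4)
  none <- image_class_means(buf, mk_img(500, 0.4))  # outside
  expect_true(all(is.na(none)))
  expect_equal(attr(none, "n_images"), 0L)
})

test_that("image proportions must sum to one", {
  buf <- buffer_route(cbind(c(0, 100), c(0, 0)), 25)
  img <- data.frame(image_id = "i1", x = 50, y = 0)
  for (cl in image_classes()) img[[cl]] <- 0.2
  expect_error(image_class_means(buf, img), "sum to 1")
})

test_that("weather join is an exact date match with day-level resolution", {
  wx <- data.frame(date = as.Date("2024-09-01") + 0:9,
                   t_max = 30:39, t_mean = 25:34, t_min = 20:29,
                   precip_mm = rep(0, 10))
  got <- weather_join(as.Date(c("2024-09-03", "2024-09-03", "2024-10-01")),
                      wx) |> suppressWarnings()
  expect_equal(got$t_max[1], 32)
  expect_equal(unlist(got[1, ]), unlist(got[2, ]))  # same day, same weather
  expect_true(all(is.na(got[3, ])))                         # absent date
  expect_warning(weather_join(as.Date("2025-01-01"), wx), "missing")
})

test_that("trip exposures satisfy the ordering invariants on generated trips", {
  cfg <- small_config(seed = 32)
  sc <- small_scene(32)
  st <- generate_trips(sc, cfg)
  for (k in 1:3) {
    tr <- segment_trips(clean_stream(st[[k]]))[[1]]
    tr$date <- attr(st[[k]], "date")
    ex <- trip_exposures(tr, sc)
    expect_lte(ex$ndvi_min, ex$ndvi_mean)
    expect_lte(ex$ndvi_mean, ex$ndvi_max)
    expect_lte(ex$noise_lden_min, ex$noise_lden_mean)
    expect_lte(ex$noise_lden_mean, ex$noise_lden_max)
    props <- unlist(ex[paste0("prop_", image_classes())])
    expect_true(all(props >= 0 & props <= 1, na.rm = TRUE))
    expect_true(all(unlist(ex[paste0("poi_", poi_categories())]) >= 0))
    expect_false(is.na(ex$t_max))
  }
})
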