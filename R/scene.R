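# Synthetic study generator: ground-truth configuration and the
# environmental scene (hexagonal layers, POIs, streetscape images, daily
# weather) with contiguous archetype zones of distinct environmental
# profile. Everything downstream of the generator is testable against the
# stored ground truth.

#' Ground-truth configuration for the synthetic study
#'
#' Defaults emulate the study conditions: 90 participants with ~25 trips
#' each, participant random intercepts (SD 0.5 rating units), unit
#' residual SD, standardized environmental effects of the magnitude seen
#' in naturalistic walking data (|beta| 0.05-0.2), SCR pulses with known
#' linear rise and exponential decay, and four separable environmental
#' archetypes.
#'
#' @param n_participants number of participants.
#' @param trips_per_participant trips per participant (>= 1).
#' @param rating_betas named numeric: exposure column -> effect (rating
#'   units per 1-SD) applied to every subjective outcome.
#' @param physio_betas named numeric: exposure column -> shift of drawn
#'   SCR amplitudes (uS per 1-SD of the exposure).
#' @param random_intercept_sd,residual_sd rating-scale SDs (>= 0).
#' @param scr_rate SCR events per minute.
#' @param scr_amp_range range (uS) amplitudes are drawn from.
#' @param scr_rise_s SCR linear rise time, s.
#' @param scr_tau_s SCR exponential decay constant, s.
#' @param rmssd_ms target RMSSD of the generated IBI series, ms.
#' @param n_archetypes number of contiguous environmental zones.
#' @param teleport_rate,dwell_rate per-trip probabilities of injecting a
#'   >500-m teleport fix / a stationary dwell.
#' @param dwell_s injected dwell duration, s.
#' @param trip_duration_range trip duration range, s.
#' @param eda_noise_sd EDA measurement noise, uS.
#' @param seed integer; fully determines the generated study.
#' @return a `gt_config`.
#' @export
ground_truth_config <- function(n_participants = 90,
                                trips_per_participant = 25,
                                rating_betas = c(prop_curbs = 0.09,
                                                 ndvi_mean = 0.13,
                                                 poi_tourism = 0.13),
                                physio_betas = c(t_max = 0.16,
                                                 noise_lden_mean = 0.18),
                                random_intercept_sd = 0.5,
                                residual_sd = 1,
                                scr_rate = 3,
                                scr_amp_range = c(0.3, 0.9),
                                scr_rise_s = 2,
                                scr_tau_s = 3,
                                rmssd_ms = 50,
                                n_archetypes = 4,
                                teleport_rate = 0,
                                dwell_rate = 0,
                                dwell_s = 300,
                                trip_duration_range = c(300, 720),
                                eda_noise_sd = 0.003,
                                seed = 1L) {
  stopifnot(n_participants >= 1, trips_per_participant >= 1,
            random_intercept_sd >= 0, residual_sd >= 0,
            scr_rate >= 0, length(scr_amp_range) == 2,
            scr_rise_s > 0, scr_tau_s > 0, rmssd_ms > 0,
            n_archetypes >= 1,
            teleport_rate >= 0, teleport_rate <= 1,
            dwell_rate >= 0, dwell_rate <= 1)
  structure(as.list(environment()), class = "gt_config")
}

#' @export
print.gt_config <- function(x, ...) {
  cat(sprintf(paste0("<gt_config> %d participants x %d trips, %d archetypes, seed %d\n",
                     "  rating betas: %s\n  physio betas: %s\n"),
              x$n_participants, x$trips_per_participant, x$n_archetypes, x$seed,
              paste(names(x$rating_betas), x$rating_betas, sep = "=", collapse = ", "),
              paste(names(x$physio_betas), x$physio_betas, sep = "=", collapse = ", ")))
  invisible(x)
}

# Built-in archetype profiles (recycled beyond 4): low-density/sparse,
# green/open, mixed-use, dense/noisy. The typology-defining axes - NDVI,
# Lden noise, POI density - are well separated and deliberately
# non-collinear; image class compositions are only loosely tied to the
# archetype (micro-scale streetscape varies within typologies).
archetype_profiles <- function(n) {
  # the three typology axes (NDVI, noise, POI density) place the four
  # archetypes near the vertices of a regular tetrahedron in standardized
  # space: green/noisy/POI-rich commercial avenues, green/quiet/POI-poor
  # residential areas, sparse/noisy arterials, and the quiet but dense
  # historic core
  base <- data.frame(
    label = c("green_commercial", "green_residential", "arterial",
              "historic_core"),
    ndvi = c(0.50, 0.55, 0.10, 0.14),
    noise = c(68, 50, 70, 52),
    poi_rate = c(0.45, 0.06, 0.10, 0.50),  # POIs per cell per category-unit
    slope = c(3, 2, 4, 5),
    vegetation = c(0.24, 0.30, 0.08, 0.10),
    sky = c(0.16, 0.26, 0.30, 0.12),
    road = c(0.18, 0.16, 0.30, 0.22),
    sidewalk = c(0.14, 0.10, 0.12, 0.20),
    cars = c(0.10, 0.05, 0.12, 0.07),
    poles = c(0.04, 0.03, 0.04, 0.06),
    curbs = c(0.08, 0.06, 0.02, 0.12),
    pedestrians = c(0.06, 0.04, 0.02, 0.11)
  )
  base[((seq_len(n) - 1L) %% 4L) + 1L, ]
}

# Relative category weights of POI placement per archetype.
poi_category_weights <- function() {
  # each archetype has signature categories so the POI block spans
  # several directions, not a single density axis: leisure/greenery and
  # commerce mark the green commercial avenues, parks and water the
  # residential zones, services the arterials, tourism/arts/commerce the
  # historic core
  rbind(green_commercial  = c(leisure = 3.24, tourism = 0.41, arts = 0.30,
                              greenery = 1.58, water = 0.19, services = 1.02,
                              commerce = 3.51, public = 1.15),
        green_residential = c(leisure = 0.90, tourism = 0.11, arts = 0.12,
                              greenery = 4.96, water = 2.54, services = 0.71,
                              commerce = 0.33, public = 0.44),
        arterial          = c(leisure = 0.35, tourism = 0.09, arts = 0.08,
                              greenery = 0.17, water = 0.12, services = 8.00,
                              commerce = 0.73, public = 1.40),
        historic_core     = c(leisure = 0.55, tourism = 2.75, arts = 1.76,
                              greenery = 0.36, water = 0.29, services = 0.31,
                              commerce = 2.32, public = 0.53))
}

#' Generate a synthetic environmental scene
#'
#' Builds the hexagonal grid over the extent, partitions it into
#' `n_archetypes` contiguous zones (K-means on cell centres), and fills
#' per-cell NDVI, Lden noise and slope from the archetype profiles plus
#' cell-level noise; scatters POIs (Poisson per cell and category),
#' places streetscape images with archetype-shaped class proportions, and
#' draws a daily weather table over the study window (Aug-Dec 2024).
#' Deterministic under the config seed.
#'
#' @param config a `gt_config`.
#' @param extent `c(xmin, xmax, ymin, ymax)` in metres (default 3 x 3 km); area must be at
#'   least 1 km^2.
#' @param hex_diameter_m grid cell diameter, default 25.
#' @param profiles optional replacement archetype profile table (same
#'   columns as the built-in one), e.g. identical rows to remove all
#'   between-zone separation.
#' @param cell_ndvi_sd,cell_noise_sd within-archetype cell-level SDs.
#' @param field_ndvi_sd,field_noise_sd SDs of the smooth spatially
#'   correlated fields (independent across layers) superimposed on the
#'   archetype means, so layers are not collinear through the zones alone.
#' @param field_scale_m correlation length of the smooth fields.
#' @param image_concentration Dirichlet-type concentration of per-image
#'   class proportions around the archetype composition (lower = noisier
#'   single images, as real segmentation output is).
#' @return an `env_scene`.
#' @export
generate_scene <- function(config, extent = c(0, 3000, 0, 3000),
                           hex_diameter_m = 25, profiles = NULL,
                           cell_ndvi_sd = 0.03, cell_noise_sd = 1.2,
                           field_ndvi_sd = 0.05, field_noise_sd = 1.5,
                           field_scale_m = 150, image_concentration = 15) {
  area <- (extent[2] - extent[1]) * (extent[4] - extent[3])
  if (!is.finite(area) || area <= 0) stop("generate_scene: degenerate extent")
  if (area < 1e6) stop("generate_scene: extent area must be >= 1 km^2")
  prof <- profiles %||% archetype_profiles(config$n_archetypes)
  k <- config$n_archetypes
  with_seed(config$seed, {
    grid <- build_hex_grid(extent, hex_diameter_m)
    nc <- length(grid$cell_id)
    centers <- cbind(grid$cx, grid$cy)
    arch <- if (k == 1L) rep(1L, nc) else {
      km <- stats::kmeans(centers, centers = k, nstart = 5, iter.max = 100)
      # stable zone numbering: by zone centre reading order
      ord <- order(km$centers[, 2], km$centers[, 1])
      match(km$cluster, ord)
    }
    # smooth independent fields (sum of Gaussian bumps, rescaled to the
    # requested SD) break the collinearity a pure zone model would impose
    smooth_field <- function(sd_target, n_bumps = 40) {
      if (sd_target <= 0) return(numeric(nc))
      cx <- runif(n_bumps, extent[1], extent[2])
      cy <- runif(n_bumps, extent[3], extent[4])
      a <- rnorm(n_bumps)
      f <- numeric(nc)
      for (b in seq_len(n_bumps))
        f <- f + a[b] * exp(-((centers[, 1] - cx[b])^2 +
                              (centers[, 2] - cy[b])^2) / (2 * field_scale_m^2))
      s <- pop_sd(f)
      if (s == 0) numeric(nc) else f / s * sd_target
    }
    ndvi <- pmin(1, pmax(-1, prof$ndvi[arch] + smooth_field(field_ndvi_sd) +
                               rnorm(nc, 0, cell_ndvi_sd)))
    noise <- prof$noise[arch] + smooth_field(field_noise_sd) +
      rnorm(nc, 0, cell_noise_sd)
    slope <- pmax(0, prof$slope[arch] + smooth_field(1.5) + rnorm(nc, 0, 1))
    # POIs: Poisson per cell x category
    w <- poi_category_weights()[((seq_len(k) - 1L) %% 4L) + 1L, , drop = FALSE]
    cats <- poi_categories()
    poi_list <- list()
    for (cat_i in seq_along(cats)) {
      lam <- prof$poi_rate[arch] * w[arch, cats[cat_i]]
      n_by_cell <- rpois(nc, lam)
      tot <- sum(n_by_cell)
      if (tot == 0L) next
      cell_rep <- rep.int(seq_len(nc), n_by_cell)
      poi_list[[cats[cat_i]]] <- data.frame(
        x = grid$cx[cell_rep] + runif(tot, -grid$R, grid$R),
        y = grid$cy[cell_rep] + runif(tot, -grid$R, grid$R),
        category = cats[cat_i])
    }
    poi <- if (length(poi_list)) do.call(rbind, poi_list)
           else data.frame(x = numeric(0), y = numeric(0), category = character(0))
    rownames(poi) <- NULL
    # streetscape images: ~1 per 2 cells, archetype-shaped proportions
    has_img <- runif(nc) < 0.5
    img_cells <- which(has_img)
    cls <- image_classes()
    # per-class smooth log-composition fields: streetscape composition
    # varies spatially within archetypes, not only between them
    lbase <- log(as.matrix(prof[arch, cls, drop = FALSE]))
    for (ci in seq_along(cls)) lbase[, ci] <- lbase[, ci] + smooth_field(0.35)
    comp <- exp(lbase[img_cells, , drop = FALSE])
    comp <- comp / rowSums(comp)
    raw <- matrix(rgamma(length(comp), shape = image_concentration * comp + 0.05),
                  nrow = nrow(comp))
    raw <- raw / rowSums(raw)
    images <- data.frame(image_id = sprintf("img%05d", seq_along(img_cells)),
                         x = grid$cx[img_cells] + runif(length(img_cells), -5, 5),
                         y = grid$cy[img_cells] + runif(length(img_cells), -5, 5))
    for (ci in seq_along(cls)) images[[cls[ci]]] <- raw[, ci]
    # daily weather over the study window
    dates <- seq(as.Date("2024-08-01"), as.Date("2024-12-18"), by = "day")
    nd <- length(dates)
    season <- seq(0, 1, length.out = nd)
    t_max <- 32 - 14 * season + rnorm(nd, 0, 2)
    t_mean <- t_max - 6 + rnorm(nd, 0, 0.8)
    t_min <- t_mean - 6 + rnorm(nd, 0, 0.8)
    precip <- rbinom(nd, 1, 0.25) * rgamma(nd, shape = 1, scale = 5)
    weather <- data.frame(date = dates, t_max = t_max, t_mean = t_mean,
                          t_min = t_min, precip_mm = round(precip, 1))
    structure(list(grid = grid, archetype = arch, ndvi = ndvi, noise = noise,
                   slope = slope, poi = poi, images = images,
                   weather = weather, profiles = prof, extent = extent,
                   frame = local_frame(38.72, -9.14)),
              class = "env_scene")
  })
}

#' Per-cell feature matrix of a scene
#'
#' The typology-defining cell features: NDVI, Lden noise, and local POI
#' density (points per cell, optionally averaged over the cell and its
#' six neighbours to tame Poisson noise). Used for archetype-recovery
#' clustering of a generated scene.
#'
#' @param scene an `env_scene`.
#' @param smooth_poi average POI counts over the 7-cell neighbourhood
#'   (default TRUE).
#' @return numeric matrix with columns ndvi, noise, poi_density.
#' @export
scene_cell_features <- function(scene, smooth_poi = TRUE) {
  g <- scene$grid
  nc <- length(g$cell_id)
  counts <- numeric(nc)
  if (nrow(scene$poi)) {
    ids <- cell_for_point(g, cbind(scene$poi$x, scene$poi$y))
    tab <- table(ids[!is.na(ids)])
    counts[as.integer(names(tab))] <- as.numeric(tab)
  }
  if (smooth_poi) {
    dy <- sqrt(3) * g$R
    acc <- counts
    nn <- rep(1, nc)
    # six hex neighbours via axial offsets (flat-topped, odd-column shift)
    for (off in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0), c(1, -1), c(-1, -1))) {
      i2 <- g$i + off[1]
      j2 <- g$j + off[2] + ifelse(off[1] != 0 & g$i %% 2 != 0, 1L, 0L)
      id2 <- g$lookup[paste(i2, j2)]
      ok <- !is.na(id2)
      # keep only true geometric neighbours (centre distance = sqrt(3) R)
      d <- sqrt((g$cx[id2[ok]] - g$cx[ok])^2 + (g$cy[id2[ok]] - g$cy[ok])^2)
      good <- which(ok)[abs(d - dy) < 1e-6]
      acc[good] <- acc[good] + counts[g$lookup[paste(i2, j2)][good]]
      nn[good] <- nn[good] + 1
    }
    counts <- acc / nn
  }
  cbind(ndvi = scene$ndvi, noise = scene$noise, poi_density = counts)
}

#' @export
print.env_scene <- function(x, ...) {
  cat(sprintf("<env_scene> %d cells, %d archetypes, %d POIs, %d images, %d weather days\n",
              length(x$grid$cell_id), length(unique(x$archetype)),
              nrow(x$poi), nrow(x$images), nrow(x$weather)))
  invisible(x)
}
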