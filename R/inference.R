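# Inference stages. The unit of analysis is the validated walking trip,
# nested within participants; all exposure predictors are z-scored over
# the pooled trip table before modelling, and every model carries a
# participant random intercept.

#' Standardize predictor columns of the trip table
#'
#' z-scores each column over all trips pooled (population SD). Missing
#' values in POI columns (names starting "poi_") are set to 0 before
#' standardization, per the missing-POI rule; zero-variance columns are
#' dropped with a warning. The scaling record (centre, scale per column)
#' is attached as attribute `scaling` for back-transformation.
#'
#' @param table trip-level data.frame.
#' @param columns columns to standardize.
#' @return the table with standardized columns (zero-variance ones
#'   removed) and a `scaling` attribute.
#' @export
standardize_columns <- function(table, columns) {
  stopifnot(all(columns %in% names(table)))
  dropped <- character(0)
  rec <- list()
  for (cl in columns) {
    x <- table[[cl]]
    if (!is.numeric(x)) stop("standardize_columns: non-numeric column ", cl)
    if (grepl("^poi_", cl)) x[is.na(x)] <- 0
    mu <- mean(x, na.rm = TRUE)
    sg <- pop_sd(x)
    if (!is.finite(sg) || sg == 0) {
      dropped <- c(dropped, cl)
      table[[cl]] <- NULL
      next
    }
    table[[cl]] <- (x - mu) / sg
    rec[[cl]] <- c(center = mu, scale = sg)
  }
  if (length(dropped))
    warning("standardize_columns: zero-variance column(s) dropped: ",
            paste(dropped, collapse = ", "))
  attr(table, "scaling") <- rec
  attr(table, "dropped") <- dropped
  table
}

#' Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations between the given variables;
#' constant variables yield missing entries.
#'
#' @param table trip-level data.frame.
#' @param vars variable names.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table, vars) {
  stopifnot(all(vars %in% names(table)))
  x <- as.matrix(table[, vars, drop = FALSE])
  npair <- crossprod(!is.na(x))
  if (any(npair < 3))
    warning("pearson_matrix: fewer than 3 complete pairs for some variables")
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Fit a random-intercept mixed-effects model
#'
#' `outcome ~ predictors + (1 | participant_id)`, restricted maximum
#' likelihood via lme4, with Wald z p-values per fixed effect. Returns an
#' `effect_table` (one row per predictor) carrying the random-intercept
#' and residual variances and a convergence flag; non-convergence is
#' flagged, never silent.
#'
#' @param outcome outcome column name.
#' @param predictors predictor column names (assumed already standardized
#'   by the calling stage).
#' @param table trip-level data.frame with a `participant_id` column.
#' @param reml use REML (default TRUE).
#' @param random "estimate" (default) estimates the participant intercept
#'   variance; "none" forces it to zero, collapsing the model to ordinary
#'   least squares (useful as a degenerate-case check: on balanced data
#'   with no participant variance the two routes agree).
#' @return an `effect_table` data.frame: outcome, predictor, beta, se, p,
#'   converged; attributes `intercept_var`, `residual_var`, `n_obs`,
#'   `n_participants`.
#' @export
fit_mixed <- function(outcome, predictors, table, reml = TRUE,
                      random = c("estimate", "none")) {
  random <- match.arg(random)
  stopifnot("participant_id" %in% names(table))
  miss <- setdiff(c(outcome, predictors), names(table))
  if (length(miss))
    stop("fit_mixed: missing column(s): ", paste(miss, collapse = ", "))
  tab <- table[, c(outcome, predictors, "participant_id"), drop = FALSE]
  tab <- tab[stats::complete.cases(tab), , drop = FALSE]
  ng <- length(unique(tab$participant_id))
  if (ng < 2L) stop("fit_mixed: need at least 2 participants")
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  if (random == "none") {
    fit <- stats::lm(stats::as.formula(paste(outcome, "~", rhs)), data = tab)
    co <- summary(fit)$coefficients
    rows <- if (length(predictors)) {
      co <- co[predictors, , drop = FALSE]
      data.frame(outcome = outcome, predictor = predictors,
                 beta = co[, "Estimate"], se = co[, "Std. Error"],
                 p = 2 * stats::pnorm(-abs(co[, "t value"])),
                 converged = TRUE, row.names = NULL)
    } else {
      data.frame(outcome = character(0), predictor = character(0),
                 beta = numeric(0), se = numeric(0), p = numeric(0),
                 converged = logical(0))
    }
    return(structure(rows, class = c("effect_table", "data.frame"),
                     intercept_var = 0,
                     residual_var = summary(fit)$sigma^2,
                     n_obs = nrow(tab), n_participants = ng))
  }
  f <- stats::as.formula(paste(outcome, "~", rhs, "+ (1 | participant_id)"))
  converged <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(f, data = tab, REML = reml),
      warning = function(w) {
        if (grepl("conver|singular", conditionMessage(w), ignore.case = TRUE))
          converged <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # estimation failed outright (e.g. rank-deficient tiny designs):
    # emit flagged rows rather than failing silently or fatally
    warning("fit_mixed: ", outcome, " did not fit: ", conditionMessage(fit))
    rows <- data.frame(outcome = rep(outcome, length(predictors)),
                       predictor = predictors,
                       beta = NA_real_, se = NA_real_, p = NA_real_,
                       converged = FALSE, row.names = NULL)
    return(structure(rows, class = c("effect_table", "data.frame"),
                     intercept_var = NA_real_, residual_var = NA_real_,
                     n_obs = nrow(tab), n_participants = ng))
  }
  if (length(fit@optinfo$conv$lme4)) converged <- FALSE
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  rows <- if (length(predictors)) {
    # aliased (rank-deficient) predictors are dropped by the fitter;
    # report them as missing rather than reindexing silently
    idx <- match(predictors, rownames(co))
    data.frame(outcome = outcome, predictor = predictors,
               beta = co[idx, "Estimate"], se = co[idx, "Std. Error"],
               p = 2 * stats::pnorm(-abs(co[idx, "t value"])),
               converged = converged, row.names = NULL)
  } else {
    data.frame(outcome = character(0), predictor = character(0),
               beta = numeric(0), se = numeric(0), p = numeric(0),
               converged = logical(0))
  }
  structure(rows, class = c("effect_table", "data.frame"),
            intercept_var = vc$vcov[vc$grp == "participant_id"],
            residual_var = vc$vcov[vc$grp == "Residual"],
            n_obs = nrow(tab), n_participants = ng)
}

#' @export
print.effect_table <- function(x, digits = 4, ...) {
  cat(sprintf("<effect_table> %d effect(s)", nrow(x)))
  iv <- attr(x, "intercept_var")
  if (!is.null(iv))
    cat(sprintf("; participant intercept var %.3g, residual var %.3g",
                iv, attr(x, "residual_var")))
  cat("\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Default H1 predictor set
#' @return character vector of environmental predictors for the subjective
#'   rating models.
#' @export
h1_predictors <- function() {
  c("ndvi_mean", "ndvi_max", "prop_vegetation", "prop_sky",
    "prop_sidewalk", "prop_curbs",
    "poi_leisure", "poi_tourism", "poi_arts", "poi_greenery", "poi_water",
    "slope")
}

#' Rating outcome columns
#' @return the four subjective scales with their ranges as an attribute.
#' @export
rating_outcomes <- function() {
  out <- c("trip_feeling_env", "unwell_well", "agitated_calm", "tired_awake")
  attr(out, "range") <- list(trip_feeling_env = c(0, 5), unwell_well = c(1, 6),
                             agitated_calm = c(1, 6), tired_awake = c(1, 6))
  out
}

#' H1: environmental predictors of subjective ratings
#'
#' Fits one random-intercept mixed model per subjective outcome, with all
#' standardized environmental predictors entered jointly.
#'
#' @param table trip-level data.frame.
#' @param predictors predictor columns (default [h1_predictors()]).
#' @param alpha significance level for the `significant` flag.
#' @return an `effect_table` with a `significant` column.
#' @export
run_h1 <- function(table, predictors = h1_predictors(), alpha = 0.05) {
  miss <- setdiff(c(rating_outcomes(), predictors), names(table))
  if (length(miss))
    stop("run_h1: missing column(s): ", paste(miss, collapse = ", "))
  tab <- standardize_columns(table, predictors)
  preds <- setdiff(predictors, attr(tab, "dropped"))
  rows <- lapply(rating_outcomes(), function(oc) fit_mixed(oc, preds, tab))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  out$significant <- !is.na(out$p) & out$p < alpha
  structure(out, class = c("effect_table", "data.frame"),
            alpha = alpha,
            models = stats::setNames(rows, rating_outcomes()))
}

#' Default H2 thematic stressor blocks
#'
#' @param noise which Lden summary carries the Noise block ("mean",
#'   the default, or "max").
#' @return named list of predictor-column blocks.
#' @export
h2_blocks <- function(noise = c("mean", "max")) {
  noise <- match.arg(noise)
  list(
    noise = paste0("noise_lden_", noise),
    temperature = c("t_max", "t_mean", "t_min"),
    technical_infrastructure = c("prop_curbs", "prop_poles"),
    functional_pois = c("poi_services", "poi_commerce", "poi_tourism",
                        "poi_leisure", "poi_public"),
    visual_elements = c("prop_cars", "prop_pedestrians")
  )
}

#' H2: stressor blocks across the physiological indicators
#'
#' Fits each thematic predictor block in a separate random-intercept
#' mixed model for each of the 27 physiological indicators (135 models by
#' default) and applies the joint retention rule: an association is
#' retained when p < `alpha` AND |beta| > `beta_gate`.
#'
#' @param table trip-level data.frame.
#' @param blocks named list of predictor blocks (default [h2_blocks()]).
#' @param outcomes physiological outcome columns (default the canonical
#'   27).
#' @param alpha significance level (default 0.05).
#' @param beta_gate minimal absolute standardized effect (default 0.1).
#' @param p_adjust optional p-adjustment across the models
#'   ("none", default, or "BH").
#' @return an `effect_table` with block, significant and retained columns;
#'   attribute `n_models` logs the number of fitted models.
#' @export
run_h2 <- function(table, blocks = h2_blocks(),
                   outcomes = physio_indicator_names(),
                   alpha = 0.05, beta_gate = 0.1,
                   p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  miss <- setdiff(outcomes, names(table))
  if (length(miss))
    stop("run_h2: missing outcome column(s): ", paste(miss, collapse = ", "))
  all_preds <- unique(unlist(blocks))
  miss <- setdiff(all_preds, names(table))
  if (length(miss))
    stop("run_h2: missing predictor column(s): ", paste(miss, collapse = ", "))
  tab <- standardize_columns(table, all_preds)
  rows <- list(); n_models <- 0L
  for (bn in names(blocks)) {
    preds <- setdiff(blocks[[bn]], attr(tab, "dropped"))
    if (!length(preds)) next
    for (oc in outcomes) {
      et <- fit_mixed(oc, preds, tab)
      n_models <- n_models + 1L
      if (nrow(et)) {
        et <- as.data.frame(et)
        et$block <- bn
        rows[[length(rows) + 1L]] <- et
      }
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out$retained <- out$significant & !is.na(out$beta) & abs(out$beta) > beta_gate
  structure(out[, c("block", "outcome", "predictor", "beta", "se", "p",
                    "converged", "significant", "retained")],
            class = c("effect_table", "data.frame"),
            alpha = alpha, beta_gate = beta_gate, n_models = n_models)
}

#' Default H3 environmental typology features
#' @return character vector of clustering feature columns.
#' @export
h3_features <- function() {
  c("ndvi_mean", "prop_sky", "prop_vegetation", "noise_lden_mean",
    paste0("poi_", poi_categories()))
}

#' Elbow selection of the number of K-means clusters
#'
#' Fits K-means over `k_range` (plus the flanking k needed for the
#' curvature) and returns the k with the maximal second difference of the
#' within-cluster sum of squares - the sharpest bend of the scree.
#'
#' @param features numeric matrix or data.frame (already standardized).
#' @param k_range candidate cluster counts, default 2:8.
#' @param nstart random restarts per k, default 10.
#' @param seed RNG seed for the restarts.
#' @return selected k; attribute `wss` holds the scree.
#' @export
choose_k_elbow <- function(features, k_range = 2:8, nstart = 10, seed = 1) {
  x <- as.matrix(features)
  ks <- sort(unique(c(max(1L, min(k_range) - 1L), k_range, max(k_range) + 1L)))
  ks <- ks[ks <= nrow(x) - 1L]
  wss <- with_seed(seed, vapply(ks, function(k) {
    if (k == 1L) sum(scale(x, scale = FALSE)^2)
    else stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50)$tot.withinss
  }, numeric(1)))
  cand <- k_range[k_range %in% ks[-c(1L, length(ks))]]
  d2 <- vapply(cand, function(k) {
    i <- match(k, ks)
    wss[i - 1L] - 2 * wss[i] + wss[i + 1L]
  }, numeric(1))
  structure(cand[which.max(d2)], wss = stats::setNames(wss, ks), d2 = stats::setNames(d2, cand))
}

#' H3: environmental typologies and psychophysiological contrasts
#'
#' K-means on the standardized environmental feature block (missing POIs
#' imputed 0 by the standardization rule), with the cluster count picked
#' by the elbow unless fixed. Cluster labels are canonically ordered by
#' descending noise mean so reports are comparable across runs. Each
#' outcome is then compared across clusters with a (tie-corrected)
#' Kruskal-Wallis test.
#'
#' @param table trip-level data.frame.
#' @param features clustering feature columns (default [h3_features()]).
#' @param outcomes outcome columns to compare (default the 27 indicators
#'   plus the four ratings).
#' @param k fixed number of clusters; NULL (default) selects by elbow.
#' @param k_range elbow search range.
#' @param nstart K-means restarts (default 10).
#' @param seed RNG seed.
#' @return a `cluster_report`: k, assignments, centroids, Kruskal-Wallis
#'   table, per-cluster outcome and feature means.
#' @export
run_h3 <- function(table, features = h3_features(),
                   outcomes = c(physio_indicator_names(), rating_outcomes()),
                   k = NULL, k_range = 2:8, nstart = 10, seed = 1) {
  miss <- setdiff(features, names(table))
  if (length(miss))
    stop("run_h3: missing feature column(s): ", paste(miss, collapse = ", "))
  outcomes <- intersect(outcomes, names(table))
  tab <- standardize_columns(table, features)
  feats <- setdiff(features, attr(tab, "dropped"))
  x <- as.matrix(tab[, feats, drop = FALSE])
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  wss <- NULL
  if (is.null(k)) {
    ksel <- choose_k_elbow(x, k_range, nstart, seed)
    wss <- attr(ksel, "wss")
    k <- as.integer(ksel)
  } else k <- as.integer(k)
  if (nrow(x) <= k) stop("run_h3: fewer trips than clusters")
  km <- with_seed(seed + 1L,
                  stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50))
  # canonical labels: descending noise mean (fall back to first feature)
  noise_col <- if ("noise_lden_mean" %in% feats) "noise_lden_mean" else feats[1]
  ord <- order(km$centers[, noise_col], decreasing = TRUE)
  relab <- match(seq_len(k), ord)
  assignments <- rep(NA_integer_, nrow(tab))
  assignments[keep] <- relab[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- seq_len(k)
  kw <- do.call(rbind, lapply(outcomes, function(oc) {
    y <- table[[oc]][keep]
    g <- factor(relab[km$cluster])
    ok <- is.finite(y)
    if (length(unique(g[ok])) < 2L || sum(ok) < 3L)
      return(data.frame(variable = oc, chi2 = NA_real_, df = NA_integer_,
                        p = NA_real_))
    kt <- stats::kruskal.test(y[ok], g[ok])
    data.frame(variable = oc, chi2 = unname(kt$statistic),
               df = unname(kt$parameter), p = kt$p.value)
  }))
  profile <- do.call(rbind, lapply(seq_len(k), function(cl) {
    sel <- which(keep)[relab[km$cluster] == cl]
    cbind(data.frame(cluster = cl, n = length(sel)),
          as.data.frame(lapply(table[sel, c(feats, outcomes), drop = FALSE],
                               function(v) mean(v, na.rm = TRUE))))
  }))
  structure(list(k = k, assignments = assignments, centroids = centroids,
                 kw = kw, profile = profile,
                 wss = wss, features = feats, seed = seed),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d over %d trips (%d features)\n",
              x$k, sum(!is.na(x$assignments)), length(x$features)))
  cat("cluster sizes:", paste(x$profile$n, collapse = ", "), "\n")
  sig <- x$kw[!is.na(x$kw$p) & x$kw$p < 0.05, ]
  cat(sprintf("Kruskal-Wallis: %d of %d outcomes differ at p < 0.05\n",
              nrow(sig), nrow(x$kw)))
  if (nrow(sig)) print.data.frame(sig, digits = 4, row.names = FALSE)
  invisible(x)
}
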