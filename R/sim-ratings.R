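# Synthetic subjective ratings and a direct table-level mixed-model
# simulator for estimator calibration.

#' Generate post-trip subjective ratings with known ground truth
#'
#' rating = clip(round(grand mean + sum(beta * z(exposure)) + participant
#' intercept + residual)) on each of the four scales (Trip Feeling
#' Environment 0-5, the three semantic differentials 1-6). Exposure
#' z-scores are pooled over the table (population SD), matching the
#' standardization the H1 stage applies.
#'
#' @param trip_table trip-level data.frame with `participant_id` and the
#'   exposure columns named in `config$rating_betas`.
#' @param config a `gt_config`.
#' @param discretize round to integers and clip to scale (default TRUE,
#'   as app scales imply); FALSE yields the latent continuous ratings.
#' @param seed optional seed for standalone reproducibility.
#' @return the table with the four rating columns appended; attribute
#'   `ground_truth` stores the participant intercepts per outcome.
#' @export
generate_ratings <- function(trip_table, config, discretize = TRUE,
                             seed = NULL) {
  betas <- config$rating_betas
  unknown <- setdiff(names(betas), names(trip_table))
  if (length(unknown))
    stop("generate_ratings: unknown predictor(s) in rating_betas: ",
         paste(unknown, collapse = ", "))
  gen <- function() {
    zs <- vapply(names(betas), function(nm) {
      x <- trip_table[[nm]]
      if (grepl("^poi_", nm)) x[is.na(x)] <- 0
      s <- pop_sd(x)
      if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x, na.rm = TRUE)) / s
    }, numeric(nrow(trip_table)))
    lin <- if (length(betas)) as.numeric(zs %*% unlist(betas)) else 0
    pids <- unique(trip_table$participant_id)
    rng <- attr(rating_outcomes(), "range")
    gt_int <- list()
    out <- trip_table
    for (oc in rating_outcomes()) {
      lo <- rng[[oc]][1]; hi <- rng[[oc]][2]
      grand <- (lo + hi) / 2
      b <- stats::setNames(rnorm(length(pids), 0, config$random_intercept_sd), pids)
      y <- grand + lin + b[as.character(trip_table$participant_id)] +
        rnorm(nrow(trip_table), 0, config$residual_sd)
      if (discretize) y <- pmin(hi, pmax(lo, round(y)))
      out[[oc]] <- as.numeric(y)
      gt_int[[oc]] <- b
    }
    attr(out, "ground_truth") <- list(intercepts = gt_int, betas = betas)
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Direct mixed-model study simulator
#'
#' Simulates the canonical repeated-measures design - standardized
#' independent predictors, participant random intercepts, Gaussian
#' residuals - without the signal-generation chain, for calibrating the
#' mixed-effects estimator: y = sum(beta_j z_j) + b_participant + e.
#'
#' @param betas named numeric vector of true standardized effects.
#' @param n_participants,trips_per_participant design size (default
#'   90 x 25).
#' @param intercept_sd participant intercept SD (default 0.5).
#' @param residual_sd residual SD (default 1).
#' @param seed RNG seed.
#' @return data.frame with `participant_id`, `y` and one column per
#'   predictor (exactly standardized); attribute `truth` echoes the
#'   parameters.
#' @export
simulate_mixed_study <- function(betas, n_participants = 90,
                                 trips_per_participant = 25,
                                 intercept_sd = 0.5, residual_sd = 1,
                                 seed = 1L) {
  p <- length(betas)
  nm <- names(betas) %||% paste0("x", seq_len(p))
  if (is.null(names(betas))) names(betas) <- nm
  n <- n_participants * trips_per_participant
  with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    X <- apply(X, 2, function(c) (c - mean(c)) / pop_sd(c))
    colnames(X) <- nm
    pid <- rep(sprintf("P%03d", seq_len(n_participants)),
               each = trips_per_participant)
    b <- rnorm(n_participants, 0, intercept_sd)
    y <- as.numeric(X %*% betas) + rep(b, each = trips_per_participant) +
      rnorm(n, 0, residual_sd)
    out <- data.frame(participant_id = pid, y = y)
    out <- cbind(out, as.data.frame(X))
    attr(out, "truth") <- list(betas = betas, intercept_sd = intercept_sd,
                               residual_sd = residual_sd)
    out
  })
}
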