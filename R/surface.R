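#' Joint (trial, distance, joint rank) response surface
#'
#' Fits a single GP over three predictors — trial index, symbolic distance
#' and joint rank — to all pairs at once, and evaluates it at a fixed trial
#' (by default the first trial of phase 3, the first exposure to the full
#' pair set). Because distance and joint rank identify pairs uniquely and
#' are mutually orthogonal, the surface can also be read at interpolated
#' coordinates between pairs where no stimulus pairing exists; such grid
#' cells are flagged `interpolated`. Trials are binned along the trial axis
#' before aggregation to keep the input set small.
#'
#' @param records Trial records including the analysis phase.
#' @param response `"accuracy"` (binomial-Laplace GP) or `"logrt"` (exact
#'   Gaussian GP on log reaction time).
#' @param phase Phase to fit (default 3, where all pairs occur).
#' @param at_trial Trial index at which the surface is evaluated (default:
#'   first trial of `phase`).
#' @param trial_bin Width of the trial-index bins (default 20).
#' @param grid_res Grid resolution in distance and joint rank (default
#'   0.1; purely a reporting choice).
#' @param optimize Tune hyperparameters by marginal likelihood.
#' @param params Starting [kernel_params()] (3 lengthscales: trial,
#'   distance, joint rank).
#' @param control Passed to [gp_fit()].
#' @param n_items List length (default 7).
#' @return An object of class `"tigp_surface"`: list with `grid` (columns
#'   `distance`, `joint_rank`, `mean`, `lo99`, `hi99`, `interpolated`),
#'   `pairs` (the valid pair coordinates with 80%/99% intervals and latent
#'   summaries), `latent_cov` (latent posterior covariance across the pair
#'   coordinates, for Monte-Carlo summaries), `fit`, `response`,
#'   `at_trial`.
#' @export
joint_surface <- function(records, response = c("accuracy", "logrt"),
                          phase = 3L, at_trial = NULL, trial_bin = 20L,
                          grid_res = 0.1, optimize = TRUE, params = NULL,
                          control = list(), n_items = 7) {
  response <- match.arg(response)
  r <- records[records$phase == phase, , drop = FALSE]
  if (nrow(r) == 0L) stop("no phase-", phase, " records", call. = FALSE)
  t0 <- min(r$trial_index)
  at_trial <- at_trial %||% t0
  bin <- floor((r$trial_index - t0) / trial_bin)
  r$.t <- t0 + bin * trial_bin + (trial_bin - 1) / 2
  key <- paste(r$.t, r$distance, r$joint_rank)

  if (response == "accuracy") {
    k <- tapply(r$correct, key, sum)
    m <- tapply(r$correct, key, length)
    X <- do.call(rbind, lapply(strsplit(names(k), " "), as.numeric))
    colnames(X) <- c("trial_index", "distance", "joint_rank")
    params <- params %||% kernel_params(
      variance = 1,
      lengthscales = c(max(diff(range(X[, 1L])) / 4, trial_bin), 2, 4))
    fit <- gp_fit(X, successes = as.integer(k), totals = as.integer(m),
                  params = params, optimize = optimize, control = control)
  } else {
    if (anyNA(r$rt_seconds) || any(r$rt_seconds <= 0))
      stop("reaction times must be positive and non-missing", call. = FALSE)
    lrt <- log(r$rt_seconds)
    y <- tapply(lrt, key, mean)
    w <- tapply(lrt, key, length)
    X <- do.call(rbind, lapply(strsplit(names(y), " "), as.numeric))
    colnames(X) <- c("trial_index", "distance", "joint_rank")
    params <- params %||% kernel_params(
      variance = max(stats::var(as.numeric(y)), 0.01),
      lengthscales = c(max(diff(range(X[, 1L])) / 4, trial_bin), 2, 4))
    fit <- gp_fit(X, y = as.numeric(y), weights = as.numeric(w),
                  params = params, optimize = optimize, control = control)
  }

  pairs <- phase_pairs(phase, n_items)
  d_grid <- seq(1, max(pairs$distance), by = grid_res)
  j_grid <- seq(min(pairs$joint_rank), max(pairs$joint_rank), by = grid_res)
  grid <- expand.grid(distance = d_grid, joint_rank = j_grid)
  Xg <- cbind(trial_index = at_trial, distance = grid$distance,
              joint_rank = grid$joint_rank)
  pg <- predict(fit, Xg)
  pair_key <- paste(pairs$distance, pairs$joint_rank)
  grid_key <- paste(round(grid$distance, 6), round(grid$joint_rank, 6))
  grid$mean <- pg$mean
  grid$lo99 <- pg$lo99
  grid$hi99 <- pg$hi99
  grid$interpolated <- !(grid_key %in% pair_key)

  Xp <- cbind(trial_index = at_trial, distance = pairs$distance,
              joint_rank = pairs$joint_rank)
  pp <- predict(fit, Xp, full_cov = TRUE)
  pair_tab <- cbind(pairs[, c("pair", "distance", "joint_rank")],
                    pp[, c("latent_mean", "latent_sd", "mean", "lo80",
                           "hi80", "lo99", "hi99")])
  rownames(pair_tab) <- NULL

  structure(list(response = response, at_trial = at_trial,
                 grid = grid, pairs = pair_tab,
                 latent_cov = attr(pp, "latent_cov"), fit = fit,
                 n_items = n_items),
            class = "tigp_surface")
}

#' @export
print.tigp_surface <- function(x, ...) {
  cat("Joint (trial, distance, joint rank) surface —", x$response,
      "at trial", x$at_trial, "\n")
  cat("  grid:", nrow(x$grid), "cells (",
      sum(!x$grid$interpolated), "at valid pair coordinates )\n")
  print(utils::head(x$pairs[, c("pair", "distance", "joint_rank", "mean",
                                "lo80", "hi80")], 5))
  cat("  ...", nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' @export
plot.tigp_surface <- function(x, ...) {
  d <- sort(unique(x$grid$distance))
  j <- sort(unique(x$grid$joint_rank))
  z <- matrix(x$grid$mean[order(x$grid$joint_rank, x$grid$distance)],
              nrow = length(d), ncol = length(j))
  image(d, j, z, col = hcl.colors(50, "viridis"),
        xlab = "symbolic distance", ylab = "joint rank",
        main = paste(x$response, "at trial", x$at_trial), ...)
  points(x$pairs$distance, x$pairs$joint_rank, pch = 21, bg = "white")
  invisible(x)
}

# a constant profile carries no trend; report 0 rather than NA
spearman_or_zero <- function(v, d) {
  if (stats::sd(v) < 1e-12) return(0)
  stats::cor(v, d, method = "spearman")
}

#' Distance-effect and terminal-item summaries
#'
#' From a fitted [joint_surface()], computes (a) the Spearman rank
#' correlation between the per-pair response estimate and symbolic
#' distance — the symbolic distance effect as a trend statistic — and (b)
#' the terminal-item contrast: mean estimate over pairs containing the
#' first or last list item minus the mean over the remaining pairs.
#' Monte-Carlo credible intervals are obtained by drawing from the joint
#' latent posterior at the pair coordinates and recomputing both
#' statistics per draw. A plain data.frame with `distance` and `mean`
#' columns (e.g. a [learning_rates()] table, with `rate` as the value) is
#' also accepted, yielding point statistics without intervals.
#'
#' @param x A `"tigp_surface"` or a data.frame with `distance` and a value
#'   column.
#' @param value Value column name for the data.frame method (default
#'   `"mean"`, or `"rate"` if present).
#' @param n_draws Posterior draws for the Monte-Carlo intervals.
#' @param seed Integer seed for the draws.
#' @return A data.frame with rows `distance_trend` and
#'   `terminal_contrast`: `estimate`, and (surface input) `lo80`, `hi80`,
#'   `lo99`, `hi99`.
#' @export
effect_stats <- function(x, value = NULL, n_draws = 2000L, seed = NULL) {
  if (inherits(x, "tigp_surface")) {
    tab <- x$pairs
    if (length(unique(tab$distance)) < 3L)
      stop("undefined trend: need at least 3 distinct distances",
           call. = FALSE)
    terminal <- LETTERS[c(1L, x$n_items)]
    is_term <- substr(tab$pair, 1, 1) %in% terminal |
      substr(tab$pair, 2, 2) %in% terminal
    link <- if (x$response == "accuracy") stats::plogis else identity
    stat <- function(v) c(
      distance_trend = spearman_or_zero(v, tab$distance),
      terminal_contrast = mean(v[is_term]) - mean(v[!is_term]))
    est <- stat(tab$mean)
    draws <- with_seed(seed, {
      S <- x$latent_cov + diag(1e-10, nrow(tab))
      Lc <- chol(S)
      Z <- matrix(stats::rnorm(n_draws * nrow(tab)), nrow(tab), n_draws)
      Fd <- tab$latent_mean + crossprod(Lc, Z)
      apply(link(Fd), 2L, stat)
    })
    qs <- apply(draws, 1L, stats::quantile,
                probs = c(0.10, 0.90, 0.005, 0.995))
    out <- data.frame(statistic = names(est), estimate = unname(est),
                      lo80 = qs[1L, ], hi80 = qs[2L, ],
                      lo99 = qs[3L, ], hi99 = qs[4L, ])
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(is.data.frame(x), "distance" %in% names(x))
  value <- value %||% if ("rate" %in% names(x)) "rate" else "mean"
  if (length(unique(x$distance)) < 3L)
    stop("undefined trend: need at least 3 distinct distances",
         call. = FALSE)
  v <- x[[value]]
  terminal <- LETTERS[c(1L, 7L)]
  is_term <- if ("pair" %in% names(x))
    substr(x$pair, 1, 1) %in% terminal | substr(x$pair, 2, 2) %in% terminal
  else rep(FALSE, nrow(x))
  data.frame(statistic = c("distance_trend", "terminal_contrast"),
             estimate = c(spearman_or_zero(v, x$distance),
                          if (any(is_term))
                            mean(v[is_term]) - mean(v[!is_term])
                          else NA_real_))
}
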