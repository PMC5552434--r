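#' Binomial counts per trial index for one pair and phase
#'
#' Correct flags are summed across sessions and subjects at each trial
#' index, turning Bernoulli trials into binomial counts with at most one
#' input per trial index — the aggregation that keeps exact GP inference
#' tractable at any number of sessions.
#'
#' @param records Trial records (see [read_records()] for the format).
#' @param pair Pair label, e.g. `"FG"`, or two item labels.
#' @param phase Phase id (1, 2 or 3).
#' @return A data.frame `trial_index`, `k` (correct), `m` (sessions
#'   contributing). Zero rows (not zero counts) when the selection is
#'   empty.
#' @export
aggregate_counts <- function(records, pair, phase) {
  labs <- sort(parse_pair(pair))
  sel <- records$phase == phase &
    records$item_lo == labs[1L] & records$item_hi == labs[2L]
  r <- records[sel, , drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(trial_index = integer(0), k = integer(0),
                      m = integer(0)))
  k <- tapply(r$correct, r$trial_index, sum)
  m <- tapply(r$correct, r$trial_index, length)
  ti <- as.integer(names(k))
  ord <- order(ti)
  data.frame(trial_index = ti[ord], k = as.integer(k[ord]),
             m = as.integer(m[ord]))
}

phase_trial_range <- function(records, phase) {
  ti <- records$trial_index[records$phase == phase]
  if (length(ti) == 0L) stop("no trials in phase ", phase, call. = FALSE)
  range(ti)
}

default_curve_params <- function(trial_index) {
  span <- max(diff(range(trial_index)), 1)
  kernel_params(variance = 1, lengthscales = max(span / 5, 1))
}

#' Accuracy time series for one pair and phase
#'
#' Fits a binomial-likelihood GP (Laplace approximation, logit link) to the
#' across-session correct counts of one pair over trial index, and predicts
#' the probability of a correct choice (with 80%/99% credible bands) at
#' every trial index of the phase.
#'
#' @inheritParams aggregate_counts
#' @param optimize Tune kernel hyperparameters by marginal likelihood
#'   (default `TRUE`).
#' @param params Starting [kernel_params()]; default lengthscale is a fifth
#'   of the phase span.
#' @param control Passed to [gp_fit()].
#' @return A data.frame of class `"tigp_curve"` (`pair`, `phase`,
#'   `trial_index`, prediction columns of [predict.tigp()]), with the
#'   fitted `"tigp"` model in `attr(, "fit")`.
#' @export
accuracy_timeseries <- function(records, pair, phase, optimize = TRUE,
                                params = NULL, control = list()) {
  series <- aggregate_counts(records, pair, phase)
  if (nrow(series) == 0L)
    stop("empty series: pair ", paste(parse_pair(pair), collapse = ""),
         " has no phase-", phase, " trials", call. = FALSE)
  params <- params %||% default_curve_params(series$trial_index)
  fit <- gp_fit(series$trial_index, successes = series$k, totals = series$m,
                params = params, optimize = optimize, control = control)
  rng <- phase_trial_range(records, phase)
  grid <- seq(rng[1L], rng[2L])
  out <- predict(fit, grid)
  names(out)[1L] <- "trial_index"
  out <- cbind(pair = paste(sort(parse_pair(pair)), collapse = ""),
               phase = phase, out)
  attr(out, "fit") <- fit
  class(out) <- c("tigp_curve", "data.frame")
  out
}

#' Log reaction-time series for one pair and phase
#'
#' Log RTs are averaged per trial index across sessions and fitted with an
#' exact Gaussian-likelihood GP whose per-index noise variance scales
#' inversely with the number of sessions averaged.
#'
#' @inheritParams accuracy_timeseries
#' @return A `"tigp_curve"` data.frame on the log-RT scale.
#' @export
rt_timeseries <- function(records, pair, phase, optimize = TRUE,
                          params = NULL, control = list()) {
  labs <- sort(parse_pair(pair))
  sel <- records$phase == phase &
    records$item_lo == labs[1L] & records$item_hi == labs[2L]
  r <- records[sel, , drop = FALSE]
  if (nrow(r) == 0L)
    stop("empty series: pair ", paste(labs, collapse = ""),
         " has no phase-", phase, " trials", call. = FALSE)
  if (anyNA(r$rt_seconds) || any(r$rt_seconds <= 0))
    stop("reaction times must be positive and non-missing", call. = FALSE)
  lrt <- log(r$rt_seconds)
  y <- tapply(lrt, r$trial_index, mean)
  w <- tapply(lrt, r$trial_index, length)
  ti <- as.integer(names(y))
  ord <- order(ti)
  ti <- ti[ord]; y <- as.numeric(y[ord]); w <- as.numeric(w[ord])
  params <- params %||% {
    p <- default_curve_params(ti)
    p$variance <- max(stats::var(y), 0.01)
    p
  }
  fit <- gp_fit(ti, y = y, weights = w, params = params,
                optimize = optimize, control = control)
  rng <- phase_trial_range(records, phase)
  out <- predict(fit, seq(rng[1L], rng[2L]))
  names(out)[1L] <- "trial_index"
  out <- cbind(pair = paste(labs, collapse = ""), phase = phase, out)
  attr(out, "fit") <- fit
  class(out) <- c("tigp_curve", "data.frame")
  out
}

#' @export
plot.tigp_curve <- function(x, xlab = "trial", ylab = "estimate", ...) {
  g <- x$trial_index
  plot(g, x$mean, type = "n", ylim = range(x$lo99, x$hi99),
       xlab = xlab, ylab = ylab, ...)
  polygon(c(g, rev(g)), c(x$lo99, rev(x$hi99)), col = grey(0.9),
          border = NA)
  polygon(c(g, rev(g)), c(x$lo80, rev(x$hi80)), col = grey(0.78),
          border = NA)
  lines(g, x$mean, lwd = 2)
  invisible(x)
}

classify_transition <- function(records, n_items = 7) {
  last_two <- LETTERS[c(n_items - 1L, n_items)]  # F, G in the 7-item design
  ifelse(records$item_lo == last_two[1L] & records$item_hi == last_two[2L],
         "fg",
  ifelse(records$item_hi == last_two[1L], "xf",
  ifelse(records$item_hi == last_two[2L], "xg", "other")))
}

#' Presentation-indexed choice profile at the phase 1 to 2 transition
#'
#' Reproduces the order-of-appearance analysis of the massed-pair
#' transition: the last four massed-phase presentations of the massed pair
#' (segment `fg_phase1`), then the 1st–6th within-session instance in
#' phase 2 of the massed pair (`fg`), of any pairing of the massed
#' rewarded item with a novel stimulus (`xf`), and of any novel pairing
#' with the never-rewarded item (`xg`). Counts are pooled across sessions
#' and subjects at each presentation index and summarised by a
#' Beta-binomial posterior under a uniform Beta(1, 1) prior, with
#' equal-tailed 80% and 99% credible intervals. Both the probability of a
#' correct choice (`accuracy`) and of choosing the massed item tracked by
#' the segment (`choice`; F for `fg`/`xf`, G for `xg`) are reported.
#'
#' @param records Trial records (phases 1 and 2 must be present).
#' @param n_presentations Phase-2 instances to report (default 6).
#' @param n_items List length (default 7).
#' @return A data.frame of class `"tigp_transition"`: `segment`,
#'   `presentation`, `k`, `m`, `accuracy`, `acc_lo80` ... `acc_hi99`,
#'   `choice`, `cho_lo80` ... `cho_hi99`. If fewer instances exist than
#'   requested, existing ones are reported and
#'   `attr(, "truncated") = TRUE`.
#' @export
transition_profile <- function(records, n_presentations = 6L, n_items = 7) {
  if (!all(c(1, 2) %in% records$phase))
    stop("transition profile needs phases 1 and 2", call. = FALSE)
  records$.class <- classify_transition(records, n_items)
  key <- interaction(records$subject, records$session, drop = TRUE)

  rows <- list()
  for (ses in split(records, key)) {
    p1 <- ses[ses$phase == 1 & ses$.class == "fg", , drop = FALSE]
    p1 <- p1[order(p1$trial_index), , drop = FALSE]
    n1 <- nrow(p1)
    take <- seq.int(max(1L, n1 - 3L), n1)
    rows[[length(rows) + 1L]] <- data.frame(
      segment = "fg_phase1", presentation = seq_along(take),
      correct = p1$correct[take],
      chose_massed = as.integer(p1$chosen[take] == p1$item_lo[take]))
    p2 <- ses[ses$phase == 2 & ses$.class != "other", , drop = FALSE]
    p2 <- p2[order(p2$trial_index), , drop = FALSE]
    for (cl in c("fg", "xf", "xg")) {
      sub <- p2[p2$.class == cl, , drop = FALSE]
      take <- seq_len(min(n_presentations, nrow(sub)))
      if (length(take) == 0L) next
      chose_massed <- if (cl == "fg")
        as.integer(sub$chosen[take] == sub$item_lo[take])   # chose F
      else
        as.integer(sub$chosen[take] == sub$item_hi[take])   # chose F or G
      rows[[length(rows) + 1L]] <- data.frame(
        segment = cl, presentation = take,
        correct = sub$correct[take], chose_massed = chose_massed)
    }
  }
  long <- do.call(rbind, rows)
  agg <- function(v) {
    k <- tapply(v, list(long$segment, long$presentation), sum)
    m <- tapply(v, list(long$segment, long$presentation), length)
    list(k = k, m = m)
  }
  acc <- agg(long$correct)
  cho <- agg(long$chose_massed)
  cells <- which(!is.na(acc$m), arr.ind = TRUE)
  beta_cols <- function(k, m, prefix) {
    out <- data.frame((k + 1) / (m + 2),
                      stats::qbeta(0.10, k + 1, m - k + 1),
                      stats::qbeta(0.90, k + 1, m - k + 1),
                      stats::qbeta(0.005, k + 1, m - k + 1),
                      stats::qbeta(0.995, k + 1, m - k + 1))
    names(out) <- paste0(prefix, c("", "_lo80", "_hi80", "_lo99", "_hi99"))
    out
  }
  k_acc <- acc$k[cells]; m_all <- acc$m[cells]; k_cho <- cho$k[cells]
  out <- cbind(
    data.frame(segment = rownames(acc$k)[cells[, 1L]],
               presentation = as.integer(colnames(acc$k)[cells[, 2L]]),
               k = as.integer(k_acc), m = as.integer(m_all)),
    stats::setNames(beta_cols(k_acc, m_all, "acc"),
                    c("accuracy", "acc_lo80", "acc_hi80", "acc_lo99",
                      "acc_hi99")),
    stats::setNames(beta_cols(k_cho, m_all, "cho"),
                    c("choice", "cho_lo80", "cho_hi80", "cho_lo99",
                      "cho_hi99")))
  out <- out[order(match(out$segment, c("fg_phase1", "fg", "xf", "xg")),
                   out$presentation), , drop = FALSE]
  rownames(out) <- NULL
  expect_p2 <- out$segment != "fg_phase1"
  truncated <- any(tapply(out$presentation[expect_p2],
                          out$segment[expect_p2], max) < n_presentations)
  if (truncated)
    warning("fewer than ", n_presentations,
            " phase-2 instances available for some segment; ",
            "reporting what exists")
  attr(out, "truncated") <- truncated
  class(out) <- c("tigp_transition", "data.frame")
  out
}

#' @export
plot.tigp_transition <- function(x, value = c("accuracy", "choice"), ...) {
  value <- match.arg(value)
  segs <- c("fg_phase1", "fg", "xf", "xg")
  x$.x <- x$presentation + 4 * (match(x$segment, segs) > 1)
  cols <- c(fg_phase1 = "black", fg = "black", xf = "darkolivegreen4",
            xg = "cyan4")
  pre <- if (value == "accuracy") "acc" else "cho"
  v <- x[[value]]
  plot(x$.x, v, ylim = c(0, 1), pch = 16, col = cols[x$segment],
       xlab = "presentation", ylab = value, ...)
  segments(x$.x, x[[paste0(pre, "_lo99")]], x$.x, x[[paste0(pre, "_hi99")]],
           col = cols[x$segment])
  segments(x$.x - 0.15, x[[paste0(pre, "_lo80")]], x$.x + 0.15,
           x[[paste0(pre, "_lo80")]], col = cols[x$segment])
  segments(x$.x - 0.15, x[[paste0(pre, "_hi80")]], x$.x + 0.15,
           x[[paste0(pre, "_hi80")]], col = cols[x$segment])
  abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Per-pair learning rates at the start of a phase
#'
#' For each pair presented in the phase, fits the accuracy GP and evaluates
#' the posterior of the latent derivative at the phase's first trial index:
#' the learning rate in log-odds of a correct response per trial. Pairs are
#' sorted by symbolic distance, then joint rank.
#'
#' @inheritParams accuracy_timeseries
#' @param phase Phase id, 2 or 3.
#' @param n_items List length (default 7).
#' @return A data.frame of class `"tigp_rates"`: `pair`, `distance`,
#'   `joint_rank`, `at_trial`, `rate`, `sd`, `lo80`, `hi80`, `lo99`,
#'   `hi99`.
#' @export
learning_rates <- function(records, phase, optimize = TRUE, params = NULL,
                           control = list(), n_items = 7) {
  if (!phase %in% c(2L, 3L))
    stop("learning rates are defined at the start of phase 2 or 3",
         call. = FALSE)
  at_trial <- phase_trial_range(records, phase)[1L]
  pairs <- phase_pairs(phase, n_items)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    series <- aggregate_counts(records, pairs$pair[i], phase)
    if (nrow(series) == 0L) return(NULL)
    p <- params %||% default_curve_params(series$trial_index)
    fit <- gp_fit(series$trial_index, successes = series$k,
                  totals = series$m, params = p, optimize = optimize,
                  control = control)
    d <- gp_derivative(fit, at_trial)
    data.frame(pair = pairs$pair[i], distance = pairs$distance[i],
               joint_rank = pairs$joint_rank[i], at_trial = at_trial,
               rate = d$mean, sd = d$sd, lo80 = d$lo80, hi80 = d$hi80,
               lo99 = d$lo99, hi99 = d$hi99)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$distance, out$joint_rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tigp_rates", "data.frame")
  out
}

#' @export
plot.tigp_rates <- function(x, ...) {
  i <- seq_len(nrow(x))
  plot(i, x$rate, pch = 16, ylim = range(x$lo99, x$hi99), xaxt = "n",
       xlab = "pair (by distance, joint rank)",
       ylab = "learning rate (log-odds / trial)", ...)
  axis(1, at = i, labels = x$pair, las = 2, cex.axis = 0.7)
  segments(i, x$lo99, i, x$hi99)
  segments(i - 0.2, x$lo80, i + 0.2, x$lo80)
  segments(i - 0.2, x$hi80, i + 0.2, x$hi80)
  abline(h = 0, lty = 3)
  invisible(x)
}
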