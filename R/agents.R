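#' Associative (delta-rule + value transfer) agent configuration
#'
#' A stimulus-value learner: each item carries a scalar reward value,
#' choices are a softmax over the two displayed values, and the chosen
#' item's value moves toward 1 after reward and toward 0 otherwise at rate
#' `alpha`. With `theta > 0` a fraction of the rewarded item's value leaks
#' to the item it was paired with (value transfer). Such agents bind value
#' to stimuli, not to list structure, so massed training of the final pair
#' predicts a persistent bias toward the massed rewarded item when it later
#' meets novel stimuli.
#'
#' @param alpha Learning rate in (0, 1].
#' @param beta Softmax inverse temperature (>= 0); `beta = 0` gives random
#'   choice.
#' @param theta Value-transfer coefficient in \[0, 1\].
#' @param v0 Initial stimulus value (default 0.5, neutral between the
#'   reward outcomes 0 and 1).
#' @return An object of class `"associative_config"`.
#' @export
associative_config <- function(alpha = 0.2, beta = 5, theta = 0, v0 = 0.5) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (theta < 0 || theta > 1) stop("theta must be in [0, 1]", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, theta = theta, v0 = v0),
            class = c("associative_config", "agent_config"))
}

#' Representational (noisy ordinal position) agent configuration
#'
#' The agent maintains a noisy estimate of each item's list position and
#' chooses the item whose noisy reading looks earlier. Trial feedback
#' reveals the displayed pair's true order, and the agent shrinks any
#' ordering violation at rate `learn_rate` (after correct choices) or
#' `relearn_rate` (after errors). `massed_prior` encodes cross-session task
#' knowledge: at the transition out of the massed phase the items seen
#' during massing are re-anchored toward the late (incorrect) end of the
#' list with that strength, because experienced subjects have learned that
#' massed-phase stimuli are ordered after stimuli introduced later in the
#' session. With `massed_prior > 0` (monkey-like) the agent avoids the
#' massed rewarded item on its very first pairing with a novel stimulus;
#' with `massed_prior = 0` (task-naive, human-like) it transiently prefers
#' it and must unlearn the preference from errors.
#'
#' @param position_noise Standard deviation of the noisy position readings
#'   (list-rank units).
#' @param learn_rate Violation-shrink step after a correct choice, in
#'   \[0, 1\].
#' @param massed_prior Strength in \[0, 1\] of the massed-items-rank-late
#'   prior applied at the phase 1 -> 2 boundary.
#' @param relearn_rate Violation-shrink step after an error, in \[0, 1\];
#'   fast post-error correction gives the rapid human-like reversal.
#' @return An object of class `"representational_config"`.
#' @export
representational_config <- function(position_noise = 0.5, learn_rate = 0.3,
                                    massed_prior = 0, relearn_rate = 0.8) {
  vals <- c(position_noise, learn_rate, massed_prior, relearn_rate)
  if (any(vals < 0)) stop("all parameters must be non-negative", call. = FALSE)
  if (massed_prior > 1) stop("massed_prior must be in [0, 1]", call. = FALSE)
  structure(list(position_noise = position_noise, learn_rate = learn_rate,
                 massed_prior = massed_prior, relearn_rate = relearn_rate),
            class = c("representational_config", "agent_config"))
}

#' Species-typical agent configurations
#'
#' Monkey-like: a representational agent with a strong massed prior and slow
#' position updates (slow learning over 760-trial sessions). Human-like: a
#' task-naive representational agent with roughly ten-fold faster updates,
#' so the transient preference for the massed rewarded item is reversed
#' within a few presentations.
#'
#' @param species `"monkey"` or `"human"`.
#' @return A [representational_config()].
#' @export
default_agent_config <- function(species = c("monkey", "human")) {
  species <- match.arg(species)
  if (species == "monkey")
    representational_config(position_noise = 0.5, learn_rate = 0.04,
                            massed_prior = 0.8, relearn_rate = 0.08)
  else
    representational_config(position_noise = 0.5, learn_rate = 0.3,
                            massed_prior = 0, relearn_rate = 0.8)
}

#' Reaction-time model configuration
#'
#' Reaction times are log-normal: log RT is Gaussian with mean
#' `mu0 + distance_slope * distance + practice_slope * trial_index` and
#' standard deviation `sigma`. The defaults by species reproduce the two
#' observed response regimes: fast oculomotor monkey responses with median
#' exp(-1.35) ~ 0.26 s and no practice trend (a floor), and slower human
#' mouse responses with median exp(0.5) ~ 1.65 s, a symbolic-distance
#' speed-up and steady within-session practice gains.
#'
#' @param mu0 Baseline mean log-RT (log seconds).
#' @param distance_slope Change in mean log-RT per unit symbolic distance
#'   (<= 0 for a distance effect).
#' @param practice_slope Per-trial trend in mean log-RT (< 0 = speeds up).
#' @param sigma Residual sd of log-RT (> 0).
#' @param species If given, fills defaults for that species and ignores the
#'   other arguments that were not explicitly supplied.
#' @return An object of class `"rt_config"`.
#' @export
rt_config <- function(mu0 = -1.35, distance_slope = 0, practice_slope = 0,
                      sigma = 0.25, species = NULL) {
  if (!is.null(species)) {
    species <- match.arg(species, c("monkey", "human"))
    if (species == "human") {
      if (missing(mu0)) mu0 <- 0.5
      if (missing(distance_slope)) distance_slope <- -0.03
      if (missing(practice_slope)) practice_slope <- -5e-4
    }
  }
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(mu0 = mu0, distance_slope = distance_slope,
                 practice_slope = practice_slope, sigma = sigma),
            class = "rt_config")
}

new_records <- function(schedule, chosen, subject = 1L, session = 1L) {
  data.frame(
    subject = subject, session = session,
    trial_index = schedule$trial_index, phase = schedule$phase,
    item_lo = schedule$item_lo, item_hi = schedule$item_hi,
    distance = schedule$distance, joint_rank = schedule$joint_rank,
    pair = schedule$pair,
    chosen = chosen,
    correct = as.integer(chosen == schedule$item_lo),
    rt_seconds = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate a session from the associative agent
#'
#' @param schedule A session schedule from [build_schedule()].
#' @param config An [associative_config()].
#' @param seed Integer seed.
#' @return A data.frame of trial records (`rt_seconds` unset; see
#'   [simulate_rt()]).
#' @export
simulate_associative <- function(schedule, config = associative_config(),
                                 seed = NULL) {
  stopifnot(inherits(config, "associative_config"))
  with_seed(seed, {
    labels <- sort(unique(c(schedule$item_lo, schedule$item_hi)))
    v <- stats::setNames(rep(config$v0, length(labels)), labels)
    chosen <- character(nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      lo <- schedule$item_lo[i]; hi <- schedule$item_hi[i]
      p_lo <- stats::plogis(config$beta * (v[[lo]] - v[[hi]]))
      pick <- if (stats::runif(1) < p_lo) lo else hi
      other <- if (pick == lo) hi else lo
      reward <- pick == lo
      v[[pick]] <- v[[pick]] + config$alpha * (as.numeric(reward) - v[[pick]])
      if (reward && config$theta > 0)
        v[[other]] <- v[[other]] +
          config$theta * config$alpha * (v[[pick]] - v[[other]])
      chosen[i] <- pick
    }
    new_records(schedule, chosen)
  })
}

#' Simulate a session from the representational agent
#'
#' @param schedule A session schedule from [build_schedule()].
#' @param config A [representational_config()].
#' @param seed Integer seed.
#' @return A data.frame of trial records (`rt_seconds` unset).
#' @export
simulate_representational <- function(schedule,
                                      config = representational_config(),
                                      seed = NULL) {
  stopifnot(inherits(config, "representational_config"))
  with_seed(seed, {
    labels <- sort(unique(c(schedule$item_lo, schedule$item_hi)))
    n <- length(labels)
    # mildly informative start: all items near the list midpoint
    psi <- stats::setNames((n + 1) / 2 +
                             stats::rnorm(n, 0, config$position_noise / 2),
                           labels)
    massed <- unique(c(schedule$item_lo[schedule$phase == 1],
                       schedule$item_hi[schedule$phase == 1]))
    anchored <- FALSE
    gap <- 1
    chosen <- character(nrow(schedule))
    for (i in seq_len(nrow(schedule))) {
      if (!anchored && schedule$phase[i] > 1) {
        # cross-session task knowledge: massed-phase items sit late in the
        # list relative to items introduced afterwards
        m <- config$massed_prior
        psi[massed] <- (1 - m) * psi[massed] + m * (n - 0.5)
        anchored <- TRUE
      }
      lo <- schedule$item_lo[i]; hi <- schedule$item_hi[i]
      read_lo <- psi[[lo]] + stats::rnorm(1, 0, config$position_noise)
      read_hi <- psi[[hi]] + stats::rnorm(1, 0, config$position_noise)
      pick <- if (read_lo <= read_hi) lo else hi
      correct <- pick == lo
      rate <- if (correct) config$learn_rate else config$relearn_rate
      viol <- psi[[lo]] - psi[[hi]] + gap
      if (viol > 0) {
        psi[[lo]] <- psi[[lo]] - rate * viol / 2
        psi[[hi]] <- psi[[hi]] + rate * viol / 2
      }
      chosen[i] <- pick
    }
    new_records(schedule, chosen)
  })
}

#' Simulate a session with parametric per-trial accuracy
#'
#' A generator with known ground truth for recovery studies: the
#' probability of a correct choice on each trial is supplied directly as a
#' function of the schedule row (trial index, distance, joint rank), and
#' choices are independent Bernoulli draws.
#'
#' @param schedule A session schedule from [build_schedule()].
#' @param config A `parametric_config(accuracy_fun)` whose `accuracy_fun`
#'   maps a schedule data.frame to a vector of correct-choice
#'   probabilities.
#' @param seed Integer seed.
#' @return A data.frame of trial records.
#' @export
simulate_parametric <- function(schedule, config, seed = NULL) {
  stopifnot(inherits(config, "parametric_config"))
  with_seed(seed, {
    p <- config$accuracy_fun(schedule)
    stopifnot(length(p) == nrow(schedule), all(p >= 0 & p <= 1))
    ok <- stats::runif(nrow(schedule)) < p
    new_records(schedule, ifelse(ok, schedule$item_lo, schedule$item_hi))
  })
}

#' @rdname simulate_parametric
#' @param accuracy_fun Function of a schedule data.frame returning per-trial
#'   correct-choice probabilities in \[0, 1\].
#' @export
parametric_config <- function(accuracy_fun) {
  stopifnot(is.function(accuracy_fun))
  structure(list(accuracy_fun = accuracy_fun),
            class = c("parametric_config", "agent_config"))
}

simulate_agent <- function(config, schedule, seed = NULL) {
  UseMethod("simulate_agent")
}
#' @export
simulate_agent.associative_config <- function(config, schedule, seed = NULL)
  simulate_associative(schedule, config, seed)
#' @export
simulate_agent.representational_config <- function(config, schedule,
                                                   seed = NULL)
  simulate_representational(schedule, config, seed)
#' @export
simulate_agent.parametric_config <- function(config, schedule, seed = NULL)
  simulate_parametric(schedule, config, seed)

#' Fill in log-normal reaction times
#'
#' @param records Trial records (need `distance` and `trial_index`).
#' @param config An [rt_config()].
#' @param seed Integer seed.
#' @return `records` with `rt_seconds` drawn from the log-normal model.
#' @export
simulate_rt <- function(records, config = rt_config(), seed = NULL) {
  stopifnot(inherits(config, "rt_config"))
  with_seed(seed, {
    mu <- config$mu0 + config$distance_slope * records$distance +
      config$practice_slope * records$trial_index
    records$rt_seconds <- exp(stats::rnorm(nrow(records), mu, config$sigma))
    records
  })
}

#' Simulate a full cohort
#'
#' One independent schedule and one fresh agent per (subject, session) —
#' stimuli are novel every session, so within-session learning restarts;
#' only the representational agent's massed prior represents knowledge
#' carried across sessions.
#'
#' @param profile A [species_profile()].
#' @param agent_config An agent configuration (associative,
#'   representational or parametric).
#' @param rt_cfg An [rt_config()] (or `NULL` to leave RTs unset).
#' @param n_subjects Number of subjects (default: 3 monkeys, 33 humans).
#' @param seed Master integer seed; every (subject, session) draws a
#'   derived sub-seed, so the full dataset is reproducible.
#' @return A data.frame of trial records over all subjects and sessions.
#' @export
#' @examples
#' prof <- species_profile("human")
#' d <- generate_cohort(prof, default_agent_config("human"),
#'                      rt_config(species = "human"), n_subjects = 2, seed = 1)
#' nrow(d)  # 2 * 380
generate_cohort <- function(profile, agent_config,
                            rt_cfg = rt_config(species = profile$name),
                            n_subjects = NULL, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"),
            inherits(agent_config, "agent_config"))
  n_subjects <- n_subjects %||% if (profile$name == "monkey") 3L else 33L
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  out <- vector("list", n_subjects * profile$sessions_per_subject)
  k <- 0L
  for (subj in seq_len(n_subjects)) {
    for (sess in seq_len(profile$sessions_per_subject)) {
      k <- k + 1L
      sched <- build_schedule(profile, seed = derive_seed(seed, 3L * k))
      rec <- simulate_agent(agent_config, sched,
                            seed = derive_seed(seed, 3L * k + 1L))
      rec$subject <- subj
      rec$session <- sess
      if (!is.null(rt_cfg))
        rec <- simulate_rt(rec, rt_cfg, seed = derive_seed(seed, 3L * k + 2L))
      out[[k]] <- rec
    }
  }
  do.call(rbind, out)
}

#' Binomial counts from a known logit-linear accuracy curve
#'
#' Draws `k_t ~ Binomial(n_sessions, plogis(intercept + slope * t))` for
#' trials `t = 1..n_trials` — the minimal ground-truth generator for
#' checking that the Gaussian-process machinery recovers a known latent
#' slope.
#'
#' @param n_trials Number of trial indices.
#' @param n_sessions Binomial total per trial index.
#' @param intercept,slope Logit-scale intercept and per-trial slope.
#' @param seed Integer seed.
#' @return A data.frame with `trial_index`, `k` (successes), `m` (totals).
#' @export
simulate_binomial_curve <- function(n_trials, n_sessions, intercept, slope,
                                    seed = NULL) {
  with_seed(seed, {
    t <- seq_len(n_trials)
    p <- stats::plogis(intercept + slope * t)
    data.frame(trial_index = t,
               k = stats::rbinom(n_trials, n_sessions, p),
               m = n_sessions)
  })
}
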