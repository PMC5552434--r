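# log(1 + exp(f)) without overflow
log1pexp <- function(f) pmax(f, 0) + log1p(exp(-abs(f)))

#' Gaussian-process regression for behavioural time series
#'
#' Fits a zero-one-noise-free latent function f over the inputs with a
#' squared-exponential (ARD) prior and either
#'
#' * a Gaussian likelihood (`likelihood = "gaussian"`) for real targets such
#'   as log reaction times — exact conjugate inference, with optional
#'   per-row weights for targets that are averages of several raw
#'   observations (noise variance `noise_variance / weights`); the prior
#'   mean is the weighted sample mean of `y`; or
#' * a binomial likelihood with logistic link
#'   (`likelihood = "binomial"`) for counts of correct choices — the latent
#'   posterior is approximated by a Laplace (Gaussian at the mode)
#'   approximation found by Newton iteration; the prior mean is 0, i.e.
#'   chance performance in a two-alternative task.
#'
#' @param X Inputs: vector or matrix with one row per observation (e.g.
#'   trial index, optionally symbolic distance and joint rank columns).
#' @param y Real targets (Gaussian likelihood).
#' @param successes,totals Binomial targets: successes `k` out of `m` per
#'   row (binomial likelihood).
#' @param likelihood `"gaussian"` or `"binomial"`; inferred from which
#'   targets are supplied when missing.
#' @param params A [kernel_params()]; starting values when
#'   `optimize = TRUE`.
#' @param noise_variance Gaussian observation noise variance (per raw
#'   observation); ignored for binomial. Default `var(y)/2`.
#' @param weights Gaussian case only: number of raw observations averaged
#'   into each row of `y` (default 1).
#' @param optimize If `TRUE`, hyperparameters are tuned by maximising the
#'   (approximate) log marginal likelihood via [gp_optimize()] before the
#'   final fit.
#' @param control List of Laplace controls: `tol` (max latent change,
#'   default 1e-8) and `maxit` (default 100); plus options passed on to
#'   [gp_optimize()] when `optimize = TRUE`.
#' @return An object of class `"tigp"`: the fitted model, with the latent
#'   mode/mean, Cholesky factors, and the (approximate) log marginal
#'   likelihood (`$lml`). Use [predict.tigp()] and [gp_derivative()].
#' @seealso [gp_optimize()], [predict.tigp()], [gp_derivative()]
#' @export
#' @examples
#' d <- simulate_binomial_curve(60, 25, intercept = -1, slope = 0.05, seed = 1)
#' fit <- gp_fit(d$trial_index, successes = d$k, totals = d$m,
#'               params = kernel_params(1, 20))
#' head(predict(fit, c(1, 30, 60)))
gp_fit <- function(X, y = NULL, successes = NULL, totals = NULL,
                   likelihood = NULL, params = kernel_params(),
                   noise_variance = NULL, weights = NULL,
                   optimize = FALSE, control = list()) {
  X <- as_input_matrix(X)
  if (is.null(likelihood))
    likelihood <- if (!is.null(y)) "gaussian" else "binomial"
  likelihood <- match.arg(likelihood, c("gaussian", "binomial"))

  if (likelihood == "gaussian") {
    if (is.null(y) || !all(is.finite(y)))
      stop("gaussian likelihood needs finite targets y", call. = FALSE)
    stopifnot(length(y) == nrow(X))
    weights <- weights %||% rep(1, length(y))
    stopifnot(length(weights) == length(y), all(weights > 0))
    noise_variance <- noise_variance %||% max(stats::var(y) / 2, 1e-6)
    if (noise_variance <= 0)
      stop("noise_variance must be > 0", call. = FALSE)
  } else {
    if (is.null(successes) || is.null(totals))
      stop("binomial likelihood needs successes and totals", call. = FALSE)
    stopifnot(length(successes) == nrow(X), length(totals) == nrow(X))
    if (any(totals < 1) || any(successes < 0) || any(successes > totals))
      stop("need 0 <= successes <= totals and totals >= 1", call. = FALSE)
  }

  if (optimize) {
    opt <- gp_optimize(X, y = y, successes = successes, totals = totals,
                       likelihood = likelihood, init = params,
                       noise_variance = noise_variance, weights = weights,
                       control = control)
    params <- opt$params
    if (likelihood == "gaussian") noise_variance <- opt$noise_variance
  }

  fit <- if (likelihood == "gaussian")
    gp_fit_gaussian(X, y, params, noise_variance, weights)
  else
    gp_fit_binomial(X, successes, totals, params, control)
  fit$call <- match.call()
  fit$optimized <- optimize
  fit
}

gp_fit_gaussian <- function(X, y, params, noise_variance, weights) {
  n <- nrow(X)
  mu0 <- stats::weighted.mean(y, weights)
  K <- se_kernel(X, params = params)
  Ky <- K + diag(noise_variance / weights, n)
  L <- tryCatch(chol(Ky), error = function(e)
    stop("numerical error: covariance not positive definite after jitter (",
         conditionMessage(e), ")", call. = FALSE))
  r <- y - mu0
  alpha <- backsolve(L, forwardsolve(t(L), r))
  lml <- -0.5 * sum(r * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
  structure(list(likelihood = "gaussian", X = X, y = y, weights = weights,
                 params = params, noise_variance = noise_variance,
                 prior_mean = mu0, alpha = alpha, L = L, lml = lml, n = n),
            class = "tigp")
}

# Laplace approximation for the binomial-logit GP (Newton iteration on the
# latent values; stable B = I + sW K sW parameterisation).
gp_fit_binomial <- function(X, k, m, params, control = list()) {
  tol <- control$tol %||% 1e-8
  maxit <- control$maxit %||% 100L
  n <- nrow(X)
  K <- se_kernel(X, params = params)
  f <- rep(0, n)
  a <- rep(0, n)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    p <- stats::plogis(f)
    W <- pmax(m * p * (1 - p), 1e-12)
    sW <- sqrt(W)
    B <- diag(n) + (sW %o% sW) * K
    L <- tryCatch(chol(B), error = function(e)
      stop("numerical error in Laplace step: ", conditionMessage(e),
           call. = FALSE))
    b <- W * f + (k - m * p)
    a_new <- b - sW * backsolve(L, forwardsolve(t(L), sW * (K %*% b)))
    f_new <- as.numeric(K %*% a_new)
    delta <- max(abs(f_new - f))
    f <- f_new
    a <- as.numeric(a_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("Laplace Newton iteration failed to converge: max latent change ",
         format(delta), " after ", maxit, " iterations", call. = FALSE)
  p <- stats::plogis(f)
  W <- pmax(m * p * (1 - p), 1e-12)
  sW <- sqrt(W)
  L <- chol(diag(n) + (sW %o% sW) * K)
  loglik <- sum(k * f - m * log1pexp(f) + lchoose(m, k))
  lml <- -0.5 * sum(a * f) + loglik - sum(log(diag(L)))
  structure(list(likelihood = "binomial", X = X, successes = k, totals = m,
                 params = params, prior_mean = 0, f_hat = f,
                 grad = k - m * p, sW = sW, L = L, K = K, lml = lml,
                 n = n, iterations = it),
            class = "tigp")
}

#' Hyperparameter optimisation by marginal likelihood
#'
#' Maximises the exact (Gaussian) or Laplace-approximate (binomial) log
#' marginal likelihood over log-transformed hyperparameters with
#' box-constrained quasi-Newton search (`optim(method = "L-BFGS-B")`) from
#' multiple starts. The returned parameters are never worse than the
#' initial ones: the initial value is always a candidate.
#'
#' @inheritParams gp_fit
#' @param init Initial [kernel_params()].
#' @param bounds Optional list with elements `lengthscales` (2-column
#'   matrix or length-2 vector of lower/upper), `variance`, and
#'   `noise_variance`, each a `c(lower, upper)` on the natural scale.
#'   Defaults span from a fraction of the input range to several times it.
#' @param control List: `n_starts` (extra jittered starts, default 2),
#'   `maxit` (per start, default 50), plus Laplace controls.
#' @return List with `params` (tuned [kernel_params()]),
#'   `noise_variance` (Gaussian case), `lml` (achieved log marginal
#'   likelihood) and `lml_init`.
#' @export
gp_optimize <- function(X, y = NULL, successes = NULL, totals = NULL,
                        likelihood = NULL, init = kernel_params(),
                        noise_variance = NULL, weights = NULL,
                        bounds = NULL, control = list()) {
  X <- as_input_matrix(X)
  if (is.null(likelihood))
    likelihood <- if (!is.null(y)) "gaussian" else "binomial"
  likelihood <- match.arg(likelihood, c("gaussian", "binomial"))
  d <- ncol(X)
  gaussian <- likelihood == "gaussian"
  if (gaussian) {
    weights <- weights %||% rep(1, length(y))
    noise_variance <- noise_variance %||% max(stats::var(y) / 2, 1e-6)
  }

  span <- apply(X, 2L, function(v) diff(range(v)))
  span[span <= 0] <- 1
  # lengthscales below the input spacing are unidentifiable; keep them out
  spacing <- apply(X, 2L, function(v) {
    u <- sort(unique(v))
    if (length(u) < 2L) 1 else min(diff(u))
  })
  default_bounds <- list(
    lengthscales = cbind(pmax(spacing, span / 100), span * 10),
    variance = c(1e-4, 100),
    noise_variance = if (gaussian)
      c(1e-8 + 1e-6 * stats::var(y), max(stats::var(y) * 10, 1e-4))
  )
  bounds <- utils::modifyList(default_bounds, bounds %||% list())
  lb_ell <- if (is.matrix(bounds$lengthscales)) bounds$lengthscales[, 1L]
            else rep(bounds$lengthscales[1L], d)
  ub_ell <- if (is.matrix(bounds$lengthscales)) bounds$lengthscales[, 2L]
            else rep(bounds$lengthscales[2L], d)

  lower <- log(c(bounds$variance[1L], lb_ell,
                 if (gaussian) bounds$noise_variance[1L]))
  upper <- log(c(bounds$variance[2L], ub_ell,
                 if (gaussian) bounds$noise_variance[2L]))

  unpack <- function(theta) {
    pars <- kernel_params(exp(theta[1L]), exp(theta[2:(1 + d)]),
                          jitter = init$jitter)
    nv <- if (gaussian) exp(theta[2 + d]) else NULL
    list(params = pars, noise_variance = nv)
  }
  objective <- function(theta) {
    u <- unpack(theta)
    lml <- tryCatch({
      fit <- if (gaussian)
        gp_fit_gaussian(X, y, u$params, u$noise_variance, weights)
      else
        gp_fit_binomial(X, successes, totals, u$params, control)
      fit$lml
    }, error = function(e) -Inf)
    if (!is.finite(lml)) 1e10 else -lml
  }

  theta0 <- pmin(pmax(log(c(init$variance,
                            rep_len(init$lengthscales, d),
                            if (gaussian) noise_variance)),
                      lower), upper)
  n_starts <- control$n_starts %||% 2L
  maxit <- control$maxit %||% 50L
  starts <- c(list(theta0), lapply(seq_len(n_starts), function(i) {
    # deterministic spread of starts across the box, no RNG involved
    frac <- i / (n_starts + 1)
    pmin(pmax(lower + frac * (upper - lower), lower), upper)
  }))

  lml_init <- -objective(theta0)
  best <- list(theta = theta0, value = -lml_init)
  attempts <- character(0)
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) { attempts <<- c(attempts, conditionMessage(e)); NULL })
    if (!is.null(res) && is.finite(res$value) && res$value < best$value)
      best <- list(theta = res$par, value = res$value)
  }
  if (!is.finite(best$value))
    stop("hyperparameter optimisation failed at every start:\n",
         paste(attempts, collapse = "\n"), call. = FALSE)
  u <- unpack(best$theta)
  list(params = u$params, noise_variance = u$noise_variance,
       lml = -best$value, lml_init = lml_init)
}
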