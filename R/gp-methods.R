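Z80 <- stats::qnorm(0.90)   # 80% equal-tailed interval half-width, sd units
Z99 <- stats::qnorm(0.995)

# Gauss-Hermite nodes/weights by Golub-Welsch (physicists' convention:
# integral of exp(-x^2) f(x) dx = sum w_i f(x_i)).
gauss_hermite <- function(n = 20L) {
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = (e$vectors[1L, ord]^2) * sqrt(pi))
}

# E[plogis(f)] for f ~ N(mu, sd^2), vectorised over mu/sd.
averaged_logistic <- function(mu, sd, gh = gauss_hermite(20L)) {
  out <- numeric(length(mu))
  for (j in seq_along(gh$nodes))
    out <- out + gh$weights[j] *
      stats::plogis(mu + sqrt(2) * sd * gh$nodes[j])
  out / sqrt(pi)
}

latent_predict <- function(object, Xnew, full_cov = FALSE) {
  Xnew <- as_input_matrix(Xnew)
  if (ncol(Xnew) != ncol(object$X))
    stop("dimension mismatch: model has ", ncol(object$X),
         " input dimension(s), newdata has ", ncol(Xnew), call. = FALSE)
  Ks <- kern_cross(Xnew, object$X, object$params)
  if (object$likelihood == "gaussian") {
    mu <- object$prior_mean + as.numeric(Ks %*% object$alpha)
    V <- forwardsolve(t(object$L), t(Ks))
  } else {
    mu <- as.numeric(Ks %*% object$grad)
    V <- forwardsolve(t(object$L), t(Ks) * object$sW)
  }
  var_diag <- pmax(object$params$variance - colSums(V^2), 1e-12)
  out <- list(mean = mu, sd = sqrt(var_diag))
  if (full_cov) {
    Kss <- se_kernel(Xnew, params = object$params)
    out$cov <- Kss - crossprod(V)
  }
  out
}

#' Posterior predictions on the response scale
#'
#' Latent predictive means and standard deviations are computed exactly
#' (Gaussian) or under the Laplace approximation (binomial). Credible
#' intervals are latent Gaussian quantiles mapped through the link —
#' identity for log-RT, logistic for accuracy — which keeps probabilities
#' in \[0, 1\] and nests the 80% interval inside the 99% one. The binomial
#' response `mean` is the averaged predictive probability
#' `E[plogis(f*)]` (Gauss-Hermite quadrature).
#'
#' @param object A fitted [gp_fit()] model.
#' @param newdata Inputs to predict at (vector or matrix matching the
#'   training dimensionality).
#' @param full_cov If `TRUE`, also return the full latent predictive
#'   covariance as `attr(value, "latent_cov")`.
#' @param ... Unused.
#' @return A data.frame with the input columns plus `latent_mean`,
#'   `latent_sd`, `mean`, `lo80`, `hi80`, `lo99`, `hi99`.
#' @export
predict.tigp <- function(object, newdata, full_cov = FALSE, ...) {
  Xnew <- as_input_matrix(newdata)
  lp <- latent_predict(object, Xnew, full_cov = full_cov)
  link <- if (object$likelihood == "binomial") stats::plogis else identity
  out <- data.frame(Xnew)
  names(out) <- colnames(object$X) %||% paste0("x", seq_len(ncol(Xnew)))
  out$latent_mean <- lp$mean
  out$latent_sd <- lp$sd
  out$mean <- if (object$likelihood == "binomial")
    averaged_logistic(lp$mean, lp$sd) else lp$mean
  out$lo80 <- link(lp$mean - Z80 * lp$sd)
  out$hi80 <- link(lp$mean + Z80 * lp$sd)
  out$lo99 <- link(lp$mean - Z99 * lp$sd)
  out$hi99 <- link(lp$mean + Z99 * lp$sd)
  if (full_cov) attr(out, "latent_cov") <- lp$cov
  out
}

#' Posterior of the latent derivative (learning rate)
#'
#' The derivative of a GP with a differentiable kernel is itself Gaussian
#' jointly with the observed process; its posterior at `newdata` follows
#' from the cross-covariances `d k(x*, x_i)/d x*`. For a binomial
#' (logit-link) fit over trial index this is the learning rate in log-odds
#' of a correct response per trial.
#'
#' @param object A fitted [gp_fit()] model.
#' @param newdata Evaluation inputs (vector or matrix).
#' @param dim Input dimension to differentiate along (default 1, the trial
#'   axis). Must index a continuous input dimension of the model.
#' @return A data.frame with the input columns plus `mean`, `sd`, `lo80`,
#'   `hi80`, `lo99`, `hi99` for the derivative, on the latent scale
#'   (log-odds/trial for binomial fits, log-RT/trial for Gaussian fits).
#' @export
gp_derivative <- function(object, newdata, dim = 1L) {
  stopifnot(inherits(object, "tigp"))
  Xnew <- as_input_matrix(newdata)
  if (ncol(Xnew) != ncol(object$X))
    stop("dimension mismatch for derivative inputs", call. = FALSE)
  if (dim < 1L || dim > ncol(object$X))
    stop("derivative requested on invalid input dimension ", dim,
         call. = FALSE)
  C <- se_kernel_grad(Xnew, object$X, object$params, dim = dim)
  if (object$likelihood == "gaussian") {
    mu <- as.numeric(C %*% object$alpha)
    V <- forwardsolve(t(object$L), t(C))
  } else {
    mu <- as.numeric(C %*% object$grad)
    V <- forwardsolve(t(object$L), t(C) * object$sW)
  }
  dvar <- se_kernel_deriv_var(object$params, dim = dim,
                              ndim = ncol(object$X))
  sd <- sqrt(pmax(dvar - colSums(V^2), 1e-14))
  out <- data.frame(Xnew)
  names(out) <- colnames(object$X) %||% paste0("x", seq_len(ncol(Xnew)))
  out$mean <- mu
  out$sd <- sd
  out$lo80 <- mu - Z80 * sd
  out$hi80 <- mu + Z80 * sd
  out$lo99 <- mu - Z99 * sd
  out$hi99 <- mu + Z99 * sd
  out
}

#' @export
print.tigp <- function(x, ...) {
  cat("Gaussian-process fit (", x$likelihood, " likelihood",
      if (x$likelihood == "binomial") ", Laplace approximation", ")\n",
      sep = "")
  cat("  n =", x$n, "inputs, d =", ncol(x$X), "dimension(s)\n")
  cat("  log marginal likelihood:", format(x$lml, digits = 6), "\n")
  invisible(x)
}

#' @export
summary.tigp <- function(object, ...) {
  print(object)
  cat("  kernel variance:", format(object$params$variance, digits = 4),
      " lengthscales:",
      paste(format(object$params$lengthscales, digits = 4), collapse = ", "),
      "\n")
  if (object$likelihood == "gaussian")
    cat("  noise variance:", format(object$noise_variance, digits = 4),
        " prior mean:", format(object$prior_mean, digits = 4), "\n")
  else
    cat("  Newton iterations:", object$iterations, "\n")
  invisible(object)
}

#' @export
coef.tigp <- function(object, ...) {
  out <- c(variance = object$params$variance,
           stats::setNames(object$params$lengthscales,
                    paste0("lengthscale",
                           seq_along(object$params$lengthscales))))
  if (object$likelihood == "gaussian")
    out <- c(out, noise_variance = object$noise_variance)
  out
}

#' @export
fitted.tigp <- function(object, ...) {
  predict(object, object$X)$mean
}

#' @export
residuals.tigp <- function(object, ...) {
  if (object$likelihood == "gaussian") {
    object$y - (object$prior_mean +
                  as.numeric(kern_cross(object$X, object$X, object$params) %*%
                               object$alpha))
  } else {
    p <- stats::plogis(object$f_hat)
    (object$successes - object$totals * p) /
      sqrt(pmax(object$totals * p * (1 - p), 1e-12))
  }
}

#' Plot a one-dimensional GP fit
#'
#' Posterior mean with 99% (light) and 80% (dark) credible bands on the
#' response scale, with the data overlaid (empirical proportions for
#' binomial fits).
#'
#' @param x A fitted [gp_fit()] model with one input dimension.
#' @param n_grid Number of grid points.
#' @param ... Passed to [plot()].
#' @export
plot.tigp <- function(x, n_grid = 200L, ...) {
  if (ncol(x$X) != 1L)
    stop("plot.tigp supports one-dimensional inputs only", call. = FALSE)
  g <- seq(min(x$X), max(x$X), length.out = n_grid)
  pr <- predict(x, g)
  obs <- if (x$likelihood == "binomial") x$successes / x$totals else x$y
  ylim <- range(pr$lo99, pr$hi99, obs)
  plot(g, pr$mean, type = "n", ylim = ylim, ...)
  polygon(c(g, rev(g)), c(pr$lo99, rev(pr$hi99)),
          col = grey(0.9), border = NA)
  polygon(c(g, rev(g)), c(pr$lo80, rev(pr$hi80)),
          col = grey(0.78), border = NA)
  lines(g, pr$mean, lwd = 2)
  points(x$X[, 1L], obs, pch = 16, cex = 0.5, col = grey(0.3))
  invisible(x)
}
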