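# Independent oracles sharing no code path with the package internals.

# Exact GP regression by dense linear algebra (solve(), determinant()).
gaussian_oracle <- function(x, y, xs, params, nv,
                            weights = rep(1, length(y))) {
  K <- params$variance *
    exp(-0.5 * outer(x, x, "-")^2 / params$lengthscales^2) +
    diag(params$jitter, length(x))
  Ky <- K + diag(nv / weights)
  Ks <- params$variance *
    exp(-0.5 * outer(xs, x, "-")^2 / params$lengthscales^2)
  mu0 <- weighted.mean(y, weights)
  Kinv <- solve(Ky)
  list(mean = mu0 + as.numeric(Ks %*% Kinv %*% (y - mu0)),
       var = params$variance - diag(Ks %*% Kinv %*% t(Ks)),
       lml = as.numeric(-0.5 * t(y - mu0) %*% Kinv %*% (y - mu0) -
                          0.5 * determinant(Ky)$modulus -
                          0.5 * length(y) * log(2 * pi)))
}

# Dense grid integration of the exact binomial-logit GP posterior on tiny
# problems; returns averaged predictive probabilities at xs.
quadrature_oracle <- function(x, k, m, xs, params, lim = 8, step = 0.08) {
  n <- length(x)
  g <- seq(-lim, lim, by = step)
  G <- as.matrix(do.call(expand.grid, rep(list(g), n)))
  K <- params$variance *
    exp(-0.5 * outer(x, x, "-")^2 / params$lengthscales^2) +
    diag(params$jitter, n)
  Ki <- solve(K)
  logpost <- -0.5 * rowSums((G %*% Ki) * G) + as.numeric(G %*% k) -
    rowSums(sweep(log1p(exp(G)), 2, m, "*"))
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  Ks <- params$variance *
    exp(-0.5 * outer(xs, x, "-")^2 / params$lengthscales^2)
  A <- Ks %*% Ki
  vcond <- pmax(params$variance - rowSums(A * Ks), 0)
  # E[plogis(f*)]: average the conditional density over a fine normal grid
  z <- seq(-6, 6, by = 0.1)
  dz <- dnorm(z); dz <- dz / sum(dz)
  vapply(seq_along(xs), function(j) {
    mu <- as.numeric(G %*% A[j, ])
    pv <- numeric(length(mu))
    for (i in seq_along(z))
      pv <- pv + dz[i] * plogis(mu + z[i] * sqrt(vcond[j]))
    sum(w * pv)
  }, 1)
}
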