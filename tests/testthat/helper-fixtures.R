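# Shared fixtures: tiny deterministic models and data built in code.

quick_mmn_config <- function() {
  mmn_config(dur_ms = 400, dt_ms = 0.4, obs_dt_ms = 4)
}

quick_assr_config <- function() {
  assr_config(grid = seq(30, 50, by = 0.5))
}

# linear-Gaussian toy model: y = J theta + noise
linear_toy <- function(n = 40, p = 3, seed = 42, noise_sd = 0.1) {
  set.seed(seed)
  J <- matrix(rnorm(n * p), n, p)
  theta <- round(rnorm(p, 0, 0.5), 2)
  y <- drop(J %*% theta) + rnorm(n, 0, noise_sd)
  list(J = J, theta = theta, y = y, noise_sd = noise_sd,
       model = function(th) drop(J %*% th),
       priors = list(mean = setNames(rep(0, p), paste0("b", seq_len(p))),
                     var = setNames(rep(1, p), paste0("b", seq_len(p)))))
}

# a first-level posterior consistent with Bayesian shrinkage: data with
# information (precision) `info` about true value theta, prior N(0, pv)
shrunk_post <- function(theta, info = 100, pv = 1 / 16) {
  p <- length(theta)
  S <- diag(1 / (info + 1 / pv), p)
  list(mean = setNames(drop(S %*% (info * theta)), names(theta)),
       cov = S,
       prior_mean = setNames(rep(0, p), names(theta)),
       prior_var = setNames(rep(pv, p), names(theta)))
}

# conjugate posterior / evidence for the linear toy at known noise variance
linear_conjugate <- function(toy, prior_var = 1, noise_var = toy$noise_sd^2,
                             prior_mean = NULL, pv = NULL) {
  J <- toy$J; y <- toy$y
  p <- ncol(J); n <- nrow(J)
  if (is.null(pv)) pv <- rep(prior_var, p)
  if (is.null(prior_mean)) prior_mean <- rep(0, p)
  P0 <- diag(1 / pv, p)
  Pi <- diag(1 / noise_var, n)
  S <- solve(t(J) %*% Pi %*% J + P0)
  m <- S %*% (t(J) %*% Pi %*% y + P0 %*% prior_mean)
  Sy <- J %*% diag(pv, p) %*% t(J) + diag(noise_var, n)
  r <- y - drop(J %*% prior_mean)
  logZ <- -0.5 * n * log(2 * pi) -
    0.5 * as.numeric(determinant(Sy, logarithm = TRUE)$modulus) -
    0.5 * drop(t(r) %*% solve(Sy, r))
  list(mean = drop(m), cov = S, logZ = logZ)
}
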