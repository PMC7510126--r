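# Independent oracles, deliberately coded without reusing package internals.

# scalar, loop-free evaluation of the kinetic model for one (tau, w)
oracle_signal <- function(f, delta, T1, tau, w,
                          alpha1 = 0.8, alpha2 = 0.75, T1a = 1.65) {
  a <- alpha1 * alpha2
  term1 <- exp(-max(w - delta, 0) / T1)
  term2 <- exp(-max(w + tau - delta, 0) / T1)
  2 * a * (f / 6000) * T1 * exp(-delta / T1a) * (term1 - term2)
}

# two-pass R^2
oracle_r2 <- function(obs, pred) {
  mu <- sum(obs) / length(obs)
  ss_tot <- sum((obs - mu)^2)
  ss_res <- sum((obs - pred)^2)
  1 - ss_res / ss_tot
}

# brute-force exact paired Wilcoxon: explicit 2^n sign matrix (n <= 12)
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  eps <- sqrt(.Machine$double.eps)
  min(1, 2 * min(mean(ws <= w_obs + eps), mean(ws >= w_obs - eps)))
}

default_schedule_df <- function() {
  data.frame(
    tau = c(1.5, 2.0, 2.5, 3.0, 3.5, 4.0, 4.0, 4.0, 4.0, 4.0, 4.0, 4.0),
    w = c(0.7, 0.7, 0.7, 0.7, 0.7, 0.7, 1.2, 1.7, 2.2, 2.7, 3.2, 3.7))
}

# small phantom used by several files; built once per test run
small_spec <- function(noise_sd = 0, seed = 1L, ...) {
  phantom_spec(grid_shape = c(28L, 28L, 28L), noise_sd = noise_sd,
               seed = seed, ...)
}
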