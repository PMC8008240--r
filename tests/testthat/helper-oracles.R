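# Shared fixtures and independent oracles for the test suite.

# analytic eta CDF of a modal mixture: P(eta <= e); independent of the
# package's density code (chi-square CDF route)
eta_cdf <- function(e, model) {
  acc <- 0
  for (k in seq_len(model$n_modes)) {
    acc <- acc + model$alpha[k] *
      stats::pchisq(2 * model$n_d * model$dt * 10^e / model$sigma2[k],
                    df = model$n_d)
  }
  acc
}

# central-difference second derivative of a scalar function
num_d2 <- function(f, x, h = 1e-5) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# random valid modal model under the current RNG state
random_model <- function(n_modes, n_d, dt = 2.5) {
  a <- stats::runif(n_modes, 0.2, 1)
  modal_model(sigma2 = 10^stats::runif(n_modes, -4, 0), alpha = a / sum(a),
              n_d = n_d, dt = dt)
}

# straight-line trajectory fixture
ballistic_traj <- function(v = 0.3, n = 21L, dt = 0.5) {
  t <- (seq_len(n) - 1L) * dt
  trajectory("ball", t, cbind(v * t, 0 * t))
}

# write a small canonical CSV and return its path
write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
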