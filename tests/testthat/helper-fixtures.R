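# shared fixtures, built in code

# small biphasic 4-channel transient set (S3->S0-like kinetics)
biphasic_channels <- function(time, taus = c(6.5e-3, 75e-3),
                              amp_fast = c(30, 2, 40, 120) * 1e-6,
                              amp_slow = c(120, 100, 150, 40) * 1e-6,
                              noise_sd = 0, seed = NULL) {
  tp <- pmax(time, 0)
  Y <- sapply(seq_along(amp_fast), function(ch) {
    v <- multiexp_eval(taus, c(amp_fast[ch], amp_slow[ch]), 0, tp)
    v[time < 0] <- 0
    v
  })
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    Y <- Y + matrix(rnorm(length(Y), 0, noise_sd), nrow(Y), ncol(Y))
  }
  Y
}

# random normalized S-state vector
random_s_state <- function() {
  p <- rexp(4)
  p <- p / sum(p)
  s_state_vector(p[1], p[2], p[3], p[4])
}

# small electrode model + time grid for fast polarography tests
small_electrode <- function(n_x = 60L) electrode_model(n_x = n_x)
o2_grid <- function(dt = 5e-4) seq(-0.020, 0.480, by = dt)
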