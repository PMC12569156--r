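test_that("kinetic source has the right limits and normalization", {
  t <- seq(1e-4, 0.15, 1e-5)
  # vanishing first step collapses to a single exponential
  r <- kinetic_source(t, 1e-9, 3e-3)
  k2 <- 1 / 3e-3
  expect_equal(r, k2 * exp(-k2 * t), tolerance = 1e-5)
  # unit normalization over a long window
  tt <- seq(0, 50 * 3e-3, 1e-6)
  r2 <- kinetic_source(tt, 3e-4, 3e-3)
  integral <- sum((r2[-1] + r2[-length(r2)]) / 2) * 1e-6
  expect_equal(integral, 1, tolerance = 1e-6)
  # symmetric under swapping the two constants
  expect_equal(kinetic_source(t, 3e-4, 3e-3),
               kinetic_source(t, 3e-3, 3e-4), tolerance = 1e-12)
  # equal-rate analytic limit
  k <- 1 / 1e-3
  expect_equal(kinetic_source(t, 1e-3, 1e-3), k^2 * t * exp(-k * t),
               tolerance = 1e-12)
  expect_error(kinetic_source(t, -1, 1), "> 0")
  # zero before the flash
  expect_equal(kinetic_source(c(-0.01, -1e-6), 3e-4, 3e-3), c(0, 0))
})

test_that("high-pass filter matches the analytic single-pole response", {
  dt <- 1e-3
  tau_f <- 0.1
  n <- 400
  alpha <- tau_f / (tau_f + dt)
  # step input decays geometrically (~ exp(-t / tau_f))
  y <- highpass_filter(rep(1, n), dt, tau_f)
  expect_equal(y, alpha^(1:n), tolerance = 1e-12)
  expect_lt(abs(y[n]), exp(-n * dt / (tau_f + dt)) * 1.01)
  # constant input is rejected
  expect_lt(abs(highpass_filter(rep(5, 1000), dt, tau_f)[1000]), 5e-4)
  # very slow filter passes the signal through
  x <- sin(seq(0, pi, length.out = 200))
  yp <- highpass_filter(x, 1e-4, 1e4)
  expect_equal(yp, x, tolerance = 1e-4)
  expect_error(highpass_filter(x, -1, 1), "positive")
})

test_that("non-uniform grids are refused", {
  tr <- list(time = c(-0.01, 0, 0.01, 0.03), signal = rep(0, 4))
  expect_error(fit_o2_transient(tr, small_electrode()), "uniform")
})

test_that("the diffusion solution conserves O2 mass", {
  tr <- simulate_o2_transient(electrode_model(), 3e-4, 3e-3)
  mb <- tr$mass_balance
  expect_equal(mb$consumed + mb$remaining, mb$generated,
               tolerance = 1e-3)
  # most O2 has reached the electrode by 480 ms
  expect_gt(mb$consumed / mb$generated, 0.5)
})

test_that("the high-pass rejects the DC component of the transient", {
  # over a window much longer than tau_f the filtered integral vanishes
  tg <- seq(-0.01, 2.5, 1e-3)
  tr <- simulate_o2_transient(small_electrode(), 3e-4, 3e-3, tg)
  raw_integral <- sum(tr$raw) * 1e-3
  filt_integral <- sum(tr$signal) * 1e-3
  expect_lt(abs(filt_integral), 0.05 * abs(raw_integral))
})

test_that("the solver converges under grid refinement", {
  s1 <- simulate_o2_transient(electrode_model(n_x = 200), 3e-4, 3e-3)
  s2 <- simulate_o2_transient(electrode_model(n_x = 400), 3e-4, 3e-3)
  expect_lt(max(abs(s1$signal - s2$signal)) / max(abs(s2$signal)), 0.005)
})

test_that("peak time grows with L^2/D while diffusion-limited", {
  tg <- seq(-0.002, 0.3, 2e-5)
  peaks <- sapply(c(1e-6, 2e-6, 5e-6), function(L) {
    tr <- simulate_o2_transient(electrode_model(thickness = L,
                                                n_x = 150),
                                2e-4, 1e-3, tg)
    tr$time[which.max(tr$signal)]
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("the impulse-response convolution equals the direct solution", {
  m <- small_electrode()
  tg <- o2_grid()
  dt <- 5e-4
  post <- which(tg > 0)
  tr <- simulate_o2_transient(m, 3e-4, 3e-3, tg, filter = FALSE)
  h <- electrode_impulse_response(m, dt, length(post))
  Rt <- flashkin:::kinetic_source_cumulative(tg[post], 3e-4, 3e-3)
  conv <- flashkin:::conv_causal(h, diff(c(0, Rt)))
  expect_equal(conv, tr$raw[post], tolerance = 1e-10)
})

test_that("noise-free transients are fitted back exactly", {
  m <- small_electrode()
  tr <- simulate_o2_transient(m, 3e-4, 3e-3, o2_grid())
  fit <- fit_o2_transient(tr, m)
  expect_equal(fit$tau_pre, 3e-4, tolerance = 1e-4)
  expect_equal(fit$tau_o2, 3e-3, tolerance = 1e-4)
  expect_equal(fit$convergence, 0)
  expect_false(fit$weakly_identified)
})

test_that("time constants are recovered within 10% at SNR 50", {
  m <- small_electrode()
  tg <- o2_grid(dt = 2e-4)  # sub-ms tau_pre needs 0.2 ms sampling
  dt <- 2e-4
  h <- highpass_filter(electrode_impulse_response(m, dt, sum(tg > 0)),
                       dt, m$tau_filter)
  base <- simulate_o2_transient(m, 3e-4, 3e-3, tg)
  peak <- max(abs(base$signal))
  hits <- 0L
  for (s in 1:10) {
    set.seed(s)
    tr <- base
    tr$signal <- tr$signal + rnorm(length(tg), 0, peak / 50)
    fit <- fit_o2_transient(tr, m, impulse = h, errors = FALSE)
    if (abs(fit$tau_pre / 3e-4 - 1) < 0.10 &&
        abs(fit$tau_o2 / 3e-3 - 1) < 0.10) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("nearly equal fitted constants are flagged", {
  m <- small_electrode()
  tr <- simulate_o2_transient(m, 2e-3, 2.1e-3, o2_grid())
  fit <- fit_o2_transient(tr, m)
  expect_true(fit$weakly_identified)
})

test_that("a temperature series propagates to the activation energy", {
  m <- small_electrode()
  tg <- o2_grid()
  # noise-free closed loop recovers the generating law almost exactly
  ser0 <- make_temperature_series(model = m, noise = 0, time = tg,
                                  seed = 1)
  dt <- 5e-4
  h <- highpass_filter(electrode_impulse_response(m, dt, sum(tg > 0)),
                       dt, m$tau_filter)
  taus0 <- vapply(ser0$transients, function(tr) {
    fit_o2_transient(tr, m, impulse = h, errors = FALSE)$tau_o2
  }, numeric(1))
  af0 <- arrhenius_fit(ser0$truth$temperature_K, taus0)
  expect_lt(abs(af0$Ea_meV - 421), 1)
  # with 2% noise the estimate stays near the generating value
  ser <- make_temperature_series(model = m, time = tg, seed = 2)
  taus <- vapply(ser$transients, function(tr) {
    fit_o2_transient(tr, m, impulse = h, errors = FALSE)$tau_o2
  }, numeric(1))
  af <- arrhenius_fit(ser$truth$temperature_K, taus)
  expect_lt(abs(af$Ea_meV - 421), 22)
})
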