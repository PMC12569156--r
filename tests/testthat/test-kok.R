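test_that("flash advance is a miss-weighted cyclic shift", {
  s <- s_state_vector(0.10, 0.90, 0, 0)
  # pure advance: cyclic shift
  expect_equal(as.numeric(advance_s_state(s, 0)), c(0, 0.10, 0.90, 0))
  # hand-computed 4x4 transition-matrix product for miss = 0.1
  expect_equal(as.numeric(advance_s_state(s, 0.1)),
               c(0.01, 0.18, 0.81, 0), tolerance = 1e-12)
  # near-total miss leaves the distribution almost unchanged
  expect_equal(as.numeric(advance_s_state(s, 0.999)), as.numeric(s),
               tolerance = 2e-3)
  expect_error(advance_s_state(s, 1), "miss")
  expect_error(s_state_vector(0.5, 0.6, 0, 0), "sum to 1")
  expect_error(s_state_vector(-0.1, 1.1, 0, 0), "\\[0, 1\\]")
})

test_that("advance conserves probability for random states and misses", {
  set.seed(42)
  for (i in 1:50) {
    s <- random_s_state()
    m <- runif(1, 0, 0.99)
    out <- advance_s_state(s, m)
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_true(all(out >= 0))
  }
})

test_that("flash weights reproduce Kok-cycle structure", {
  W0 <- flash_weights(kok_params(miss = 0, n_flashes = 12))
  # third flash drives the O2 transition for the dominant S1 fraction
  expect_equal(unname(W0[3, "S3_to_S0"]), 0.90)
  # miss = 0: exact period-four permutation pattern
  expect_equal(W0[1:4, ], W0[5:8, ], ignore_attr = TRUE)
  expect_equal(W0[1:4, ], W0[9:12, ], ignore_attr = TRUE)
  # rows always sum to 1 - miss
  W <- flash_weights(kok_params(miss = 0.12, n_flashes = 10))
  expect_equal(rowSums(W), rep(0.88, 10), tolerance = 1e-12)
  # damping: the period-four S3->S0 peak decays over successive cycles
  W16 <- flash_weights(kok_params(miss = 0.12, n_flashes = 16))
  peaks <- W16[c(3, 7, 11, 15), "S3_to_S0"]
  expect_true(all(diff(peaks) < 0))
})

test_that("deconvolution round-trips noise-free synthetic data", {
  p <- kok_params(miss = 0.12)
  g <- make_ir_dataset(p, noise_sd = 0, seed = 1)
  dc <- deconvolve_flashes(g$data, p)
  expect_lt(max(abs(dc$signatures - g$truth$signatures)), 1e-10)
  expect_lt(max(abs(dc$residuals)), 1e-10)

  ga <- make_ir_dataset(p, noise_sd = 0, artifact = TRUE, seed = 1)
  dca <- deconvolve_flashes(ga$data, p, artifact = TRUE)
  expect_lt(max(abs(dca$signatures - ga$truth$signatures)), 1e-10)
  expect_lt(max(abs(dca$artifact - ga$truth$artifact)), 1e-10)
})

test_that("heat-artifact waveform is recovered within the noise floor", {
  p <- kok_params(miss = 0.12)
  ga <- make_ir_dataset(p, noise_sd = 5e-6, artifact = TRUE, seed = 3)
  dca <- deconvolve_flashes(ga$data, p, artifact = TRUE)
  err <- dca$artifact - ga$truth$artifact
  # per-point recovery error is noise times the artifact-column
  # pseudoinverse norm; stay within a few noise sd
  expect_lt(sqrt(mean(err^2)), 5 * 5e-6)
})

test_that("noisy signature recovery error matches linear-model theory", {
  p <- kok_params(miss = 0.12)
  W <- flash_weights(p)
  theory_sd <- sqrt(diag(solve(crossprod(W))))  # per unit noise sd
  sigma <- 5e-6
  t_short <- seq(-0.02, 0.1, 5e-3)  # small grid, many noise draws
  errs <- matrix(NA_real_, 40, 4)
  for (i in 1:40) {
    g <- make_ir_dataset(p, time = t_short, noise_sd = sigma, seed = 100 + i)
    dc <- deconvolve_flashes(g$data, p)
    e <- dc$signatures - g$truth$signatures
    errs[i, ] <- apply(e, 1, function(m) sqrt(mean(m^2)))
  }
  emp <- colMeans(errs)
  expect_equal(emp, sigma * theory_sd, tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("degenerate Kok parameters give a named singularity error", {
  p <- kok_params(miss = 0, initial = s_state_vector(0.25, 0.25, 0.25,
                                                     0.25))
  g <- make_ir_dataset(p, noise_sd = 0, seed = 1)
  expect_error(deconvolve_flashes(g$data, p), "rank-deficient")
  # the offending columns are named
  expect_error(deconvolve_flashes(g$data, p), "_to_S")
})

test_that("flash amplitude pattern averages the late window", {
  p <- kok_params(miss = 0.12)
  g <- make_ir_dataset(p, noise_sd = 0, seed = 1)
  pat <- flash_amplitude_pattern(g$data)
  expect_equal(dim(pat), c(10, 4))
  # constant signal gives the constant back for every flash
  const <- g$data
  const$signal[] <- 3.3e-5
  expect_equal(as.vector(flash_amplitude_pattern(const)),
               rep(3.3e-5, 40))
  expect_error(flash_amplitude_pattern(g$data, window = c(5, 6)),
               "no time points")
})

test_that("S3->S0-dominated channels peak on flashes 3 and 7", {
  # signatures with late-window amplitude only in the S3->S0 transition
  sgn <- default_ir_signatures()
  for (tr in c("S0_to_S1", "S1_to_S2", "S2_to_S3")) {
    sgn[[tr]]$amplitudes[] <- 0
  }
  g <- make_ir_dataset(kok_params(miss = 0.10), signatures = sgn,
                       noise_sd = 0, seed = 1)
  pat <- flash_amplitude_pattern(g$data)
  for (ch in 1:4) {
    first_cycle <- which.max(abs(pat[1:4, ch]))
    second_cycle <- 4 + which.max(abs(pat[5:8, ch]))
    expect_equal(first_cycle, 3L)
    expect_equal(second_cycle, 7L)
  }
})

test_that("miss factor is recovered from seeded synthetic trains", {
  # noise-free, miss = 0: estimate at the lower search edge
  g0 <- make_ir_dataset(kok_params(miss = 0), noise_sd = 0, seed = 1)
  e0 <- estimate_miss(g0$data, kok_params())
  expect_true(e0$identifiable)
  expect_lt(e0$miss, 2e-3)
  # realistic noise, miss = 0.12: within +/- 0.02
  for (s in 1:5) {
    g <- make_ir_dataset(kok_params(miss = 0.12), noise_sd = 5e-6,
                         seed = s)
    e <- estimate_miss(g$data, kok_params())
    expect_lt(abs(e$miss - 0.12), 0.02)
  }
  # the amplitude-pattern route agrees
  g <- make_ir_dataset(kok_params(miss = 0.12), noise_sd = 5e-6, seed = 9)
  pat <- flash_amplitude_pattern(g$data)
  ep <- estimate_miss(pat, kok_params())
  expect_lt(abs(ep$miss - 0.12), 0.02)
})

test_that("flat flash dependence is flagged as unidentifiable", {
  g <- make_ir_dataset(kok_params(miss = 0.12), noise_sd = 0, seed = 1)
  g$data$signal[] <- 1e-4  # no flash dependence at all
  e <- estimate_miss(g$data, kok_params())
  expect_false(e$identifiable)
  expect_true(is.na(e$miss))
})

test_that("deconvolution residual RMS approaches the injected noise", {
  sigma <- 5e-6
  p <- kok_params(miss = 0.12)
  g <- make_ir_dataset(p, noise_sd = sigma, seed = 5)
  dc <- deconvolve_flashes(g$data, p)
  # residual RMS = sigma * sqrt(1 - k/n) for k regressors, n flashes
  expect_equal(sqrt(mean(dc$residuals^2)), sigma * sqrt(1 - 4 / 10),
               tolerance = 0.05)
})

test_that("signature_matrix exposes a fit-ready time x channel matrix", {
  p <- kok_params(miss = 0.12)
  g <- make_ir_dataset(p, noise_sd = 0, seed = 1)
  dc <- deconvolve_flashes(g$data, p)
  m <- signature_matrix(dc, "S3_to_S0")
  expect_equal(dim(m), c(length(g$data$time), 4L))
  expect_equal(m[, 2], dc$signatures["S3_to_S0", 2, ],
               ignore_attr = TRUE)
})
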