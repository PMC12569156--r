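test_that("generation is bit-identical under a fixed seed", {
  g1 <- make_ir_dataset(seed = 42)
  g2 <- make_ir_dataset(seed = 42)
  expect_identical(g1$data$signal, g2$data$signal)
  g3 <- make_ir_dataset(seed = 43)
  expect_false(identical(g1$data$signal, g3$data$signal))

  s1 <- make_temperature_series(model = small_electrode(), seed = 7)
  s2 <- make_temperature_series(model = small_electrode(), seed = 7)
  expect_identical(s1$transients[[3]]$signal, s2$transients[[3]]$signal)
})

test_that("the generator does not disturb the global RNG stream", {
  set.seed(99)
  a <- runif(3)
  set.seed(99)
  invisible(make_ir_dataset(seed = 1))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("ground truth scores the deconvolution without re-derivation", {
  p <- kok_params(miss = 0.12)
  g <- make_ir_dataset(p, noise_sd = 0, seed = 2)
  expect_equal(dim(g$truth$weights), c(10L, 4L))
  expect_equal(g$truth$miss, 0.12)
  dc <- deconvolve_flashes(g$data, p)
  expect_lt(max(abs(dc$signatures - g$truth$signatures)), 1e-10)
})

test_that("generated sets pass the same validation as read data", {
  g <- make_ir_dataset(seed = 3)
  path <- tempfile(fileext = ".csv")
  write_flash_transients(g$data, path)
  back <- read_flash_transients(path)
  expect_s3_class(back, "flash_transient_set")
  expect_equal(back$signal, g$data$signal, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("temperature-series taus follow the Arrhenius laws", {
  ser <- make_temperature_series(model = small_electrode(), noise = 0,
                                 seed = 1)
  # tau_O2 at 20 C from the default law sits near the published 1.72 ms
  kB <- eyring_constants[["kB_eV_per_K"]]
  tau20 <- 1 / exp(ser$laws$lnA_o2 - 0.421 / (kB * 293.15))
  expect_gt(tau20, 1.6e-3)
  expect_lt(tau20, 1.9e-3)
  # monotone decreasing with temperature
  expect_true(all(diff(ser$truth$tau_o2_s) < 0))
  expect_equal(nrow(ser$truth), 8L)
})

test_that("scheme-weighted transients reflect the populations", {
  sch <- sequential_scheme(1 / 0.99e-3, 1 / 6.5e-3, 1 / 75e-3)
  times <- seq(0, 0.5, 1e-3)
  w <- cbind(chD = c(0, 0, 0, 1e-4))
  rownames(w) <- c("A", "B", "C", "D")
  out <- make_scheme_ir(sch, w, times, noise_sd = 0)
  traj <- scheme_populations(sch, times)
  expect_equal(as.numeric(out$y), 1e-4 * traj$P_D, tolerance = 1e-12)
})

test_that("N298A-like scheme signals resolve two millisecond phases", {
  # distinct C and D spectral weights make the water-insertion step
  # visible as a second kinetic phase
  sch <- sequential_scheme(1 / 0.99e-3, 1 / 6.5e-3, 1 / 75e-3)
  times <- seq(0, 0.6, 1e-3)
  w <- rbind(A = c(0, 0, 0, 0),
             B = c(-6e-5, -5e-5, -5e-5, -6.5e-5),
             C = c(3e-5, 0.2e-5, 4e-5, 12e-5),
             D = c(15e-5, 10e-5, 19e-5, 16e-5))
  out <- make_scheme_ir(sch, w, times, noise_sd = 5e-6, seed = 5)
  fit <- fit_multiexp(times, out$y, 3)
  # two resolvable ms phases near 6.5 and 75 ms among the fitted taus
  expect_true(any(abs(fit$taus / 6.5e-3 - 1) < 0.3))
  expect_true(any(abs(fit$taus / 75e-3 - 1) < 0.3))
})

test_that("wild-type-like insertion is kinetically invisible", {
  # with k_CD = 20 k_BC the slow-phase amplitude drops below the 5 uOD
  # noise floor: a two-component fit leaves no structured residual
  sch <- sequential_scheme(1 / 0.48e-3, 1 / 4.7e-3)
  times <- seq(0, 0.5, 1e-3)
  w <- rbind(A = c(0, 0), B = c(-6e-5, -5e-5), C = c(4e-5, 10e-5),
             D = c(15e-5, 16e-5))
  out <- make_scheme_ir(sch, w, times, noise_sd = 0)
  # difference between the C and D weighting only matters while C is
  # populated; its peak contribution stays below 5 uOD
  contrib <- abs((w["C", ] - w["D", ])) %o% rep(1, length(times)) *
    rep(scheme_populations(sch, times)$P_C, each = 2)
  expect_lt(max(contrib), 5e-6)
})
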