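#' Bare-platinum electrode diffusion model
#'
#' Geometry and instrument parameters of the simplified Clark-type
#' (bare-platinum) electrode forward model: a 1-D sample layer of thickness
#' `L` on the electrode, effective O2 diffusion coefficient `D`, an
#' absorbing boundary at the electrode surface (diffusion-limited O2
#' reduction at -0.95 V polarization, `c = 0`), a reflecting far boundary,
#' flash-generated O2 deposited uniformly over the fraction of the layer
#' adjacent to the electrode, and a first-order high-pass instrument
#' response. Only these stated ingredients are modelled; drift and
#' electrode-polarization kinetics are not.
#'
#' @param thickness Sample layer thickness `L` in metres.
#' @param n_x Number of spatial grid points (>= 10).
#' @param D Effective diffusion coefficient in m^2/s.
#' @param source_fraction Fraction of the layer (measured from the
#'   electrode) over which the O2 source is deposited uniformly.
#' @param tau_filter High-pass filter time constant in seconds (0.100 s for
#'   the instrument emulated here).
#' @param amplitude Overall signal scale (arbitrary current units per unit
#'   O2 flux).
#' @return List of class `electrode_model`.
#' @export
electrode_model <- function(thickness = 10e-6, n_x = 200L, D = 2e-9,
                            source_fraction = 1, tau_filter = 0.100,
                            amplitude = 1) {
  if (thickness <= 0 || D <= 0 || tau_filter <= 0) {
    stop("thickness, D and tau_filter must be positive")
  }
  n_x <- as.integer(n_x)
  if (n_x < 10L) stop("`n_x` must be at least 10")
  if (source_fraction <= 0 || source_fraction > 1) {
    stop("`source_fraction` must be in (0, 1]")
  }
  structure(list(thickness = thickness, n_x = n_x, D = D,
                 source_fraction = source_fraction,
                 tau_filter = tau_filter, amplitude = amplitude),
            class = "electrode_model")
}

#' Two-step kinetic O2 source
#'
#' Normalized O2 generation rate of the sequential two-step source: a
#' preceding step with time constant `tau_pre` followed by the O2-forming
#' step with `tau_o2`. With `k1 = 1/tau_pre`, `k2 = 1/tau_o2`:
#' `r(t) = k1 k2 / (k1 - k2) * (exp(-k2 t) - exp(-k1 t))`, and the analytic
#' equal-rate limit `r(t) = k^2 t exp(-k t)`. The rate integrates to 1 over
#' `[0, Inf)` and is symmetric under swapping the two time constants.
#'
#' @param t Times in seconds (rate is 0 for `t < 0`).
#' @param tau_pre,tau_o2 Time constants in seconds, both > 0.
#' @return O2 generation rate (1/s) at `t`.
#' @export
kinetic_source <- function(t, tau_pre, tau_o2) {
  if (tau_pre <= 0 || tau_o2 <= 0) stop("both time constants must be > 0")
  k1 <- 1 / tau_pre
  k2 <- 1 / tau_o2
  tp <- pmax(t, 0)
  r <- if (rates_close(k1, k2)) {
    k1^2 * tp * exp(-k1 * tp)
  } else {
    k1 * k2 / (k1 - k2) * (exp(-k2 * tp) - exp(-k1 * tp))
  }
  r[t < 0] <- 0
  r
}

# cumulative source integral R(t) = int_0^t r ds (closed form), used for
# exact per-step injection amounts in the diffusion solver
kinetic_source_cumulative <- function(t, tau_pre, tau_o2) {
  k1 <- 1 / tau_pre
  k2 <- 1 / tau_o2
  tp <- pmax(t, 0)
  R <- if (rates_close(k1, k2)) {
    1 - exp(-k1 * tp) * (1 + k1 * tp)
  } else {
    1 - (k1 * exp(-k2 * tp) - k2 * exp(-k1 * tp)) / (k1 - k2)
  }
  R[t < 0] <- 0
  R
}

#' First-order high-pass filter
#'
#' Discrete first-order high-pass with time constant `tau_f` on a uniform
#' time grid: `y_n = alpha * (y_{n-1} + x_n - x_{n-1})`,
#' `alpha = tau_f / (tau_f + dt)`, starting from rest (`x_0 = y_0 = 0`).
#' Removes the DC component: a constant input decays as `exp(-t / tau_f)`.
#'
#' @param x Input series on a uniform grid.
#' @param dt Sample interval in seconds.
#' @param tau_f Filter time constant in seconds.
#' @return Filtered series of the same length.
#' @export
highpass_filter <- function(x, dt, tau_f) {
  if (dt <= 0 || tau_f <= 0) stop("`dt` and `tau_f` must be positive")
  alpha <- tau_f / (tau_f + dt)
  u <- alpha * diff(c(0, x))
  as.numeric(stats::filter(u, alpha, method = "recursive"))
}

check_uniform_grid <- function(time) {
  dt <- diff(time)
  if (length(dt) == 0L) stop("time grid too short")
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) {
    stop("time grid must be uniform for the diffusion solver/filter; ",
         "resample first")
  }
  dt[1]
}

# Crank-Nicolson machinery for the interior+far nodes (electrode node held
# at c = 0). Returns the dense inverse propagator and helpers.
cn_setup <- function(model, dt) {
  N <- model$n_x
  dx <- model$thickness / (N - 1L)
  M <- N - 1L                       # unknown nodes 2..N
  mu <- model$D * dt / dx^2
  # tridiagonal Laplacian stencil (Dirichlet at electrode, Neumann far end)
  tri <- matrix(0, M, M)
  for (i in seq_len(M)) {
    tri[i, i] <- -2
    if (i > 1L) tri[i, i - 1L] <- 1
    if (i < M) tri[i, i + 1L] <- 1
  }
  tri[M, M - 1L] <- 2               # reflecting ghost node
  M1 <- diag(M) - mu / 2 * tri
  inv_M1 <- solve(M1)
  x_nodes <- dx * seq_len(M)        # positions of unknown nodes
  node_mass <- rep(dx, M)
  node_mass[M] <- dx / 2            # half cell at the reflecting boundary
  dep <- as.numeric(x_nodes <= model$source_fraction * model$thickness +
                      1e-12 * model$thickness)
  if (sum(dep) == 0L) dep[1L] <- 1
  w <- dep / sum(dep * node_mass)   # unit deposited amount
  apply_tri <- function(c) {
    v <- -2 * c
    v[seq_len(M - 1L)] <- v[seq_len(M - 1L)] + c[2:M]
    v[2:M] <- v[2:M] + c[seq_len(M - 1L)]
    v[M] <- v[M] + c[M - 1L]        # reflecting row doubles the neighbour
    v
  }
  # recorded signal: second-order one-sided gradient at the electrode
  # (c = 0 at the boundary node)
  flux <- function(c) model$D * (4 * c[1L] - c[2L]) / (2 * dx)
  # mass accounting: the Crank-Nicolson update loses exactly
  # D * (c2 + c2') / (2 dx) per step through the Dirichlet boundary, so
  # this first-order gradient keeps generated = consumed + remaining to
  # machine precision
  flux_balance <- function(c) model$D * c[1L] / dx
  list(inv_M1 = inv_M1, apply_tri = apply_tri, mu = mu, w = w,
       node_mass = node_mass, flux = flux, flux_balance = flux_balance,
       dx = dx)
}

# march the CN scheme; `inject` is the amount deposited in each step.
# Returns electrode flux after each step and the final concentration.
cn_march <- function(setup, inject) {
  M <- length(setup$w)
  conc <- numeric(M)
  flux_out <- numeric(length(inject))
  consumed <- 0
  f_prev <- 0
  for (n in seq_along(inject)) {
    rhs <- conc + setup$mu / 2 * setup$apply_tri(conc) +
      inject[n] * setup$w
    conc <- drop(setup$inv_M1 %*% rhs)
    if (anyNA(conc) || any(!is.finite(conc))) {
      stop("diffusion solver produced non-finite values (n_x = ", M + 1L,
           ", mu = ", format(setup$mu, digits = 3), "); refine the grid")
    }
    flux_out[n] <- setup$flux(conc)
    f_new <- setup$flux_balance(conc)
    consumed <- consumed + (f_prev + f_new) / 2
    f_prev <- f_new
  }
  list(flux = flux_out, conc = conc, consumed = consumed)
}

#' Electrode impulse response
#'
#' Electrode O2 flux following deposition of a unit amount of O2 with the
#' model's source profile in the first time step (Crank-Nicolson solution).
#' Because the diffusion problem is linear and time-invariant, the response
#' to any source time course is the convolution of this impulse response
#' with the per-step injected amounts; [fit_o2_transient()] exploits this.
#'
#' @param model `electrode_model`.
#' @param dt Time step in seconds.
#' @param n_steps Number of steps.
#' @return Numeric vector of electrode flux values after each step.
#' @export
electrode_impulse_response <- function(model, dt, n_steps) {
  stopifnot(inherits(model, "electrode_model"))
  setup <- cn_setup(model, dt)
  cn_march(setup, c(1, numeric(n_steps - 1L)))$flux
}

#' Simulate a flash-induced O2 electrode transient
#'
#' Forward model: the two-step kinetic source [kinetic_source()] deposits
#' O2 into the sample layer; the 1-D diffusion equation
#' `dc/dt = D d2c/dx2 + r(t) g(x)` is solved by an unconditionally stable
#' Crank-Nicolson scheme with `c = 0` at the electrode and zero flux at the
#' far boundary; the raw signal is the diffusive flux into the electrode,
#' `D dc/dx` at `x = 0`; and the recorded signal is that flux passed
#' through the first-order high-pass instrument response. Per-step source
#' amounts use the closed-form cumulative source integral, so the injected
#' O2 is exact regardless of the time step.
#'
#' @param model `electrode_model`.
#' @param tau_pre,tau_o2 Source time constants in seconds.
#' @param time Uniform time grid in seconds covering a pre-flash baseline
#'   (default -20 ms to +480 ms around the flash at t = 0).
#' @param temperature_K Stored with the transient.
#' @param filter Apply the high-pass instrument response (default `TRUE`).
#' @return Object of class `o2_transient`: list with `time`, `signal`
#'   (filtered, in model amplitude units), `raw` (unfiltered flux),
#'   `temperature_K`, `tau_filter` and `mass_balance` (list with
#'   `generated`, `consumed`, `remaining`).
#' @export
simulate_o2_transient <- function(model, tau_pre, tau_o2,
                                  time = seq(-0.020, 0.480, by = 5e-4),
                                  temperature_K = NA_real_,
                                  filter = TRUE) {
  stopifnot(inherits(model, "electrode_model"))
  dt <- check_uniform_grid(time)
  post <- which(time > 0)
  if (length(post) < 2L) stop("time grid must extend beyond the flash")
  t_post <- time[post]
  Rt <- kinetic_source_cumulative(t_post, tau_pre, tau_o2)
  inject <- diff(c(kinetic_source_cumulative(max(time[time <= 0], 0),
                                             tau_pre, tau_o2), Rt))
  setup <- cn_setup(model, dt)
  sol <- cn_march(setup, inject)
  raw <- numeric(length(time))
  raw[post] <- sol$flux
  consumed <- sol$consumed * dt
  remaining <- sum(sol$conc * setup$node_mass)
  signal <- model$amplitude *
    (if (filter) highpass_filter(raw, dt, model$tau_filter) else raw)
  structure(list(time = time, signal = signal,
                 raw = model$amplitude * raw,
                 temperature_K = temperature_K,
                 tau_filter = if (filter) model$tau_filter else NA_real_,
                 mass_balance = list(generated = sum(inject),
                                     consumed = consumed,
                                     remaining = remaining)),
            class = "o2_transient")
}

#' @export
print.o2_transient <- function(x, ...) {
  cat(sprintf("<o2_transient> %d points, %g .. %g s", length(x$time),
              min(x$time), max(x$time)))
  if (!is.na(x$temperature_K)) cat(sprintf(", T = %.2f K", x$temperature_K))
  cat("\n")
  invisible(x)
}

#' Fit source time constants to an O2 electrode transient
#'
#' Least-squares extraction of the two source time constants (and the
#' signal amplitude, solved linearly) from a measured or synthetic
#' transient, with the electrode geometry fixed. The forward model during
#' optimization is the convolution of the (high-pass-filtered) electrode
#' impulse response with the closed-form per-step source amounts, which is
#' identical to the direct Crank-Nicolson solution. The source is symmetric
#' in its two time constants; the fitted pair is sorted and the smaller one
#' reported as `tau_pre` (the sub-millisecond preceding step), the larger
#' as `tau_o2`.
#'
#' @param transient `o2_transient` (or list with uniform `time` and
#'   `signal`); the signal should be baseline-corrected (the pre-flash mean
#'   is removed automatically).
#' @param model `electrode_model` with the fixed geometry; its
#'   `tau_filter` must match the instrument response in the data.
#' @param start Optional list of starting pairs `c(tau_pre, tau_o2)`;
#'   default a ladder of ms-range pairs.
#' @param tau_range Admissible range for both time constants (s).
#' @param impulse Optional precomputed high-pass-filtered impulse response
#'   (from [electrode_impulse_response()] followed by
#'   [highpass_filter()], on the same `dt` and post-flash length); useful
#'   when fitting many transients with one geometry.
#' @param errors Compute Gauss-Newton parameter uncertainties via the
#'   numerical Hessian (default `TRUE`; skip for speed in large
#'   simulation studies).
#' @return Object of class `o2_fit`: list with `tau_pre`, `tau_o2`,
#'   `se_tau_pre`, `se_tau_o2` (Gauss-Newton, via numerical Hessian in log
#'   space), `amplitude`, `ssr`, `convergence`, `weakly_identified`
#'   (`TRUE` when the fitted constants differ by < 20%), `fitted` and
#'   `residuals`.
#' @export
fit_o2_transient <- function(transient, model, start = NULL,
                             tau_range = c(2e-5, 1), impulse = NULL,
                             errors = TRUE) {
  time <- transient$time
  y <- transient$signal
  dt <- check_uniform_grid(time)
  y <- y - mean(y[time <= 0])
  post <- which(time > 0)
  n_post <- length(post)
  if (is.null(impulse)) {
    h <- electrode_impulse_response(model, dt, n_post)
    h <- highpass_filter(h, dt, model$tau_filter)
  } else {
    if (length(impulse) != n_post) {
      stop("`impulse` length (", length(impulse),
           ") must match the number of post-flash points (", n_post, ")")
    }
    h <- impulse
  }

  # precompute the impulse-response FFT once; each objective evaluation
  # then costs two FFTs of power-of-two length
  m_fft <- stats::nextn(2L * n_post, 2L)
  Fh <- stats::fft(c(h, numeric(m_fft - n_post)))
  t_src <- time[post]
  predict_shape <- function(tau1, tau2) {
    Rt <- kinetic_source_cumulative(t_src, tau1, tau2)
    a <- diff(c(0, Rt))
    Fa <- stats::fft(c(a, numeric(m_fft - n_post)))
    s <- numeric(length(time))
    s[post] <- Re(stats::fft(Fh * Fa, inverse = TRUE))[seq_len(n_post)] /
      m_fft
    s
  }
  obj <- function(par) {
    tau <- exp(par)
    if (any(tau < tau_range[1]) || any(tau > tau_range[2])) return(1e30)
    s <- predict_shape(tau[1], tau[2])
    ss <- sum(s * s)
    if (ss == 0) return(1e30)
    amp <- sum(s * y) / ss
    sum((y - amp * s)^2)
  }

  if (is.null(start)) {
    start <- list(c(3e-4, 3e-3), c(1e-3, 1e-2), c(1e-4, 1e-3),
                  c(3e-3, 3e-2))
  }
  best <- NULL
  for (s0 in start) {
    fit <- stats::optim(log(s0), obj, method = "Nelder-Mead",
                        control = list(maxit = 800, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  tau <- sort(exp(best$par))
  s <- predict_shape(tau[1], tau[2])
  amp <- sum(s * y) / sum(s * s)
  resid <- y - amp * s
  ssr <- sum(resid^2)

  # covariance of log-taus from the numerical Hessian of the SSR
  H <- if (errors) {
    tryCatch(stats::optimHess(log(tau), obj), error = function(e) NULL)
  } else NULL
  se_log <- c(NA_real_, NA_real_)
  if (!is.null(H)) {
    sigma2 <- ssr / max(length(y) - 3L, 1L)
    covl <- tryCatch(2 * sigma2 * solve(H), error = function(e) NULL)
    if (!is.null(covl)) se_log <- sqrt(pmax(diag(covl), 0))
  }
  structure(list(tau_pre = tau[1], tau_o2 = tau[2],
                 se_tau_pre = tau[1] * se_log[1],
                 se_tau_o2 = tau[2] * se_log[2],
                 amplitude = amp, ssr = ssr,
                 convergence = best$convergence,
                 weakly_identified = tau[2] / tau[1] < 1.2,
                 fitted = amp * s, residuals = resid,
                 temperature_K = transient$temperature_K),
            class = "o2_fit")
}

#' @export
print.o2_fit <- function(x, ...) {
  cat("<o2_fit>\n")
  cat(sprintf("  tau_pre = %.4g ms (+/- %.2g)\n",
              1e3 * x$tau_pre, 1e3 * x$se_tau_pre))
  cat(sprintf("  tau_O2  = %.4g ms (+/- %.2g)\n",
              1e3 * x$tau_o2, 1e3 * x$se_tau_o2))
  if (x$weakly_identified) {
    cat("  note: time constants differ by < 20% (weakly identified)\n")
  }
  invisible(x)
}

# causal discrete convolution: out[n] = sum_m h[n - m + 1] * a[m],
# via FFT zero-padded to a highly composite length
conv_causal <- function(h, a) {
  n <- length(a)
  m <- stats::nextn(length(h) + n, 2L)
  Fh <- stats::fft(c(h, numeric(m - length(h))))
  Fa <- stats::fft(c(a, numeric(m - n)))
  Re(stats::fft(Fh * Fa, inverse = TRUE))[seq_len(n)] / m
}
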