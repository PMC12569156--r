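#' Evaluate a sum-of-rising-exponentials model
#'
#' Kinetic model used throughout for flash-induced transients:
#' `y(t) = sum_i A_i * (1 - exp(-t / tau_i)) + y0`.
#'
#' @param taus Time constants in seconds, all > 0.
#' @param amplitudes One amplitude per component (signal units).
#' @param y0 Offset.
#' @param time Time grid in seconds.
#' @return Numeric vector `y(time)`.
#' @export
#' @examples
#' multiexp_eval(c(0.005, 0.075), c(1, -0.5), 0, seq(0, 0.5, 0.01))
multiexp_eval <- function(taus, amplitudes, y0, time) {
  if (any(taus <= 0) || anyNA(taus)) stop("all `taus` must be > 0")
  if (length(amplitudes) != length(taus)) {
    stop("`amplitudes` and `taus` must have equal length")
  }
  y <- rep(y0, length(time))
  for (i in seq_along(taus)) {
    y <- y + amplitudes[i] * (1 - exp(-time / taus[i]))
  }
  y
}

# design matrix of the linear sub-problem: one rising exponential per
# component plus the offset column
multiexp_design <- function(taus, time) {
  Phi <- matrix(1, length(time), length(taus) + 1L)
  for (i in seq_along(taus)) Phi[, i] <- 1 - exp(-time / taus[i])
  Phi
}

#' Subtract the pre-flash baseline
#'
#' Signals are fitted as post-flash difference from the pre-flash baseline;
#' the baseline is the mean over the pre-flash window.
#'
#' @param time Time grid (s), flash at t = 0.
#' @param y Signal vector or `time x channel` matrix.
#' @param window Baseline window, default all `t < 0`.
#' @return `y` with the per-channel baseline mean removed.
#' @export
baseline_correct <- function(time, y, window = c(-Inf, 0)) {
  idx <- which(time >= window[1] & time < window[2])
  if (length(idx) == 0L) stop("no time points in the baseline window")
  if (is.matrix(y)) {
    sweep(y, 2L, colMeans(y[idx, , drop = FALSE]))
  } else {
    y - mean(y[idx])
  }
}

#' Global multi-exponential fit with shared time constants
#'
#' Fits `y_ch(t) = sum_i A_{i,ch} (1 - exp(-t/tau_i)) + y0_ch` to one or
#' several channels, with the time constants shared across channels and the
#' amplitudes and offsets free per channel. The problem is separable: at
#' every trial set of time constants, the amplitudes and offsets are the
#' exact linear least-squares solution (variable projection), and only the
#' time constants are optimized nonlinearly (in log space, L-BFGS-B, with
#' multistart over log-spaced initializations).
#'
#' @param time Time grid in seconds.
#' @param y Signal vector or `time x channel` matrix.
#' @param n_components Number of exponential components (1..6).
#' @param window Fit window `[t_lo, t_hi]` in seconds; default `[0,
#'   max(time)]`.
#' @param tau_bounds Bounds `[lo, hi]` on the time constants (s). Default:
#'   `[0.3 * median(dt), 5 * window length]`.
#' @param tau_init `"auto"` (log-spaced between `3 * median(dt)` and half
#'   the window length) or a numeric vector of starting values.
#' @param n_starts Number of multistart initializations (the base start
#'   plus draws log-uniform over the initialization range).
#' @param seed Integer seed for the multistart draws (applied to a local
#'   RNG stream; the global RNG state is preserved).
#' @param max_iter,tol Optimizer control (`maxit` and `factr`-style relative
#'   tolerance passed to [stats::optim()]).
#' @return Object of class `multiexp_fit`: list with `taus` (ascending),
#'   `amplitudes` (`n_components x n_channels`), `y0` (per channel), `ssr`,
#'   `tau_se` (asymptotic, from the Gauss-Newton covariance), `cov`
#'   (covariance of all free parameters, taus first), `convergence`
#'   (optimizer code, 0 = success), `at_bounds` (logical per tau), `time`,
#'   `fitted`, `residuals`, `window` and `n_obs`.
#' @export
fit_multiexp <- function(time, y, n_components,
                         window = NULL, tau_bounds = NULL,
                         tau_init = "auto", n_starts = 8L,
                         seed = 1L, max_iter = 500L, tol = 1e-10) {
  if (!is.matrix(y)) y <- matrix(y, ncol = 1L)
  if (nrow(y) != length(time)) stop("nrow(y) must equal length(time)")
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > 6L) {
    stop("`n_components` must be between 1 and 6")
  }
  if (is.null(window)) window <- c(0, max(time))
  idx <- time_window_idx(time, window)
  t_fit <- time[idx]
  Y <- y[idx, , drop = FALSE]
  if (length(t_fit) < 10L * n_components) {
    stop("fit window holds ", length(t_fit), " points; need at least ",
         10L * n_components, " for ", n_components, " components")
  }
  dt_med <- stats::median(diff(t_fit))
  span <- diff(range(t_fit))
  if (is.null(tau_bounds)) tau_bounds <- c(0.3 * dt_med, 5 * span)
  if (tau_bounds[1] <= 0 || tau_bounds[1] >= tau_bounds[2]) {
    stop("`tau_bounds` must be positive with lo < hi")
  }

  # objective normalized by the signal power so optimizer stopping rules
  # see O(1) values regardless of the (micro-OD) data scale
  y_scale <- sum(Y^2)
  if (y_scale == 0) y_scale <- 1
  ssr_at <- function(log_tau) {
    Phi <- multiexp_design(exp(log_tau), t_fit)
    sum(qr.resid(qr(Phi), Y)^2) / y_scale
  }

  if (identical(tau_init, "auto")) {
    base_init <- exp(seq(log(max(3 * dt_med, tau_bounds[1])),
                         log(min(0.5 * span, tau_bounds[2])),
                         length.out = n_components))
  } else {
    if (length(tau_init) != n_components || any(tau_init <= 0)) {
      stop("`tau_init` must hold ", n_components, " positive values")
    }
    base_init <- as.numeric(tau_init)
  }
  base_init <- pmin(pmax(base_init, tau_bounds[1]), tau_bounds[2])

  # multistart: the log-spaced base start, plus starts drawn log-uniformly
  # over the initialization range (sorted, so components stay ordered),
  # with seed-controlled jitter
  init_lo <- log(max(3 * dt_med, tau_bounds[1]))
  init_hi <- log(min(2 * span, tau_bounds[2]))
  starts <- matrix(log(base_init), nrow = 1L)
  if (n_starts > 1L) {
    uu <- with_local_seed(seed, matrix(stats::runif((n_starts - 1L) *
                                                    n_components),
                                       n_starts - 1L, n_components))
    more <- t(apply(init_lo + uu * (init_hi - init_lo), 1L, sort))
    if (n_components == 1L) more <- matrix(as.vector(more), ncol = 1L)
    more <- pmin(pmax(more, log(tau_bounds[1])), log(tau_bounds[2]))
    starts <- rbind(starts, more)
  }

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], ssr_at, method = "L-BFGS-B",
                   lower = log(tau_bounds[1]), upper = log(tau_bounds[2]),
                   control = list(maxit = max_iter,
                                  factr = max(tol / .Machine$double.eps,
                                              10),
                                  pgtol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all multistart optimizations failed")

  ord <- order(exp(best$par))
  taus <- exp(best$par)[ord]
  Phi <- multiexp_design(taus, t_fit)
  B <- qr.coef(qr(Phi), Y)
  B[is.na(B)] <- 0   # rank-deficient (duplicated tau): keep one column
  A <- B[seq_len(n_components), , drop = FALSE]
  y0 <- B[n_components + 1L, ]
  fitted <- Phi %*% B
  resid <- Y - fitted
  ssr <- sum(resid^2)

  covp <- multiexp_covariance(taus, A, t_fit, resid)
  tau_se <- sqrt(pmax(diag(covp)[seq_len(n_components)], 0))

  at_bounds <- taus / tau_bounds[1] < 1 + 1e-6 |
    taus / tau_bounds[2] > 1 - 1e-6
  structure(list(taus = taus, amplitudes = A, y0 = y0, ssr = ssr,
                 tau_se = tau_se, cov = covp,
                 convergence = best$convergence,
                 at_bounds = at_bounds,
                 time = t_fit, fitted = fitted, residuals = resid,
                 window = window, n_obs = length(Y),
                 n_components = n_components,
                 channels = colnames(y)),
            class = "multiexp_fit")
}

# Gauss-Newton covariance of (taus, A by channel, y0 by channel)
multiexp_covariance <- function(taus, A, t_fit, resid) {
  m <- length(taus)
  nc <- ncol(A)
  nt <- length(t_fit)
  p <- m + nc * (m + 1L)
  J <- matrix(0, nt * nc, p)
  Phi <- multiexp_design(taus, t_fit)
  for (ch in seq_len(nc)) {
    rows <- (ch - 1L) * nt + seq_len(nt)
    for (i in seq_len(m)) {
      J[rows, i] <- -A[i, ch] * (t_fit / taus[i]^2) * exp(-t_fit / taus[i])
    }
    cols <- m + (ch - 1L) * (m + 1L) + seq_len(m + 1L)
    J[rows, cols] <- Phi
  }
  dof <- max(nt * nc - p, 1L)
  sigma2 <- sum(resid^2) / dof
  covp <- tryCatch(sigma2 * solve(crossprod(J)),
                   error = function(e) matrix(NA_real_, p, p))
  covp
}

#' @export
print.multiexp_fit <- function(x, ...) {
  cat("<multiexp_fit>", x$n_components, "component(s),",
      ncol(x$amplitudes), "channel(s)\n")
  tau_ms <- x$taus * 1e3
  se_ms <- x$tau_se * 1e3
  for (i in seq_along(tau_ms)) {
    cat(sprintf("  tau_%d = %.4g ms (+/- %.2g)\n", i, tau_ms[i], se_ms[i]))
  }
  cat("  SSR =", format(x$ssr, digits = 4),
      "| convergence =", x$convergence, "\n")
  invisible(x)
}

#' Subset-refit uncertainties for a global multi-exponential fit
#'
#' Repeats the global fit on channel subsets (by default every leave-one-out
#' and, when feasible, every leave-two-out subset of size >= 2) and reports
#' the across-subset mean and standard deviation of the shared time
#' constants and of the per-channel amplitudes. This is the uncertainty
#' measure appropriate when channel-to-channel consistency, not counting
#' statistics, dominates the error.
#'
#' @param time,y,n_components,... As for [fit_multiexp()].
#' @param drop Subset sizes to generate, as numbers of channels left out
#'   (default `c(1, 2)`); subsets smaller than 2 channels are never used.
#' @return Object of class `multiexp_subsets`: list with `tau_mean`,
#'   `tau_sd`, `amp_mean`, `amp_sd` (component x channel), `taus` (matrix of
#'   per-subset time constants) and `subsets`.
#' @export
subset_uncertainty <- function(time, y, n_components, drop = c(1L, 2L),
                               ...) {
  if (!is.matrix(y)) y <- matrix(y, ncol = 1L)
  nc <- ncol(y)
  if (nc < 3L) {
    feasible <- if (nc >= 3L) "leave-one-out" else "none"
    stop("subset uncertainties need >= 3 channels (got ", nc,
         "); feasible schemes with ", nc, " channels: ", feasible)
  }
  drop <- drop[nc - drop >= 2L]
  subsets <- list()
  for (d in drop) {
    cmb <- utils::combn(nc, nc - d)
    subsets <- c(subsets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  if (length(subsets) == 0L) stop("no feasible channel subsets")
  m <- n_components
  taus <- matrix(NA_real_, length(subsets), m)
  amp_sum <- matrix(0, m, nc)
  amp_sq <- matrix(0, m, nc)
  amp_n <- matrix(0L, m, nc)
  for (s in seq_along(subsets)) {
    ss <- subsets[[s]]
    fit <- fit_multiexp(time, y[, ss, drop = FALSE], m, ...)
    taus[s, ] <- fit$taus
    for (j in seq_along(ss)) {
      amp_sum[, ss[j]] <- amp_sum[, ss[j]] + fit$amplitudes[, j]
      amp_sq[, ss[j]] <- amp_sq[, ss[j]] + fit$amplitudes[, j]^2
      amp_n[, ss[j]] <- amp_n[, ss[j]] + 1L
    }
  }
  amp_mean <- amp_sum / amp_n
  amp_var <- (amp_sq - amp_n * amp_mean^2) / pmax(amp_n - 1L, 1L)
  structure(list(tau_mean = colMeans(taus),
                 tau_sd = apply(taus, 2L, stats::sd),
                 amp_mean = amp_mean,
                 amp_sd = sqrt(pmax(amp_var, 0)),
                 taus = taus,
                 subsets = subsets),
            class = "multiexp_subsets")
}

#' @export
print.multiexp_subsets <- function(x, ...) {
  cat("<multiexp_subsets>", length(x$subsets), "channel subsets\n")
  for (i in seq_along(x$tau_mean)) {
    cat(sprintf("  tau_%d = %.4g ms (sd %.2g ms)\n", i,
                1e3 * x$tau_mean[i], 1e3 * x$tau_sd[i]))
  }
  invisible(x)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
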