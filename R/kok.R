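#' S-state population vector
#'
#' Probabilities of the four semi-stable Kok S-states (S0..S3) of the
#' Mn4CaOx cluster. Populations must be non-negative and sum to one.
#'
#' @param p0,p1,p2,p3 Probabilities of S0..S3.
#' @return Named numeric vector of class `s_state_vector`.
#' @export
#' @examples
#' s_state_vector(0.10, 0.90, 0, 0)  # dark-adapted: 90% S1, 10% S0
s_state_vector <- function(p0, p1, p2, p3) {
  p <- c(S0 = p0, S1 = p1, S2 = p2, S3 = p3)
  validate_s_state(p)
  structure(p, class = "s_state_vector")
}

validate_s_state <- function(p) {
  if (length(p) != 4L || anyNA(p)) {
    stop("S-state vector must hold 4 finite probabilities")
  }
  if (any(p < 0) || any(p > 1)) {
    stop("S-state probabilities must lie in [0, 1]; got (",
         paste(signif(p, 6), collapse = ", "), ")")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    stop("S-state probabilities must sum to 1 (deviation ",
         format(sum(p) - 1), ")")
  }
  invisible(p)
}

#' Kok-cycle flash-train parameters
#'
#' Parameters of the classical Kok model for a train of saturating flashes:
#' a single (S-state-independent) miss factor, the initial dark-adapted
#' S-state distribution, the number of flashes, and relative flash energies.
#' The defaults encode the standard 10-flash protocol on dark-adapted
#' samples: 90% S1 / 10% S0 start, and a final flash of about 3x energy used
#' to separate the flash-induced heat artifact.
#'
#' @param miss Per-flash probability in `[0, 1)` that a centre fails to
#'   advance to the next S-state.
#' @param initial `s_state_vector` before the first flash.
#' @param n_flashes Number of flashes (>= 1).
#' @param flash_energies Relative energy per flash; default 1 for flashes
#'   1..(n-1) and 3 for the last flash when `n_flashes >= 2`.
#' @return List of class `kok_params`.
#' @export
kok_params <- function(miss = 0.12,
                       initial = s_state_vector(0.10, 0.90, 0, 0),
                       n_flashes = 10,
                       flash_energies = NULL) {
  if (!is.numeric(miss) || length(miss) != 1L || miss < 0 || miss >= 1) {
    stop("`miss` must be a single probability in [0, 1)")
  }
  validate_s_state(initial)
  n_flashes <- as.integer(n_flashes)
  if (is.na(n_flashes) || n_flashes < 1L) stop("`n_flashes` must be >= 1")
  if (is.null(flash_energies)) {
    flash_energies <- rep(1, n_flashes)
    if (n_flashes >= 2L) flash_energies[n_flashes] <- 3
  }
  if (length(flash_energies) != n_flashes || any(flash_energies <= 0)) {
    stop("`flash_energies` must be positive and of length `n_flashes`")
  }
  structure(list(miss = miss, initial = initial, n_flashes = n_flashes,
                 flash_energies = as.numeric(flash_energies)),
            class = "kok_params")
}

#' Advance an S-state distribution by one flash
#'
#' One flash either advances a centre cyclically (S_i -> S_{i+1 mod 4},
#' probability `1 - miss`) or leaves it unchanged (probability `miss`):
#' `p'_i = miss * p_i + (1 - miss) * p_{i-1 mod 4}`.
#'
#' @param state `s_state_vector` (or any valid 4-probability vector).
#' @param miss Miss factor in `[0, 1)`.
#' @return Advanced `s_state_vector`.
#' @export
#' @examples
#' advance_s_state(s_state_vector(0.10, 0.90, 0, 0), miss = 0.1)
advance_s_state <- function(state, miss) {
  validate_s_state(state)
  if (!is.numeric(miss) || length(miss) != 1L || miss < 0 || miss >= 1) {
    stop("`miss` must be a single probability in [0, 1)")
  }
  p <- as.numeric(state)
  out <- miss * p + (1 - miss) * p[c(4L, 1L, 2L, 3L)]
  structure(c(S0 = out[1], S1 = out[2], S2 = out[3], S3 = out[4]),
            class = "s_state_vector")
}

#' Per-flash S-state transition weights
#'
#' Propagates the S-state distribution through the flash train and returns
#' the matrix `W` with `W[n, j]` = probability that flash `n` drives the
#' transition S_j -> S_{j+1 mod 4}, i.e. `(1 - miss)` times the S_j
#' population immediately before flash `n`. Each row sums to `1 - miss`.
#' This is the linear design matrix of the flash-train deconvolution.
#'
#' @param params `kok_params`.
#' @return `n_flashes x 4` matrix with columns `S0_to_S1`, `S1_to_S2`,
#'   `S2_to_S3`, `S3_to_S0`.
#' @export
flash_weights <- function(params) {
  stopifnot(inherits(params, "kok_params"))
  W <- matrix(0, params$n_flashes, 4L,
              dimnames = list(NULL, c("S0_to_S1", "S1_to_S2",
                                      "S2_to_S3", "S3_to_S0")))
  state <- params$initial
  for (n in seq_len(params$n_flashes)) {
    W[n, ] <- (1 - params$miss) * as.numeric(state)
    state <- advance_s_state(state, params$miss)
  }
  W
}

#' Deconvolve flash transients into pure S-state-transition signatures
#'
#' Solves, independently at every time point and channel, the linear
#' least-squares problem `Y(n, t) = sum_j W[n, j] x_j(t) (+ E_n a(t))` for
#' the four transition signatures `x_j(t)` (and optionally one heat-artifact
#' waveform `a(t)` per channel whose amplitude scales with the relative
#' flash energy `E_n`). `W` is the Kok transition-weight matrix of
#' [flash_weights()].
#'
#' @param data `flash_transient_set`.
#' @param params `kok_params`; `params$n_flashes` must match the data.
#' @param artifact If `TRUE`, append the flash-energy column and estimate
#'   the artifact waveform jointly.
#' @return Object of class `transition_signatures`: list with `time`,
#'   `signatures` (4 x channel x time array), `artifact` (channel x time
#'   matrix or `NULL`), `fitted` and `residuals` (same shape as
#'   `data$signal`), `weights` (the design matrix) and `params`.
#' @export
deconvolve_flashes <- function(data, params, artifact = FALSE) {
  stopifnot(inherits(data, "flash_transient_set"),
            inherits(params, "kok_params"))
  n_flash <- dim(data$signal)[1]
  if (params$n_flashes != n_flash) {
    stop("params$n_flashes (", params$n_flashes,
         ") does not match the data (", n_flash, " flashes)")
  }
  min_flash <- if (artifact) 5L else 4L
  if (n_flash < min_flash) {
    stop("deconvolution needs at least ", min_flash, " flashes",
         if (artifact) " when the artifact column is included" else "")
  }
  W <- flash_weights(params)
  D <- if (artifact) cbind(W, heat_artifact = data$flash_energies) else W
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    kept <- qrD$pivot[seq_len(qrD$rank)]
    bad <- colnames(D)[setdiff(seq_len(ncol(D)), kept)]
    stop("deconvolution design matrix is rank-deficient (rank ", qrD$rank,
         " of ", ncol(D), "); linearly dependent column(s): ",
         paste(bad, collapse = ", "),
         ". Degenerate miss/initial-population combination?")
  }
  n_chan <- dim(data$signal)[2]
  n_time <- length(data$time)
  sig <- array(NA_real_, c(4L, n_chan, n_time),
               dimnames = list(colnames(W), data$channels, NULL))
  art <- if (artifact) matrix(NA_real_, n_chan, n_time,
                              dimnames = list(data$channels, NULL)) else NULL
  fitted <- array(NA_real_, dim(data$signal))
  for (ch in seq_len(n_chan)) {
    Y <- data$signal[, ch, , drop = TRUE]           # n_flash x n_time
    if (is.null(dim(Y))) Y <- matrix(Y, nrow = n_flash)
    beta <- qr.coef(qrD, Y)                          # ncol(D) x n_time
    sig[, ch, ] <- beta[1:4, , drop = FALSE]
    if (artifact) art[ch, ] <- beta[5L, ]
    fitted[, ch, ] <- D %*% beta
  }
  structure(list(time = data$time,
                 signatures = sig,
                 artifact = art,
                 fitted = fitted,
                 residuals = data$signal - fitted,
                 weights = W,
                 params = params,
                 channels = data$channels),
            class = "transition_signatures")
}

#' @export
print.transition_signatures <- function(x, ...) {
  cat("<transition_signatures>\n")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat("  artifact column:", if (is.null(x$artifact)) "no" else "yes", "\n")
  cat("  residual RMS:", format(sqrt(mean(x$residuals^2)), digits = 4), "\n")
  invisible(x)
}

#' Extract one transition's signatures as a time x channel matrix
#'
#' Convenience accessor turning a deconvolution result into the input
#' expected by [fit_multiexp()].
#'
#' @param x `transition_signatures` from [deconvolve_flashes()].
#' @param transition One of `"S0_to_S1"`, `"S1_to_S2"`, `"S2_to_S3"`,
#'   `"S3_to_S0"`.
#' @return Numeric matrix `length(x$time) x n_channels`.
#' @export
signature_matrix <- function(x, transition = "S3_to_S0") {
  stopifnot(inherits(x, "transition_signatures"))
  transition <- match.arg(transition, dimnames(x$signatures)[[1L]])
  m <- t(x$signatures[transition, , , drop = TRUE])
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
  colnames(m) <- x$channels
  m
}

#' Flash-number amplitude pattern
#'
#' Mean difference signal in a late time window (default 0.700-0.800 s after
#' the flash, where the S-state transitions are complete) for each flash and
#' channel. On data from a cycling sample this reproduces the damped
#' period-of-four oscillation characteristic of the Kok cycle.
#'
#' @param data `flash_transient_set`.
#' @param window Length-2 numeric, averaging window in seconds.
#' @return `n_flashes x n_channels` matrix of window-mean amplitudes.
#' @export
flash_amplitude_pattern <- function(data, window = c(0.700, 0.800)) {
  stopifnot(inherits(data, "flash_transient_set"))
  idx <- time_window_idx(data$time, window)
  n_flash <- dim(data$signal)[1]
  n_chan <- dim(data$signal)[2]
  out <- matrix(NA_real_, n_flash, n_chan,
                dimnames = list(NULL, data$channels))
  for (ch in seq_len(n_chan)) {
    out[, ch] <- rowMeans(data$signal[, ch, idx, drop = FALSE], dims = 1)
  }
  out
}

#' Estimate the miss factor from flash-train data
#'
#' Finds the scalar miss factor that minimizes the residual sum of squares
#' of the Kok deconvolution (for a `flash_transient_set`) or of the
#' equivalent linear model for a per-flash amplitude pattern (matrix input,
#' flashes in rows). The search combines a coarse grid over `bounds` with
#' golden-section refinement around the grid optimum. If the objective is
#' flat in `miss` (no period-four oscillation, e.g. constant signals), the
#' miss factor is unidentifiable and no point estimate is returned.
#'
#' @param data `flash_transient_set` or amplitude-pattern matrix
#'   (`n_flashes x n_channels`).
#' @param params `kok_params` supplying the initial populations and flash
#'   energies; its `miss` entry is ignored (treated as free).
#' @param bounds Search interval for the miss factor.
#' @param artifact Include the heat-artifact column in the deconvolution
#'   objective (data-set input only).
#' @param n_grid Number of coarse grid points.
#' @param tol Absolute tolerance of the golden-section refinement.
#' @return List with `miss` (point estimate, or `NA` if unidentifiable),
#'   `objective` (data.frame of grid `miss` and residual SSR),
#'   `identifiable` (logical) and `ssr` at the optimum.
#' @export
estimate_miss <- function(data, params = kok_params(),
                          bounds = c(0, 0.5), artifact = FALSE,
                          n_grid = 26L, tol = 1e-3) {
  stopifnot(length(bounds) == 2L, bounds[1] >= 0, bounds[2] < 1,
            bounds[1] < bounds[2])
  if (inherits(data, "flash_transient_set")) {
    n_flash <- dim(data$signal)[1]
    objective <- function(m) {
      p <- params
      p$miss <- m
      fit <- deconvolve_flashes(data, p, artifact = artifact)
      sum(fit$residuals^2)
    }
  } else if (is.matrix(data)) {
    n_flash <- nrow(data)
    objective <- function(m) {
      p <- params
      p$miss <- m
      W <- flash_weights(p)
      res <- qr.resid(qr(W), data)
      sum(res^2)
    }
  } else {
    stop("`data` must be a flash_transient_set or an amplitude matrix")
  }
  if (n_flash < 8L) {
    stop("miss-factor estimation needs at least 8 flashes (got ",
         n_flash, ")")
  }
  grid <- seq(bounds[1], bounds[2], length.out = n_grid)
  ssr <- vapply(grid, objective, numeric(1))
  obj_df <- data.frame(miss = grid, ssr = ssr)
  # flat objective => no oscillation information about the miss factor
  if (diff(range(ssr)) <= 1e-6 * max(ssr, .Machine$double.eps)) {
    return(list(miss = NA_real_, objective = obj_df,
                identifiable = FALSE, ssr = min(ssr)))
  }
  i <- which.min(ssr)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- stats::optimize(objective, lower = lo, upper = hi, tol = tol)
  # golden-section can stay marginally above the grid optimum near an edge
  if (opt$objective <= ssr[i]) {
    miss_hat <- opt$minimum
    ssr_hat <- opt$objective
  } else {
    miss_hat <- grid[i]
    ssr_hat <- ssr[i]
  }
  list(miss = miss_hat, objective = obj_df, identifiable = TRUE,
       ssr = ssr_hat)
}
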