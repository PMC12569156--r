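#' Default schematic S-state transition signatures
#'
#' Multi-exponential parameter sets (one per S-state transition and
#' channel) used by [make_ir_dataset()]. These are synthetic conventions,
#' not digitized experimental curves: the S3 -> S0 transition is biphasic
#' (6.5 ms and 75 ms) with channel-dependent amplitude ratios (slow phase
#' dominating at 1384 and 1514 cm^-1, fast phase at 1544 cm^-1, fast phase
#' essentially absent at 1400 cm^-1) plus a sub-millisecond negative
#' proton-transfer phase; the other transitions are single-exponential with
#' distinct channel amplitude patterns. Amplitudes are in OD (1e-6 = 1
#' micro-OD).
#'
#' @param channels Channel labels (default the four probe wavenumbers).
#' @return Named list with one element per transition; each element is a
#'   list with `taus` (s), `amplitudes` (component x channel matrix, OD)
#'   and `y0` (per channel, OD).
#' @export
default_ir_signatures <- function(channels = c("1384", "1400", "1514",
                                               "1544")) {
  nc <- length(channels)
  amp <- function(...) {
    m <- rbind(...) * 1e-6
    colnames(m) <- channels
    m
  }
  if (nc != 4L) {
    # generic fallback: deterministic channel patterns of the same scale
    base <- outer(c(1, -0.6), seq_len(nc), function(a, j) a * (60 + 15 * j))
    return(stats::setNames(lapply(1:4, function(j) {
      list(taus = c(5e-4, c(0.002, 0.0002, 0.0015, 0.0065)[j]),
           amplitudes = base * 1e-6 * j / 2,
           y0 = rep(0, nc))
    }), c("S0_to_S1", "S1_to_S2", "S2_to_S3", "S3_to_S0")))
  }
  list(
    S0_to_S1 = list(taus = c(5e-4, 2e-3),
                    amplitudes = amp(c(-40, -30, 25, -35),
                                     c(60, 45, -50, 70)),
                    y0 = rep(0, nc)),
    S1_to_S2 = list(taus = c(1e-4, 1.2e-3),
                    amplitudes = amp(c(30, 45, -20, 25),
                                     c(-80, -60, 65, -45)),
                    y0 = rep(0, nc)),
    S2_to_S3 = list(taus = c(5e-4, 1.5e-3),
                    amplitudes = amp(c(-25, 20, 30, -30),
                                     c(45, -70, -55, 60)),
                    y0 = rep(0, nc)),
    S3_to_S0 = list(taus = c(9.9e-4, 6.5e-3, 7.5e-2),
                    amplitudes = amp(c(-60, -55, -50, -65),
                                     c(30, 2, 40, 120),
                                     c(120, 100, 150, 40)),
                    y0 = rep(0, nc))
  )
}

eval_signatures <- function(signatures, time, channels) {
  nc <- length(channels)
  x <- array(0, c(length(signatures), nc, length(time)),
             dimnames = list(names(signatures), channels, NULL))
  tp <- pmax(time, 0)
  for (j in seq_along(signatures)) {
    sg <- signatures[[j]]
    for (ch in seq_len(nc)) {
      v <- multiexp_eval(sg$taus, sg$amplitudes[, ch], sg$y0[ch], tp)
      v[time < 0] <- 0
      x[j, ch, ] <- v
    }
  }
  x
}

#' Default flash-induced heat-artifact waveform
#'
#' Slow thermal relaxation waveform whose amplitude in the composed data
#' scales with the relative flash energy; per-channel amplitudes are a
#' fixed schematic pattern (OD units).
#'
#' @param time Time grid (s).
#' @param channels Channel labels.
#' @return `channel x time` matrix.
#' @export
default_heat_artifact <- function(time, channels) {
  amp <- 1e-6 * (15 + 5 * seq_along(channels))
  tp <- pmax(time, 0)
  wav <- 1 - exp(-tp / 0.25)
  out <- outer(amp, wav)
  out[, time < 0] <- 0
  rownames(out) <- channels
  out
}

#' Generate a synthetic flash-train IR dataset
#'
#' Composes flash transients as `Y(n, ch, t) = sum_j W[n, j] x_j(ch, t) +
#' E_n a(ch, t) + noise`, where `W` is the Kok transition-weight matrix for
#' the given parameters, `x_j` are the transition signatures, `a` the heat
#' artifact scaled by relative flash energy `E_n`, and the noise is i.i.d.
#' Gaussian per sample (default sigma 5e-6 OD, i.e. 5 micro-OD). Fully
#' deterministic for a fixed seed; the ground truth needed to score any
#' downstream estimator is returned alongside.
#'
#' @param params `kok_params` (miss factor, initial populations, flash
#'   count and energies).
#' @param signatures Transition signature definitions as in
#'   [default_ir_signatures()].
#' @param time Time grid (s) with a pre-flash baseline window.
#' @param noise_sd Gaussian noise standard deviation in OD.
#' @param artifact `NULL` for none, `TRUE` for
#'   [default_heat_artifact()], or a `channel x time` matrix.
#' @param temperature_K Stored in the metadata (default 283.15 K).
#' @param seed Integer seed (local RNG stream; global RNG preserved).
#' @return List with `data` (a [flash_transient_set()]) and `truth` (list
#'   with `weights`, `signatures` evaluated as a 4 x channel x time array,
#'   `artifact`, `miss` and `seed`).
#' @export
make_ir_dataset <- function(params = kok_params(),
                            signatures = default_ir_signatures(),
                            time = seq(-0.1, 0.9, by = 1e-3),
                            noise_sd = 5e-6,
                            artifact = NULL,
                            temperature_K = 283.15,
                            seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  channels <- colnames(signatures[[1L]]$amplitudes)
  if (is.null(channels)) {
    channels <- paste0("ch", seq_len(ncol(signatures[[1L]]$amplitudes)))
  }
  x <- eval_signatures(signatures, time, channels)
  W <- flash_weights(params)
  nf <- params$n_flashes
  nc <- length(channels)
  nt <- length(time)
  if (isTRUE(artifact)) artifact <- default_heat_artifact(time, channels)
  Y <- array(0, c(nf, nc, nt))
  for (ch in seq_len(nc)) {
    Y[, ch, ] <- W %*% x[, ch, ]          # nf x 4 times 4 x nt
    if (!is.null(artifact)) {
      Y[, ch, ] <- Y[, ch, ] +
        outer(params$flash_energies, artifact[ch, ])
    }
  }
  if (noise_sd > 0) {
    Y <- Y + with_local_seed(seed,
                             array(stats::rnorm(length(Y), 0, noise_sd),
                                   dim(Y)))
  }
  data <- flash_transient_set(time, Y, channels = channels,
                              flash_energies = params$flash_energies,
                              temperature_K = temperature_K,
                              flash_spacing_s = 1, seed = seed)
  list(data = data,
       truth = list(weights = W, signatures = x, artifact = artifact,
                    miss = params$miss, noise_sd = noise_sd, seed = seed))
}

#' Generate a synthetic O2-polarography temperature series
#'
#' For each temperature, the two source time constants follow the given
#' Arrhenius laws (`ln k = ln A - E_a / (k_B T)`); a transient is produced
#' with [simulate_o2_transient()] and i.i.d. Gaussian noise scaled to the
#' peak of the noise-free signal is added. Defaults emulate the wild-type
#' study design: eight temperatures from 0 to 35 C, `E_a` 421 meV / `ln A`
#' 23.0 for the O2 step, `E_a` 269 meV for the preceding step with `ln A`
#' set so that `tau_pre(20 C)` is about 0.3 ms, and 2% noise.
#'
#' @param model `electrode_model`.
#' @param Ea_o2_meV,lnA_o2 Arrhenius law of the O2-evolution step.
#' @param Ea_pre_meV,lnA_pre Arrhenius law of the preceding step.
#' @param temperatures_C Temperatures in Celsius.
#' @param noise Relative noise level (fraction of the peak amplitude).
#' @param time Uniform time grid (s).
#' @param seed Integer seed.
#' @return List with `transients` (list of `o2_transient`) and `truth`
#'   (data frame with `temperature_K`, `tau_pre_s`, `tau_o2_s`; plus the
#'   law parameters and `seed`).
#' @export
make_temperature_series <- function(model = electrode_model(),
                                    Ea_o2_meV = 421, lnA_o2 = 23.0,
                                    Ea_pre_meV = 269, lnA_pre = 18.8,
                                    temperatures_C = seq(0, 35, 5),
                                    noise = 0.02,
                                    time = seq(-0.020, 0.480, by = 5e-4),
                                    seed = 1L) {
  if (noise < 0) stop("`noise` must be >= 0")
  T_K <- temperatures_C + 273.15
  if (any(T_K < 270) || any(T_K > 320)) {
    stop("temperatures must lie within 270-320 K")
  }
  kB <- eyring_constants[["kB_eV_per_K"]]
  tau_from_law <- function(Ea_meV, lnA) {
    1 / exp(lnA - (Ea_meV * 1e-3) / (kB * T_K))
  }
  tau_pre <- tau_from_law(Ea_pre_meV, lnA_pre)
  tau_o2 <- tau_from_law(Ea_o2_meV, lnA_o2)
  eps <- with_local_seed(seed,
                         matrix(stats::rnorm(length(time) * length(T_K)),
                                length(time), length(T_K)))
  # one Crank-Nicolson impulse solve per geometry; each temperature is
  # then the convolution with its closed-form source (identical to the
  # direct solution by linearity)
  dt <- check_uniform_grid(time)
  post <- which(time > 0)
  h_raw <- electrode_impulse_response(model, dt, length(post))
  transients <- vector("list", length(T_K))
  for (i in seq_along(T_K)) {
    Rt <- kinetic_source_cumulative(time[post], tau_pre[i], tau_o2[i])
    raw <- numeric(length(time))
    raw[post] <- conv_causal(h_raw, diff(c(0, Rt)))
    signal <- model$amplitude * highpass_filter(raw, dt, model$tau_filter)
    if (noise > 0) {
      signal <- signal + noise * max(abs(signal)) * eps[, i]
    }
    transients[[i]] <- structure(
      list(time = time, signal = signal, raw = model$amplitude * raw,
           temperature_K = T_K[i], tau_filter = model$tau_filter,
           mass_balance = NULL),
      class = "o2_transient")
  }
  list(transients = transients,
       truth = data.frame(temperature_K = T_K, tau_pre_s = tau_pre,
                          tau_o2_s = tau_o2),
       laws = list(Ea_o2_meV = Ea_o2_meV, lnA_o2 = lnA_o2,
                   Ea_pre_meV = Ea_pre_meV, lnA_pre = lnA_pre),
       seed = seed)
}

#' Generate single-transition transients from a sequential scheme
#'
#' Links the intermediate populations of a [sequential_scheme()] to
#' observable channel signals: `y(ch, t) = sum_X w[X, ch] * P_X(t) +
#' noise`, with one spectral weight per species and channel. Useful for
#' testing whether downstream exponential fitting resolves the kinetic
#' phases implied by a population scheme.
#'
#' @param scheme `sequential_scheme`.
#' @param weights `4 x n_channels` matrix of species spectral weights
#'   (rows A, B, C, D), in signal units.
#' @param time Non-negative time grid (s).
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param seed Integer seed.
#' @return List with `time`, `y` (`time x channel` matrix) and `truth`
#'   (the population trajectory and weights).
#' @export
make_scheme_ir <- function(scheme, weights, time, noise_sd = 5e-6,
                           seed = 1L) {
  stopifnot(inherits(scheme, "sequential_scheme"))
  if (!is.matrix(weights) || nrow(weights) != 4L) {
    stop("`weights` must be a 4 x n_channels matrix (rows A, B, C, D)")
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    stop("`weights` must be finite")
  }
  traj <- scheme_populations(scheme, time)
  P <- t(as.matrix(traj[, c("P_A", "P_B", "P_C", "P_D")]))  # 4 x nt
  y <- t(weights) %*% P                                     # nc x nt
  y <- t(y)                                                 # nt x nc
  if (noise_sd > 0) {
    y <- y + with_local_seed(seed,
                             matrix(stats::rnorm(length(y), 0, noise_sd),
                                    nrow(y), ncol(y)))
  }
  colnames(y) <- colnames(weights)
  list(time = as.numeric(time), y = y,
       truth = list(trajectory = traj, weights = weights,
                    noise_sd = noise_sd, seed = seed))
}
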