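#' Physical constants (electron-volt units)
#'
#' Boltzmann constant `k_B = 8.617333e-5 eV/K` and Planck constant
#' `h = 4.135668e-15 eV s`, as used in all activation-energy conversions.
#'
#' @format Named numeric vector with elements `kB_eV_per_K` and `h_eV_s`.
#' @export
eyring_constants <- c(kB_eV_per_K = 8.617333e-5, h_eV_s = 4.135668e-15)

#' Arrhenius regression of temperature-dependent time constants
#'
#' Ordinary least squares of `ln(1/tau)` on `1/T`:
#' `ln k = ln A - E_a / (k_B T)`. The activation energy is the negative
#' slope times `k_B` (reported in meV) and `ln A` is the intercept
#' (`A` in 1/s). 1-sigma errors come from the regression covariance (the
#' 1-sigma confidence interval of the slope).
#'
#' @param temperature_K Absolute temperatures in kelvin (>= 3 distinct
#'   values; 2 allowed only with `allow_two_points = TRUE`, when the line
#'   is exact).
#' @param tau_s Time constants in seconds, one per temperature.
#' @param weights Optional regression weights (e.g. inverse variances of
#'   `ln k`); default unweighted.
#' @param allow_two_points Permit an exact two-point fit (no error
#'   estimates).
#' @return Object of class `arrhenius_fit`: list with `Ea_meV`, `lnA`,
#'   `se_Ea_meV`, `se_lnA`, `cov` (2x2, slope/intercept order Ea then lnA,
#'   in meV and natural-log units), `lm` (the underlying [stats::lm()]
#'   fit) and `tau_at(T)` (predicted time constant at temperature `T` in
#'   K).
#' @export
arrhenius_fit <- function(temperature_K, tau_s, weights = NULL,
                          allow_two_points = FALSE) {
  T_K <- as.numeric(temperature_K)
  tau <- as.numeric(tau_s)
  if (length(T_K) != length(tau)) stop("temperature and tau lengths differ")
  if (anyNA(T_K) || anyNA(tau) || any(T_K <= 0) || any(tau <= 0)) {
    stop("temperatures and time constants must be positive and finite")
  }
  n_min <- if (allow_two_points) 2L else 3L
  if (length(unique(T_K)) < n_min) {
    stop("need at least ", n_min, " distinct temperatures (got ",
         length(unique(T_K)), ")")
  }
  if (diff(range(T_K)) <= 0) stop("zero temperature spread")
  kB <- eyring_constants[["kB_eV_per_K"]]
  df <- data.frame(lnk = log(1 / tau), invT = 1 / T_K)
  fit <- if (is.null(weights)) stats::lm(lnk ~ invT, data = df)
         else stats::lm(lnk ~ invT, data = df, weights = weights)
  co <- stats::coef(fit)
  Ea_meV <- -co[["invT"]] * kB * 1e3
  lnA <- co[["(Intercept)"]]
  if (length(T_K) > 2L) {
    # vcov warns on numerically perfect fits (legitimate for noise-free
    # round trips); the zero errors it returns are what we want
    V <- suppressWarnings(stats::vcov(fit))
    se_Ea <- sqrt(V["invT", "invT"]) * kB * 1e3
    se_lnA <- sqrt(V["(Intercept)", "(Intercept)"])
    covEL <- matrix(c(V["invT", "invT"] * (kB * 1e3)^2,
                      -V["invT", "(Intercept)"] * kB * 1e3,
                      -V["(Intercept)", "invT"] * kB * 1e3,
                      V["(Intercept)", "(Intercept)"]), 2L, 2L,
                    dimnames = list(c("Ea_meV", "lnA"),
                                    c("Ea_meV", "lnA")))
  } else {
    se_Ea <- se_lnA <- NA_real_
    covEL <- matrix(NA_real_, 2L, 2L,
                    dimnames = list(c("Ea_meV", "lnA"),
                                    c("Ea_meV", "lnA")))
  }
  tau_at <- function(T0) 1 / exp(lnA - (Ea_meV * 1e-3) / (kB * T0))
  structure(list(Ea_meV = Ea_meV, lnA = lnA,
                 se_Ea_meV = se_Ea, se_lnA = se_lnA, cov = covEL,
                 lm = fit, tau_at = tau_at,
                 temperature_K = T_K, tau_s = tau),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat("<arrhenius_fit>", length(x$tau_s), "temperatures\n")
  cat(sprintf("  E_a   = %.1f +/- %.1f meV\n", x$Ea_meV, x$se_Ea_meV))
  cat(sprintf("  ln A  = %.2f +/- %.2f (A in 1/s)\n", x$lnA, x$se_lnA))
  invisible(x)
}

#' Eyring transition-state decomposition
#'
#' Converts an Arrhenius activation energy and a time constant at the
#' reference temperature into the enthalpy, Gibbs free energy, and entropic
#' contribution of activation:
#' `dH = E_a - k_B T0`, `dG = k_B T0 ln(k_B T0 tau / h)`,
#' `-T0 dS = dG - dH`, all in meV. The decomposition satisfies the Eyring
#' equation `k = (k_B T0 / h) exp(-dG / k_B T0)` with `k = 1/tau` exactly.
#'
#' @param Ea_meV Activation energy in meV.
#' @param tau_s Time constant at the reference temperature (s).
#' @param T0 Reference temperature in kelvin (default 293.15, i.e. 20 C).
#' @return Object of class `eyring_result`: list with `dH_meV`, `dG_meV`,
#'   `negT0dS_meV`, `Ea_meV`, `tau_s`, `T0_K` and the constants used.
#' @export
#' @examples
#' eyring(421, 1.72e-3)  # ~396 / 583 / 187 meV
eyring <- function(Ea_meV, tau_s, T0 = 293.15) {
  if (tau_s <= 0) stop("`tau_s` must be positive")
  if (T0 <= 0) stop("`T0` must be positive (kelvin)")
  kB <- eyring_constants[["kB_eV_per_K"]]
  h <- eyring_constants[["h_eV_s"]]
  kBT_meV <- kB * T0 * 1e3
  dH <- Ea_meV - kBT_meV
  dG <- kBT_meV * log(kB * T0 / h * tau_s)
  structure(list(dH_meV = dH, dG_meV = dG, negT0dS_meV = dG - dH,
                 Ea_meV = Ea_meV, tau_s = tau_s, T0_K = T0,
                 constants = eyring_constants),
            class = "eyring_result")
}

#' @export
print.eyring_result <- function(x, ...) {
  cat(sprintf("<eyring_result> T0 = %.2f K, tau = %.3g ms\n",
              x$T0_K, 1e3 * x$tau_s))
  cat(sprintf("  dH   = %.1f meV\n", x$dH_meV))
  cat(sprintf("  dG   = %.1f meV\n", x$dG_meV))
  cat(sprintf("  -TdS = %.1f meV\n", x$negT0dS_meV))
  invisible(x)
}

#' Error propagation for the Eyring decomposition
#'
#' Propagation rules for the activation thermodynamics: the enthalpy error
#' equals the activation-energy error, `sigma(dH) = sigma(E_a)`; the
#' free-energy error follows first-order from the relative error of the
#' time constant, `sigma(dG) = k_B T0 * sigma_tau / tau` (or is supplied
#' directly); and the entropic error is the sum,
#' `sigma(-T0 dS) = sigma(dG) + sigma(dH)`.
#'
#' @param sigma_Ea_meV 1-sigma error of the activation energy (meV).
#' @param tau_s,sigma_tau_s Time constant at `T0` and its 1-sigma error
#'   (used to derive `sigma(dG)` when `sigma_dG_meV` is not given).
#' @param sigma_dG_meV Optional free-energy error in meV, overriding the
#'   tau-based propagation.
#' @param T0 Reference temperature in kelvin.
#' @return Named numeric vector with `sigma_dH_meV`, `sigma_dG_meV`,
#'   `sigma_negT0dS_meV`.
#' @export
eyring_errors <- function(sigma_Ea_meV, tau_s = NULL, sigma_tau_s = NULL,
                          sigma_dG_meV = NULL, T0 = 293.15) {
  if (sigma_Ea_meV < 0) stop("errors must be non-negative")
  if (is.null(sigma_dG_meV)) {
    if (is.null(tau_s) || is.null(sigma_tau_s)) {
      stop("supply either `sigma_dG_meV` or both `tau_s` and `sigma_tau_s`")
    }
    if (sigma_tau_s < 0 || tau_s <= 0) stop("invalid tau error inputs")
    kB <- eyring_constants[["kB_eV_per_K"]]
    sigma_dG_meV <- kB * T0 * 1e3 * sigma_tau_s / tau_s
  }
  if (sigma_dG_meV < 0) stop("errors must be non-negative")
  c(sigma_dH_meV = sigma_Ea_meV,
    sigma_dG_meV = sigma_dG_meV,
    sigma_negT0dS_meV = sigma_dG_meV + sigma_Ea_meV)
}
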