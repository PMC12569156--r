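#' Sequential intermediate scheme of the oxygen-evolving transition
#'
#' Irreversible first-order chain A -> B -> C -> D describing the
#' S3 -> S4 -> S0 transition: A = Yz(ox) S3+ (before proton removal), B =
#' Yz(ox) S3n (before the rate-limiting oxyl-radical formation and O2
#' release), C = S0+ (post O2-release, before water insertion), D = S0n
#' (stable S0). Every step is assumed strongly exergonic, so backward rates
#' are neglected.
#'
#' @param k_ab,k_bc,k_cd Rate constants in 1/s, all > 0. Rates are the
#'   reciprocals of the measured time constants (`k = 1/tau`).
#' @return List of class `sequential_scheme`.
#' @seealso [scheme_populations()], [default_kcd()]
#' @export
sequential_scheme <- function(k_ab, k_bc, k_cd = default_kcd(k_bc)) {
  k <- c(k_ab = k_ab, k_bc = k_bc, k_cd = k_cd)
  if (anyNA(k) || any(k <= 0)) {
    stop("all rate constants must be positive (k_ab, k_bc, k_cd in 1/s)")
  }
  structure(list(k_ab = k_ab, k_bc = k_bc, k_cd = k_cd,
                 labels = c(A = "Yz_ox S3+", B = "Yz_ox S3n",
                            C = "S0+ (post O2 release)", D = "S0n")),
            class = "sequential_scheme")
}

#' Default water-insertion rate when the C intermediate is unresolved
#'
#' When the post-O2-release intermediate C does not accumulate to a
#' resolvable extent (wild-type-like behaviour), its decay rate is fixed at
#' 20 times the rate of the step that forms it.
#'
#' @param k_bc Rate constant of the O2-forming step (1/s).
#' @return `20 * k_bc`.
#' @export
default_kcd <- function(k_bc) {
  if (any(k_bc <= 0)) stop("`k_bc` must be positive")
  20 * k_bc
}

# relative-degeneracy test used to switch to the analytic limit formulas
rates_close <- function(ka, kb, tol = 1e-9) {
  abs(ka - kb) <= tol * max(ka, kb)
}

# phi(z) = (1 - exp(-z)) / z for z >= 0, stable at z -> 0 (phi(0) = 1)
phi1 <- function(z) {
  out <- ifelse(z < 1e-8, 1 - z / 2, -expm1(-z) / z)
  out
}

# first divided difference of f(k) = exp(-k t), symmetric in (a, b),
# anchored at the smaller rate so no intermediate overflows:
# f[a,b] = (f(a) - f(b)) / (a - b) = -t exp(-lo t) phi1((hi - lo) t)
exp_dd2 <- function(a, b, t) {
  lo <- min(a, b)
  hi <- max(a, b)
  -t * exp(-lo * t) * phi1((hi - lo) * t)
}

#' Closed-form populations of the sequential scheme
#'
#' Bateman solution of the irreversible chain A -> B -> C -> D with
#' `P_A(0) = 1`. Near-degenerate rate constants (relative difference below
#' `1e-9`) are handled by the analytic confluent limit formulas
#' (t^n-weighted exponentials), so the solution is continuous across
#' degeneracies. The cumulative O2 curve `P_C + P_D` (O2 appears with the
#' B -> C step) is included.
#'
#' @param scheme `sequential_scheme`.
#' @param time Non-negative time grid in seconds.
#' @return Data frame of class `population_trajectory` with columns `time`,
#'   `P_A`, `P_B`, `P_C`, `P_D`, `O2`.
#' @export
scheme_populations <- function(scheme, time) {
  stopifnot(inherits(scheme, "sequential_scheme"))
  t <- as.numeric(time)
  if (anyNA(t) || any(t < 0)) stop("`time` must be non-negative")
  k1 <- scheme$k_ab; k2 <- scheme$k_bc; k3 <- scheme$k_cd

  P_A <- exp(-k1 * t)

  # Bateman terms as divided differences of exp(-k t) over the rate
  # nodes, computed through expm1 so near-degenerate rates lose no
  # precision: P_B = -k1 f[k1,k2], P_C = k1 k2 f[k1,k2,k3]
  P_B <- -k1 * exp_dd2(k1, k2, t)

  ks <- c(k1, k2, k3)
  spread <- (max(ks) - min(ks)) / max(ks)
  if (spread <= 1e-7) {
    # fully confluent limit f[k,k,k] = t^2/2 exp(-k t) at the mean rate
    kbar <- mean(ks)
    P_C <- k1 * k2 * t^2 / 2 * exp(-kbar * t)
  } else {
    # second divided difference through the closest pair (p, q), so the
    # only small denominator is handled inside exp_dd2
    gaps <- c(abs(k1 - k2), abs(k1 - k3), abs(k2 - k3))
    pq <- list(c(1, 2, 3), c(1, 3, 2), c(2, 3, 1))[[which.min(gaps)]]
    p <- ks[pq[1]]; q <- ks[pq[2]]; r <- ks[pq[3]]
    dd3 <- (exp_dd2(p, q, t) - exp_dd2(q, r, t)) / (p - r)
    P_C <- k1 * k2 * dd3
  }

  P_C <- pmin(pmax(P_C, 0), 1)
  P_B <- pmin(pmax(P_B, 0), 1)
  P_D <- 1 - P_A - P_B - P_C
  P_D <- pmin(pmax(P_D, 0), 1)

  out <- data.frame(time = t, P_A = P_A, P_B = P_B, P_C = P_C, P_D = P_D,
                    O2 = P_C + P_D)
  class(out) <- c("population_trajectory", "data.frame")
  attr(out, "scheme") <- scheme
  out
}

#' Cumulative O2-release curve of a population trajectory
#'
#' O2 is released with the B -> C step (C is the post-release S0+ state), so
#' the cumulative fraction of released dioxygen is `P_C + P_D =
#' 1 - P_A - P_B`. It starts at 0, is non-decreasing and tends to 1.
#'
#' @param trajectory `population_trajectory` from [scheme_populations()].
#' @return Numeric vector of cumulative O2 fractions.
#' @export
o2_release_curve <- function(trajectory) {
  stopifnot(inherits(trajectory, "population_trajectory"))
  trajectory$P_C + trajectory$P_D
}

#' Half-rise time of the O2 curve
#'
#' Time at which the cumulative O2 fraction reaches one half, found by
#' root-finding on the closed-form solution.
#'
#' @param scheme `sequential_scheme`.
#' @param upper Upper search bound in seconds (default `50 / min(rate)`).
#' @return Half-rise time in seconds.
#' @export
o2_half_rise_time <- function(scheme,
                              upper = 50 / min(scheme$k_ab, scheme$k_bc,
                                               scheme$k_cd)) {
  f <- function(t) {
    tr <- scheme_populations(scheme, t)
    tr$O2 - 0.5
  }
  stats::uniroot(f, lower = 0, upper = upper, tol = 1e-12)$root
}
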