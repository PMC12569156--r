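#' Flash-indexed set of time-resolved difference transients
#'
#' Container for flash-train data: one common time grid (seconds, flash at
#' t = 0) and a `flash x channel x time` array of difference signals
#' (typically delta-absorbance in OD units for IR data, or electrode current
#' in arbitrary units).
#'
#' @param time Numeric vector of time points in seconds, strictly increasing.
#'   Should cover a pre-flash baseline window (negative times) and the
#'   post-flash response.
#' @param signal Numeric array of dimension `n_flashes x n_channels x
#'   length(time)`, without missing values.
#' @param channels Character vector of channel labels (wavenumbers in cm^-1
#'   for IR data, or detector names).
#' @param flash_energies Relative flash energies, one per flash (used for the
#'   heat-artifact column in [deconvolve_flashes()]).
#' @param temperature_K Sample temperature in kelvin, or `NA`.
#' @param flash_spacing_s Spacing between consecutive flashes in seconds.
#' @param seed Integer seed if the set is synthetic, else `NA`.
#'
#' @return An object of class `flash_transient_set`: a list with elements
#'   `time`, `signal`, `channels`, `flash_energies` and `metadata`.
#' @seealso [deconvolve_flashes()], [flash_amplitude_pattern()],
#'   [make_ir_dataset()]
#' @export
flash_transient_set <- function(time, signal, channels = NULL,
                                flash_energies = NULL,
                                temperature_K = NA_real_,
                                flash_spacing_s = 1,
                                seed = NA_integer_) {
  time <- as.numeric(time)
  if (length(time) < 2L || anyNA(time) || any(diff(time) <= 0)) {
    stop("`time` must be a strictly increasing numeric vector without NA")
  }
  if (length(dim(signal)) != 3L) {
    stop("`signal` must be a 3-d array: flash x channel x time")
  }
  if (dim(signal)[3] != length(time)) {
    stop("third dimension of `signal` (", dim(signal)[3],
         ") must match length(time) (", length(time), ")")
  }
  if (anyNA(signal)) stop("`signal` contains missing values")
  n_flash <- dim(signal)[1]
  n_chan <- dim(signal)[2]
  if (is.null(channels)) channels <- paste0("ch", seq_len(n_chan))
  if (length(channels) != n_chan) {
    stop("length(channels) must equal dim(signal)[2]")
  }
  if (is.null(flash_energies)) flash_energies <- rep(1, n_flash)
  if (length(flash_energies) != n_flash || any(flash_energies <= 0)) {
    stop("`flash_energies` must be positive, one value per flash")
  }
  structure(
    list(time = time,
         signal = signal,
         channels = as.character(channels),
         flash_energies = as.numeric(flash_energies),
         metadata = list(temperature_K = temperature_K,
                         flash_spacing_s = flash_spacing_s,
                         seed = seed)),
    class = "flash_transient_set")
}

#' @export
print.flash_transient_set <- function(x, ...) {
  cat("<flash_transient_set>\n")
  cat("  flashes :", dim(x$signal)[1], "\n")
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  cat(sprintf("  time    : %g .. %g s (%d points)\n",
              min(x$time), max(x$time), length(x$time)))
  if (!is.na(x$metadata$temperature_K)) {
    cat("  T       :", x$metadata$temperature_K, "K\n")
  }
  invisible(x)
}

#' @export
dim.flash_transient_set <- function(x) dim(x$signal)

# index of time points inside [lo, hi]; errors when empty
time_window_idx <- function(time, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  idx <- which(time >= window[1] & time <= window[2])
  if (length(idx) == 0L) {
    stop(sprintf("window [%g, %g] s contains no time points (grid %g..%g s)",
                 window[1], window[2], min(time), max(time)))
  }
  idx
}
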