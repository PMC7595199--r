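#' Spectral estimation configuration
#'
#' Defaults follow the qEEG convention used throughout the package: a dense
#' 0.5--31 Hz grid in 0.1 Hz steps (306 frequencies) and a complex Morlet
#' wavelet with wavenumber 15 (cycles per Gaussian envelope), trading time
#' resolution for a narrow spectral bandwidth of f/15.
#'
#' @param f_min,f_max,f_step Frequency grid in Hz (`f_min > 0`).
#' @param wavenumber Morlet cycles parameter; the Gaussian envelope has
#'   standard deviation `wavenumber / (2 * pi * f)` seconds at frequency `f`.
#' @param edge_sigmas Edge policy: at each frequency the first and last
#'   `ceiling(edge_sigmas * sigma_t * rate)` samples are discarded before
#'   time-averaging, removing convolution edge artifacts.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(f_min = 0.5, f_max = 31, f_step = 0.1,
                            wavenumber = 15, edge_sigmas = 3) {
  if (f_min <= 0) abort_param("f_min must be > 0")
  if (f_step <= 0) abort_param("f_step must be > 0")
  if (f_max <= f_min) abort_param("f_max must exceed f_min")
  if (wavenumber <= 0) abort_param("wavenumber must be > 0")
  structure(list(f_min = f_min, f_max = f_max, f_step = f_step,
                 wavenumber = wavenumber, edge_sigmas = edge_sigmas),
            class = "spectral_config")
}

config_grid <- function(config) {
  m <- round((config$f_max - config$f_min) / config$f_step) + 1L
  config$f_min + config$f_step * (seq_len(m) - 1L)
}

#' Time-averaged Morlet wavelet power spectrum
#'
#' Convolves one channel with a unit-energy complex Morlet wavelet at each
#' grid frequency, squares the magnitude, discards edge-contaminated samples
#' (see [spectral_config()]), and averages over the retained time points.
#' The convolution is computed in the frequency domain using the analytic
#' Gaussian transfer function of the Morlet wavelet, with zero padding so
#' no circular wrap-around reaches retained samples.
#'
#' Absolute units are arbitrary-but-consistent (unit-energy mother wavelet);
#' every downstream index is a ratio, so only relative power matters.
#'
#' @param signal Numeric vector, one channel's samples in microvolts.
#' @param rate Sampling rate in samples/s.
#' @param config A [spectral_config()].
#' @return A `power_spectrum`: list with `frequencies`, `power`
#'   (nonnegative, same length) and the config used.
#' @export
wavelet_power <- function(signal, rate, config = spectral_config()) {
  if (!is.numeric(signal)) abort_param("signal must be numeric")
  if (!all(is.finite(signal))) abort_param("signal contains non-finite samples")
  n <- length(signal)
  freqs <- config_grid(config)
  sigma_t <- config$wavenumber / (2 * pi * freqs)  # seconds, per frequency
  trim <- ceiling(config$edge_sigmas * sigma_t * rate)
  support <- 2L * trim + 1L
  need <- 2L * max(support)
  if (n < need)
    abort_length(sprintf(
      "signal too short: %d samples, need at least %d (2 x wavelet support at %.2f Hz)",
      n, need, config$f_min))

  pad <- max(trim)                        # keeps wrap-around out of the signal
  L <- stats::nextn(n + 2L * pad, 2)
  X <- stats::fft(c(signal, numeric(L - n)))
  nu <- (seq_len(L) - 1L) / L * rate      # DFT frequencies, 0..rate
  power <- numeric(length(freqs))
  Y <- complex(L)
  for (k in seq_along(freqs)) {
    f <- freqs[k]; st <- sigma_t[k]
    # analytic transfer function of the unit-energy Morlet wavelet
    # (positive-frequency Gaussian only -> analytic signal); evaluated
    # only where it exceeds exp(-40) of its peak
    half_width <- sqrt(40 / (2 * pi^2 * st^2))
    win <- which(abs(nu - f) <= half_width)
    H <- (4 * pi * st^2)^0.25 * exp(-2 * pi^2 * st^2 * (nu[win] - f)^2)
    Y[] <- 0
    Y[win] <- X[win] * H
    w <- stats::fft(Y, inverse = TRUE) / L
    keep <- (trim[k] + 1L):(n - trim[k])
    power[k] <- mean(Mod(w[keep])^2)
  }
  structure(list(frequencies = freqs, power = power, config = config),
            class = "power_spectrum")
}

as_power_spectrum <- function(frequencies, power) {
  if (length(frequencies) != length(power))
    abort_param("frequencies and power must have equal length")
  if (any(power < 0)) abort_param("power must be nonnegative")
  structure(list(frequencies = frequencies, power = power, config = NULL),
            class = "power_spectrum")
}

#' Canonical qEEG band definitions
#'
#' Closed intervals in Hz: delta 1--3, theta 4--7, alpha 8--13, beta 14--20.
#' The gaps between bands (3--4, 7--8, 13--14 Hz) belong to no band.
#' @return Named list of `c(lo, hi)` pairs.
#' @export
qeeg_bands <- function() {
  list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 13), beta = c(14, 20))
}

band_mask <- function(frequencies, band, tol = 1e-6) {
  frequencies >= band[1] - tol & frequencies <= band[2] + tol
}

#' Band and relative band powers
#'
#' Sums spectral power over the grid bins falling in each closed band
#' interval (see [qeeg_bands()]); relative powers divide each band by the
#' four-band total.
#'
#' @param spec A `power_spectrum` whose grid covers 1--20 Hz.
#' @return A list of class `band_powers`: `delta`, `theta`, `alpha`, `beta`
#'   and `relative_delta` ... `relative_beta`.
#' @export
band_powers <- function(spec) {
  f <- spec$frequencies
  if (min(f) > 1 + 1e-6 || max(f) < 20 - 1e-6)
    abort_param("spectrum grid must cover 1-20 Hz for band powers")
  bands <- qeeg_bands()
  sums <- vapply(bands, function(b) sum(spec$power[band_mask(f, b)]), 0)
  total <- sum(sums)
  if (total <= 0)
    abort_degenerate("degenerate spectrum: four-band total power is zero")
  out <- as.list(sums)
  for (nm in names(bands)) out[[paste0("relative_", nm)]] <- sums[[nm]] / total
  structure(out, class = "band_powers")
}

#' Export a set of spectra as a long table
#'
#' @param spectra Named list of `power_spectrum` objects (names = channels).
#' @return A data frame with columns `channel`, `frequency`, `power`.
#' @export
spectra_table <- function(spectra) {
  do.call(rbind, lapply(names(spectra), function(ch) {
    data.frame(channel = ch,
               frequency = spectra[[ch]]$frequencies,
               power = spectra[[ch]]$power)
  }))
}
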