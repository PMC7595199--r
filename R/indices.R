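#' Pairwise-derived brain symmetry index (pdBSI)
#'
#' For each homologous left/right electrode pair and each in-band grid
#' frequency, the normalized spectral asymmetry `|R - L| / (R + L)` is
#' computed; the index is its mean over the M pairs and N in-band
#' frequencies (frequencies where `R + L = 0` are excluded from N).  A value
#' of 0 means perfectly symmetric hemispheres; 1 means power confined to one
#' side at every frequency.
#'
#' The normalized mean is the convention of the original pairwise index (a
#' raw double sum grows without bound in the number of frequency bins);
#' `normalize = FALSE` gives the raw sum for comparison.
#'
#' @param left,right A `power_spectrum` or list of them (homologous pairs in
#'   matching order); grids must be identical.
#' @param band Closed frequency interval `c(lo, hi)` in Hz (default 1--30).
#' @param normalize Divide the double sum by `M * N` (default `TRUE`).
#' @return A list of class `symmetry_result`: `pdbsi`, `per_frequency`
#'   (pair-averaged asymmetry at each in-band frequency), `frequencies`,
#'   `band`, `n_pairs`, `n_freqs`.
#' @export
pdbsi <- function(left, right, band = c(1, 30), normalize = TRUE) {
  if (inherits(left, "power_spectrum")) left <- list(left)
  if (inherits(right, "power_spectrum")) right <- list(right)
  if (length(left) != length(right) || length(left) < 1)
    abort_param("need at least one homologous left/right spectrum pair")
  f <- left[[1]]$frequencies
  for (s in c(left, right))
    if (length(s$frequencies) != length(f) || max(abs(s$frequencies - f)) > 1e-9)
      abort_param("all spectra must share one frequency grid")
  sel <- band_mask(f, band)
  if (!any(sel)) abort_param("no grid frequencies inside the requested band")

  M <- length(left)
  asym <- matrix(NA_real_, sum(sel), M)
  for (j in seq_len(M)) {
    R <- right[[j]]$power[sel]; L <- left[[j]]$power[sel]
    tot <- R + L
    a <- ifelse(tot > 0, abs(R - L) / tot, NA_real_)
    asym[, j] <- a
  }
  vals <- asym[!is.na(asym)]
  if (!length(vals)) abort_degenerate("all in-band frequencies have zero total power")
  total <- sum(vals)
  n_eff <- length(vals)
  structure(list(
    pdbsi = if (normalize) total / n_eff else total,
    per_frequency = rowMeans(asym, na.rm = TRUE),
    frequencies = f[sel], band = band,
    n_pairs = M, n_freqs = n_eff / M,
    normalized = normalize), class = "symmetry_result")
}

#' Low/high frequency split of the pdBSI
#'
#' Splits the 1--30 Hz range at `split` Hz and computes the pdBSI over
#' `[1, split]` and `(split, 30]` separately.  Stroke shifts asymmetry
#' differentially: it tends to rise at low frequencies and fall above
#' roughly 10 Hz, so the two halves carry complementary information.
#'
#' @inheritParams pdbsi
#' @param split Boundary in Hz, strictly inside (1, 30); default 10.
#' @return List with elements `low` and `high`, each a `symmetry_result`.
#' @export
pdbsi_split <- function(left, right, split = 10, normalize = TRUE) {
  if (!is.numeric(split) || length(split) != 1 || split <= 1 || split >= 30)
    abort_param("split frequency must lie strictly inside (1, 30) Hz")
  low <- pdbsi(left, right, band = c(1, split), normalize = normalize)
  # open left endpoint: shift by half a grid step past the split
  if (inherits(left, "power_spectrum")) f <- left$frequencies
  else f <- left[[1]]$frequencies
  step <- min(diff(sort(unique(f))))
  high <- pdbsi(left, right, band = c(split + step / 2, 30),
                normalize = normalize)
  list(low = low, high = high)
}

#' EEG slowing ratios (DAR and DTABR)
#'
#' DAR is summed delta power divided by summed alpha power; DTABR is
#' (delta + theta) / (alpha + beta).  Both rise when ischemia slows the
#' EEG (more low-frequency, less alpha/beta power).
#'
#' @param bp A [band_powers()] result.
#' @param channel_scope Free-text note recording which channel(s) the band
#'   powers came from (e.g. `"contralateral"`); carried through unchanged.
#' @return A list of class `slowing_indices` with `dar`, `dtabr`,
#'   `channel_scope`.
#' @export
slowing <- function(bp, channel_scope = "single") {
  if (bp$alpha <= 0)
    abort_degenerate("degenerate spectrum: alpha power is zero, DAR undefined")
  if (bp$alpha + bp$beta <= 0)
    abort_degenerate("degenerate spectrum: alpha+beta power is zero, DTABR undefined")
  structure(list(dar = bp$delta / bp$alpha,
                 dtabr = (bp$delta + bp$theta) / (bp$alpha + bp$beta),
                 channel_scope = channel_scope),
            class = "slowing_indices")
}

#' Fixed-mode aperiodic (1/f) spectral fit
#'
#' Characterizes the aperiodic background of a power spectrum as
#' `P(f) = 10^intercept * f^(-slope)` by a two-pass robust line fit of
#' `log10(power)` on `log10(f)`:
#'
#' 1. ordinary least squares over all in-range points;
#' 2. refit using only points whose pass-1 residual is negative or at most
#'    the 40th percentile of the positive residuals.
#'
#' Oscillatory peaks sit strictly above the background, so pass 2 discards
#' the most elevated points and recovers the background slope even under
#' strong peak contamination; on a peak-free exact power law both passes
#' coincide and the fit is exact.
#'
#' @param spec A `power_spectrum` with strictly positive power in range.
#' @param fit_range Frequency interval in Hz (default 0.5--30).
#' @return A list of class `aperiodic_fit`: `intercept` (log10 power at
#'   1 Hz), `slope` (positive = decaying), `residual_rms` (log10 units,
#'   pass-2 points), `fit_range`, `n_points`.
#' @export
aperiodic_fit <- function(spec, fit_range = c(0.5, 30)) {
  f <- spec$frequencies
  sel <- band_mask(f, fit_range)
  if (sum(sel) < 10)
    abort_param("need at least 10 grid points inside fit_range")
  p <- spec$power[sel]
  if (any(p <= 0))
    abort_domain("nonpositive power inside fit_range; aperiodic fit needs log power")
  lf <- log10(f[sel]); lp <- log10(p)

  fit1 <- stats::lm.fit(cbind(1, lf), lp)
  res <- fit1$residuals
  pos <- res[res > 0]
  keep <- if (length(pos)) res <= stats::quantile(pos, 0.4) else rep(TRUE, length(res))
  if (sum(keep) < 2) keep <- rep(TRUE, length(res))
  fit2 <- stats::lm.fit(cbind(1, lf[keep]), lp[keep])

  structure(list(intercept = unname(fit2$coefficients[1]),
                 slope = -unname(fit2$coefficients[2]),
                 residual_rms = sqrt(mean(fit2$residuals^2)),
                 fit_range = fit_range,
                 n_points = sum(keep)),
            class = "aperiodic_fit")
}
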