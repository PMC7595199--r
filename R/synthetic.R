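#' Synthesis parameters for the synthetic stroke-EEG cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a 1/f aperiodic EEG background with narrowband oscillations,
#' severity-scaled slowing (delta power boosted, alpha suppressed) applied
#' to the lesioned hemisphere's channels, log-power jitter between
#' homologous channels, and per-axis motion variability that orders with
#' severity (accelerometer X rising, Z falling).
#'
#' Defaults encode an eyes-closed resting state: a 3-minute session at
#' 256 Hz, background exponent 1.5, a prominent 10 Hz alpha rhythm, and
#' delta/alpha power gains of x1/x1.5/x2.5/x4 and x1/x0.8/x0.6/x0.4 across
#' control/small/moderate/large severity.
#'
#' @param seed Integer master seed.
#' @param n_per_group Named counts for control/small/moderate/large.
#' @param duration Session length in seconds (default 180).
#' @param eeg_rate,motion_rate Sampling rates in samples/s (256 and 52).
#' @param background_slope 1/f exponent chi of the aperiodic background.
#' @param background_rms Background RMS amplitude in microvolts.
#' @param band_amplitudes Named oscillation RMS amplitudes (uV) for
#'   delta/theta/alpha/beta, centred at 2/5.5/10/17 Hz with 1 Hz bandwidth.
#' @param severity_gain List with elements `delta` (multiplicative power
#'   boost, monotone non-decreasing over severity) and `alpha` (power
#'   attenuation, monotone non-increasing), each a named vector over the
#'   four severity levels, applied to lesioned-hemisphere channels.
#' @param asymmetry_noise SD of per-channel log-power jitter (homologous
#'   channels draw independent jitters).
#' @param motion_profile List with `accel_sd` and `gyro_sd` (4 x 3 matrices,
#'   severity x axis), `accel_mean` and `gyro_mean` (length-3).
#' @return A list of class `synthesis_params`.
#' @export
synthesis_params <- function(
    seed = 1L,
    n_per_group = c(control = 9, small = 4, moderate = 9, large = 3),
    duration = 180, eeg_rate = 256, motion_rate = 52,
    background_slope = 1.5, background_rms = 8,
    band_amplitudes = c(delta = 4, theta = 3, alpha = 6, beta = 2),
    severity_gain = list(
      delta = c(control = 1, small = 1.5, moderate = 2.5, large = 4),
      alpha = c(control = 1, small = 0.8, moderate = 0.6, large = 0.4)),
    asymmetry_noise = 0.1,
    motion_profile = default_motion_profile()) {
  lv <- severity_levels()
  n_per_group <- n_per_group[lv]
  names(n_per_group) <- lv
  n_per_group[is.na(n_per_group)] <- 0
  if (any(band_amplitudes < 0) || background_rms < 0)
    abort_param("amplitudes must be nonnegative")
  if (any(diff(severity_gain$delta[lv]) < 0))
    abort_param("severity_gain$delta must be monotone non-decreasing")
  if (any(diff(severity_gain$alpha[lv]) > 0))
    abort_param("severity_gain$alpha must be monotone non-increasing")
  if (asymmetry_noise < 0) abort_param("asymmetry_noise must be >= 0")
  if (duration <= 0) abort_param("duration must be positive")
  structure(list(seed = as.integer(seed), n_per_group = n_per_group,
                 duration = duration, eeg_rate = eeg_rate,
                 motion_rate = motion_rate,
                 background_slope = background_slope,
                 background_rms = background_rms,
                 band_amplitudes = band_amplitudes,
                 severity_gain = severity_gain,
                 asymmetry_noise = asymmetry_noise,
                 motion_profile = motion_profile),
            class = "synthesis_params")
}

#' @rdname synthesis_params
#' @export
default_motion_profile <- function() {
  lv <- severity_levels()
  accel_sd <- rbind(control  = c(0.020, 0.030, 0.060),
                    small    = c(0.030, 0.030, 0.045),
                    moderate = c(0.045, 0.030, 0.030),
                    large    = c(0.060, 0.030, 0.020))
  gyro_sd <- matrix(3, 4, 3, dimnames = list(lv, c("X", "Y", "Z")))
  colnames(accel_sd) <- c("X", "Y", "Z")
  list(accel_sd = accel_sd, gyro_sd = gyro_sd,
       accel_mean = c(X = 0, Y = 0, Z = 1), gyro_mean = c(X = 0, Y = 0, Z = 0))
}

band_centers <- function() c(delta = 2, theta = 5.5, alpha = 10, beta = 17)

# FFT-domain amplitude shaping: exact target 1/f exponent.  The scale
# factor is the *expected* RMS (analytic, from the shaping amplitudes),
# not the realization's RMS: normalizing each realization exactly would
# couple every frequency to the (highly variable) low-frequency draw and
# inject a spurious broadband asymmetry between homologous channels.
shaped_noise <- function(n, amp, rms) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  x <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE) / n)
  x * rms / sqrt(sum(amp^2) / n)         # E[mean(x^2)] = rms^2
}

colored_noise <- function(n, rate, chi, rms) {
  nu <- (seq_len(n) - 1) / n * rate
  nu <- pmin(nu, rate - nu)              # |frequency| on the DFT grid
  shaped_noise(n, c(0, nu[-1]^(-chi / 2)), rms)
}

# Narrowband oscillation: white noise shaped by a Gaussian mask
# (FWHM = bw Hz) centred on the band frequency.
narrowband_noise <- function(n, rate, center, bw, rms) {
  nu <- (seq_len(n) - 1) / n * rate
  nu <- pmin(nu, rate - nu)
  sigma <- bw / (2 * sqrt(2 * log(2)))
  shaped_noise(n, exp(-(nu - center)^2 / (2 * sigma^2)), rms)
}

#' Generate one synthetic session recording
#'
#' Each EEG channel is 1/f-filtered Gaussian noise plus narrowband
#' oscillations in the four canonical bands; channels over the lesioned
#' hemisphere receive the severity's delta boost and alpha attenuation
#' (power gains, i.e. sqrt on amplitude).  Motion streams are Gaussian with
#' per-axis mean and SD from the motion profile.  Bit-identical under a
#' fixed seed.
#'
#' @param params A [synthesis_params()] object.
#' @param severity `"control"`, `"small"`, `"moderate"` or `"large"`.
#' @param lateralization `"left"`, `"right"` (strokes) or `"none"`
#'   (controls only).
#' @param seed Integer seed for this recording.
#' @param participant_id Identifier stored in the recording.
#' @return A `qeeg_recording` (eyes-closed).
#' @export
synth_recording <- function(params, severity, lateralization,
                            seed = params$seed, participant_id = "synth") {
  severity <- match.arg(severity, severity_levels())
  lateralization <- match.arg(lateralization, c("left", "right", "none"))
  if ((severity != "control") && lateralization == "none")
    abort_param("stroke severities require a lesion lateralization")
  if (severity == "control" && lateralization != "none")
    abort_param("controls must have lateralization 'none'")

  chans <- muse_channels()
  n <- round(params$duration * params$eeg_rate)
  nm <- round(params$duration * params$motion_rate)
  centers <- band_centers()

  with_seed(seed, {
    eeg <- matrix(0, n, nrow(chans), dimnames = list(NULL, chans$name))
    for (k in seq_len(nrow(chans))) {
      lesioned <- chans$hemisphere[k] == lateralization
      jit <- function() if (params$asymmetry_noise > 0)
        exp(stats::rnorm(1, 0, params$asymmetry_noise) / 2) else 1
      x <- colored_noise(n, params$eeg_rate, params$background_slope,
                         params$background_rms * jit())
      for (b in names(centers)) {
        amp <- params$band_amplitudes[[b]]
        gain <- 1
        if (lesioned && b %in% names(params$severity_gain))
          gain <- params$severity_gain[[b]][[severity]]
        x <- x + narrowband_noise(n, params$eeg_rate, centers[[b]], 1,
                                  amp * sqrt(gain) * jit())
      }
      eeg[, k] <- x
    }
    mp <- params$motion_profile
    accel <- vapply(1:3, function(a)
      stats::rnorm(nm, mp$accel_mean[a], mp$accel_sd[severity, a]),
      numeric(nm))
    gyro <- vapply(1:3, function(a)
      stats::rnorm(nm, mp$gyro_mean[a], mp$gyro_sd[severity, a]),
      numeric(nm))
    colnames(accel) <- colnames(gyro) <- c("X", "Y", "Z")
    new_recording(participant_id, "eyes_closed", eeg, params$eeg_rate,
                  accel, gyro, params$motion_rate,
                  duration = params$duration)
  })
}

#' Expected band powers of the generator (analytic oracle)
#'
#' Returns the expected in-band variance (uV^2) of a generated channel,
#' computed from the generator's own spectral shaping on the DFT grid:
#' the background's 1/f share of each band plus the Gaussian mask share of
#' each oscillation.  Used as an independent oracle for spectral tests.
#'
#' @inheritParams synth_recording
#' @param lesioned Does the channel sit over the lesioned hemisphere?
#' @return Named vector of expected delta/theta/alpha/beta variance.
#' @export
synth_expected_band_powers <- function(params, severity, lesioned = FALSE) {
  n <- round(params$duration * params$eeg_rate)
  nu <- (seq_len(n) - 1) / n * params$eeg_rate
  nu <- pmin(nu, params$eeg_rate - nu)
  bg_psd <- c(0, nu[-1]^(-params$background_slope))
  bg_psd <- bg_psd / sum(bg_psd) * params$background_rms^2
  centers <- band_centers()
  sigma <- 1 / (2 * sqrt(2 * log(2)))
  osc_psd <- lapply(names(centers), function(b) {
    m2 <- exp(-(nu - centers[[b]])^2 / (2 * sigma^2))^2
    gain <- 1
    if (lesioned && b %in% names(params$severity_gain))
      gain <- params$severity_gain[[b]][[severity]]
    m2 / sum(m2) * params$band_amplitudes[[b]]^2 * gain
  })
  total_psd <- bg_psd + Reduce(`+`, osc_psd)
  vapply(qeeg_bands(), function(bd)
    sum(total_psd[nu >= bd[1] - 1e-9 & nu <= bd[2] + 1e-9]), 0)
}

#' Generate a synthetic cohort (manifest + recordings)
#'
#' Samples demographics (ages uniform 19--91, genders balanced across the
#' cohort), lesion lateralization (75% left among strokes, matching the
#' left-hemisphere predominance of typical stroke cohorts), severity-graded
#' clinical scores, and one eyes-closed recording per participant.
#'
#' @param params A [synthesis_params()] object.
#' @return List with `cohort` (a `qeeg_cohort`) and `recordings` (named list
#'   of `qeeg_recording`, by participant id).
#' @export
synth_cohort <- function(params) {
  ntot <- sum(params$n_per_group)
  if (ntot < 1) abort_param("cohort must contain at least one participant")
  lv <- severity_levels()
  sev <- rep(lv, times = params$n_per_group[lv])

  cohort <- with_seed(params$seed, {
    ids <- sprintf("S%02d", seq_len(ntot))
    lat <- ifelse(sev == "control", "none",
                  ifelse(stats::runif(ntot) < 0.75, "left", "right"))
    genders <- sample(rep_len(c("M", "F"), ntot))
    ages <- sample(19:91, ntot, replace = TRUE)
    days <- rep(NA_real_, ntot); nihss <- rep(NA_real_, ntot)
    rng <- list(small = list(d = 0:6, s = 0:8),
                moderate = list(d = 0:8, s = 1:16),
                large = list(d = 2:16, s = 9:14))
    for (i in seq_len(ntot)) if (sev[i] != "control") {
      days[i]  <- sample(rng[[sev[i]]]$d, 1)
      nihss[i] <- sample(rng[[sev[i]]]$s, 1)
    }
    data.frame(id = ids,
               group = ifelse(sev == "control", "control", "stroke"),
               severity = sev, lateralization = lat,
               days_post_onset = days, nihss = nihss,
               gender = genders, age = ages,
               stringsAsFactors = FALSE)
  })
  cohort <- validate_cohort(cohort)

  recordings <- lapply(seq_len(ntot), function(i)
    synth_recording(params, sev[i], cohort$lateralization[i],
                    seed = derive_seed(params$seed, i),
                    participant_id = cohort$id[i]))
  names(recordings) <- cohort$id
  list(cohort = cohort, recordings = recordings)
}
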