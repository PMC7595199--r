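#' Construct a validated session recording
#'
#' A `qeeg_recording` bundles the time-aligned streams captured in one
#' resting-state session: multichannel EEG (microvolts), plus the headband's
#' 3-axis accelerometer (g) and gyroscope (deg/s).  Motion streams share one
#' sampling rate, which may differ from the EEG rate; motion features are
#' rate-invariant statistics so no resampling is done.
#'
#' @param participant_id Participant identifier (single string).
#' @param condition `"eyes_closed"` or `"eyes_open"`.
#' @param eeg Numeric matrix of EEG samples, one row per time point, one
#'   column per channel; column names must be canonical electrode labels
#'   (see [muse_channels()]). `TP9` and `TP10` are required; the frontal
#'   pair is optional (frontal electrodes commonly lose contact).
#' @param eeg_rate EEG sampling rate in samples/s (nominal 256).
#' @param accel,gyro Numeric matrices with 3 columns (X, Y, Z) of
#'   accelerometer (g) and gyroscope (deg/s) samples.
#' @param motion_rate Sampling rate shared by both motion streams.
#' @param duration Session duration in seconds; must be consistent with the
#'   EEG row count to within one sample.
#' @return An object of class `qeeg_recording`.
#' @export
new_recording <- function(participant_id, condition, eeg, eeg_rate,
                          accel, gyro, motion_rate,
                          duration = nrow(eeg) / eeg_rate) {
  rec <- structure(
    list(participant_id = as.character(participant_id),
         condition = condition,
         eeg = eeg, eeg_rate = eeg_rate,
         accel = accel, gyro = gyro, motion_rate = motion_rate,
         duration = duration,
         channels = channel_spec(colnames(eeg))),
    class = "qeeg_recording")
  validate_recording(rec)
}

#' Validate a recording's invariants
#'
#' Checks finiteness of all samples, consistency of duration with the EEG
#' row count (to within one sample), presence of the posterior electrode
#' pair, and the shared motion rate.
#'
#' @param rec A `qeeg_recording`.
#' @return `rec`, invisibly unchanged, or an error describing the violation.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "qeeg_recording"))
    abort_format("not a qeeg_recording")
  if (length(rec$participant_id) != 1L || !nzchar(rec$participant_id))
    abort_format("participant_id must be a single non-empty string")
  if (!rec$condition %in% c("eyes_closed", "eyes_open"))
    abort_format("condition must be 'eyes_closed' or 'eyes_open'")
  if (!is.matrix(rec$eeg) || !is.numeric(rec$eeg))
    abort_format("eeg must be a numeric matrix")
  if (nrow(rec$eeg) == 0L)
    abort_format("recording has no EEG samples")
  for (ch in c("TP9", "TP10"))
    if (!ch %in% colnames(rec$eeg))
      abort_format(sprintf("missing required channel: %s", ch))
  if (!all(is.finite(rec$eeg)))
    abort_format("non-finite EEG samples after validation")
  if (!is.numeric(rec$eeg_rate) || rec$eeg_rate <= 0)
    abort_format("eeg_rate must be positive")
  if (!is.numeric(rec$duration) || rec$duration <= 0)
    abort_format("duration must be positive")
  if (abs(nrow(rec$eeg) - rec$duration * rec$eeg_rate) > 1 + 1e-6)
    abort_format(sprintf(
      "EEG row count %d inconsistent with duration %.3f s at %g Hz",
      nrow(rec$eeg), rec$duration, rec$eeg_rate))
  for (nm in c("accel", "gyro")) {
    m <- rec[[nm]]
    if (!is.matrix(m) || ncol(m) != 3L)
      abort_format(sprintf("%s must be a 3-column matrix", nm))
    if (nrow(m) > 0 && !all(is.finite(m)))
      abort_format(sprintf("non-finite %s samples", nm))
  }
  if (nrow(rec$accel) > 0 || nrow(rec$gyro) > 0) {
    if (!is.numeric(rec$motion_rate) || rec$motion_rate <= 0)
      abort_format("motion_rate must be positive")
  }
  invisible(rec)
}

#' @export
print.qeeg_recording <- function(x, ...) {
  cat(sprintf(
    "qeeg_recording: participant %s, %s, %.1f s\n  EEG: %d x %d (%g Hz): %s\n  motion: %d accel / %d gyro samples at %g Hz\n",
    x$participant_id, x$condition, x$duration,
    nrow(x$eeg), ncol(x$eeg), x$eeg_rate,
    paste(colnames(x$eeg), collapse = ", "),
    nrow(x$accel), nrow(x$gyro), x$motion_rate))
  invisible(x)
}
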