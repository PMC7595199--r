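#' Per-axis head-motion variability statistics
#'
#' Computes, for each axis of a 3-axis motion stream, the root mean square
#' of the raw samples (`sqrt(mean(x^2))`, DC retained so accelerometer RMS
#' keeps the gravity component and therefore posture information) and the
#' population standard deviation (`sqrt(mean((x - mean(x))^2))`).  The two
#' are tied by `rms^2 = sd^2 + mean^2`.
#'
#' @param stream Numeric matrix with one column per axis (>= 2 rows).
#' @param axis_labels Column labels (default `X`, `Y`, `Z`; passed through,
#'   not interpreted).
#' @return A list of class `motion_stats` with named numeric vectors `rms`
#'   and `sd` (one element per axis) and `mean`.
#' @export
motion_stats <- function(stream, axis_labels = colnames(stream) %||% c("X", "Y", "Z")) {
  if (is.null(dim(stream))) stream <- matrix(stream, ncol = 1)
  if (nrow(stream) < 2)
    abort_length("motion stream needs at least 2 samples per axis")
  if (!all(is.finite(stream))) abort_param("non-finite motion samples")
  if (length(axis_labels) != ncol(stream))
    abort_param("axis_labels length must match the number of axes")
  mu  <- colMeans(stream)
  rms <- sqrt(colMeans(stream^2))
  sd_ <- sqrt(colMeans(sweep(stream, 2, mu)^2))
  names(mu) <- names(rms) <- names(sd_) <- axis_labels
  structure(list(rms = rms, sd = sd_, mean = mu), class = "motion_stats")
}

#' Full motion feature block for a recording
#'
#' Applies [motion_stats()] to the accelerometer and gyroscope streams and
#' returns the 12 features (2 sensors x 2 statistics x 3 axes) used as
#' movement predictors.
#'
#' @param rec A `qeeg_recording` with non-empty motion streams.
#' @return Named numeric vector:
#'   `accel_rms_x` ... `gyro_sd_z`.
#' @export
motion_features <- function(rec) {
  a <- motion_stats(rec$accel)
  g <- motion_stats(rec$gyro)
  out <- c(a$rms, a$sd, g$rms, g$sd)
  names(out) <- c(paste0("accel_rms_", c("x", "y", "z")),
                  paste0("accel_sd_",  c("x", "y", "z")),
                  paste0("gyro_rms_",  c("x", "y", "z")),
                  paste0("gyro_sd_",   c("x", "y", "z")))
  out
}
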