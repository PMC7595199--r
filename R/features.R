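#' Names of the per-participant predictor variables
#'
#' The predictor set: 2 demographic, 12 EEG-derived and 12 movement
#' variables.  `gender` is encoded as the binary column `gender_male` in
#' design matrices.
#'
#' @return Character vector of the 26 predictor names in stable order.
#' @export
qeeg_predictors <- function() {
  c("gender_male", "age",
    "pdbsi", "pdbsi_low", "pdbsi_high", "pdbsi_frontal",
    "dar_contra", "dtabr_contra",
    "aperiodic_intercept", "aperiodic_slope",
    "relative_delta", "relative_theta", "relative_alpha", "relative_beta",
    paste0("accel_rms_", c("x", "y", "z")),
    paste0("accel_sd_",  c("x", "y", "z")),
    paste0("gyro_rms_",  c("x", "y", "z")),
    paste0("gyro_sd_",   c("x", "y", "z")))
}

# Posterior channel carrying the lesioned hemisphere's activity.
contra_channel <- function(lateralization) {
  switch(lateralization, left = "TP9", right = "TP10", none = NA_character_)
}

#' Assemble the predictor vector for one participant
#'
#' Runs the full single-participant chain: Morlet spectra for every
#' available channel, symmetry indices (posterior pdBSI, low/high split,
#' frontal pdBSI when the frontal pair is usable), slowing ratios on the
#' lesioned-hemisphere posterior channel (controls: mean of TP9/TP10),
#' the aperiodic fit and relative band powers on the TP9/TP10-averaged
#' spectrum, and the 12 motion statistics.
#'
#' Frontal electrodes commonly lose contact; if either is absent the
#' frontal pdBSI is set to `NA` (later imputed by the cohort median in
#' [build_design_matrix()], with the imputation flagged).
#'
#' @param rec An eyes-closed `qeeg_recording`.
#' @param meta The participant's cohort row (id, severity, lateralization,
#'   gender, age, ...).
#' @param config List of options: `spectral` (a [spectral_config()]),
#'   `split` (low/high pdBSI boundary, default 10 Hz), `normalize`
#'   (pdBSI normalization, default `TRUE`), `fit_range` (aperiodic fit,
#'   default 0.5--30 Hz clamped to the grid).
#' @return One-row data frame: `id`, the predictors of [qeeg_predictors()]
#'   (with `gender` kept categorical), `severity` and `group`.
#' @export
assemble_features <- function(rec, meta, config = list()) {
  validate_recording(rec)
  if (rec$condition != "eyes_closed")
    abort_param("feature extraction is defined for eyes-closed recordings only")
  sc <- config$spectral %||% spectral_config()
  split <- config$split %||% 10
  normalize <- config$normalize %||% TRUE
  fit_range <- config$fit_range %||%
    c(max(sc$f_min, 0.5), min(sc$f_max, 30))

  chans <- colnames(rec$eeg)
  if (!all(c("TP9", "TP10") %in% chans))
    abort_feature("no usable posterior channel pair (TP9/TP10 required)")
  spectra <- lapply(chans, function(ch)
    wavelet_power(rec$eeg[, ch], rec$eeg_rate, sc))
  names(spectra) <- chans

  sym <- pdbsi(spectra$TP9, spectra$TP10, band = c(1, 30),
               normalize = normalize)
  sp <- pdbsi_split(spectra$TP9, spectra$TP10, split = split,
                    normalize = normalize)
  frontal <- if (all(c("AF7", "AF8") %in% chans))
    pdbsi(spectra$AF7, spectra$AF8, band = c(1, 30),
          normalize = normalize)$pdbsi else NA_real_

  post_mean <- as_power_spectrum(
    spectra$TP9$frequencies,
    (spectra$TP9$power + spectra$TP10$power) / 2)
  contra <- contra_channel(meta$lateralization)
  slow <- if (is.na(contra))
    slowing(band_powers(post_mean), "posterior mean (control)")
  else
    slowing(band_powers(spectra[[contra]]), sprintf("contralateral (%s)", contra))

  ap <- aperiodic_fit(post_mean, fit_range = fit_range)
  bp <- band_powers(post_mean)
  mot <- motion_features(rec)

  out <- data.frame(
    id = as.character(meta$id),
    gender = meta$gender, age = as.numeric(meta$age),
    pdbsi = sym$pdbsi, pdbsi_low = sp$low$pdbsi, pdbsi_high = sp$high$pdbsi,
    pdbsi_frontal = frontal,
    dar_contra = slow$dar, dtabr_contra = slow$dtabr,
    aperiodic_intercept = ap$intercept, aperiodic_slope = ap$slope,
    relative_delta = bp$relative_delta, relative_theta = bp$relative_theta,
    relative_alpha = bp$relative_alpha, relative_beta = bp$relative_beta,
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(as.list(mot)))
  out$severity <- as.character(meta$severity)
  out$group <- as.character(meta$group)
  out
}

task_levels <- function(task) {
  switch(task,
         severity = severity_levels(),
         stroke_vs_control = c("control", "stroke"),
         moderate_large_vs_rest = c("rest", "moderate_large"),
         abort_task(sprintf("unknown task: %s", task)))
}

task_label <- function(severity, task) {
  switch(task,
         severity = factor(severity, levels = severity_levels()),
         stroke_vs_control = factor(
           ifelse(severity == "control", "control", "stroke"),
           levels = c("control", "stroke")),
         moderate_large_vs_rest = factor(
           ifelse(severity %in% c("moderate", "large"),
                  "moderate_large", "rest"),
           levels = c("rest", "moderate_large")))
}

#' Build the labeled design matrix for a classification task
#'
#' Assembles (or reuses) the per-participant feature vectors, encodes
#' gender as the binary `gender_male` column, maps severity to the task's
#' labels and imputes missing frontal pdBSI by the cohort median (imputed
#' ids recorded in the `frontal_imputed` attribute).
#'
#' Tasks: `"severity"` (4-class), `"stroke_vs_control"` (positive =
#' stroke), `"moderate_large_vs_rest"` (positive = moderate or large).
#'
#' @param cohort A `qeeg_cohort`.
#' @param recordings Named list of recordings (by participant id); may be
#'   `NULL` when `features` is supplied.
#' @param task One of the three task names.
#' @param config Feature-extraction options, see [assemble_features()].
#' @param features Optional precomputed feature table (rows matched to
#'   `cohort$id`) to skip spectral re-computation.
#' @return Data frame with the 26 predictor columns of [qeeg_predictors()]
#'   plus `id` and `label` (factor); attribute `frontal_imputed` lists ids
#'   whose frontal pdBSI was imputed.
#' @export
build_design_matrix <- function(cohort, recordings = NULL,
                                task = c("severity", "stroke_vs_control",
                                         "moderate_large_vs_rest"),
                                config = list(), features = NULL) {
  task <- match.arg(task)
  if (nrow(cohort) == 0) abort_task("empty cohort")
  if (is.null(features)) {
    if (is.null(recordings)) abort_param("need recordings or features")
    features <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i)
      assemble_features(recordings[[cohort$id[i]]], cohort[i, ], config)))
  }
  features <- features[match(cohort$id, features$id), , drop = FALSE]
  if (anyNA(features$id)) abort_param("features missing for some cohort ids")

  label <- task_label(as.character(cohort$severity), task)
  if (length(unique(stats::na.omit(label))) < 2)
    abort_task(sprintf("task '%s' needs at least 2 classes in the cohort", task))

  df <- features
  df$gender_male <- as.numeric(df$gender == "M")
  imputed <- character(0)
  if (anyNA(df$pdbsi_frontal)) {
    med <- stats::median(df$pdbsi_frontal, na.rm = TRUE)
    if (is.na(med)) med <- stats::median(df$pdbsi, na.rm = TRUE)
    imputed <- df$id[is.na(df$pdbsi_frontal)]
    df$pdbsi_frontal[is.na(df$pdbsi_frontal)] <- med
  }
  out <- df[, c("id", qeeg_predictors())]
  out$label <- label
  if (!all(is.finite(as.matrix(out[qeeg_predictors()]))))
    abort_feature("non-finite predictor values in design matrix")
  attr(out, "task") <- task
  attr(out, "frontal_imputed") <- imputed
  out
}
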