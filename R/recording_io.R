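#' Read a session recording
#'
#' Reads one resting-state session (EEG + accelerometer + gyroscope) from
#' disk and returns a validated [new_recording()] object.  Two formats are
#' supported:
#'
#' * `"delimited"` — a directory in the MuseLSL CSV layout: `EEG.csv`,
#'   `ACC.csv` and `GYRO.csv`, each with a leading `timestamps` column
#'   (seconds) followed by the channel/axis columns, plus a `meta.json`
#'   carrying participant id, condition and nominal rates.
#' * `"edf"` — a single 16-bit EDF file (see [write_session()]).
#'
#' Timestamp cleanup is deterministic: duplicated timestamps keep the first
#' sample; jittered timestamps are linearly interpolated onto the nominal
#' sampling grid provided every gap is shorter than 50 ms; a longer gap is
#' treated as a dropped-connection artifact and the recording is rejected
#' with an integrity error (sessions with connectivity dropouts are not
#' analysable).  Non-monotone timestamps beyond half a sample period are an
#' integrity error.
#'
#' @param path Directory (delimited) or `.edf` file.
#' @param format `"delimited"` or `"edf"`; by default inferred from `path`.
#' @return A `qeeg_recording`.
#' @seealso [write_session()], [read_cohort()]
#' @export
read_session <- function(path, format = c("auto", "delimited", "edf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") return(read_session_edf(path))
  read_session_delimited(path)
}

#' Write a session recording
#'
#' Writes a recording so that [read_session()] recovers it: value-identical
#' samples for the delimited format, and identical up to one 16-bit
#' quantization step for EDF.
#'
#' @param rec A validated `qeeg_recording`.
#' @param path Target directory (delimited) or `.edf` file path.
#' @param format `"delimited"` or `"edf"`; inferred from `path` by default.
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path, format = c("auto", "delimited", "edf")) {
  validate_recording(rec)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") return(invisible(write_session_edf(rec, path)))
  invisible(write_session_delimited(rec, path))
}

# ---- delimited (MuseLSL CSV layout) ---------------------------------------

read_session_delimited <- function(path) {
  if (!dir.exists(path))
    abort_io(sprintf("session directory not found: %s", path))
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path))
    abort_format("delimited session is missing meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)

  eeg_path <- file.path(path, "EEG.csv")
  if (!file.exists(eeg_path)) abort_format("delimited session is missing EEG.csv")
  eeg_raw <- utils::read.csv(eeg_path, check.names = FALSE)
  labs <- canonical_channel(names(eeg_raw)[-1])
  names(eeg_raw)[-1] <- ifelse(is.na(labs), names(eeg_raw)[-1], labs)
  for (ch in c("TP9", "TP10"))
    if (!ch %in% names(eeg_raw))
      abort_format(sprintf("missing required channel: %s", ch))
  keep <- intersect(muse_channels()$name, names(eeg_raw))
  eeg <- clean_stream(eeg_raw[[1]], as.matrix(eeg_raw[keep]), meta$eeg_rate)

  read_motion <- function(fname) {
    p <- file.path(path, fname)
    if (!file.exists(p))
      return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("X", "Y", "Z"))))
    d <- utils::read.csv(p, check.names = FALSE)
    m <- clean_stream(d[[1]], as.matrix(d[-1]), meta$motion_rate)
    colnames(m) <- c("X", "Y", "Z")
    m
  }
  accel <- read_motion("ACC.csv")
  gyro  <- read_motion("GYRO.csv")

  new_recording(meta$participant_id, meta$condition, eeg, meta$eeg_rate,
                accel, gyro, meta$motion_rate %||% meta$eeg_rate,
                duration = nrow(eeg) / meta$eeg_rate)
}

# full-precision CSV so text round trips are value-identical
write_csv17 <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_session_delimited <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) abort_io(sprintf("cannot create directory: %s", path))
  ts <- (seq_len(nrow(rec$eeg)) - 1L) / rec$eeg_rate
  write_csv17(data.frame(timestamps = ts, rec$eeg, check.names = FALSE),
              file.path(path, "EEG.csv"))
  wm <- function(m, fname) {
    if (nrow(m) == 0) return(invisible())
    tm <- (seq_len(nrow(m)) - 1L) / rec$motion_rate
    write_csv17(data.frame(timestamps = tm, m, check.names = FALSE),
                file.path(path, fname))
  }
  wm(rec$accel, "ACC.csv")
  wm(rec$gyro, "GYRO.csv")
  jsonlite::write_json(
    list(participant_id = rec$participant_id, condition = rec$condition,
         eeg_rate = rec$eeg_rate, motion_rate = rec$motion_rate,
         duration = rec$duration),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  path
}

# Deterministic timestamp cleanup: keep-first on duplicates, reject
# non-monotone streams and gaps >= 50 ms, then linear interpolation onto
# the nominal grid (skipped when timestamps already sit on it).
clean_stream <- function(ts, x, rate) {
  ts <- as.numeric(ts)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (length(ts) != nrow(x)) abort_format("timestamp column length mismatch")
  if (length(ts) == 0) abort_format("empty stream")
  half <- 0.5 / rate
  d <- diff(ts)
  if (any(d < -half))
    abort_integrity("non-monotone timestamps beyond tolerance")
  dup <- c(FALSE, d < half)            # keep-first
  ts <- ts[!dup]; x <- x[!dup, , drop = FALSE]
  if (length(ts) > 1) {
    d <- diff(ts)
    if (any(d > 1 / rate + 0.050))
      abort_integrity(sprintf(
        "timestamp gap of %.3f s exceeds the 50 ms interpolation limit",
        max(d)))
    grid <- ts[1] + (0:round((ts[length(ts)] - ts[1]) * rate)) / rate
    if (length(grid) != length(ts) || max(abs(grid - ts)) > 1e-9) {
      x <- apply(x, 2, function(col)
        stats::approx(ts, col, xout = grid, rule = 2)$y)
      if (is.null(dim(x))) x <- matrix(x, ncol = 1)
    }
  }
  x
}

# ---- cohort manifest -------------------------------------------------------

severity_levels <- function() c("control", "small", "moderate", "large")

#' Read a cohort manifest
#'
#' The manifest is a delimited text table with one row per participant and
#' columns `id`, `group` (`stroke`/`control`), `severity`
#' (`control`/`small`/`moderate`/`large`), `lateralization`
#' (`left`/`right`/`none`), `days_post_onset`, `nihss`, `gender` (`M`/`F`)
#' and `age`.  Consistency is enforced: `severity == "control"` and
#' `lateralization == "none"` exactly for control rows; ids unique;
#' `days_post_onset` and `nihss` must be absent (NA) for controls.
#'
#' @param path Path to the delimited manifest.
#' @return A `data.frame` of class `qeeg_cohort`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("manifest not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' Validate (and type) a cohort table
#'
#' @param df A data frame with the manifest columns of [read_cohort()].
#' @return The validated `qeeg_cohort` data frame.
#' @export
validate_cohort <- function(df) {
  req <- c("id", "group", "severity", "lateralization", "days_post_onset",
           "nihss", "gender", "age")
  miss <- setdiff(req, names(df))
  if (length(miss))
    abort_format(sprintf("manifest missing column(s): %s",
                         paste(miss, collapse = ", ")))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    abort_format("duplicate participant id in manifest")
  if (!all(df$group %in% c("stroke", "control")))
    abort_format("group must be 'stroke' or 'control'")
  if (!all(df$severity %in% severity_levels()))
    abort_format("invalid severity level")
  if (!all(df$lateralization %in% c("left", "right", "none")))
    abort_format("invalid lateralization")
  if (!all(df$gender %in% c("M", "F")))
    abort_format("gender must be 'M' or 'F'")
  bad <- (df$severity == "control") != (df$group == "control")
  if (any(bad))
    abort_integrity(sprintf(
      "severity/group inconsistency for id(s): %s",
      paste(df$id[bad], collapse = ", ")))
  bad <- (df$lateralization == "none") != (df$group == "control")
  if (any(bad))
    abort_integrity(sprintf(
      "lateralization must be 'none' exactly for controls (id(s): %s)",
      paste(df$id[bad], collapse = ", ")))
  ctrl <- df$group == "control"
  if (any(!is.na(df$days_post_onset[ctrl])) || any(!is.na(df$nihss[ctrl])))
    abort_integrity("controls cannot carry days_post_onset or nihss")
  df$severity <- factor(df$severity, levels = severity_levels())
  class(df) <- c("qeeg_cohort", "data.frame")
  df
}

#' Write a cohort manifest
#'
#' @param cohort A `qeeg_cohort` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  df$severity <- as.character(df$severity)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
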