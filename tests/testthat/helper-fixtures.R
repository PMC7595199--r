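# Shared fixture builders.  All fixtures are generated in code; recordings
# used in tests are kept short (seconds, not minutes) to stay inside the
# suite's time budget -- the generator's statistical structure does not
# depend on duration.

# Tiny deterministic recording without going through the synthesizer.
tiny_recording <- function(n = 512, rate = 256,
                           channels = c("TP9", "AF7", "AF8", "TP10"),
                           motion_rate = 52, seed = 1,
                           motion_n = round(n / rate * motion_rate)) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    eeg <- matrix(rnorm(n * length(channels)), n,
                  dimnames = list(NULL, channels))
    accel <- matrix(rnorm(motion_n * 3, mean = rep(c(0, 0, 1), each = motion_n),
                          sd = 0.05), motion_n,
                    dimnames = list(NULL, c("X", "Y", "Z")))
    gyro <- matrix(rnorm(motion_n * 3, sd = 3), motion_n,
                   dimnames = list(NULL, c("X", "Y", "Z")))
    new_recording("T01", "eyes_closed", eeg, rate, accel, gyro, motion_rate)
  })
}

# Hand-written delimited session directory (for parser edge cases).
write_raw_session <- function(dir, ts, eeg_cols, rate = 256,
                              meta = list(participant_id = "T01",
                                          condition = "eyes_closed",
                                          eeg_rate = rate,
                                          motion_rate = rate)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(timestamps = ts, eeg_cols, check.names = FALSE)
  utils::write.csv(df, file.path(dir, "EEG.csv"), row.names = FALSE)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  dir
}

fixture_path <- function(name)
  system.file("extdata", name, package = "qeegstroke")

short_spectral <- function() spectral_config(f_min = 1, f_max = 21)
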