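# Minimal EDF (European Data Format, 16-bit) codec for headband sessions.
#
# Layout written: one data record per second; signals are the EEG channels
# (uV), then ACC X/Y/Z (g), then GYRO X/Y/Z (deg/s).  Sampling rates must
# therefore be integer Hz.  The last record is padded by repeating the final
# sample; the true duration is stashed in the 44-byte reserved header field
# ("DUR <seconds>") so reads trim the padding away exactly.
#
# Quantization: physical min/max are taken from the data, serialized to the
# 8-character ASCII header fields, and the *serialized* values are used for
# digitization, so a write/read round trip is exact to one quantization step
# of (phys_max - phys_min) / 65535.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = 1)
  edf_pad(s, width)
}

write_session_edf <- function(rec, path) {
  if (rec$eeg_rate %% 1 != 0)
    abort_param("EDF export requires an integer EEG sampling rate")
  has_motion <- nrow(rec$accel) > 0 || nrow(rec$gyro) > 0
  if (has_motion && rec$motion_rate %% 1 != 0)
    abort_param("EDF export requires an integer motion sampling rate")

  sigs <- list()
  for (ch in colnames(rec$eeg))
    sigs[[paste("EEG", ch)]] <-
      list(x = rec$eeg[, ch], rate = rec$eeg_rate, dim = "uV")
  if (nrow(rec$accel) > 0)
    for (ax in c("X", "Y", "Z"))
      sigs[[paste("ACC", ax)]] <-
        list(x = rec$accel[, ax], rate = rec$motion_rate, dim = "g")
  if (nrow(rec$gyro) > 0)
    for (ax in c("X", "Y", "Z"))
      sigs[[paste("GYRO", ax)]] <-
        list(x = rec$gyro[, ax], rate = rec$motion_rate, dim = "deg/s")

  ns <- length(sigs)
  n_records <- max(1L, as.integer(ceiling(
    max(vapply(sigs, function(s) length(s$x) / s$rate, 0)))))

  # serialized physical range, re-parsed so writer and reader agree exactly
  for (i in seq_along(sigs)) {
    x <- sigs[[i]]$x
    pmin <- min(x); pmax <- max(x)
    if (pmax <= pmin) { pmin <- pmin - 1; pmax <- pmax + 1 }
    span <- pmax - pmin
    pmin_s <- edf_num(pmin - 0.005 * span); pmax_s <- edf_num(pmax + 0.005 * span)
    sigs[[i]]$pmin <- as.numeric(pmin_s); sigs[[i]]$pmax <- as.numeric(pmax_s)
    sigs[[i]]$pmin_s <- pmin_s; sigs[[i]]$pmax_s <- pmax_s
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$participant_id, 80),
    edf_pad(rec$condition, 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad(sprintf("DUR %.6f", rec$duration), 44),
    edf_pad(n_records, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4),
    paste(vapply(names(sigs), edf_pad, "", width = 16), collapse = ""),
    paste(vapply(sigs, function(s) edf_pad("", 80), ""), collapse = ""),
    paste(vapply(sigs, function(s) edf_pad(s$dim, 8), ""), collapse = ""),
    paste(vapply(sigs, function(s) s$pmin_s, ""), collapse = ""),
    paste(vapply(sigs, function(s) s$pmax_s, ""), collapse = ""),
    paste(vapply(sigs, function(s) edf_pad(-32768, 8), ""), collapse = ""),
    paste(vapply(sigs, function(s) edf_pad(32767, 8), ""), collapse = ""),
    paste(vapply(sigs, function(s) edf_pad("", 80), ""), collapse = ""),
    paste(vapply(sigs, function(s) edf_pad(s$rate, 8), ""), collapse = ""),
    paste(vapply(sigs, function(s) edf_pad("", 32), ""), collapse = ""))
  writeBin(charToRaw(hdr), con)

  dig <- lapply(sigs, function(s) {
    need <- n_records * s$rate
    x <- s$x
    if (length(x) < need) x <- c(x, rep(x[length(x)], need - length(x)))
    v <- round(-32768 + (x - s$pmin) * 65535 / (s$pmax - s$pmin))
    as.integer(pmin(pmax(v, -32768), 32767))
  })
  for (r in seq_len(n_records))
    for (i in seq_along(sigs)) {
      spr <- sigs[[i]]$rate
      writeBin(dig[[i]][((r - 1) * spr + 1):(r * spr)], con,
               size = 2, endian = "little")
    }
  path
}

read_session_edf <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("EDF file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  num <- function(s) as.numeric(trimws(s))

  rd(8)                                   # version
  pid <- trimws(rd(80))
  condition <- trimws(rd(80))
  rd(16)                                  # date + time
  rd(8)                                   # header bytes
  reserved <- trimws(rd(44))
  n_records <- num(rd(8))
  rec_dur <- num(rd(8))
  ns <- as.integer(num(rd(4)))
  if (is.na(ns) || ns < 1) abort_format("invalid EDF header: signal count")

  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "")   # transducer
  vapply(seq_len(ns), function(i) rd(8), "")    # dimension
  pmin <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) num(rd(8)), 0)
  vapply(seq_len(ns), function(i) rd(80), "")   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(num(rd(8))), 0L)
  vapply(seq_len(ns), function(i) rd(32), "")   # per-signal reserved

  data <- lapply(seq_len(ns), function(i) numeric(n_records * spr[i]))
  for (r in seq_len(n_records))
    for (i in seq_len(ns)) {
      v <- readBin(con, integer(), spr[i], size = 2, endian = "little",
                   signed = TRUE)
      data[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin[i] + (v - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }

  duration <- n_records * rec_dur
  m <- regmatches(reserved, regexec("DUR ([0-9.]+)", reserved))[[1]]
  if (length(m) == 2) duration <- as.numeric(m[2])

  is_eeg  <- startsWith(labels, "EEG ")
  is_acc  <- startsWith(labels, "ACC ")
  is_gyro <- startsWith(labels, "GYRO ")
  if (!any(is_eeg)) abort_format("EDF file contains no EEG signals")
  eeg_rate <- spr[which(is_eeg)[1]] / rec_dur
  eeg_chans <- canonical_channel(sub("^EEG ", "", labels[is_eeg]))
  for (ch in c("TP9", "TP10"))
    if (!ch %in% eeg_chans) abort_format(sprintf("missing required channel: %s", ch))
  n_eeg <- round(duration * eeg_rate)
  eeg <- vapply(which(is_eeg), function(i) data[[i]][seq_len(n_eeg)],
                numeric(n_eeg))
  colnames(eeg) <- eeg_chans

  grab3 <- function(sel, prefix) {
    if (!any(sel))
      return(list(m = matrix(numeric(0), 0, 3,
                             dimnames = list(NULL, c("X", "Y", "Z"))),
                  rate = NA_real_))
    rate <- spr[which(sel)[1]] / rec_dur
    n <- round(duration * rate)
    m <- vapply(c("X", "Y", "Z"), function(ax) {
      i <- which(labels == paste(prefix, ax))
      data[[i]][seq_len(n)]
    }, numeric(n))
    list(m = m, rate = rate)
  }
  acc <- grab3(is_acc, "ACC")
  gyr <- grab3(is_gyro, "GYRO")
  motion_rate <- acc$rate
  if (is.na(motion_rate)) motion_rate <- gyr$rate
  if (is.na(motion_rate)) motion_rate <- eeg_rate

  new_recording(pid, condition, eeg, eeg_rate, acc$m, gyr$m, motion_rate,
                duration = n_eeg / eeg_rate)
}
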