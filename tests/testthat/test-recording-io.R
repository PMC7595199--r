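test_that("delimited sessions parse, round-trip and validate", {
  # 3-row fixture with 4 EEG columns at 256 Hz
  d <- write_raw_session(tempfile(), ts = (0:2) / 256,
                         eeg_cols = data.frame(TP9 = 1:3, AF7 = 4:6,
                                               AF8 = 7:9, TP10 = 10:12))
  rec <- read_session(d)
  expect_s3_class(rec, "qeeg_recording")
  expect_equal(nrow(rec$eeg), 3)
  expect_equal(ncol(rec$eeg), 4)
  expect_equal(unname(rec$eeg[, "TP10"]), c(10, 11, 12))

  # write o read is the identity on samples and metadata
  rec2 <- tiny_recording()
  d2 <- tempfile()
  write_session(rec2, d2)
  back <- read_session(d2)
  expect_identical(back$eeg, rec2$eeg)
  expect_identical(back$accel, rec2$accel)
  expect_identical(back$gyro, rec2$gyro)
  expect_equal(back$eeg_rate, rec2$eeg_rate)
  expect_equal(back$participant_id, rec2$participant_id)

  # missing required channel named in the error
  d3 <- write_raw_session(tempfile(), ts = (0:2) / 256,
                          eeg_cols = data.frame(TP9 = 1:3, AF7 = 4:6,
                                                AF8 = 7:9))
  expect_error(read_session(d3), "TP10", class = "qeeg_format_error")
})

test_that("vendor channel aliases are canonicalised on input", {
  d <- write_raw_session(tempfile(), ts = (0:2) / 256,
                         eeg_cols = stats::setNames(
                           data.frame(1:3, 4:6, 7:9, 10:12),
                           c("T9", "A7", "A8", "T10")))
  rec <- read_session(d)
  expect_setequal(colnames(rec$eeg), c("TP9", "AF7", "AF8", "TP10"))
})

test_that("timestamp cleanup is deterministic and bounded", {
  base <- data.frame(TP9 = rnorm(10), AF7 = rnorm(10), AF8 = rnorm(10),
                     TP10 = rnorm(10))
  # duplicated timestamp: keep-first, then the < 50 ms hole is filled by
  # linear interpolation back onto the nominal grid
  ts <- (0:9) / 256
  ts[5] <- ts[4]
  d <- write_raw_session(tempfile(), ts, base)
  rec <- read_session(d)
  expect_equal(nrow(rec$eeg), 10)
  expect_equal(rec$eeg[4, "TP9"], base$TP9[4], ignore_attr = TRUE)  # kept first
  expect_equal(rec$eeg[5, "TP9"], (base$TP9[4] + base$TP9[6]) / 2,
               ignore_attr = TRUE)                                  # refilled

  # jitter below 50 ms: interpolated back onto the grid, same row count
  set.seed(2)
  ts2 <- (0:9) / 256 + runif(10, 0, 0.3 / 256)
  d2 <- write_raw_session(tempfile(), ts2, base)
  expect_equal(nrow(read_session(d2)$eeg), 10)

  # gap >= 50 ms: integrity error
  ts3 <- (0:9) / 256
  ts3[6:10] <- ts3[6:10] + 0.08
  d3 <- write_raw_session(tempfile(), ts3, base)
  expect_error(read_session(d3), "gap", class = "qeeg_integrity_error")

  # non-monotone beyond tolerance: integrity error
  ts4 <- (0:9) / 256
  ts4[5] <- ts4[5] - 0.01
  d4 <- write_raw_session(tempfile(), ts4, base)
  expect_error(read_session(d4), class = "qeeg_integrity_error")
})

test_that("EDF round trip is exact to one quantization step", {
  rec <- tiny_recording(n = 1024, seed = 3)
  path <- tempfile(fileext = ".edf")
  write_session(rec, path)
  back <- read_session(path)
  expect_equal(colnames(back$eeg), colnames(rec$eeg))
  expect_equal(back$participant_id, rec$participant_id)
  expect_equal(back$condition, rec$condition)
  expect_equal(nrow(back$eeg), nrow(rec$eeg))
  for (ch in colnames(rec$eeg)) {
    step <- (max(rec$eeg[, ch]) - min(rec$eeg[, ch])) * 1.01 / 65535
    expect_lt(max(abs(back$eeg[, ch] - rec$eeg[, ch])), step)
  }
  step_a <- (max(rec$accel) - min(rec$accel)) * 1.01 / 65535
  expect_lt(max(abs(back$accel - rec$accel)), step_a)

  # 180 s at 256 Hz -> 46080 rows on re-read
  long <- new_recording(
    "T02", "eyes_closed",
    matrix(rnorm(46080 * 2), 46080, dimnames = list(NULL, c("TP9", "TP10"))),
    256,
    matrix(rnorm(180 * 52 * 3), 180 * 52, dimnames = list(NULL, c("X", "Y", "Z"))),
    matrix(rnorm(180 * 52 * 3), 180 * 52, dimnames = list(NULL, c("X", "Y", "Z"))),
    52)
  p2 <- tempfile(fileext = ".edf")
  write_session(long, p2)
  expect_equal(nrow(read_session(p2)$eeg), 46080)
})

test_that("empty or invalid recordings are refused", {
  expect_error(
    new_recording("X", "eyes_closed",
                  matrix(numeric(0), 0, 2, dimnames = list(NULL, c("TP9", "TP10"))),
                  256,
                  matrix(numeric(0), 0, 3), matrix(numeric(0), 0, 3), 52,
                  duration = 1),
    class = "qeeg_format_error")
  bad <- tiny_recording()
  bad$eeg[3, 1] <- NA
  expect_error(validate_recording(bad), "non-finite",
               class = "qeeg_format_error")
})

test_that("cohort manifests parse, type and validate", {
  co <- read_cohort(fixture_path("example_cohort.csv"))
  expect_s3_class(co, "qeeg_cohort")
  expect_equal(nrow(co), 25)
  expect_equal(sum(co$group == "stroke"), 16)
  expect_equal(sum(co$group == "control"), 9)
  expect_equal(as.integer(table(co$severity)), c(9L, 4L, 9L, 3L))

  # round trip
  p <- tempfile(fileext = ".csv")
  write_cohort(co, p)
  expect_equal(as.data.frame(read_cohort(p)), as.data.frame(co))

  # single-control manifest
  one <- co[co$id == "1", ]
  write_cohort(one, p)
  expect_equal(nrow(read_cohort(p)), 1)

  # duplicate id
  dup <- rbind(co, co[1, ])
  expect_error(validate_cohort(as.data.frame(dup)), "duplicate",
               class = "qeeg_format_error")

  # stroke row with severity = control -> consistency error
  bad <- as.data.frame(co)
  bad$severity <- as.character(bad$severity)
  bad$severity[bad$id == "2"] <- "control"
  expect_error(validate_cohort(bad), class = "qeeg_integrity_error")
})
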