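test_that("eeg_record validates its fields", {
  r <- eeg_record(sin(1:256), 128, subject_id = "s1", channel = "Fp1-A1")
  expect_s3_class(r, "eeg_record")
  expect_equal(duration(r), 2)
  expect_error(eeg_record(c(1, NA), 128), "finite")
  expect_error(eeg_record(1:10, -1), "positive")
  expect_error(eeg_record(1:10, c(128, 500)), "positive")
})

test_that("channel matching is case-insensitive and separator-tolerant", {
  expect_equal(match_channel(c("Fp1-A1", "FP1A1", "fp1_a1", "EEG Fp2-A2", "Cz")),
               c("Fp1-A1", "Fp1-A1", "Fp1-A1", "Fp2-A2", NA))
})

test_that("EDF round-trips both channels within amplitude quantization", {
  recs <- list(
    simulate_eeg(sampling_rate = 128, duration = 10, slowing = 0.3,
                 artifact_rates = c(), seed = 11, subject_id = "edf1"),
    simulate_eeg(sampling_rate = 128, duration = 10, slowing = 0.8,
                 artifact_rates = c(), seed = 12, subject_id = "edf1",
                 channel = "Fp2-A2"))
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(recs, path)
  back <- read_edf(path)
  expect_length(back, 2)
  expect_equal(vapply(back, `[[`, character(1), "channel"),
               c("Fp1-A1", "Fp2-A2"))
  for (i in 1:2) {
    expect_equal(back[[i]]$sampling_rate, 128)  # header passthrough, no resampling
    quant <- max(abs(recs[[i]]$samples)) / 32767 * 1.01
    expect_lt(max(abs(back[[i]]$samples - recs[[i]]$samples)), quant)
  }
})

test_that("EDF sampling rate is taken from the header for a 500 Hz device", {
  rec <- simulate_eeg(sampling_rate = 500, duration = 2, artifact_rates = c(),
                      seed = 3)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_equal(read_edf(path)[[1]]$sampling_rate, 500)
})

test_that("EDF reader reports missing channels and corrupt files", {
  rec <- simulate_eeg(duration = 2, seed = 1, channel = "Cz",
                      artifact_rates = c())
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_error(read_edf(path), "channel not found.*Cz")
  expect_error(read_edf(file.path(tempdir(), "nope.edf")), "cannot read")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeLines("not an edf file", bad)
  expect_error(read_edf(bad), "corrupt")
})

test_that("signal CSV round-trips exactly and checks its dialect", {
  recs <- list(
    simulate_eeg(duration = 2, seed = 5, artifact_rates = c()),
    simulate_eeg(duration = 2, seed = 6, artifact_rates = c(),
                 channel = "Fp2-A2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_csv_signal(recs, path)
  back <- read_csv_signal(path, sampling_rate = 128)
  expect_length(back, 2)
  expect_identical(back[[1]]$samples, recs[[1]]$samples)  # exact round-trip
  expect_identical(back[[2]]$samples, recs[[2]]$samples)
  expect_equal(back[[1]]$channel, "Fp1-A1")
  # sampling rate inferred from time_s when not given
  inferred <- read_csv_signal(path)
  expect_equal(inferred[[1]]$sampling_rate, 128)
  expect_equal(length(inferred[[1]]$samples) / inferred[[1]]$sampling_rate, 2)
})

test_that("signal CSV reader rejects bad input with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,Fp1-A1", "0,1.5", "0.0078125,oops", "0.015625,2"), path)
  expect_error(read_csv_signal(path, 128), "row 2.*oops")
  empty <- withr::local_tempfile(fileext = ".csv")
  file.create(empty)
  expect_error(read_csv_signal(empty, 128), "format error|no lines")
  noheader <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), noheader)
  expect_error(read_csv_signal(noheader, 128), "format error")
})

test_that("score tables round-trip with empty cells for missing values", {
  tab <- data.frame(
    subject_id = sprintf("S%02d", 1:10),
    channel = rep(c("Fp1-A1", "Fp2-A2"), 5),
    delirium_label = c(rep(c(0L, 1L), 4), NA, NA),
    bseeg_score = c(rnorm(9), NA),
    tda_score = c(NA, rnorm(9)),
    n_windows_total = rep(45L, 10),
    n_windows_passed = c(40L, 0L, rep(38L, 8)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(tab, path)
  raw <- readLines(path)
  expect_false(any(grepl("NA|NaN", raw)))   # dialect: empty cells, never text
  back <- read_scores(path)
  expect_equal(back, tab)
  # header-only file for an empty table
  write_scores(tab[0, ], path)
  expect_length(readLines(path), 1L)
  expect_equal(nrow(read_scores(path)), 0L)
})

test_that("score writer enforces window-count consistency", {
  tab <- data.frame(subject_id = "a", channel = "Fp1-A1",
                    delirium_label = 1L, bseeg_score = 0.2, tda_score = 0.1,
                    n_windows_total = 10L, n_windows_passed = 12L)
  expect_error(write_scores(tab, tempfile()), "exceed")
  expect_error(write_scores(tab[, 1:4], tempfile()), "lacks columns")
})
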