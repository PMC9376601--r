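test_that("a 7-column CSV round-trips through read_recording unchanged", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_phone_csv(path, n = 6000, rate = 100, seed = 11)
  rec <- read_recording(path, dialect = "phone", subject_id = "t1")
  expect_s3_class(rec, "tremor_recording")
  expect_equal(rec$rate, 100)
  expect_length(rec$channels, 6)
  for (ch in names(rec$channels)) {
    expect_length(rec$channels[[ch]], 6000)
    expect_equal(as.numeric(rec$channels[[ch]]), df[[ch]])
  }
  out <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, out, dialect = "phone")
  rec2 <- read_recording(out, dialect = "phone")
  for (ch in names(rec$channels))
    expect_equal(as.numeric(rec2$channels[[ch]]),
                 as.numeric(rec$channels[[ch]]))
})

test_that("lpms dialect converts deg/s to rad/s exactly once", {
  path <- withr::local_tempfile(fileext = ".csv")
  n <- 1700
  df <- data.frame(TimeStamp = (0:(n - 1)) / 100)
  for (cc in c("AccX", "AccY", "AccZ")) df[[cc]] <- 0.5
  for (cc in c("GyroX", "GyroY", "GyroZ")) df[[cc]] <- 180 / pi  # 1 rad/s
  write.csv(df, path, row.names = FALSE)
  rec <- read_recording(path, dialect = "lpms")
  expect_equal(unique(as.numeric(rec$channels$av_z)), 1.0, tolerance = 1e-12)
  expect_equal(attr(rec$channels$av_z, "unit"), "rad/s")
  expect_equal(unique(as.numeric(rec$channels$la_x)), 0.5)
  # write + re-read in the same dialect must not convert a second time
  out <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, out, dialect = "lpms")
  rec2 <- read_recording(out, dialect = "lpms")
  expect_equal(unique(as.numeric(rec2$channels$av_z)), 1.0, tolerance = 1e-12)
})

test_that("format and data errors name the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_phone_csv(path, n = 1700)
  df$av_z <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "missing channel av_z",
               class = "tremorsense_format_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  df2 <- write_phone_csv(path2, n = 1700)
  df2$t[100] <- df2$t[99]          # non-monotonic timestamp
  write.csv(df2, path2, row.names = FALSE)
  expect_tremor_error(read_recording(path2), "data")

  expect_tremor_error(read_recording(withr::local_tempfile()), "format")
})

test_that("recording constructor enforces the pipeline contract", {
  ch <- function(n) setNames(lapply(1:6, function(i) rnorm(n)),
                             c("la_x","la_y","la_z","av_x","av_y","av_z"))
  expect_tremor_error(recording(ch(100), rate = 100), "data")      # < 16 s
  expect_tremor_error(recording(ch(2000), rate = 20), "parameter") # rate
  bad <- ch(2000); bad$la_x <- bad$la_x[1:100]
  expect_tremor_error(recording(bad, rate = 100), "data")
  expect_s3_class(recording(ch(1600), rate = 100), "tremor_recording")
})

test_that("resample_uniform matches hand linear interpolation", {
  # f(t) = t sampled irregularly; linear interpolation reproduces t exactly
  tt <- c(0, 0.008, 0.012, 0.02)
  chans <- setNames(lapply(1:6, function(i) tt),
                    c("la_x","la_y","la_z","av_x","av_y","av_z"))
  rec <- recording(chans, rate = 200, timestamps = tt, validate = FALSE)
  out <- resample_uniform(rec, 100)
  expect_equal(as.numeric(out$channels$la_x), c(0, 0.01, 0.02),
               tolerance = 1e-12)
  expect_equal(out$rate, 100)
  expect_tremor_error(resample_uniform(rec, 20), "parameter")
})

test_that("resample_uniform is the identity on already-uniform input", {
  set.seed(42)
  n <- 2000
  chans <- setNames(lapply(1:6, function(i) rnorm(n)),
                    c("la_x","la_y","la_z","av_x","av_y","av_z"))
  rec <- recording(chans, rate = 100)
  out <- resample_uniform(rec, 100)
  expect_equal(as.numeric(out$channels$av_y), as.numeric(rec$channels$av_y),
               tolerance = 1e-9)
})

test_that("resampling 200 Hz -> 100 Hz preserves a 6 Hz spectral peak", {
  n <- 4000
  x <- sin(2 * pi * 6 * (0:(n - 1)) / 200)
  chans <- setNames(lapply(1:6, function(i) x),
                    c("la_x","la_y","la_z","av_x","av_y","av_z"))
  rec <- recording(chans, rate = 200)
  out <- resample_uniform(rec, 100)
  expect_equal(dft_peak_freq(as.numeric(out$channels$la_x), 100), 6,
               tolerance = 0.06)
})

test_that("control reference averages scores and round-trips through JSON", {
  expect_equal(write_control_reference(c(1, 1, 1))$mean_index, 1.0)
  expect_equal(write_control_reference(c(1, 3))$mean_index, 2.0)
  expect_tremor_error(write_control_reference(numeric(0)), "parameter")
  expect_tremor_error(write_control_reference(c(1, -2)), "parameter")

  path <- withr::local_tempfile(fileext = ".json")
  ref <- write_control_reference(c(0.5, 1.25, 3.75), path = path,
                                 band = c(3.5, 10),
                                 pipeline_config_hash = "abc123")
  back <- read_control_reference(path)
  expect_equal(back$mean_index, ref$mean_index)
  expect_equal(back$n_subjects, 3L)
  expect_equal(back$band, c(3.5, 10))
  expect_equal(back$pipeline_config_hash, "abc123")
})
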