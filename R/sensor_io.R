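#' @importFrom utils read.csv write.csv
NULL

CHANNELS <- c("la_x", "la_y", "la_z", "av_x", "av_y", "av_z")
CHANNEL_UNITS <- c(la_x = "m/s^2", la_y = "m/s^2", la_z = "m/s^2",
                   av_x = "rad/s", av_y = "rad/s", av_z = "rad/s")

#' Inertial recording container
#'
#' A `tremor_recording` bundles uniformly sampled inertial channels with the
#' metadata the scoring pipeline needs: sampling rate, sensor kind
#' (`"finger"` for a finger-mounted IMU, `"phone"` for a hand-strapped
#' smartphone) and the postural test position (`"P1"`: arms forward,
#' `"P2"`: arms abducted). The canonical channel set is the six streams of a
#' 6-DOF IMU: `la_x`, `la_y`, `la_z` (linear acceleration, m/s^2) and
#' `av_x`, `av_y`, `av_z` (angular velocity, rad/s).
#'
#' With `validate = TRUE` the constructor enforces the contract the pipeline
#' assumes: all channels the same length, at least two 8-s analysis windows
#' of samples (length >= 16 * rate), and a sampling rate above 20
#' samples/s so that the 3.5-10 Hz tremor band sits comfortably below
#' Nyquist.
#'
#' @param channels named list of numeric vectors (typically the six canonical
#'   channels; a subset is allowed for single-channel debugging).
#' @param rate sampling rate in samples/s.
#' @param sensor `"finger"`, `"phone"`.
#' @param position `"P1"`, `"P2"` or `"unknown"`.
#' @param subject_id opaque subject identifier.
#' @param timestamps optional vector of original sample times in seconds
#'   (kept until [resample_uniform()] maps the data onto a uniform grid).
#' @param validate enforce the pipeline contract (default `TRUE`).
#' @return an object of class `tremor_recording`.
#' @export
recording <- function(channels, rate, sensor = c("phone", "finger"),
                      position = c("unknown", "P1", "P2"),
                      subject_id = "", timestamps = NULL, validate = TRUE) {
  sensor <- match.arg(sensor)
  position <- match.arg(position)
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_param("channels must be a named list of numeric vectors")
  lens <- lengths(channels)
  if (length(unique(lens)) != 1L)
    stop_data("all channels must have the same length (got %s)",
              paste(lens, collapse = ", "))
  if (validate) {
    if (rate <= 20)
      stop_param("sampling rate must exceed 20 samples/s (got %g)", rate)
    min_len <- 16 * rate
    if (lens[1] < min_len)
      stop_data("recording too short: %d samples, need >= %g (16 s at %g Hz)",
                lens[1], min_len, rate)
    if (anyNA(unlist(channels, use.names = FALSE)))
      stop_data("recording contains missing samples")
  }
  for (nm in names(channels)) {
    if (is.null(attr(channels[[nm]], "unit")) && nm %in% names(CHANNEL_UNITS))
      attr(channels[[nm]], "unit") <- CHANNEL_UNITS[[nm]]
  }
  structure(list(channels = channels, rate = rate, sensor = sensor,
                 position = position, subject_id = subject_id,
                 timestamps = timestamps),
            class = "tremor_recording")
}

#' @export
print.tremor_recording <- function(x, ...) {
  cat(sprintf("<tremor_recording> %s sensor, position %s, subject '%s'\n",
              x$sensor, x$position, x$subject_id))
  cat(sprintf("  %d channels x %d samples at %g Hz (%.1f s)\n",
              length(x$channels), length(x$channels[[1]]), x$rate,
              length(x$channels[[1]]) / x$rate))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CSV dialects
#
# The field has no standard file layout for phone/IMU exports, so column
# naming and gyro units are isolated in a small dialect registry with two
# built-ins: "phone" (plain SI columns, as an app export) and "lpms"
# (vendor-style names with the gyro in deg/s, as an LPMS-class IMU export).

.dialects <- new.env(parent = emptyenv())

#' Register or look up a CSV dialect
#'
#' A dialect maps file column names onto the canonical channels and declares
#' the gyro unit so that angular velocity is converted to rad/s exactly once
#' at ingestion.
#'
#' @param name dialect name.
#' @param time_col name of the time column (seconds).
#' @param columns named character vector mapping canonical channel name ->
#'   file column name.
#' @param gyro_unit `"rad/s"` or `"deg/s"`.
#' @export
register_dialect <- function(name, time_col, columns, gyro_unit = "rad/s") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(CHANNELS %in% names(columns)))
    stop_param("dialect must map all six channels; missing %s",
               paste(setdiff(CHANNELS, names(columns)), collapse = ", "))
  gyro_unit <- match.arg(gyro_unit, c("rad/s", "deg/s"))
  assign(name, list(name = name, time_col = time_col,
                    columns = columns, gyro_unit = gyro_unit),
         envir = .dialects)
  invisible(name)
}

#' @rdname register_dialect
#' @export
get_dialect <- function(name) {
  if (!exists(name, envir = .dialects))
    stop_param("unknown CSV dialect '%s' (known: %s)", name,
               paste(ls(.dialects), collapse = ", "))
  get(name, envir = .dialects)
}

.register_builtin_dialects <- function() {
  register_dialect("phone", time_col = "t",
                   columns = c(la_x = "la_x", la_y = "la_y", la_z = "la_z",
                               av_x = "av_x", av_y = "av_y", av_z = "av_z"),
                   gyro_unit = "rad/s")
  register_dialect("lpms", time_col = "TimeStamp",
                   columns = c(la_x = "AccX", la_y = "AccY", la_z = "AccZ",
                               av_x = "GyroX", av_y = "GyroY", av_z = "GyroZ"),
                   gyro_unit = "deg/s")
}

#' Read an inertial recording from CSV
#'
#' Reads a timestamped CSV with the six IMU channels, converts units to SI
#' (deg/s gyro columns become rad/s when the dialect says so) and infers the
#' sampling rate from the median timestamp increment. Original timestamps are
#' preserved on the returned object until [resample_uniform()] is applied.
#'
#' @param path CSV file path.
#' @param dialect dialect name, see [register_dialect()]. Default `"phone"`.
#' @inheritParams recording
#' @param validate enforce the recording contract (default `TRUE`).
#' @return a [recording()].
#' @export
read_recording <- function(path, dialect = "phone",
                           sensor = c("phone", "finger"),
                           position = c("unknown", "P1", "P2"),
                           subject_id = "", validate = TRUE) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  d <- get_dialect(dialect)
  df <- read.csv(path, check.names = FALSE)
  if (!d$time_col %in% names(df))
    stop_format("missing time column %s", d$time_col)
  for (ch in CHANNELS) {
    if (!d$columns[[ch]] %in% names(df))
      stop_format("missing channel %s", ch)
  }
  tt <- as.numeric(df[[d$time_col]])
  if (any(diff(tt) <= 0))
    stop_data("timestamps are not strictly increasing")
  chans <- list()
  for (ch in CHANNELS) {
    v <- as.numeric(df[[d$columns[[ch]]]])
    if (startsWith(ch, "av_") && d$gyro_unit == "deg/s") v <- v * pi / 180
    attr(v, "unit") <- CHANNEL_UNITS[[ch]]
    chans[[ch]] <- v
  }
  rate <- 1 / median(diff(tt))
  recording(chans, rate = rate, sensor = match.arg(sensor),
            position = match.arg(position), subject_id = subject_id,
            timestamps = tt, validate = validate)
}

#' Write an inertial recording to CSV
#'
#' Inverse of [read_recording()]: writes the channels under the dialect's
#' column names, converting angular velocity back to deg/s if the dialect
#' stores gyro data that way.
#'
#' @param rec a [recording()].
#' @param path output CSV path.
#' @param dialect dialect name.
#' @export
write_recording <- function(rec, path, dialect = "phone") {
  d <- get_dialect(dialect)
  n <- length(rec$channels[[1]])
  tt <- rec$timestamps
  if (is.null(tt)) tt <- (seq_len(n) - 1) / rec$rate
  df <- data.frame(tt)
  names(df) <- d$time_col
  for (ch in CHANNELS) {
    v <- as.numeric(rec$channels[[ch]])
    if (startsWith(ch, "av_") && d$gyro_unit == "deg/s") v <- v * 180 / pi
    df[[d$columns[[ch]]]] <- v
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Linearly interpolates every channel onto a uniform grid at `target_rate`
#' spanning the original time range. With the tremor band ending at 10 Hz
#' and rates at or near 100 Hz, linear interpolation error is negligible in
#' the band of interest. Idempotent on already-uniform input at the same
#' rate (up to floating-point representation).
#'
#' @param rec a [recording()].
#' @param target_rate target sampling rate in samples/s; must exceed 20.
#' @return a [recording()] with uniform sampling and `timestamps = NULL`.
#' @export
resample_uniform <- function(rec, target_rate) {
  if (target_rate <= 20)
    stop_param("target_rate must exceed 20 samples/s (got %g)", target_rate)
  n <- length(rec$channels[[1]])
  if (n < 2) stop_data("need at least 2 samples to resample")
  tt <- rec$timestamps
  if (is.null(tt)) tt <- (seq_len(n) - 1) / rec$rate
  grid <- seq(tt[1], tt[n], by = 1 / target_rate)
  chans <- lapply(rec$channels, function(v) {
    out <- approx(tt, as.numeric(v), xout = grid, method = "linear")$y
    attr(out, "unit") <- attr(v, "unit")
    out
  })
  recording(chans, rate = target_rate, sensor = rec$sensor,
            position = rec$position, subject_id = rec$subject_id,
            timestamps = NULL, validate = FALSE)
}

# ---------------------------------------------------------------------------
# Control reference

#' Control-cohort reference
#'
#' Holds the population-average control tremor index used to express scores
#' in decibels, together with the band and a hash of the pipeline
#' configuration under which the control scores were computed. Scores are
#' only comparable to a reference produced under the same configuration,
#' which is why the hash travels with the reference.
#'
#' @param mean_index positive control-population mean tremor index.
#' @param n_subjects number of control subjects averaged.
#' @param band analysis band in Hz, `c(low, high)`.
#' @param pipeline_config_hash hash string from [config_hash()].
#' @return an object of class `control_reference`.
#' @export
control_reference <- function(mean_index, n_subjects, band = c(3.5, 10),
                              pipeline_config_hash = "") {
  if (!is.numeric(mean_index) || length(mean_index) != 1L || mean_index <= 0)
    stop_param("mean_index must be a positive scalar")
  if (n_subjects < 1) stop_param("n_subjects must be >= 1")
  structure(list(mean_index = as.numeric(mean_index),
                 n_subjects = as.integer(n_subjects),
                 band = as.numeric(band),
                 pipeline_config_hash = as.character(pipeline_config_hash)),
            class = "control_reference")
}

#' Build and write a control reference from control scores
#'
#' `mean_index` is the arithmetic mean of the per-subject control tremor
#' indices (on the linear scale, not dB).
#'
#' @param scores positive per-subject control tremor indices.
#' @param path output JSON path, or `NULL` to skip writing.
#' @inheritParams control_reference
#' @return the [control_reference()], invisibly when written.
#' @export
write_control_reference <- function(scores, path = NULL, band = c(3.5, 10),
                                    pipeline_config_hash = "") {
  if (length(scores) == 0) stop_param("scores must be a nonempty list")
  scores <- as.numeric(scores)
  if (any(scores <= 0)) stop_param("all control scores must be positive")
  ref <- control_reference(mean(scores), length(scores), band,
                           pipeline_config_hash)
  if (!is.null(path)) {
    jsonlite::write_json(unclass(ref), path, auto_unbox = TRUE, digits = NA)
    return(invisible(ref))
  }
  ref
}

#' @rdname write_control_reference
#' @export
read_control_reference <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  control_reference(x$mean_index, x$n_subjects, x$band,
                    x$pipeline_config_hash)
}
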