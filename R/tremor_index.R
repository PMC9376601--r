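# Scoring stage: Gaussian smoothing of the ratio spectrum, band-limited
# per-window tremor index, and aggregation to the per-recording score.

#' Index configuration
#'
#' Parameters of the scoring stage.
#'
#' @param band tremor band in Hz; the per-window index is the smoothed-ratio
#'   maximum inside this band (default `c(3.5, 10)`).
#' @param smooth_sigma standard deviation of the Gaussian smoothing kernel
#'   in Hz (default 1).
#' @param top_fraction fraction of the highest (window, channel) indices
#'   kept for the per-recording median (default 1/3).
#' @return an object of class `index_config`.
#' @export
index_config <- function(band = c(3.5, 10), smooth_sigma = 1,
                         top_fraction = 1 / 3) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop_param("band must be c(low, high) with 0 < low < high")
  if (smooth_sigma <= 0) stop_param("smooth_sigma must be positive")
  if (top_fraction <= 0 || top_fraction > 1)
    stop_param("top_fraction must be in (0, 1]")
  structure(list(band = as.numeric(band), smooth_sigma = smooth_sigma,
                 top_fraction = top_fraction),
            class = "index_config")
}

#' Smooth a spectrum with a Gaussian kernel
#'
#' Convolves the spectral values with a unit-sum Gaussian kernel of standard
#' deviation `sigma` (in Hz, converted to bins), truncated at +/- 3 sigma,
#' with the spectrum reflected at its edges (edge bin included in the
#' mirror). A constant spectrum is unchanged and total kernel mass is
#' exactly 1.
#'
#' @param spectrum a `tremor_spectrum` on a uniform frequency grid.
#' @param sigma kernel standard deviation in Hz.
#' @return a `tremor_spectrum` of the same kind on the same grid.
#' @export
smooth_spectrum <- function(spectrum, sigma) {
  if (sigma <= 0) stop_param("sigma must be positive")
  df <- diff(spectrum$freqs)
  if (max(abs(df - df[1])) > 1e-9 * df[1])
    stop_param("smoothing requires a uniform frequency grid")
  sigma_bins <- sigma / df[1]
  half <- ceiling(3 * sigma_bins)
  kern <- exp(-0.5 * ((-half):half / sigma_bins)^2)
  kern <- kern / sum(kern)
  v <- spectrum$values
  n <- length(v)
  if (half >= n) stop_param("kernel wider than spectrum (sigma too large)")
  padded <- c(v[half:1], v, v[n:(n - half + 1)])
  sm <- stats::filter(padded, kern, method = "convolution", sides = 2)
  out <- as.numeric(sm[(half + 1):(half + n)])
  new_spectrum(spectrum$freqs, out, spectrum$kind, spectrum$window_start,
               spectrum$channel)
}

#' Per-window tremor index
#'
#' Smooths the oscillatory ratio spectrum with a Gaussian kernel
#' (`smooth_sigma`), restricts it to the tremor band, and takes the maximum;
#' the index value is that maximum and the peak frequency is where it is
#' attained (ties resolved to the lowest frequency).
#'
#' @param ratio a `tremor_spectrum` with `kind = "ratio"`.
#' @param config an [index_config()].
#' @return an object of class `window_index` with fields `value`,
#'   `peak_freq`, `window_start`, `channel`.
#' @export
window_index <- function(ratio, config = index_config()) {
  if (!identical(ratio$kind, "ratio"))
    stop_param("window_index expects a ratio spectrum (got kind '%s')",
               ratio$kind)
  if (config$band[1] < min(ratio$freqs) || config$band[2] > max(ratio$freqs))
    stop_param("band [%g, %g] Hz lies outside the spectrum grid [%g, %g] Hz",
               config$band[1], config$band[2],
               min(ratio$freqs), max(ratio$freqs))
  sm <- smooth_spectrum(ratio, config$smooth_sigma)
  in_band <- sm$freqs >= config$band[1] & sm$freqs <= config$band[2]
  vals <- sm$values[in_band]
  freqs <- sm$freqs[in_band]
  i <- which.max(vals)    # first maximum = lowest frequency on ties
  structure(list(value = vals[i], peak_freq = freqs[i],
                 window_start = ratio$window_start, channel = ratio$channel),
            class = "window_index")
}

#' Aggregate window indices into a per-recording tremor score
#'
#' Pools the per-(window, channel) indices of one recording, keeps the top
#' `ceil(top_fraction * n)` values, and takes their median (midpoint mean
#' for an even count). `dominant_freq` is the median peak frequency of the
#' kept windows, carried as diagnostic metadata.
#'
#' @param indices list of [window_index()] objects (all windows of all
#'   channels of one recording, pooled).
#' @param config an [index_config()].
#' @return an object of class `tremor_score` with fields `index`, `db`
#'   (`NULL` until [to_decibel()]), `control_mean`, `n_windows_total`,
#'   `n_windows_used`, `dominant_freq`.
#' @export
aggregate_score <- function(indices, config = index_config()) {
  if (length(indices) == 0) stop_data("no window indices to aggregate")
  vals <- vapply(indices, function(i) i$value, numeric(1))
  pfs <- vapply(indices, function(i) i$peak_freq, numeric(1))
  n <- length(vals)
  k <- ceiling(config$top_fraction * n)
  ord <- order(vals, decreasing = TRUE)
  kept <- ord[seq_len(k)]
  structure(list(index = median(vals[kept]), db = NULL, control_mean = NULL,
                 n_windows_total = n, n_windows_used = k,
                 dominant_freq = median(pfs[kept])),
            class = "tremor_score")
}

#' @export
print.tremor_score <- function(x, ...) {
  cat(sprintf("<tremor_score> index %.4g", x$index))
  if (!is.null(x$db)) cat(sprintf(" (%.2f dB vs control mean %.4g)",
                                  x$db, x$control_mean))
  cat(sprintf("\n  dominant frequency %.3g Hz; %d of %d windows used\n",
              x$dominant_freq, x$n_windows_used, x$n_windows_total))
  invisible(x)
}

#' Express a tremor score in decibels relative to a control cohort
#'
#' Computes `db = 10 * log10(index / control_mean)`: a subject at the
#' control-population mean scores 0 dB, and +10 dB means a tremor index ten
#' times the control mean.
#'
#' @param score a [aggregate_score()] result.
#' @param control a [control_reference()].
#' @return the score with `db` and `control_mean` filled in.
#' @export
to_decibel <- function(score, control) {
  if (score$index <= 0) stop_param("tremor index must be positive")
  if (control$mean_index <= 0) stop_param("control mean must be positive")
  score$db <- 10 * log10(score$index / control$mean_index)
  score$control_mean <- control$mean_index
  score
}

#' Score a recording end to end
#'
#' Composition of the whole pipeline: ratio [spectrogram()] ->
#' [window_index()] per window and channel -> [aggregate_score()] ->
#' optionally [to_decibel()] against a control reference. Deterministic for
#' fixed input and configuration, and invariant to the overall gain of the
#' recording (the ratio spectrum is scale-free).
#'
#' @param rec a [recording()].
#' @param spectral a [spectral_config()].
#' @param index a [index_config()].
#' @param control optional [control_reference()].
#' @return a `tremor_score`.
#' @export
score_recording <- function(rec, spectral = spectral_config(),
                            index = index_config(), control = NULL) {
  ratios <- spectrogram(rec, spectral)
  indices <- lapply(ratios, window_index, config = index)
  score <- aggregate_score(indices, index)
  if (!is.null(control)) score <- to_decibel(score, control)
  score
}

#' Serialize a tremor score to JSON
#'
#' @param score a `tremor_score`.
#' @param path output path, or `NULL` to return the JSON string.
#' @export
score_to_json <- function(score, path = NULL) {
  x <- list(index = score$index,
            db = if (is.null(score$db)) NA else score$db,
            control_mean = if (is.null(score$control_mean)) NA
                           else score$control_mean,
            n_windows_total = score$n_windows_total,
            n_windows_used = score$n_windows_used,
            dominant_freq_hz = score$dominant_freq)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                         na = "null")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
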