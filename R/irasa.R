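# IRASA spectral stage: windowing, mixed (ordinary) PSD, fractal PSD by
# irregular resampling, and the oscillatory ratio spectrum.
#
# IRASA exploits the self-affinity of 1/f^beta processes: resampling the
# signal by a non-integer factor h (and 1/h) shifts any rhythmic peak to
# f/h (and f*h) while the power-law background reproduces itself up to a
# scale factor that cancels in the geometric mean of the pair. The median
# across a set of h factors is then an estimate of the fractal component
# alone; dividing the mixed PSD by it isolates the rhythmic content.

#' Spectral configuration
#'
#' Parameters of the windowed IRASA stage.
#'
#' @param window_length analysis window length in seconds (default 8, giving
#'   a 0.125 Hz frequency resolution).
#' @param overlap_fraction fractional overlap between consecutive windows
#'   (default 0.5, i.e. a 4-s hop).
#' @param hset irregular-resampling factors; the default
#'   `seq(1.10, 1.90, by = 0.05)` (17 factors) is the convention of the
#'   IRASA method. All factors must exceed 1.
#' @param detrend detrending applied per window; only `"linear"` is
#'   implemented.
#' @param taper taper applied per window; only `"hann"` is implemented.
#' @param ratio_floor the fractal denominator is floored at
#'   `ratio_floor * max(fractal)` before division, guarding against
#'   blow-ups at near-zero bins left by detrending.
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(window_length = 8, overlap_fraction = 0.5,
                            hset = seq(1.10, 1.90, by = 0.05),
                            detrend = "linear", taper = "hann",
                            ratio_floor = 1e-12) {
  if (window_length <= 0) stop_param("window_length must be positive")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop_param("overlap_fraction must be in [0, 1)")
  if (any(hset <= 1)) stop_param("all resampling factors must exceed 1")
  detrend <- match.arg(detrend, "linear")
  taper <- match.arg(taper, "hann")
  structure(list(window_length = window_length,
                 overlap_fraction = overlap_fraction,
                 hset = as.numeric(hset), detrend = detrend, taper = taper,
                 ratio_floor = ratio_floor),
            class = "spectral_config")
}

new_spectrum <- function(freqs, values, kind, window_start = 0,
                         channel = NA_character_) {
  structure(list(freqs = freqs, values = values, kind = kind,
                 window_start = window_start, channel = channel),
            class = "tremor_spectrum")
}

#' @export
print.tremor_spectrum <- function(x, ...) {
  cat(sprintf("<tremor_spectrum> kind=%s channel=%s t=%gs, %d bins (%g-%g Hz)\n",
              x$kind, x$channel, x$window_start, length(x$freqs),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Segment a channel into overlapping analysis windows
#'
#' Cuts the samples into blocks of `window_length` seconds starting at
#' 0, hop, 2*hop, ... where `hop = window_length * (1 - overlap_fraction)`;
#' a trailing partial window is dropped.
#'
#' @param x numeric sample vector of one channel.
#' @param rate sampling rate in samples/s.
#' @param config a [spectral_config()].
#' @return list of `list(window_start = seconds, samples = block)`.
#' @export
segment_windows <- function(x, rate, config = spectral_config()) {
  n_win <- round(config$window_length * rate)
  n <- length(x)
  if (n < n_win)
    stop_data("input too short: %d samples, need >= %d (%g s at %g Hz)",
              n, n_win, config$window_length, rate)
  hop <- round(config$window_length * (1 - config$overlap_fraction) * rate)
  starts <- seq(1L, n - n_win + 1L, by = hop)
  lapply(starts, function(s) {
    list(window_start = (s - 1) / rate, samples = x[s:(s + n_win - 1L)])
  })
}

# ---------------------------------------------------------------------------
# Periodogram plan
#
# For a fixed (block length, rate, config) all geometry is constant: the
# Hann taper, its power normalisation, the frequency grids of every
# resampled length and the interpolation abscissae. Computing it once per
# configuration and caching it makes per-window IRASA cheap enough to score
# whole cohorts.

.plan_cache <- new.env(parent = emptyenv())

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

.psd_geometry <- function(n, rate) {
  w <- .hann(n)
  nf <- n %/% 2 + 1L
  list(n = n, taper = w, scale = 2 / (rate * sum(w^2)), nfreq = nf,
       freqs = (0:(nf - 1)) * rate / n)
}

# Precomputed linear interpolation from a fixed source grid onto a fixed
# target grid (clamped at the ends, i.e. approx(..., rule = 2)).
.interp_plan <- function(xin, xout) {
  lo <- findInterval(xout, xin)
  lo <- pmin(pmax(lo, 1L), length(xin) - 1L)
  w <- (xout - xin[lo]) / (xin[lo + 1L] - xin[lo])
  list(lo = lo, w = pmin(pmax(w, 0), 1))
}

.interp_apply <- function(y, p) y[p$lo] * (1 - p$w) + y[p$lo + 1L] * p$w

.irasa_plan <- function(n, rate, config) {
  key <- paste(n, rate, paste(config$hset, collapse = ","), sep = "|")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  base <- .psd_geometry(n, rate)
  pairs <- lapply(config$hset, function(h) {
    n_up <- round(n * h)
    n_dn <- round(n / h)
    up <- .psd_geometry(n_up, rate)
    dn <- .psd_geometry(n_dn, rate)
    list(h = h, up = up, dn = dn,
         # resampled sample positions, in original sample-index units
         sig_up = .interp_plan(seq_len(n), seq(1, n, length.out = n_up)),
         sig_dn = .interp_plan(seq_len(n), seq(1, n, length.out = n_dn)),
         # power regridding back onto the base frequency grid
         psd_up = .interp_plan(up$freqs, base$freqs),
         psd_dn = .interp_plan(dn$freqs, base$freqs))
  })
  plan <- list(base = base, pairs = pairs)
  .plan_cache[[key]] <- plan
  plan
}

# row-wise median of a matrix via one global two-key sort (fast for the
# many-rows x few-columns shape produced by the h-factor sweep)
.row_medians <- function(m) {
  k <- ncol(m)
  s <- matrix(m[order(row(m), m)], ncol = k, byrow = TRUE)
  if (k %% 2 == 1) s[, (k + 1) %/% 2]
  else (s[, k %/% 2] + s[, k %/% 2 + 1L]) / 2
}

.detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n) - (n + 1) / 2            # centred regressor
  x - mean(x) - t * (sum(t * x) / sum(t * t))
}

# One-sided PSD of a (already detrended) block using a precomputed geometry.
# DC and Nyquist bins are not doubled.
.raw_psd <- function(x, g) {
  X <- fft(x * g$taper)
  p <- g$scale * (Mod(X[seq_len(g$nfreq)])^2)
  p[1] <- p[1] / 2
  if (g$n %% 2 == 0) p[g$nfreq] <- p[g$nfreq] / 2
  p
}

#' Mixed (ordinary) power spectral density of one window
#'
#' One-sided PSD of the linearly detrended, Hann-tapered block, normalised
#' so that the integral of the PSD over frequency approximates the signal
#' variance (Parseval).
#'
#' @param block samples of exactly `window_length * rate` points.
#' @param rate sampling rate in samples/s.
#' @param config a [spectral_config()].
#' @param window_start,channel provenance metadata carried on the spectrum.
#' @return a `tremor_spectrum` with `kind = "mixed"` on the grid
#'   `0, 1/window_length, ..., rate/2` Hz.
#' @export
mixed_spectrum <- function(block, rate, config = spectral_config(),
                           window_start = 0, channel = NA_character_) {
  n <- round(config$window_length * rate)
  if (length(block) != n)
    stop_param("block must have exactly %d samples (got %d)", n, length(block))
  plan <- .irasa_plan(n, rate, config)
  x <- .detrend_linear(block)
  new_spectrum(plan$base$freqs, .raw_psd(x, plan$base), "mixed",
               window_start, channel)
}

#' Fractal power spectral density of one window (IRASA)
#'
#' For each resampling factor `h` in the configured set, the detrended block
#' is linearly resampled to `round(n*h)` and `round(n/h)` points (nominal
#' rate unchanged, so rhythmic peaks shift to `f/h` and `f*h`), each version
#' is Hann-tapered and its periodogram interpolated back onto the original
#' frequency grid, and the pair is combined as a bin-wise geometric mean.
#' The fractal estimate is the bin-wise median across the factor set.
#'
#' @inheritParams mixed_spectrum
#' @return a `tremor_spectrum` with `kind = "fractal"` on the same grid as
#'   [mixed_spectrum()].
#' @export
fractal_spectrum <- function(block, rate, config = spectral_config(),
                             window_start = 0, channel = NA_character_) {
  n <- round(config$window_length * rate)
  if (length(block) != n)
    stop_param("block must have exactly %d samples (got %d)", n, length(block))
  plan <- .irasa_plan(n, rate, config)
  x <- .detrend_linear(block)
  base_f <- plan$base$freqs
  geo <- vapply(plan$pairs, function(p) {
    s_up <- .interp_apply(.raw_psd(.interp_apply(x, p$sig_up), p$up), p$psd_up)
    s_dn <- .interp_apply(.raw_psd(.interp_apply(x, p$sig_dn), p$dn), p$psd_dn)
    sqrt(s_up * s_dn)
  }, numeric(length(base_f)))
  frac <- .row_medians(geo)
  new_spectrum(base_f, frac, "fractal", window_start, channel)
}

#' Oscillatory ratio spectrum
#'
#' Bin-wise ratio of the mixed to the fractal PSD. The ratio is ~1 where the
#' window contains only scale-free background and rises above 1 at rhythmic
#' peaks; it is unitless and invariant to signal gain. The fractal
#' denominator is floored at `ratio_floor * max(fractal)`.
#'
#' @param mixed a `tremor_spectrum` with `kind = "mixed"`.
#' @param fractal a `tremor_spectrum` with `kind = "fractal"` on the same
#'   frequency grid.
#' @param ratio_floor relative denominator floor (see [spectral_config()]).
#' @return a `tremor_spectrum` with `kind = "ratio"`.
#' @export
oscillatory_ratio <- function(mixed, fractal, ratio_floor = 1e-12) {
  if (!identical(mixed$kind, "mixed") || !identical(fractal$kind, "fractal"))
    stop_param("expected spectra of kind 'mixed' and 'fractal' (got %s, %s)",
               mixed$kind, fractal$kind)
  if (length(mixed$freqs) != length(fractal$freqs) ||
      any(mixed$freqs != fractal$freqs))
    stop_param("mixed and fractal spectra are on different frequency grids")
  eps <- ratio_floor * max(fractal$values)
  new_spectrum(mixed$freqs, mixed$values / pmax(fractal$values, eps), "ratio",
               mixed$window_start, mixed$channel)
}

#' Ratio spectrogram of a recording
#'
#' Runs the full IRASA stage on every channel of a recording: windows each
#' channel, computes the mixed and fractal PSDs per window, and returns the
#' oscillatory ratio spectra ordered by (channel, window start).
#'
#' @param rec a [recording()].
#' @param config a [spectral_config()].
#' @return list of `tremor_spectrum` objects with `kind = "ratio"`, of
#'   length `n_channels * n_windows`.
#' @export
spectrogram <- function(rec, config = spectral_config()) {
  out <- list()
  for (ch in names(rec$channels)) {
    wins <- segment_windows(as.numeric(rec$channels[[ch]]), rec$rate, config)
    for (w in wins) {
      m <- mixed_spectrum(w$samples, rec$rate, config, w$window_start, ch)
      f <- fractal_spectrum(w$samples, rec$rate, config, w$window_start, ch)
      out[[length(out) + 1L]] <- oscillatory_ratio(m, f, config$ratio_floor)
    }
  }
  out
}
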