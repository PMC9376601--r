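# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair counting for the AUC, an
# explicit sort for the top-third median, and plain untapered DFTs for
# spectral peak locations.

brute_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

brute_top_median <- function(values, top_fraction = 1 / 3) {
  k <- ceiling(top_fraction * length(values))
  kept <- sort(values, decreasing = TRUE)[seq_len(k)]
  if (k %% 2 == 1) kept[(k + 1) / 2] else mean(kept[k / 2 + 0:1])
}

# argmax frequency of a plain (untapered, undetrended beyond mean removal)
# DFT power spectrum, searched over positive frequencies only
dft_peak_freq <- function(x, rate) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  f <- (0:(n - 1)) * rate / n
  keep <- f > 0 & f <= rate / 2
  f[keep][which.max(p[keep])]
}

# least-squares slope of log10(power) vs log10(f) from a plain periodogram,
# averaged in log space over frequency bins in [f_lo, f_hi]
loglog_slope <- function(x, rate, f_lo = 1, f_hi = 12) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2 / n
  f <- (0:(n - 1)) * rate / n
  keep <- f >= f_lo & f <= f_hi
  coef(lm(log10(p[keep]) ~ log10(f[keep])))[[2]]
}

# a small uniform recording fixture written through the phone dialect
write_phone_csv <- function(path, n = 2000, rate = 100, seed = 1,
                            gyro_unit_factor = 1) {
  set.seed(seed)
  df <- data.frame(t = (0:(n - 1)) / rate)
  for (ch in c("la_x", "la_y", "la_z", "av_x", "av_y", "av_z"))
    df[[ch]] <- rnorm(n)
  write.csv(df, path, row.names = FALSE)
  df
}

expect_tremor_error <- function(expr, class) {
  expect_error(expr, class = paste0("tremorsense_", class, "_error"))
}
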