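# Cohort-level statistics: ROC/AUC group separation, score-to-severity
# correlation, and the spectral peak-over-background sensor comparison.

#' ROC curve and AUC
#'
#' The AUC is computed as the rank statistic: the probability that a random
#' positive outscores a random negative, with ties counted one half
#' (equivalently the normalised Mann-Whitney U). The empirical ROC curve is
#' also returned; its trapezoidal area equals the rank AUC to within
#' 1e-12, which the unit tests assert.
#'
#' @param scores_pos scores of the positive class (patients).
#' @param scores_neg scores of the negative class (controls).
#' @return an object of class `roc_result` with `auc`, `thresholds`, `tpr`,
#'   `fpr`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0 || length(scores_neg) == 0)
    stop_param("both score lists must be nonempty")
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  # empirical curve over the distinct thresholds, decreasing
  th <- sort(unique(c(scores_pos, scores_neg, Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scores_pos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scores_neg >= t), numeric(1))
  structure(list(auc = auc, thresholds = th, tpr = tpr, fpr = fpr,
                 n_pos = np, n_neg = nn),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positives vs %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Correlate tremor scores with clinical severity
#'
#' Pearson correlation of scores against severity ratings, with the
#' least-squares line for plotting.
#'
#' @param scores per-subject tremor scores.
#' @param severities matching clinical severity ratings.
#' @return list with `r`, `r2`, `slope`, `intercept`, `n`.
#' @export
correlate_severity <- function(scores, severities) {
  if (length(scores) != length(severities) || length(scores) < 3)
    stop_param("need equal-length vectors of at least 3 subjects")
  if (sd(scores) == 0 || sd(severities) == 0)
    stop_data("correlation undefined: zero variance")
  r <- cor(scores, severities)
  slope <- cov(scores, severities) / var(scores)
  list(r = r, r2 = r^2, slope = slope,
       intercept = mean(severities) - slope * mean(scores),
       n = length(scores))
}

#' Spectral peak-over-background ratio
#'
#' Measures how far the in-band spectral peak stands above the in-band
#' background, the statistic used to compare sensor signal-to-noise. The
#' background is the median of the in-band values after excluding all bins
#' within +/- 1 Hz of the peak; at least 5 bins must survive the exclusion.
#' Being a ratio of two values of the same spectrum, it is invariant to
#' spectrum scaling.
#'
#' @param spectrum a `tremor_spectrum`.
#' @param band `c(low, high)` in Hz.
#' @param exclude_hz half-width of the peak exclusion zone in Hz.
#' @return the peak/background ratio.
#' @export
peak_over_background <- function(spectrum, band = c(3.5, 10),
                                 exclude_hz = 1) {
  if (band[1] < min(spectrum$freqs) || band[2] > max(spectrum$freqs))
    stop_param("band [%g, %g] Hz outside the spectrum grid",
               band[1], band[2])
  in_band <- spectrum$freqs >= band[1] & spectrum$freqs <= band[2]
  f <- spectrum$freqs[in_band]
  v <- spectrum$values[in_band]
  i <- which.max(v)
  bg <- v[abs(f - f[i]) > exclude_hz]
  if (length(bg) < 5)
    stop_param("band too narrow: only %d background bins outside +/- %g Hz of the peak",
               length(bg), exclude_hz)
  v[i] / median(bg)
}

#' Recording-averaged oscillatory ratio spectrum
#'
#' Mean of the per-window ratio spectra over all windows and the selected
#' channels; the whole-recording summary spectrum used for paired-sensor
#' comparisons.
#'
#' @param rec a [recording()].
#' @param spectral a [spectral_config()].
#' @param channels channel subset to average over (default: all).
#' @return a `tremor_spectrum` with `kind = "ratio"`.
#' @export
mean_ratio_spectrum <- function(rec, spectral = spectral_config(),
                                channels = names(rec$channels)) {
  sp <- spectrogram(rec, spectral)
  sp <- Filter(function(s) s$channel %in% channels, sp)
  vals <- rowMeans(vapply(sp, function(s) s$values,
                          numeric(length(sp[[1]]$freqs))))
  new_spectrum(sp[[1]]$freqs, vals, "ratio", 0, paste(channels, collapse = "+"))
}

#' Cohort evaluation report
#'
#' Assembles the cohort-level summary: dB-normalised scores (each sensor x
#' position condition is normalised to its own control-group mean), ROC/AUC
#' of each patient group against controls per condition, the Pearson
#' correlation of dB scores with the severity rating per group and
#' condition, and a paired Wilcoxon signed-rank comparison of the two
#' sensors when both are present.
#'
#' @param table a cohort table as produced by [simulate_cohort()]
#'   (`subject_id`, `group`, `severity`, `score_<sensor>_<position>`).
#' @param control_ref optional named list of [control_reference()] objects
#'   per score column; by default the control means are computed from the
#'   table's own CTRL rows.
#' @return a `cohort_report` list with `auc`, `r2`, `scores_db`,
#'   `control_means`, `sensor_comparison`.
#' @export
cohort_report <- function(table, control_ref = NULL) {
  score_cols <- grep("^score_", names(table), value = TRUE)
  if (length(score_cols) == 0) stop_data("table has no score columns")
  ctrl <- table$group == "CTRL"
  pats <- !ctrl
  if (!any(ctrl)) stop_data("cohort has no control subjects")
  if (!any(pats)) stop_data("cohort has no patient subjects")

  control_means <- lapply(score_cols, function(cc) {
    if (!is.null(control_ref) && !is.null(control_ref[[cc]]))
      control_ref[[cc]]$mean_index
    else mean(table[[cc]][ctrl])
  })
  names(control_means) <- score_cols

  scores_db <- table[, c("subject_id", "group", "severity")]
  for (cc in score_cols)
    scores_db[[cc]] <- 10 * log10(table[[cc]] / control_means[[cc]])

  parse_col <- function(cc) {
    parts <- strsplit(sub("^score_", "", cc), "_")[[1]]
    list(sensor = parts[1], position = parts[2])
  }
  auc <- list(); r2 <- list()
  for (g in intersect(c("ET", "PD"), unique(table$group))) {
    sel <- table$group == g
    for (cc in score_cols) {
      pc <- parse_col(cc)
      auc[[g]][[pc$sensor]][[pc$position]] <-
        roc_auc(table[[cc]][sel], table[[cc]][ctrl])$auc
      r2[[g]][[pc$sensor]][[pc$position]] <-
        if (sum(sel) >= 3 && sd(table$severity[sel]) > 0)
          correlate_severity(scores_db[[cc]][sel], table$severity[sel])$r2
        else NA_real_
    }
  }

  sensor_comparison <- NULL
  pos_names <- unique(vapply(score_cols, function(cc) parse_col(cc)$position,
                             character(1)))
  if (all(c("score_finger_P1", "score_phone_P1") %in% score_cols)) {
    sensor_comparison <- lapply(pos_names, function(pos) {
      a <- scores_db[[sprintf("score_finger_%s", pos)]][pats]
      b <- scores_db[[sprintf("score_phone_%s", pos)]][pats]
      w <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)
      list(position = pos, wilcoxon_p = w$p.value,
           mean_db_finger = mean(a), mean_db_phone = mean(b))
    })
    names(sensor_comparison) <- pos_names
  }

  structure(list(auc = auc, r2 = r2, scores_db = scores_db,
                 control_means = control_means,
                 sensor_comparison = sensor_comparison),
            class = "cohort_report")
}

#' Serialize a cohort report to JSON
#'
#' @param report a [cohort_report()].
#' @param path output path, or `NULL` to return the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  x <- list(auc = report$auc, r2 = report$r2,
            control_means = report$control_means,
            scores_db = report$scores_db,
            sensor_comparison = report$sensor_comparison)
  if (is.null(path))
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                         dataframe = "rows")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
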