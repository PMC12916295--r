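# Sensor-level mismatch-negativity statistics: difference waveforms,
# windowed amplitude, robust outlier exclusion, paired tests and severity
# regression. The elementary statistics are computed from their textbook
# formulas and are cross-checked against the base R implementations in the
# test suite.

#' Mismatch-negativity difference waveform
#'
#' Deviant response minus the mean of the repeated-tone responses,
#' per time point (and per mode if matrices are supplied).
#'
#' @param deviant numeric vector or (time x mode) matrix
#' @param repeats a single response like `deviant`, or a list of them
#'   (e.g. tones 2-11), averaged before subtraction
#' @return difference waveform with the shape of `deviant`
#' @export
mmn_waveform <- function(deviant, repeats) {
  if (!is.list(repeats)) repeats <- list(repeats)
  dims <- function(x) if (is.matrix(x)) dim(x) else length(x)
  for (r in repeats)
    if (!identical(dims(r), dims(deviant)))
      stop("deviant and repeated responses must share the time axis",
           call. = FALSE)
  deviant - Reduce(`+`, repeats) / length(repeats)
}

#' Mean amplitude over a time window
#'
#' @param waveform numeric vector (one waveform) with a matching `time`
#'   axis in ms
#' @param time time axis (ms)
#' @param lo,hi inclusive window bounds (ms); default the canonical
#'   140-160 ms mismatch-negativity window
#' @export
window_mean <- function(waveform, time, lo = 140, hi = 160) {
  if (length(waveform) != length(time))
    stop("waveform and time axis lengths differ", call. = FALSE)
  idx <- which(time >= lo & time <= hi)
  if (!length(idx))
    stop("window [", lo, ", ", hi, "] ms contains no samples", call. = FALSE)
  mean(waveform[idx])
}

#' Robust two-session outlier mask
#'
#' Marks subjects for exclusion whose amplitude deviates by more than
#' `k` scaled median absolute deviations (MAD x 1.4826) from the median at
#' BOTH sessions; a subject extreme at only one session is retained.
#'
#' @param baseline,followup paired amplitude vectors
#' @param k threshold in scaled MADs (default 3)
#' @return logical vector, `TRUE` = keep
#' @export
mad_outlier_mask <- function(baseline, followup, k = 3) {
  if (length(baseline) != length(followup))
    stop("sessions must be paired", call. = FALSE)
  if (length(baseline) < 3)
    stop("need at least 3 subjects", call. = FALSE)
  flag <- function(x) {
    m <- median(x)
    s <- mad(x)  # scaled by 1.4826 by default
    if (s == 0) {
      warning("MAD is zero; no exclusions applied", call. = FALSE)
      return(rep(FALSE, length(x)))
    }
    abs(x - m) > k * s
  }
  !(flag(baseline) & flag(followup))
}

#' Paired t-test with effect size
#'
#' Standard paired t statistic on the differences `a - b`, two-sided
#' p-value, and Cohen's d = mean(diff)/sd(diff).
#'
#' @param a,b paired numeric vectors (n >= 2)
#' @return list(t, df, p, d, mean_diff)
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stop("paired_t: need paired vectors of length >= 2", call. = FALSE)
  d <- a - b
  s <- sd(d)
  if (s == 0) stop("paired_t: zero-variance differences", call. = FALSE)
  n <- length(d)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1), d = mean(d) / s,
       mean_diff = mean(d))
}

#' Simple linear regression of amplitude on a covariate
#'
#' Ordinary least squares slope/intercept, Pearson correlation and its
#' two-sided p-value.
#'
#' @param amplitude response vector
#' @param covariate predictor vector (e.g. baseline MMSE), non-constant
#' @return list(slope, intercept, r, p, n)
#' @export
amplitude_vs_covariate <- function(amplitude, covariate) {
  n <- length(amplitude)
  if (length(covariate) != n || n < 3)
    stop("need n >= 3 paired observations", call. = FALSE)
  if (sd(covariate) == 0)
    stop("constant covariate: degenerate design", call. = FALSE)
  sxy <- sum((covariate - mean(covariate)) * (amplitude - mean(amplitude)))
  sxx <- sum((covariate - mean(covariate))^2)
  slope <- sxy / sxx
  intercept <- mean(amplitude) - slope * mean(covariate)
  r <- sxy / sqrt(sxx * sum((amplitude - mean(amplitude))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(slope = slope, intercept = intercept, r = r,
       p = 2 * pt(-abs(t), n - 2), n = n)
}

#' Sensor-level analysis of a cohort of ERP datasets
#'
#' Computes, per dataset, the mismatch-negativity waveform (deviant minus
#' standard, first spatial mode) and its mean amplitude in the
#' 140-160 ms window.
#'
#' @param datasets list of `erp_dataset`s
#' @param mode spatial mode used for the summary amplitude (default 1)
#' @param lo,hi amplitude window (ms)
#' @return data.frame(subject, session, amplitude)
#' @export
sensor_amplitudes <- function(datasets, mode = 1, lo = 140, hi = 160) {
  rows <- lapply(datasets, function(d) {
    w <- mmn_waveform(d$deviant[, mode], d$standard[, mode])
    data.frame(subject = d$subject, session = d$session,
               amplitude = window_mean(w, d$time, lo, hi),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
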