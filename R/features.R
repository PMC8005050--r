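#' Per-axis moment features
#'
#' For one axis of one burst: arithmetic mean, sample standard deviation
#' (n-1 denominator), inverse coefficient of variation (mean/sd), excess
#' kurtosis and skewness (plain moment estimators, no small-sample bias
#' correction; a Gaussian has kurtosis 0). A zero-variance burst yields
#' sentinel values instead of infinities so downstream tree models stay
#' usable: ICV becomes `sign(mean) * 1e9`, skewness and kurtosis 0.
#'
#' @param values numeric vector, length >= 5.
#' @return named numeric `c(mean, sd, icv, kurtosis, skewness)`.
#' @export
axis_moments <- function(values) {
  n <- length(values)
  if (n < 5) stop("axis_moments requires at least 5 samples, got ", n)
  m <- mean(values)
  s <- stats::sd(values)
  if (s == 0)
    return(c(mean = m, sd = 0, icv = sign(m) * 1e9, kurtosis = 0,
             skewness = 0))
  d <- values - m
  m2 <- mean(d^2)
  c(mean = m, sd = s, icv = m / s,
    kurtosis = mean(d^4) / m2^2 - 3,
    skewness = mean(d^3) / m2^(3 / 2))
}

#' Amplitude-weighted mean frequency of a burst
#'
#' The weighted mean of the discrete Fourier magnitude spectrum of the
#' mean-removed sequence: `sum(f_k * A_k) / sum(A_k)` over the positive
#' frequency bins `f_k = k * rate / n`, `k = 1..floor(n/2)`. The DC bin is
#' excluded (with it, the statistic would merely duplicate the per-axis
#' mean). Only meaningful for fixed-length bursts: the value depends on the
#' burst length, which is why the continuous device's variable-length
#' sections omit it. A constant input has an all-zero spectrum and returns
#' the sentinel 0 (outside the valid open interval `(0, rate/2]`).
#'
#' @param values numeric vector, length >= 5.
#' @param sample_rate sampling rate in Hz.
#' @return weighted mean frequency in Hz.
#' @export
weighted_mean_frequency <- function(values, sample_rate) {
  n <- length(values)
  if (n < 5) stop("weighted_mean_frequency requires at least 5 samples")
  amp <- Mod(stats::fft(values - mean(values)))
  k <- seq_len(floor(n / 2))
  a <- amp[k + 1]
  if (sum(a) == 0) return(0)
  f <- k * sample_rate / n
  sum(f * a) / sum(a)
}

#' Combined three-axis features: q, pitch and roll
#'
#' `q` is the burst mean of the per-sample Euclidean norm
#' `sqrt(sway^2 + surge^2 + heave^2)`. Pitch and roll follow the static-
#' gravity convention for a sensor whose heave axis carries -/+1 g at rest:
#' `pitch = atan2(-mean(surge), sqrt(mean(sway)^2 + mean(heave)^2))` and
#' `roll = atan2(mean(sway), mean(heave))`, in radians. Raw counts are
#' unit-free, so the device's zero-g count offset is subtracted first
#' (`zero_offset`, 2048 for the burst device, 0 for the continuous one);
#' both devices then share one formula on the semantic axes.
#'
#' @param sway,surge,heave equal-length numeric vectors.
#' @param zero_offset raw count corresponding to 0 g.
#' @return named numeric `c(q, pitch, roll)`.
#' @export
combined_features <- function(sway, surge, heave, zero_offset = 0) {
  stopifnot(length(sway) == length(surge), length(surge) == length(heave),
            length(sway) >= 5)
  sw <- sway - zero_offset
  su <- surge - zero_offset
  he <- heave - zero_offset
  c(q = mean(sqrt(sw^2 + su^2 + he^2)),
    pitch = atan2(-mean(su), sqrt(mean(sw)^2 + mean(he)^2)),
    roll = atan2(mean(sw), mean(he)))
}

feature_names <- function(mode) {
  ax <- c("sway", "surge", "heave")
  nm <- c(paste0("mn_", ax), paste0("sd_", ax), paste0("icv_", ax))
  if (mode == "burst") nm <- c(nm, paste0("wm_", ax))
  c(nm, paste0("kurt_", ax), paste0("skew_", ax), "q", "pitch", "roll")
}

#' Per-burst predictor vector
#'
#' Assembles the full predictor set for one burst: per-axis mean, sd and
#' inverse coefficient of variation, (burst mode only) spectral weighted mean
#' frequency, per-axis excess kurtosis and skewness, and the combined q,
#' pitch and roll — 21 named entries for fixed-length bursts, 18 for
#' variable-length continuous sections (no `wm_*`).
#'
#' @param burst an [acc_burst()] of length >= 5.
#' @param spec the `device_spec` the burst came from (mode, sample rate and
#'   zero-g offset).
#' @return named numeric of length 21 (burst) or 18 (continuous).
#' @export
feature_vector <- function(burst, spec) {
  if (burst_length(burst) < 5)
    stop("burst too short for feature extraction (need >= 5 samples)")
  ax <- c(sway = "sway", surge = "surge", heave = "heave")
  mom <- lapply(ax, function(a) axis_moments(burst[[a]]))
  out <- c(vapply(mom, `[[`, 0, "mean"), vapply(mom, `[[`, 0, "sd"),
           vapply(mom, `[[`, 0, "icv"))
  if (spec$mode == "burst")
    out <- c(out, vapply(ax, function(a)
      weighted_mean_frequency(burst[[a]], spec$sample_rate), 0))
  out <- c(out, vapply(mom, `[[`, 0, "kurtosis"),
           vapply(mom, `[[`, 0, "skewness"),
           combined_features(burst$sway, burst$surge, burst$heave,
                             zero_offset = spec$zero_offset))
  stats::setNames(out, feature_names(spec$mode))
}

#' Feature table for a dataset
#'
#' One row per burst: `individual`, `burst_id`, `label`, then the 21 or 18
#' named predictors. Continuous sections shorter than `min_length` samples
#' are discarded with a message (moment and spectral features degenerate on
#' tiny sections).
#'
#' @param dataset an `acc_dataset` (or plain list of labeled bursts).
#' @param spec the `device_spec`.
#' @param min_length minimum samples per burst (default 5).
#' @return data frame of features.
#' @export
feature_table <- function(dataset, spec, min_length = 5) {
  bursts <- if (inherits(dataset, "acc_dataset")) dataset$bursts else dataset
  lens <- vapply(bursts, burst_length, 0L)
  if (any(lens < min_length)) {
    message(sum(lens < min_length), " section(s) shorter than ", min_length,
            " samples discarded")
    bursts <- bursts[lens >= min_length]
  }
  if (!length(bursts)) stop("no bursts long enough for feature extraction")
  feats <- t(vapply(bursts, feature_vector, spec = spec,
                    FUN.VALUE = numeric(length(feature_names(spec$mode)))))
  out <- data.frame(
    individual = vapply(bursts, `[[`, "", "individual"),
    burst_id = paste(vapply(bursts, `[[`, "", "individual"),
                     sprintf("%.3f", vapply(bursts, `[[`, 0, "start_time")),
                     sep = "@"),
    label = vapply(bursts, `[[`, "", "label"),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(feats))
}
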