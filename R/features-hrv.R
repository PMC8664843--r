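# Moment helpers. Population conventions throughout: standard deviations
# divide by n, skewness is m3/m2^(3/2), kurtosis is m4/m2^2 (normal -> 3,
# not excess-adjusted); degenerate (zero-variance) inputs yield 0.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

skewness_pop <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

kurtosis_pop <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2
}

# Shannon entropy in bits of a fixed-width histogram
hist_entropy <- function(x, bin_width) {
  if (!length(x)) return(NA_real_)
  if (bin_width <= 0 || diff(range(x)) == 0) return(0)
  bins <- floor((x - min(x)) / bin_width)
  p <- tabulate(bins + 1L)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

# Freedman-Diaconis bin width (entropy of interval statistics)
fd_bin_width <- function(x) {
  iqr <- stats::IQR(x)
  if (iqr == 0) return(0)
  2 * iqr / length(x)^(1 / 3)
}

eight_stats <- function(x) {
  c(mean = mean(x), median = median(x), std = sd_pop(x),
    sk = skewness_pop(x), ku = kurtosis_pop(x),
    entropy = hist_entropy(x, fd_bin_width(x)), min = min(x), max = max(x))
}

#' Extract the NN interval series from a fiducial table
#'
#' The normal-to-normal (NN) interval is the spacing between consecutive J
#' peaks on the designated GCG axis (Y by default). Intervals that would
#' bridge an invalid or missing beat, or span two different chunks, are
#' dropped rather than interpolated.
#'
#' @param fiducials A fiducial table from [annotate_chunk()] (possibly
#'   row-bound over many chunks).
#' @param config A [cm_config()] (`nn_axis`).
#' @return Numeric vector of NN intervals in ms (possibly empty).
#' @export
nn_series <- function(fiducials, config = cm_config()) {
  config <- as_cm_config(config)
  sel <- fiducials$axis == config$nn_axis & fiducials$valid
  if (sum(sel) < 2) return(numeric())
  nn <- unlist(lapply(split(seq_len(nrow(fiducials))[sel],
                            fiducials$chunk_ref[sel]), function(idx) {
    idx <- idx[order(fiducials$beat[idx])]
    ok <- diff(fiducials$beat[idx]) == 1L
    (diff(fiducials$t_J[idx]) * 1000)[ok]
  }), use.names = FALSE)
  nn
}

#' Time-domain HRV features of an NN series
#'
#' Computes the 15 time-domain descriptors: AVNN, SDNN, RMSSD, pNN50, NN
#' median/skewness/kurtosis, the entropy family (ENN, SENN, CENN), the
#' Poincare-map indices VAI and VLI, and SD1, SD2, SD1/SD2.
#'
#' The Poincare map scatters `NN_{i+1}` against `NN_i` (B points for B+1
#' intervals). VAI is the mean absolute deviation of the point angles from
#' the 45-degree identity line; VLI the root-mean-square deviation of the
#' point distances from their mean distance. SD1 and SD2 follow the published
#' formulas verbatim: `SD1 = std(|NN_{i+1}-NN_i| / sqrt(2))` and SD2 the same
#' expression shifted by the constant `2*AVNN` - which, std being
#' shift-invariant, makes the printed SD2 identical to SD1. The
#' `sd2_convention = "conventional"` switch substitutes the usual long-axis
#' statistic `std((NN_{i+1}+NN_i)/sqrt(2))`.
#'
#' ENN is the Shannon entropy (bits) of the NN histogram at fixed bin width
#' `nn_bin_ms`; SENN is the self-entropy (mutual information) between
#' consecutive intervals, and CENN the conditional entropy of `NN_{i+1}`
#' given `NN_i`, both computed from the same binned joint distribution, so
#' that marginal entropy of `NN_{i+1}` = SENN + CENN exactly.
#'
#' pNN50 divides the count of successive differences over 50 ms by the total
#' number of NN intervals (as published); set `pnn50_denominator = "diffs"`
#' for the conventional denominator.
#'
#' @param nn Numeric NN series in ms (length >= 3).
#' @param config A [cm_config()].
#' @return Named numeric vector of 15 features (`*_time`); `SD1_SD2_time` is
#'   `NA` when SD2 is 0 (flagged missing, resolved by the imputation policy).
#' @export
time_hrv_features <- function(nn, config = cm_config()) {
  config <- as_cm_config(config)
  stopifnot(length(nn) >= 3, all(nn > 0))
  d <- diff(nn)
  nn50 <- sum(abs(d) > 50)
  denom <- if (config$pnn50_denominator == "total") length(nn) else length(d)
  x <- nn[-length(nn)]
  y <- nn[-1]
  theta <- atan(y / x) * 180 / pi
  l <- sqrt(x^2 + y^2)
  sd1 <- sd_pop(abs(d) / sqrt(2))
  sd2 <- if (config$sd2_convention == "as_printed") {
    sd_pop(abs(d) / sqrt(2) - 2 * mean(nn))
  } else {
    sd_pop((x + y) / sqrt(2))
  }
  bw <- config$nn_bin_ms
  # joint binning shared by ENN / SENN / CENN
  bx <- floor((x - min(nn)) / bw)
  by <- floor((y - min(nn)) / bw)
  joint <- table(bx, by) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  h_joint <- ent(as.numeric(joint))
  senn <- ent(px) + ent(py) - h_joint # mutual information
  cenn <- h_joint - ent(px)           # conditional entropy H(y | x)
  c(
    AVNN_time = mean(nn),
    SDNN_time = sd_pop(nn),
    RMSSD_time = sqrt(mean(d^2)),
    pNN50_time = nn50 / denom,
    NN_med_time = median(nn),
    NN_sk_time = skewness_pop(nn),
    NN_ku_time = kurtosis_pop(nn),
    ENN_time = hist_entropy(nn, bw),
    SENN_time = senn,
    CENN_time = cenn,
    VAI_time = mean(abs(theta - 45)),
    VLI_time = sqrt(mean((l - mean(l))^2)),
    SD1_time = sd1,
    SD2_time = sd2,
    SD1_SD2_time = if (sd2 == 0) NA_real_ else sd1 / sd2
  )
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-detrended segment averaging with one-sided density
#' scaling, so that the integral of the PSD over frequency matches the signal
#' variance (Parseval).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param segment_s Segment length in seconds (truncated to the signal).
#' @param overlap Segment overlap fraction.
#' @return A tibble with columns `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, segment_s = 120, overlap = 0.5) {
  nper <- min(length(x), round(segment_s * fs))
  stopifnot(nper >= 8)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  step <- max(1L, floor(nper * (1 - overlap)))
  starts <- seq(1L, length(x) - nper + 1L, by = step)
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  scale <- 1 / (fs * sum(w^2))
  for (s in starts) {
    seg <- x[s:(s + nper - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg)[seq_len(nfreq)])^2 * scale
    p[2:(nfreq - 1L)] <- 2 * p[2:(nfreq - 1L)]
    if (nper %% 2 == 1) p[nfreq] <- 2 * p[nfreq]
    acc <- acc + p
  }
  tibble::tibble(freq = (seq_len(nfreq) - 1) * fs / nper,
                 psd = acc / length(starts))
}

trapz_band <- function(freq, psd, lo, hi) {
  keep <- freq >= lo & freq <= hi
  if (sum(keep) < 2) return(0)
  f <- freq[keep]
  p <- psd[keep]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Frequency-domain HRV features of a recording
#'
#' Per axis, the band powers of the very-low-frequency (0.0033-0.04 Hz),
#' low-frequency (0.04-0.15 Hz) and high-frequency (0.15-0.4 Hz) bands, the
#' LF/HF ratio, and the total spectral power, estimated by [welch_psd()] on
#' the raw (pre-band-pass) signal over artifact-free runs. Runs shorter than
#' two Welch segments cannot support the estimate; if no run qualifies the
#' axis' five features are returned as `NA` (flagged missing) with a warning.
#'
#' @param rec A [recording()].
#' @param mask An [artifact_mask()] for `rec`.
#' @param config A [cm_config()] (`welch_segment_s`, `welch_overlap`, band
#'   edges).
#' @return Named numeric vector of 30 features
#'   (`{vlf,lf,hf}_HRV_{AXIS}_freq`, `lfhfRatio_{AXIS}_freq`,
#'   `TotalPow_{AXIS}_freq` for the six axes).
#' @export
freq_hrv_features <- function(rec, mask, config = cm_config()) {
  config <- as_cm_config(config)
  runs <- mask_runs(mask)
  min_len <- 2 * round(config$welch_segment_s * rec$fs)
  runs <- runs[runs$end_idx - runs$start_idx + 1L >= min_len, , drop = FALSE]
  out <- c()
  warned <- FALSE
  for (ch in CHANNELS_IMU) {
    ax <- toupper(sub("gyr", "gcg", sub("acc", "scg", ch)))
    nm <- paste0(c("vlf_HRV_", "lf_HRV_", "hf_HRV_", "lfhfRatio_", "TotalPow_"),
                 ax, "_freq")
    if (nrow(runs) == 0) {
      if (!warned) {
        warning("no artifact-free run spans two Welch segments (",
                config$welch_segment_s, " s); frequency-HRV features flagged ",
                "missing", call. = FALSE)
        warned <- TRUE
      }
      out <- c(out, setNames(rep(NA_real_, 5), nm))
      next
    }
    acc <- NULL
    wts <- 0
    for (r in seq_len(nrow(runs))) {
      seg <- rec$samples[[ch]][runs$start_idx[r]:runs$end_idx[r]]
      p <- welch_psd(seg, rec$fs, config$welch_segment_s, config$welch_overlap)
      wt <- length(seg)
      acc <- if (is.null(acc)) p$psd * wt else acc + p$psd * wt
      wts <- wts + wt
      freq <- p$freq
    }
    psd <- acc / wts
    vlf <- trapz_band(freq, psd, config$vlf_band[1], config$vlf_band[2])
    lf <- trapz_band(freq, psd, config$lf_band[1], config$lf_band[2])
    hf <- trapz_band(freq, psd, config$hf_band[1], config$hf_band[2])
    tot <- trapz_band(freq, psd, config$vlf_band[1], rec$fs / 2)
    out <- c(out, setNames(c(vlf, lf, hf,
                             if (hf > 0) lf / hf else NA_real_, tot), nm))
  }
  out
}
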