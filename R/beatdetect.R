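#' Per-sample RMS fusion of three axes
#'
#' Combines the three axes of a modality into its resultant vector:
#' the per-sample square root of the mean of squares across channels.
#'
#' @param channels Numeric matrix or data frame with exactly 3 same-length
#'   columns.
#' @return Numeric vector.
#' @export
axis_rms_fuse <- function(channels) {
  m <- as.matrix(channels)
  if (ncol(m) != 3) stop("exactly 3 channels required", call. = FALSE)
  sqrt(rowMeans(m^2))
}

#' Hilbert-transform amplitude envelope
#'
#' Magnitude of the analytic signal (computed via the FFT construction of the
#' Hilbert transform), optionally smoothed by a zero-phase low-pass filter to
#' remove abrupt changes.
#'
#' @param x Numeric signal (length >= 4).
#' @param fs Sampling rate in Hz.
#' @param smooth_hz Low-pass cut-off in Hz for the smoothing stage; `NULL`
#'   skips smoothing.
#' @param order Low-pass filter order (default 2).
#' @return Numeric envelope, same length as `x` (nonnegative before
#'   smoothing).
#' @export
hilbert_envelope <- function(x, fs, smooth_hz = 2, order = 2) {
  n <- length(x)
  stopifnot(n >= 4)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  analytic <- fft(X * h, inverse = TRUE) / n
  env <- Mod(analytic)
  if (!is.null(smooth_hz)) {
    env <- lowpass(env, fs, smooth_hz, order)
  }
  env
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer())
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

local_minima <- function(x) local_maxima(-x)

#' Adaptive dual-threshold peak picking (Pan-Tompkins style)
#'
#' Tracks running signal (SPK) and noise (NPK) peak levels with exponential
#' updates; a candidate local maximum is accepted as a beat when it exceeds
#' `NPK + frac * (SPK - NPK)` and lies outside the refractory period. When no
#' beat has been found for `searchback` times the running beat interval, the
#' largest rejected candidate in the gap exceeding half the threshold is
#' accepted retrospectively.
#'
#' @param e Nonnegative detection signal (e.g. a fused envelope).
#' @param fs Sampling rate in Hz.
#' @param refractory_s Minimum beat spacing in seconds.
#' @param alpha Exponential update weight for the accepted level (classical
#'   0.125).
#' @param frac Threshold interpolation fraction between NPK and SPK
#'   (classical 0.25).
#' @param searchback Search-back trigger as a multiple of the running beat
#'   interval (classical 1.66).
#' @return Integer vector of accepted peak indices.
#' @export
adaptive_peaks <- function(e, fs, refractory_s = 0.3, alpha = 0.125,
                           frac = 0.25, searchback = 1.66) {
  cand <- local_maxima(e)
  if (!length(cand)) return(integer())
  # learning phase: initialize levels from the first two seconds
  init_n <- min(length(e), round(2 * fs))
  spk <- max(e[seq_len(init_n)])
  npk <- mean(e[seq_len(init_n)])
  refractory <- round(refractory_s * fs)
  beats <- integer()
  rr <- numeric()
  pending <- integer() # rejected candidates since the last beat
  for (c in cand) {
    thr <- npk + frac * (spk - npk)
    if (length(beats) && (c - beats[length(beats)]) < refractory) next
    if (e[c] >= thr) {
      beats <- c(beats, c)
      spk <- alpha * e[c] + (1 - alpha) * spk
      pending <- integer()
    } else {
      npk <- alpha * e[c] + (1 - alpha) * npk
      pending <- c(pending, c)
      # search-back for a missed beat
      if (length(beats) >= 2) {
        rr <- diff(beats)
        rr_avg <- mean(tail(rr, 8))
        gap <- c - beats[length(beats)]
        if (gap > searchback * rr_avg && length(pending)) {
          ok <- pending[e[pending] >= thr / 2 &
                          (pending - beats[length(beats)]) >= refractory]
          if (length(ok)) {
            back <- ok[which.max(e[ok])]
            beats <- sort(c(beats, back))
            spk <- 0.25 * e[back] + 0.75 * spk
            pending <- pending[pending > back]
          }
        }
      }
    }
  }
  beats
}

#' Detect heartbeats in a clean chunk
#'
#' The three SCG axes and the three GCG axes are each RMS-fused into
#' resultant vectors; each resultant's Hilbert envelope is smoothed by a 2-Hz
#' low-pass, normalized by its own median (so neither modality's physical
#' units dominate), and the two normalized envelopes are summed. Beats are
#' the adaptive-threshold peaks of the summed envelope; each beat is then
#' refined per axis to the signed local maximum of the band-passed axis
#' signal within a 50-ms window centred on the fused peak.
#'
#' @param chunk A `cm_chunk` from [segment_chunks()].
#' @param config A [cm_config()].
#' @return An object of class `cm_beats`: `fused_peak_times` (s, absolute),
#'   `per_axis` (tibble: beat, axis, time), `usable` (FALSE when fewer than
#'   2 beats were found), `chunk_start`, `fs`. Unusable chunks are excluded
#'   downstream rather than raising.
#' @export
detect_beats <- function(chunk, config = cm_config()) {
  config <- as_cm_config(config)
  fs <- chunk$fs
  env_scg <- hilbert_envelope(axis_rms_fuse(chunk$samples[SCG_AXES]), fs,
                              config$envelope_lp_hz, config$envelope_lp_order)
  env_gcg <- hilbert_envelope(axis_rms_fuse(chunk$samples[GCG_AXES]), fs,
                              config$envelope_lp_hz, config$envelope_lp_order)
  norm_env <- function(env) {
    m <- median(env)
    if (m <= 0) m <- mean(abs(env)) + .Machine$double.eps
    env / m
  }
  e <- pmax(norm_env(env_scg), 0) + pmax(norm_env(env_gcg), 0)
  peaks <- adaptive_peaks(e, fs, config$refractory_s, config$pt_alpha,
                          config$pt_threshold_frac, config$pt_searchback_factor)
  usable <- length(peaks) >= 2
  half <- round(config$refine_halfwindow_s * fs)
  per_axis <- NULL
  if (usable) {
    rows <- list()
    for (axis in CHANNELS_IMU) {
      sig <- chunk$samples[[axis]]
      t_ax <- vapply(peaks, function(p) {
        lo <- max(1L, p - half)
        hi <- min(length(sig), p + half)
        (lo + which.max(sig[lo:hi]) - 2L) / fs + chunk$start_time
      }, numeric(1))
      rows[[axis]] <- tibble::tibble(
        beat = seq_along(peaks),
        axis = sub("gyr", "gcg", sub("acc", "scg", axis)),
        time = t_ax
      )
    }
    per_axis <- dplyr::bind_rows(rows)
  }
  structure(
    list(fused_peak_times = (peaks - 1L) / fs + chunk$start_time,
         per_axis = per_axis, usable = usable,
         chunk_start = chunk$start_time, fs = fs),
    class = "cm_beats"
  )
}

#' Match detected beats against reference beat times
#'
#' Greedy one-to-one nearest matching within a tolerance, yielding the
#' recall/precision of detection and the timing error of the matched beats.
#'
#' @param detected Numeric vector of detected beat times (s).
#' @param reference Numeric vector of reference beat times (s).
#' @param tol_s Matching tolerance in seconds (default 0.15).
#' @return A list: `recall`, `precision`, `mean_abs_error_s`, `matches`
#'   (tibble with `detected`, `reference`, `error_s`).
#' @export
beat_detection_scores <- function(detected, reference, tol_s = 0.15) {
  used <- rep(FALSE, length(reference))
  rows <- list()
  for (t in sort(detected)) {
    d <- abs(reference - t)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol_s) {
      used[j] <- TRUE
      ref_j <- reference[j]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        detected = t, reference = ref_j, error_s = t - ref_j)
    }
  }
  matches <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(detected = numeric(), reference = numeric(),
                   error_s = numeric())
  list(
    recall = if (length(reference)) nrow(matches) / length(reference) else NA_real_,
    precision = if (length(detected)) nrow(matches) / length(detected) else NA_real_,
    mean_abs_error_s = if (nrow(matches)) mean(abs(matches$error_s)) else NA_real_,
    matches = matches
  )
}
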