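#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the stated order and applies it
#' forward-backward (zero phase), so fiducial times are not skewed by group
#' delay; the effective attenuation order doubles.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Cut-off frequencies in Hz, `0 < lo < hi < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, lo, hi, order = 4) {
  if (!(lo > 0 && hi > lo && hi < fs / 2)) {
    stop("require 0 < lo < hi < fs/2 (Nyquist)", call. = FALSE)
  }
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  # the pass-band excludes DC, so demeaning changes nothing in the ideal
  # response while removing most of the cold-start transient
  reflect_filtfilt(bf, x - mean(x), n_pad = round(3 * fs / lo))
}

# forward-backward filtering with odd-reflection padding, which suppresses
# the start/end transients of a cold-started IIR filter
reflect_filtfilt <- function(bf, x, n_pad) {
  n <- length(x)
  np <- min(n - 1L, n_pad)
  if (np < 1) return(as.numeric(signal::filtfilt(bf, x)))
  pre <- 2 * x[1] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- as.numeric(signal::filtfilt(bf, c(pre, x, post)))
  y[(np + 1L):(np + n)]
}

#' Zero-phase Butterworth low-pass filter
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param hi Cut-off frequency in Hz.
#' @param order Filter order (default 2).
#' @return Filtered signal, same length as `x`.
#' @export
lowpass <- function(x, fs, hi, order = 2) {
  stopifnot(hi > 0, hi < fs / 2)
  bf <- signal::butter(order, hi / (fs / 2), type = "low")
  reflect_filtfilt(bf, x, n_pad = round(3 * fs / hi))
}

#' Band-pass all channels of a recording
#'
#' SCG (accelerometer) channels get the wider band, GCG (gyroscope) channels
#' the narrower one, as appropriate for their spectral content.
#'
#' @param rec A [recording()].
#' @param config A [cm_config()] (`scg_band`, `gcg_band`, `filter_order`).
#' @return A tibble of filtered IMU channels.
#' @export
bandpass_recording <- function(rec, config = cm_config()) {
  config <- as_cm_config(config)
  out <- rec$samples[CHANNELS_IMU]
  for (ch in SCG_AXES) {
    out[[ch]] <- bandpass(out[[ch]], rec$fs, config$scg_band[1],
                          config$scg_band[2], config$filter_order)
  }
  for (ch in GCG_AXES) {
    out[[ch]] <- bandpass(out[[ch]], rec$fs, config$gcg_band[1],
                          config$gcg_band[2], config$filter_order)
  }
  out
}

#' Centred moving root-mean-square
#'
#' Sliding-window RMS with the window truncated at the edges, so the output
#' has the same length as the input.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param M Window length in ms (must be at least 2 samples and no longer
#'   than the signal).
#' @return Numeric vector of per-sample RMS values.
#' @export
moving_rms <- function(x, fs, M) {
  w <- round(M / 1000 * fs)
  if (w < 2) stop("RMS window must span at least 2 samples", call. = FALSE)
  if (w > length(x)) stop("RMS window longer than the signal", call. = FALSE)
  n <- length(x)
  cs <- cumsum(c(0, x^2))
  half_lo <- floor((w - 1) / 2)
  half_hi <- ceiling((w - 1) / 2)
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Motion-artifact mask from the sliding RMS of the resultant signal
#'
#' The six band-passed channels are combined into a per-sample resultant
#' magnitude (root mean square across channels); its sliding RMS over an
#' `M`-ms window is compared against a removal threshold of twice its median.
#' Samples above the threshold are masked on all channels jointly; samples
#' exactly at the threshold are kept. Masked-out regions are never spliced:
#' downstream chunking treats each clean run separately.
#'
#' @param rec A [recording()].
#' @param M RMS window length in ms (default from `config$rms_window_ms`).
#' @param config A [cm_config()].
#' @return An object of class `cm_mask`: list with `keep` (logical vector),
#'   `rms`, `threshold`, `M`.
#' @export
artifact_mask <- function(rec, M = NULL, config = cm_config()) {
  config <- as_cm_config(config)
  if (is.null(M)) M <- config$rms_window_ms
  filt <- bandpass_recording(rec, config)
  resultant <- sqrt(rowMeans(as.matrix(filt)^2))
  r <- moving_rms(resultant, rec$fs, M)
  thr <- config$artifact_threshold_factor * median(r)
  structure(
    list(keep = r <= thr, rms = r, threshold = thr, M = M),
    class = "cm_mask"
  )
}

#' Maximal artifact-free runs of a mask
#' @param mask A `cm_mask` (or logical vector).
#' @return Tibble with columns `start_idx`, `end_idx` (1-based, inclusive).
#' @export
mask_runs <- function(mask) {
  keep <- if (inherits(mask, "cm_mask")) mask$keep else mask
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start_idx = starts[r$values], end_idx = ends[r$values])
}

#' Segment a recording into fixed-length artifact-free chunks
#'
#' Within each maximal clean run, `N`-second windows are tiled from the run's
#' start with stride `N * (1 - overlap)`; runs shorter than `N` seconds yield
#' nothing and trailing partial windows are discarded. Chunks never contain a
#' masked sample.
#'
#' @param rec A [recording()].
#' @param mask An [artifact_mask()] for `rec`.
#' @param N Chunk length in seconds.
#' @param overlap Fraction in `[0, 1)`: 0 for the detection task, 0.5 for the
#'   severity task.
#' @param config A [cm_config()] (supplies the band-pass settings used to
#'   produce the chunk's filtered channels).
#' @return A list of `cm_chunk` objects: `samples` (filtered channels),
#'   `raw` (unfiltered channels), `start_time` (s), `fs`, `subject_id`, `N`.
#' @export
segment_chunks <- function(rec, mask, N = NULL, overlap = NULL,
                           config = cm_config()) {
  config <- as_cm_config(config)
  if (is.null(N)) N <- config$chunk_s
  if (is.null(overlap)) overlap <- config$overlap
  stopifnot(N > 0, overlap >= 0, overlap < 1)
  filt <- bandpass_recording(rec, config)
  runs <- mask_runs(mask)
  len <- floor(N * rec$fs)
  stride <- max(1L, round(len * (1 - overlap)))
  chunks <- list()
  for (r in seq_len(nrow(runs))) {
    s0 <- runs$start_idx[r]
    s1 <- runs$end_idx[r]
    if (s1 - s0 + 1L < len) next
    starts <- seq(s0, s1 - len + 1L, by = stride)
    for (st in starts) {
      idx <- st:(st + len - 1L)
      chunks[[length(chunks) + 1L]] <- structure(
        list(samples = filt[idx, ], raw = rec$samples[idx, CHANNELS_IMU],
             start_time = (st - 1L) / rec$fs, fs = rec$fs,
             subject_id = rec$subject_id, N = N),
        class = "cm_chunk"
      )
    }
  }
  chunks
}
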