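# fast core: returns c(t_A, t_I, t_J, t_K, t_L, t_P, MA, valid) as numerics
annotate_beat_core <- function(axis_signal, fs, j_time, window, t0, ik_w,
                               al_w) {
  to_idx <- function(t) round((t - t0) * fs) + 1L
  n <- length(axis_signal)
  w0 <- max(1L, to_idx(window[1]))
  w1 <- min(n, to_idx(window[2]))
  ji <- to_idx(j_time)
  out <- c(t_A = NA_real_, t_I = NA_real_, t_J = j_time, t_K = NA_real_,
           t_L = NA_real_, t_P = NA_real_, MA = NA_real_, valid = 0)
  if (ji <= w0 || ji >= w1) return(out)
  seg <- axis_signal[w0:w1]
  jn <- ji - w0 + 1L
  # fiducials are signed deflections: A and L are positive peaks, I and K
  # negative troughs; requiring the sign suppresses the small ripple
  # extrema a band-passed signal develops between distant fiducials
  maxima <- local_maxima(seg)
  maxima <- maxima[seg[maxima] > 0]
  minima <- local_minima(seg)
  minima <- minima[seg[minima] < 0]

  pick <- function(cands, lo, hi, side) {
    cands <- cands[cands >= lo & cands <= hi]
    if (!length(cands)) return(NA_integer_)
    if (side == "last") max(cands) else min(cands)
  }
  i_idx <- pick(minima, jn - ik_w, jn - 1L, "last")
  k_idx <- pick(minima, jn + 1L, jn + ik_w, "first")
  l_idx <- if (is.na(k_idx)) NA_integer_ else
    pick(maxima, k_idx + 1L, k_idx + al_w, "first")
  a_idx <- if (is.na(i_idx)) NA_integer_ else
    pick(maxima, i_idx - al_w, i_idx - 1L, "last")

  d <- abs(diff(seg)) * fs
  if (!length(d)) return(out)
  p_idx <- which.max(d)

  tt <- function(i) (w0 + i - 2L) / fs + t0
  t_a <- if (is.na(a_idx)) NA_real_ else tt(a_idx)
  t_i <- if (is.na(i_idx)) NA_real_ else tt(i_idx)
  t_k <- if (is.na(k_idx)) NA_real_ else tt(k_idx)
  t_l <- if (is.na(l_idx)) NA_real_ else tt(l_idx)
  t_p <- tt(p_idx) + 0.5 / fs # P sits between the two differenced samples
  if (anyNA(c(t_a, t_i, t_k, t_l)) ||
      !(t_a < t_i && t_i < j_time && j_time < t_k && t_k < t_l)) {
    return(out)
  }
  c(t_A = t_a, t_I = t_i, t_J = j_time, t_K = t_k, t_L = t_l, t_P = t_p,
    MA = max(d), valid = 1)
}

#' Annotate the fiducial points of one beat on one GCG axis
#'
#' Operates on the 1-10 Hz band-passed axis signal. Taking the per-axis
#' refined J peak as anchor: I is the nearest local minimum preceding J
#' within 150 ms; K the nearest local minimum following J within 150 ms; L
#' the first local maximum after K within 200 ms; A the last local maximum
#' before I within 200 ms. P is the point of maximum absolute first
#' difference (times `fs`, i.e. the maximum angular acceleration) within the
#' beat window, and MA is that maximum. A beat whose required extrema are
#' absent, or whose recovered times violate the ordering A < I < J < K < L,
#' is flagged invalid and excluded from features - never silently guessed.
#'
#' @param axis_signal Numeric 1-10 Hz filtered axis signal.
#' @param fs Sampling rate in Hz.
#' @param j_time J-peak time in seconds (sample 1 of `axis_signal` is at
#'   time `t0`).
#' @param window Numeric length-2 beat window `(start, end)` in seconds.
#' @param t0 Time of the first sample of `axis_signal` (default 0).
#' @param config A [cm_config()] (`ik_window_s`, `al_window_s`).
#' @return A one-row tibble: `t_A, t_I, t_J, t_K, t_L, t_P, MA, valid`; all
#'   times `NA` and `valid = FALSE` for an invalid beat.
#' @export
annotate_beat <- function(axis_signal, fs, j_time, window, t0 = 0,
                          config = cm_config()) {
  config <- as_cm_config(config)
  v <- annotate_beat_core(axis_signal, fs, j_time, window, t0,
                          round(config$ik_window_s * fs),
                          round(config$al_window_s * fs))
  row <- tibble::as_tibble(as.list(v[1:7]))
  row$valid <- v[["valid"]] == 1
  if (!row$valid) {
    row[c("t_A", "t_I", "t_K", "t_L", "t_P", "MA")] <- NA_real_
  }
  row
}

#' Annotate all beats of a chunk on both GCG axes
#'
#' Each GCG axis (X and Y) is band-passed to 1-10 Hz, then every detected
#' beat is annotated within a beat window spanning from 40% of the local
#' inter-beat interval before the J peak to 60% after it (the first beat
#' uses the following interval as surrogate), clipped to the chunk bounds.
#'
#' @param chunk A `cm_chunk`.
#' @param beats The `cm_beats` detected from this chunk.
#' @param config A [cm_config()].
#' @return A fiducial table tibble: `chunk_ref, beat, axis, t_A, t_I, t_J,
#'   t_K, t_L, t_P, MA, valid` (empty when the chunk was unusable).
#' @export
annotate_chunk <- function(chunk, beats, config = cm_config()) {
  config <- as_cm_config(config)
  empty <- tibble::tibble(
    chunk_ref = character(), beat = integer(), axis = character(),
    t_A = numeric(), t_I = numeric(), t_J = numeric(), t_K = numeric(),
    t_L = numeric(), t_P = numeric(), MA = numeric(), valid = logical()
  )
  if (!isTRUE(beats$usable)) return(empty)
  fs <- chunk$fs
  chunk_ref <- sprintf("%s@%.3f", chunk$subject_id, chunk$start_time)
  fused <- beats$fused_peak_times
  nb <- length(fused)
  ibi_prev <- diff(fused)
  ibi_local <- c(ibi_prev[1], ibi_prev) # first beat: following interval
  t_min <- chunk$start_time
  t_max <- chunk$start_time + (nrow(chunk$samples) - 1L) / fs
  ik_w <- round(config$ik_window_s * fs)
  al_w <- round(config$al_window_s * fs)
  mats <- list()
  for (ax in c("gcg_x", "gcg_y")) {
    raw_name <- sub("gcg", "gyr", ax)
    sig <- bandpass(chunk$raw[[raw_name]], fs, config$annot_band[1],
                    config$annot_band[2], config$filter_order)
    ax_times <- beats$per_axis$time[beats$per_axis$axis == ax]
    rows <- matrix(NA_real_, nb, 8)
    for (b in seq_len(nb)) {
      win <- c(max(t_min, fused[b] - config$beat_window_before * ibi_local[b]),
               min(t_max, fused[b] + config$beat_window_after * ibi_local[b]))
      rows[b, ] <- annotate_beat_core(sig, fs, ax_times[b], win,
                                      chunk$start_time, ik_w, al_w)
    }
    colnames(rows) <- c("t_A", "t_I", "t_J", "t_K", "t_L", "t_P", "MA",
                        "valid")
    mats[[ax]] <- rows
  }
  out <- dplyr::bind_rows(lapply(names(mats), function(ax) {
    m <- mats[[ax]]
    tibble::tibble(chunk_ref = chunk_ref, beat = seq_len(nb), axis = ax,
                   t_A = m[, 1], t_I = m[, 2], t_J = m[, 3], t_K = m[, 4],
                   t_L = m[, 5], t_P = m[, 6], MA = m[, 7],
                   valid = m[, 8] == 1)
  }))
  out
}
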