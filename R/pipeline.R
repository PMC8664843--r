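#' Run preprocessing, beat detection and annotation on one recording
#'
#' Applies the band-pass filters, builds the artifact mask with RMS window
#' `M`, tiles `N`-second chunks, detects beats in each chunk and annotates
#' the GCG fiducials.
#'
#' @param rec A [recording()].
#' @param M RMS window in ms (default `config$rms_window_ms`).
#' @param N Chunk length in seconds (default `config$chunk_s`).
#' @param overlap Chunk overlap fraction (default `config$overlap`).
#' @param config A [cm_config()].
#' @return A list: `mask`, `chunks`, `beats` (list per chunk), `fiducials`
#'   (list of per-chunk fiducial tables).
#' @export
process_recording <- function(rec, M = NULL, N = NULL, overlap = NULL,
                              config = cm_config()) {
  config <- as_cm_config(config)
  mask <- artifact_mask(rec, M, config)
  chunks <- segment_chunks(rec, mask, N, overlap, config)
  beats <- lapply(chunks, detect_beats, config = config)
  fiducials <- purrr::map2(chunks, beats, annotate_chunk, config = config)
  list(mask = mask, chunks = chunks, beats = beats, fiducials = fiducials)
}

# valid-beat fraction on the NN axis for one chunk's fiducial table
chunk_valid_fraction <- function(fid, config) {
  rows <- fid[fid$axis == config$nn_axis, ]
  if (!nrow(rows)) return(0)
  mean(rows$valid)
}

chunk_feature_row <- function(fid, config) {
  gcg <- gcg_interval_features(interval_block(fid))
  if (is.null(gcg)) return(NULL)
  nn <- nn_series(fid, config)
  manifest <- feature_manifest()
  time_names <- manifest$name[manifest$block == "time_hrv"]
  th <- if (length(nn) >= 3) time_hrv_features(nn, config) else
    setNames(rep(NA_real_, length(time_names)), time_names)
  c(gcg, th)
}

#' Extract chunk-level and subject-level feature matrices from a cohort
#'
#' Runs the full chain (filtering, artifact masking at RMS window `M`,
#' `N`-second chunking, beat detection, fiducial annotation, feature
#' computation) over a list of recordings.
#'
#' At chunk level every usable chunk is a sample carrying the 88 GCG interval
#' statistics and the 15 time-domain HRV features (103 columns; chunks are
#' too short for the spectral bands). At subject level each recording is one
#' sample: the GCG and time-HRV statistics pool all the subject's valid
#' beats and NN intervals (not averages of chunk features), and the 30
#' frequency-domain HRV features are added (133 columns).
#'
#' Chunks with fewer than half their beats valid on the NN axis, or fewer
#' than 3 valid fiducial rows, are excluded. Features uncomputable on a
#' sample are resolved per `config$impute_policy`.
#'
#' @param cohort A list of [recording()]s, or of `list(recording, truth)`
#'   pairs as returned by [generate_cohort()].
#' @param level `"chunk"` or `"subject"`.
#' @param M,N,overlap Filter/chunk parameters (default from `config`).
#' @param config A [cm_config()].
#' @return A [feature_matrix()]; its `subject_ids` attribute maps samples to
#'   subjects for leakage-safe splitting.
#' @export
extract_cohort_features <- function(cohort, level = c("chunk", "subject"),
                                    M = NULL, N = NULL, overlap = NULL,
                                    config = cm_config()) {
  level <- match.arg(level)
  config <- as_cm_config(config)
  recs <- lapply(cohort, function(x) if (inherits(x, "cm_recording")) x else x$recording)
  rows <- list()
  ids <- character()
  labels <- character()
  subjects <- character()
  manifest <- feature_manifest()
  for (rec in recs) {
    proc <- process_recording(rec, M, N, overlap, config)
    keep <- vapply(proc$fiducials, function(f) {
      nrow(f) > 0 && chunk_valid_fraction(f, config) >= config$min_valid_fraction
    }, logical(1))
    fids <- proc$fiducials[keep]
    if (level == "chunk") {
      for (fid in fids) {
        row <- chunk_feature_row(fid, config)
        if (is.null(row)) next
        rows[[length(rows) + 1L]] <- row
        ids <- c(ids, fid$chunk_ref[1])
        labels <- c(labels, rec$label)
        subjects <- c(subjects, rec$subject_id)
      }
    } else {
      pooled <- dplyr::bind_rows(fids)
      if (!nrow(pooled)) next
      gcg <- gcg_interval_features(interval_block(pooled))
      if (is.null(gcg)) next
      nn <- nn_series(pooled, config)
      time_names <- manifest$name[manifest$block == "time_hrv"]
      th <- if (length(nn) >= 3) time_hrv_features(nn, config) else
        setNames(rep(NA_real_, length(time_names)), time_names)
      fr <- suppressWarnings(freq_hrv_features(rec, proc$mask, config))
      rows[[length(rows) + 1L]] <- c(gcg, th, fr)
      ids <- c(ids, rec$subject_id)
      labels <- c(labels, rec$label)
      subjects <- c(subjects, rec$subject_id)
    }
  }
  if (!length(rows)) stop("no usable samples in cohort", call. = FALSE)
  vals <- tibble::as_tibble(do.call(rbind, rows))
  want <- if (level == "chunk") {
    manifest$name[manifest$block != "freq_hrv"]
  } else {
    manifest$name
  }
  stopifnot(identical(names(vals), want))
  fm <- feature_matrix(vals, sample_ids = ids, labels = labels,
                       subject_ids = subjects)
  impute_features(fm, config$impute_policy)
}
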