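#' Pipeline configuration
#'
#' Every numeric tunable of the pipeline lives in one flat named list so that
#' any stage can be re-parameterized from code or from a YAML file. Values not
#' supplied fall back to the defaults below.
#'
#' Key groups:
#' \describe{
#'   \item{Band-pass}{`scg_band` (Hz, default 1-45), `gcg_band` (Hz, default
#'     1-20), `annot_band` (Hz, 1-10, used before fiducial annotation),
#'     `filter_order` (Butterworth order 4, applied zero-phase so the
#'     effective order doubles).}
#'   \item{Artifact masking}{`rms_window_ms` (sliding RMS length M, 500 ms in
#'     the literature mode), `artifact_threshold_factor` (mask where the RMS
#'     exceeds this multiple of its median; 2).}
#'   \item{Chunking}{`chunk_s` (chunk length N in seconds, 10), `overlap`
#'     (fraction, 0 for the detection task, 0.5 for the severity task).}
#'   \item{Beat detection}{`envelope_lp_hz` (2 Hz, 2nd order), refractory
#'     period `refractory_s` (0.3 s), Pan-Tompkins update weight `pt_alpha`
#'     (0.125), threshold fraction `pt_threshold_frac` (0.25), search-back
#'     factor `pt_searchback_factor` (1.66), per-axis refinement half-window
#'     `refine_halfwindow_s` (0.025 s).}
#'   \item{Fiducial annotation}{search windows `ik_window_s` (0.15 s for I and
#'     K around J), `al_window_s` (0.2 s for A before I and L after K), beat
#'     window fractions `beat_window_before`/`beat_window_after` (0.4/0.6 of
#'     the local inter-beat interval around J), `min_valid_fraction` (chunks
#'     with fewer valid beats are dropped, 0.5).}
#'   \item{HRV}{`pnn50_denominator` ("total" as published, or "diffs"),
#'     `sd2_convention` ("as_printed" or "conventional"), `nn_bin_ms`
#'     (entropy bin width for NN, 1000/128 ms), `nn_axis` ("gcg_y").}
#'   \item{Frequency HRV}{`welch_segment_s` (120), `welch_overlap` (0.5),
#'     band edges `vlf_band`, `lf_band`, `hf_band` in Hz.}
#'   \item{Modeling}{`cv_folds` (10), `test_fraction` (0.2), `impute_policy`
#'     ("median" or "error").}
#'   \item{Filter optimization}{bounds `m_bounds_ms` (100-2000 ms) and
#'     `n_bounds_s` (2-25 s), `bo_init_points` (8), `bo_budget` (40),
#'     `bo_candidate_pool` (512).}
#' }
#'
#' @param ... Named overrides of individual defaults.
#' @return A named list with class `cm_config`.
#' @examples
#' cfg <- cm_config(chunk_s = 11.2, overlap = 0.5)
#' cfg$chunk_s
#' @export
cm_config <- function(...) {
  defaults <- list(
    scg_band = c(1, 45),
    gcg_band = c(1, 20),
    annot_band = c(1, 10),
    filter_order = 4,
    rms_window_ms = 500,
    artifact_threshold_factor = 2,
    chunk_s = 10,
    overlap = 0,
    envelope_lp_hz = 2,
    envelope_lp_order = 2,
    refractory_s = 0.3,
    pt_alpha = 0.125,
    pt_threshold_frac = 0.25,
    pt_searchback_factor = 1.66,
    refine_halfwindow_s = 0.025,
    ik_window_s = 0.15,
    al_window_s = 0.20,
    beat_window_before = 0.4,
    beat_window_after = 0.6,
    min_valid_fraction = 0.5,
    nn_axis = "gcg_y",
    pnn50_denominator = "total",
    sd2_convention = "as_printed",
    nn_bin_ms = 1000 / 128,
    welch_segment_s = 120,
    welch_overlap = 0.5,
    vlf_band = c(0.0033, 0.04),
    lf_band = c(0.04, 0.15),
    hf_band = c(0.15, 0.4),
    cv_folds = 10,
    test_fraction = 0.2,
    impute_policy = "median",
    m_bounds_ms = c(100, 2000),
    n_bounds_s = c(2, 25),
    bo_init_points = 8,
    bo_budget = 40,
    bo_candidate_pool = 512
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown config entries: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  structure(defaults, class = "cm_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file holds a flat mapping of config names to values; unknown names are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cm_config` list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  do.call(cm_config, vals)
}

as_cm_config <- function(config) {
  if (inherits(config, "cm_config")) config else do.call(cm_config, as.list(config))
}
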