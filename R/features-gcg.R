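GCG_PARAMS <- c("IVCT", "LVET", "IVRT", "LI", "LJ", "KI", "PI", "PJ", "KP",
                "LP", "MA")
GCG_STATS <- c("mean", "median", "std", "sk", "ku", "entropy", "min", "max")
TIME_FEATURES <- c("AVNN_time", "SDNN_time", "RMSSD_time", "pNN50_time",
                   "NN_med_time", "NN_sk_time", "NN_ku_time", "ENN_time",
                   "SENN_time", "CENN_time", "VAI_time", "VLI_time",
                   "SD1_time", "SD2_time", "SD1_SD2_time")

#' Canonical feature manifest
#'
#' Enumerates the full feature space in canonical column order: 88 GCG
#' interval statistics (11 timing/amplitude parameters times 8 statistics),
#' 15 time-domain HRV features, and 30 frequency-domain HRV features (5 per
#' axis). Chunk-level matrices carry the first two blocks (103 columns);
#' subject-level matrices carry all three.
#'
#' @return A tibble with columns `name` and `block`
#'   (`"gcg"`, `"time_hrv"`, `"freq_hrv"`).
#' @examples
#' table(feature_manifest()$block)
#' @export
feature_manifest <- function() {
  gcg <- as.vector(t(outer(GCG_PARAMS, GCG_STATS,
                           function(p, s) paste0(p, "_", s, "_GCG"))))
  axes <- toupper(sub("gyr", "gcg", sub("acc", "scg", CHANNELS_IMU)))
  freq <- as.vector(vapply(axes, function(ax) {
    paste0(c("vlf_HRV_", "lf_HRV_", "hf_HRV_", "lfhfRatio_", "TotalPow_"),
           ax, "_freq")
  }, character(5)))
  tibble::tibble(
    name = c(gcg, TIME_FEATURES, freq),
    block = c(rep("gcg", length(gcg)), rep("time_hrv", length(TIME_FEATURES)),
              rep("freq_hrv", length(freq)))
  )
}

#' Per-beat GCG timing-interval block
#'
#' Converts valid fiducial rows into the 11 per-beat parameters: the three
#' physiological intervals IVCT (J-I), LVET (K-J), IVRT (L-K); the auxiliary
#' pairwise intervals L-I, L-J, K-I, P-I, P-J, K-P, L-P (all ms); and the MA
#' amplitude. The additive identity L-I = (L-K) + (K-J) + (J-I) holds by
#' construction.
#'
#' @param fiducials A fiducial table ([annotate_chunk()] output, possibly
#'   row-bound).
#' @return A tibble with columns `chunk_ref, beat, axis` and the 11
#'   parameters; invalid rows are excluded.
#' @export
interval_block <- function(fiducials) {
  rows <- dplyr::filter(fiducials, .data$valid)
  tibble::tibble(
    chunk_ref = rows$chunk_ref, beat = rows$beat, axis = rows$axis,
    IVCT = (rows$t_J - rows$t_I) * 1000,
    LVET = (rows$t_K - rows$t_J) * 1000,
    IVRT = (rows$t_L - rows$t_K) * 1000,
    LI = (rows$t_L - rows$t_I) * 1000,
    LJ = (rows$t_L - rows$t_J) * 1000,
    KI = (rows$t_K - rows$t_I) * 1000,
    PI = (rows$t_P - rows$t_I) * 1000,
    PJ = (rows$t_P - rows$t_J) * 1000,
    KP = (rows$t_K - rows$t_P) * 1000,
    LP = (rows$t_L - rows$t_P) * 1000,
    MA = rows$MA
  )
}

#' GCG interval statistics over a scope
#'
#' For each of the 11 parameters of [interval_block()], computes mean,
#' median, standard deviation, skewness, kurtosis, entropy
#' (Freedman-Diaconis binning), min and max over all valid (beat, axis) rows
#' in scope, both GCG axes pooled - 88 named features.
#'
#' @param block An [interval_block()] tibble (already restricted to the
#'   scope: one chunk, or all of a subject's beats).
#' @return Named numeric vector of 88 features, or `NULL` when fewer than 3
#'   valid rows are in scope (scope excluded).
#' @export
gcg_interval_features <- function(block) {
  if (nrow(block) < 3) return(NULL)
  out <- c()
  for (p in GCG_PARAMS) {
    st <- eight_stats(block[[p]])
    out <- c(out, setNames(st, paste0(p, "_", names(st), "_GCG")))
  }
  out
}
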