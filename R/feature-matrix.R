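#' Construct a feature matrix
#'
#' A feature matrix is a tibble with one row per sample (a signal chunk or a
#' subject), an identifier column `sample_id`, a `label` column, and one
#' numeric column per feature. Feature names follow the canonical scheme
#' `{param}_{stat}_GCG` for GCG interval statistics, `{name}_time` for
#' time-domain HRV, and `{band}_{AXIS}_freq` for frequency-domain HRV.
#'
#' @param values A data frame of numeric feature columns (may already contain
#'   `sample_id`/`label`, otherwise supply them separately).
#' @param sample_ids Character vector of unique sample identifiers.
#' @param labels Class labels aligned with `sample_ids`.
#' @param subject_ids Optional subject identifier per row (used by the
#'   leakage guard when samples are chunks).
#' @return A tibble of class `cm_features` with attribute `subject_ids`.
#' @export
feature_matrix <- function(values, sample_ids = values$sample_id,
                           labels = values$label,
                           subject_ids = attr(values, "subject_ids")) {
  force(sample_ids)
  force(labels)
  force(subject_ids)
  values <- tibble::as_tibble(values)
  values$sample_id <- NULL
  values$label <- NULL
  stopifnot(length(sample_ids) == nrow(values))
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids", call. = FALSE)
  if (anyDuplicated(names(values))) {
    stop("duplicate feature names", call. = FALSE)
  }
  if (!all(vapply(values, is.numeric, logical(1)))) {
    stop("all feature columns must be numeric", call. = FALSE)
  }
  out <- tibble::tibble(sample_id = as.character(sample_ids),
                        label = as.character(labels))
  out <- dplyr::bind_cols(out, values)
  attr(out, "subject_ids") <- if (is.null(subject_ids)) {
    as.character(sample_ids)
  } else {
    as.character(subject_ids)
  }
  class(out) <- c("cm_features", class(out))
  out
}

#' Names of the feature columns of a feature matrix
#' @param fm A [feature_matrix()].
#' @return Character vector (excludes `sample_id` and `label`).
#' @export
feature_names <- function(fm) setdiff(names(fm), c("sample_id", "label"))

feature_values <- function(fm) {
  as.matrix(fm[feature_names(fm)])
}

#' Write a feature matrix to CSV
#'
#' One row per sample, header row of feature names, label column last.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "cm_features"))
  if (anyDuplicated(fm$sample_id)) stop("duplicate sample_ids", call. = FALSE)
  out <- fm[c("sample_id", feature_names(fm), "label")]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path.
#' @return A [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(sample_id = "c", label = "c",
                                                 .default = "d"))
  feature_matrix(dat)
}

#' Impute or reject missing feature values
#'
#' Features can be uncomputable on a sample (too few beats for HRV, no clean
#' run long enough for spectral estimation). Assembly resolves these per an
#' explicit policy: `"median"` replaces missing entries by the per-column
#' median over the non-missing samples (0 if a column is entirely missing);
#' `"error"` raises.
#'
#' @param fm A [feature_matrix()] possibly containing `NA`.
#' @param policy `"median"` or `"error"`.
#' @return A complete `cm_features` with no `NA`.
#' @export
impute_features <- function(fm, policy = c("median", "error")) {
  policy <- match.arg(policy)
  feats <- feature_names(fm)
  n_missing <- sum(is.na(fm[feats]))
  if (n_missing == 0) return(fm)
  if (policy == "error") {
    stop(n_missing, " missing feature values and impute policy is 'error'",
         call. = FALSE)
  }
  for (f in feats) {
    col <- fm[[f]]
    if (anyNA(col)) {
      fill <- median(col, na.rm = TRUE)
      if (is.na(fill)) fill <- 0
      fm[[f]][is.na(col)] <- fill
    }
  }
  fm
}
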