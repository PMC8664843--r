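CHANNELS_IMU <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
SCG_AXES <- c("acc_x", "acc_y", "acc_z")
GCG_AXES <- c("gyr_x", "gyr_y", "gyr_z")
CLASS_LABELS <- c("healthy", "mild", "moderate", "severe")

#' Construct a 6-axis cardiomechanical recording
#'
#' A recording bundles synchronously sampled SCG (3-axis accelerometer) and
#' GCG (3-axis gyroscope) channels, an optional ECG reference channel, the
#' sampling rate and subject metadata. Channels are stored in the canonical
#' order `acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z[, ecg]` and all downstream
#' code addresses them by name. Time is measured in seconds from the start of
#' the recording.
#'
#' @param samples A data frame with one column per channel (a `time` column,
#'   if present, is validated against `fs` and dropped).
#' @param fs Sampling rate in Hz.
#' @param subject_id Opaque subject identifier.
#' @param label One of `"healthy"`, `"mild"`, `"moderate"`, `"severe"`, or
#'   `NA` for unlabeled data.
#' @param units Named character vector documenting channel units, e.g.
#'   `c(acc = "m/s^2", gyr = "deg/s")`.
#' @return An object of class `cm_recording`: a list with elements `samples`
#'   (tibble), `fs`, `subject_id`, `label`, `units`.
#' @examples
#' x <- tibble::tibble(
#'   acc_x = rnorm(512), acc_y = rnorm(512), acc_z = rnorm(512),
#'   gyr_x = rnorm(512), gyr_y = rnorm(512), gyr_z = rnorm(512)
#' )
#' rec <- recording(x, fs = 256, subject_id = "S01", label = "healthy")
#' n_samples(rec)
#' @export
recording <- function(samples, fs, subject_id = "unknown", label = NA_character_,
                      units = c(acc = "m/s^2", gyr = "deg/s")) {
  stopifnot(is.data.frame(samples), is.numeric(fs), fs > 0)
  samples <- tibble::as_tibble(samples)
  if ("time" %in% names(samples)) {
    tcol <- samples$time
    if (length(tcol) > 1) {
      dt <- diff(tcol)
      if (any(abs(dt - 1 / fs) > 1 / fs)) {
        stop("non-uniform timestamps (beyond one-sample tolerance) for fs = ", fs,
             call. = FALSE)
      }
    }
    samples$time <- NULL
  }
  missing_ch <- setdiff(CHANNELS_IMU, names(samples))
  if (length(missing_ch)) {
    stop("recording is missing mandatory channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  order <- c(CHANNELS_IMU, intersect("ecg", names(samples)))
  extra <- setdiff(names(samples), order)
  if (length(extra)) {
    stop("unknown channel(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  samples <- samples[order]
  if (anyNA(samples)) {
    stop("recording contains missing samples; represent gaps via the artifact mask",
         call. = FALSE)
  }
  if (!is.na(label)) label <- match.arg(label, CLASS_LABELS)
  structure(
    list(samples = samples, fs = fs, subject_id = as.character(subject_id),
         label = label, units = units),
    class = "cm_recording"
  )
}

#' @export
print.cm_recording <- function(x, ...) {
  cat(sprintf("<cm_recording> %s | %.1f s @ %g Hz | %d channel(s) | label: %s\n",
              x$subject_id, n_samples(x) / x$fs, x$fs, ncol(x$samples),
              ifelse(is.na(x$label), "unlabeled", x$label)))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec A `cm_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$samples)

#' Duration of a recording in seconds
#' @param rec A `cm_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) n_samples(rec) / rec$fs

#' Read a recording from a delimited text file
#'
#' The container is plain CSV with `#`-prefixed `key: value` header lines
#' (`fs`, `subject_id`, `label`, units) followed by the columns
#' `time,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z[,ecg]`. A column-mapping schema
#' can rename nonstandard headers.
#'
#' @param path File path.
#' @param schema Optional named character vector mapping canonical channel
#'   names to the file's column names, e.g. `c(acc_x = "ax")`.
#' @return A [recording()].
#' @export
read_recording <- function(path, schema = NULL) {
  stopifnot(file.exists(path))
  hdr <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  meta <- list(fs = NA_real_, subject_id = "unknown", label = NA_character_)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), ":", fixed = TRUE)[[1]]
    if (length(kv) >= 2) {
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":"))
    }
  }
  if (is.na(suppressWarnings(as.numeric(meta$fs)))) {
    stop("recording header must declare fs", call. = FALSE)
  }
  dat <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(dat)) {
        names(dat)[names(dat) == schema[[canon]]] <- canon
      }
    }
  }
  missing_ch <- setdiff(CHANNELS_IMU, names(dat))
  if (length(missing_ch)) {
    stop("file lacks mandatory channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  units <- c(acc = meta$acc_unit %||% "m/s^2", gyr = meta$gyr_unit %||% "deg/s")
  lab <- meta$label
  if (identical(lab, "NA") || identical(lab, "unlabeled")) lab <- NA_character_
  recording(dat, fs = as.numeric(meta$fs), subject_id = meta$subject_id,
            label = lab, units = units)
}

#' Write a recording to a delimited text file
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param digits Significant digits written (default 10, so a round trip
#'   preserves samples to better than 1e-9 of signal scale).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 10) {
  stopifnot(inherits(rec, "cm_recording"))
  hdr <- c(
    sprintf("# fs: %.10g", rec$fs),
    sprintf("# subject_id: %s", rec$subject_id),
    sprintf("# label: %s", ifelse(is.na(rec$label), "NA", rec$label)),
    sprintf("# acc_unit: %s", rec$units[["acc"]]),
    sprintf("# gyr_unit: %s", rec$units[["gyr"]])
  )
  dat <- rec$samples
  dat <- tibble::add_column(dat, time = (seq_len(nrow(dat)) - 1) / rec$fs,
                            .before = 1)
  body <- vapply(dat, function(col) format(col, digits = digits, trim = TRUE,
                                           scientific = TRUE),
                 character(nrow(dat)))
  lines <- c(hdr, paste(names(dat), collapse = ","),
             apply(matrix(body, nrow = nrow(dat)), 1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
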