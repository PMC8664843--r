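# Shared fixtures, generated once per test run. Kept small: a clean one-
# minute recording processed at the literature chunk size, reused by the
# detection/annotation/feature tests.

fx_cache <- new.env(parent = emptyenv())

fx_clean <- function(noise_sd = 0.05) {
  key <- paste0("clean_", noise_sd)
  if (is.null(fx_cache[[key]])) {
    cfg <- synth_config(duration = 60, noise_sd = noise_sd, artifact_rate = 0,
                        seed = 7)
    gen <- generate_recording(cfg, "fix1")
    proc <- process_recording(gen$recording, N = 11.2)
    fx_cache[[key]] <- list(cfg = cfg, gen = gen, proc = proc)
  }
  fx_cache[[key]]
}

# small labeled cohort for model-layer tests (fast, separable)
fx_cohort_fm <- function() {
  if (is.null(fx_cache$cohort_fm)) {
    cohort <- generate_cohort(3, synth_config(duration = 60), seed = 11,
                              labels = c("healthy", "severe"))
    fx_cache$cohort_fm <- list(
      cohort = cohort,
      fm = extract_cohort_features(cohort, level = "chunk")
    )
  }
  fx_cache$cohort_fm
}

# fabricated linearly separable feature matrix (no signal chain involved)
fx_separable_fm <- function(n_per_class = 20, p = 4, seed = 3) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  lab <- rep(c("healthy", "severe"), each = n_per_class)
  # two point masses: any split between them classifies train and test
  # identically, so a perfect CV score is a property of the learner, not of
  # where it happens to place the threshold inside the margin
  x[, 1] <- ifelse(lab == "severe", 10, 0)
  feature_matrix(tibble::as_tibble(x),
                 sample_ids = sprintf("s%02d", seq_len(n)), labels = lab,
                 subject_ids = sprintf("subj%02d", seq_len(n)))
}

# truth beats whose waveform support lies wholly inside a chunk (a beat cut
# by a chunk boundary is not recoverable from that chunk by construction)
fx_truth_in_chunks <- function(truth, chunks, margin = 0.35) {
  keep <- vapply(truth$beat_times, function(t) {
    any(vapply(chunks, function(c) {
      t >= c$start_time + margin & t <= c$start_time + c$N - margin
    }, logical(1)))
  }, logical(1))
  truth$beat_times[keep]
}

detected_j_times <- function(proc, axis = "gcg_y", margin = 0.35) {
  unlist(purrr::map2(proc$beats, proc$chunks, function(b, ch) {
    if (!b$usable) return(numeric())
    t <- b$per_axis$time[b$per_axis$axis == axis]
    t[t >= ch$start_time + margin & t <= ch$start_time + ch$N - margin]
  }))
}

# match annotated rows to true fiducial rows by nearest J time
fx_match_fiducials <- function(fid, truth, axis = "gcg_y") {
  f <- fid[fid$valid & fid$axis == axis, ]
  tb <- truth$fiducials[truth$fiducials$axis == axis, ]
  j <- vapply(f$t_J, function(t) which.min(abs(tb$t_J - t)), integer(1))
  list(est = f, true = tb[j, ])
}
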