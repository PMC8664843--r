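fab_fid <- function(j_times, valid = rep(TRUE, length(j_times)),
                    axis = "gcg_y") {
  tibble::tibble(
    chunk_ref = "c1", beat = seq_along(j_times), axis = axis,
    t_A = j_times - 0.21, t_I = j_times - 0.09, t_J = j_times,
    t_K = j_times + 0.12, t_L = j_times + 0.24, t_P = j_times + 0.02,
    MA = 20, valid = valid
  )
}

test_that("NN series differences consecutive valid J peaks and drops bridges", {
  expect_equal(nn_series(fab_fid(c(1.0, 1.8, 2.6))), c(800, 800))
  fid <- fab_fid(c(1.0, 1.8, 2.7, 3.5), valid = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(nn_series(fid), 800) # interval bridging the invalid beat dropped
  expect_length(nn_series(fab_fid(1.0)), 0)
})

test_that("constant NN series zeroes every dispersion feature", {
  f <- time_hrv_features(rep(800, 10))
  expect_equal(f[["AVNN_time"]], 800)
  for (nm in c("SDNN_time", "RMSSD_time", "pNN50_time", "VAI_time",
               "VLI_time", "SD1_time", "NN_sk_time", "ENN_time"))
    expect_equal(f[[nm]], 0)
  expect_true(is.na(f[["SD1_SD2_time"]])) # SD2 = 0 flagged missing
})

test_that("hand-enumerable NN series matches direct formulas", {
  nn <- c(800, 860, 812, 900) # diffs 60, -48, 88
  f <- time_hrv_features(nn)
  expect_equal(f[["pNN50_time"]], 2 / 4)
  expect_equal(f[["RMSSD_time"]], sqrt((60^2 + 48^2 + 88^2) / 3))
  expect_equal(f[["AVNN_time"]], mean(nn))
  expect_equal(f[["NN_med_time"]], median(nn))
  f2 <- time_hrv_features(nn, cm_config(pnn50_denominator = "diffs"))
  expect_equal(f2[["pNN50_time"]], 2 / 3)
})

test_that("Poincare indices match an independent per-point loop", {
  set.seed(5)
  nn <- 800 + rnorm(40, 0, 50)
  f <- time_hrv_features(nn)
  B <- length(nn) - 1
  vai <- 0; l <- numeric(B)
  for (i in seq_len(B)) {
    theta <- atan2(nn[i + 1], nn[i]) * 180 / pi
    vai <- vai + abs(theta - 45) / B
    l[i] <- sqrt(nn[i]^2 + nn[i + 1]^2)
  }
  vli <- sqrt(sum(abs(l - mean(l))^2) / B)
  expect_equal(f[["VAI_time"]], vai, tolerance = 1e-12)
  expect_equal(f[["VLI_time"]], vli, tolerance = 1e-12)
  # SD1 as printed: population std of |successive difference| / sqrt(2)
  d <- abs(diff(nn)) / sqrt(2)
  expect_equal(f[["SD1_time"]], sqrt(mean((d - mean(d))^2)), tolerance = 1e-12)
})

test_that("printed SD2 equals SD1 exactly; conventional SD2 does not", {
  for (seed in 1:5) {
    set.seed(seed)
    nn <- 800 + rnorm(30, 0, 60)
    f <- time_hrv_features(nn)
    expect_equal(f[["SD2_time"]], f[["SD1_time"]], tolerance = 1e-12)
    expect_equal(f[["SD1_SD2_time"]], 1, tolerance = 1e-12)
  }
  set.seed(1)
  nn <- 800 + rnorm(30, 0, 60)
  fc <- time_hrv_features(nn, cm_config(sd2_convention = "conventional"))
  expect_gt(fc[["SD2_time"]], fc[["SD1_time"]]) # long axis dominates
})

test_that("entropy family obeys ENN-marginal = SENN + CENN exactly", {
  set.seed(7)
  nn <- 800 + rnorm(200, 0, 50)
  cfg <- cm_config()
  f <- time_hrv_features(nn, cfg)
  # independent binning of the marginal of NN_{i+1} on the shared grid
  bw <- cfg$nn_bin_ms
  y <- nn[-1]
  p <- tabulate(floor((y - min(nn)) / bw) + 1L)
  p <- p[p > 0] / length(y)
  h_y <- -sum(p * log2(p))
  expect_equal(f[["SENN_time"]] + f[["CENN_time"]], h_y, tolerance = 1e-9)
  expect_gte(f[["SENN_time"]], -1e-12) # mutual information is nonnegative
})

test_that("moment conventions are population-style, kurtosis not excess", {
  x <- c(1, 2, 2, 3, 7)
  f <- time_hrv_features(x * 100)
  m <- x * 100
  m2 <- mean((m - mean(m))^2)
  expect_equal(f[["SDNN_time"]], sqrt(m2), tolerance = 1e-12)
  expect_equal(f[["NN_sk_time"]], mean((m - mean(m))^3) / m2^1.5,
               tolerance = 1e-12)
  expect_equal(f[["NN_ku_time"]], mean((m - mean(m))^4) / m2^2,
               tolerance = 1e-12)
})

test_that("Welch PSD satisfies Parseval on white noise and locates a tone", {
  set.seed(3)
  fs <- 8
  x <- rnorm(fs * 600)
  p <- welch_psd(x, fs, segment_s = 120)
  tot <- sum(diff(p$freq) * (head(p$psd, -1) + tail(p$psd, -1)) / 2)
  expect_equal(tot, var(x), tolerance = 0.1 * var(x))

  t <- seq(0, 600 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * 0.1 * t)
  ps <- welch_psd(tone, fs, segment_s = 120)
  in_lf <- ps$freq >= 0.04 & ps$freq <= 0.15
  fband <- ps$freq[in_lf]; pband <- ps$psd[in_lf]
  lf <- sum(diff(fband) * (head(pband, -1) + tail(pband, -1)) / 2)
  expect_equal(lf, 0.5, tolerance = 0.05 * 0.5)
})

test_that("frequency-HRV features resolve the bands of a planted tone", {
  fs <- 256
  n <- fs * 600
  t <- (seq_len(n) - 1) / fs
  set.seed(2)
  chans <- tibble::as_tibble(setNames(
    as.data.frame(replicate(6, sin(2 * pi * 0.1 * t))),
    c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")))
  rec <- recording(chans, fs = fs)
  mask <- structure(list(keep = rep(TRUE, n), rms = numeric(n),
                         threshold = 0, M = 500), class = "cm_mask")
  f <- freq_hrv_features(rec, mask)
  expect_length(f, 30)
  expect_equal(unname(f[["lf_HRV_GCG_Y_freq"]]), 0.5, tolerance = 0.025)
  expect_lt(f[["hf_HRV_GCG_Y_freq"]], 0.01 * f[["lf_HRV_GCG_Y_freq"]])
  expect_gt(f[["lfhfRatio_GCG_Y_freq"]], 50)

  # short recording: no run spans two Welch segments -> flagged missing
  short <- recording(chans[seq_len(fs * 60), ], fs = fs)
  mask_s <- structure(list(keep = rep(TRUE, fs * 60), rms = numeric(fs * 60),
                           threshold = 0, M = 500), class = "cm_mask")
  expect_warning(fs_short <- freq_hrv_features(short, mask_s), "missing")
  expect_true(all(is.na(fs_short)))
})

test_that("GCG interval statistics match a brute-force evaluation", {
  blk <- interval_block(fab_fid(c(1, 1.9, 2.7, 3.6, 4.4)))
  blk$IVCT <- c(80, 85, 90, 95, 120) # hand-written values
  blk$MA <- c(10, 20, 20, 30, 15)
  f <- gcg_interval_features(blk)
  expect_length(f, 88)
  x <- blk$IVCT
  expect_equal(f[["IVCT_mean_GCG"]], mean(x), tolerance = 1e-9)
  expect_equal(f[["IVCT_median_GCG"]], median(x), tolerance = 1e-9)
  expect_equal(f[["IVCT_std_GCG"]], sqrt(mean((x - mean(x))^2)),
               tolerance = 1e-9)
  expect_equal(f[["IVCT_sk_GCG"]],
               mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5,
               tolerance = 1e-9)
  expect_equal(f[["IVCT_ku_GCG"]],
               mean((x - mean(x))^4) / mean((x - mean(x))^2)^2,
               tolerance = 1e-9)
  expect_equal(f[["IVCT_min_GCG"]], 80)
  expect_equal(f[["IVCT_max_GCG"]], 120)
  # Freedman-Diaconis entropy, independently
  bw <- 2 * IQR(x) / length(x)^(1 / 3)
  cnt <- tabulate(floor((x - min(x)) / bw) + 1L)
  pr <- cnt[cnt > 0] / length(x)
  expect_equal(f[["IVCT_entropy_GCG"]], -sum(pr * log2(pr)), tolerance = 1e-9)

  # constant parameter: degenerate statistics
  blk$LVET <- rep(110, 5)
  fc <- gcg_interval_features(blk)
  expect_equal(unname(fc[c("LVET_std_GCG", "LVET_sk_GCG",
                           "LVET_entropy_GCG")]), c(0, 0, 0))
  expect_equal(fc[["LVET_min_GCG"]], fc[["LVET_max_GCG"]])

  expect_null(gcg_interval_features(blk[1:2, ])) # < 3 rows: scope excluded
})

test_that("assembled matrices carry the canonical blocks", {
  fmx <- fx_cohort_fm()
  fm <- fmx$fm
  man <- feature_manifest()
  expect_equal(length(feature_names(fm)), 103)
  expect_identical(feature_names(fm), man$name[man$block != "freq_hrv"])
  expect_false(anyNA(feature_values(fm)))
  expect_gt(nrow(fm), length(fmx$cohort)) # several chunks per subject

  fm_s <- suppressWarnings(
    extract_cohort_features(fmx$cohort[1:2], level = "subject"))
  expect_equal(length(feature_names(fm_s)), 133)
  expect_identical(feature_names(fm_s), man$name)
  expect_equal(anyDuplicated(feature_names(fm_s)), 0L)
  expect_equal(nrow(fm_s), 2)
})
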