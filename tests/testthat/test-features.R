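test_that("preprocessing decimates with anti-aliasing and band-passes 4-45 Hz", {
  fs_in <- 512; dur <- 6
  tt <- (seq_len(fs_in * dur) - 1) / fs_in
  mk <- function(freq) eeg_trial(matrix(sin(2 * pi * freq * tt), 1),
                                 fs_in, "Fp1", c(0, 0))
  out <- preprocess_trial(mk(10), target_fs = 128)
  expect_equal(out$fs, 128)
  expect_equal(ncol(out$data), fs_in * dur / 4)
  # passband: 10 Hz survives
  rms <- function(x) sqrt(mean(x^2))
  expect_gte(rms(out$data), 0.9 * rms(mk(10)$data))
  # stopband: 1 Hz is crushed
  low <- preprocess_trial(mk(1), target_fs = 128)
  expect_lt(rms(low$data), 0.05 * rms(mk(1)$data))
  expect_error(preprocess_trial(mk(10), target_fs = 1024), "exceeds")
  short <- eeg_trial(matrix(rnorm(64), 1), 128, "Fp1", c(0, 0))
  expect_error(preprocess_trial(short, target_fs = 128), "short")
})

test_that("time statistics follow the stated conventions", {
  n <- 512
  ramp <- seq_len(n)
  alt <- rep(c(1, -1), n / 2)
  tr <- eeg_trial(rbind(ramp, alt, rep(2, n)), 128,
                  c("Fp1", "AF3", "F3"), c(0, 0))
  st <- time_stats(tr)
  expect_equal(st[["Fp1.mean"]], mean(ramp))
  expect_equal(st[["Fp1.var"]], sum((ramp - mean(ramp))^2) / n)  # population
  expect_equal(st[["AF3.zcr"]], 1)          # every consecutive pair crosses
  expect_equal(st[["F3.apen"]], 0)          # constant signal
  expect_equal(st[["F3.var"]], 0)
  # sample-variance convention is switchable
  st2 <- time_stats(tr, var_type = "sample")
  expect_equal(st2[["Fp1.var"]], stats::var(ramp))
})

test_that("approximate entropy matches the independent pracma oracle", {
  skip_if_not_installed("pracma")
  withr::with_seed(4, {
    for (x in list(rnorm(150), sin(2 * pi * 6 * (0:149) / 128) + 0.2 * rnorm(150))) {
      ours <- approx_entropy_ts(x, m = 2, r = 0.2 * sd(x))
      ref <- pracma::approx_entropy(x, edim = 2, r = 0.2 * sd(x))
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  })
})

test_that("band PSD picks out a pure tone and scales quadratically", {
  tr <- tone_trial(10, n_channels = 2)
  p <- band_psd(tr)
  ch1 <- p[paste0("Fp1.psd.", c("theta", "slow_alpha", "alpha", "beta", "gamma"))]
  expect_equal(names(which.max(ch1)), "Fp1.psd.alpha")
  zero <- eeg_trial(matrix(0, 2, 512), 128, c("Fp1", "AF3"), c(0, 0))
  expect_true(all(band_psd(zero) == 0))
  tr2 <- tr; tr2$data <- 2 * tr$data
  expect_equal(band_psd(tr2), 4 * p, tolerance = 1e-12)
})

test_that("power differences are right-minus-left over 4 bands and 14 pairs", {
  schema <- feature_schema()
  tr <- tone_trial(10)                       # identical channels
  psd <- band_psd(tr)
  d <- power_differences(psd, schema)
  expect_length(d, 56)
  expect_true(all(abs(d) < 1e-12))
  # antisymmetry: boost one right channel, its pair differences negate on swap
  tr2 <- tr
  i_right <- match("Fp2", tr$channels); i_left <- match("Fp1", tr$channels)
  tr2$data[i_right, ] <- 2 * tr2$data[i_right, ]
  d2 <- power_differences(band_psd(tr2), schema)
  tr3 <- tr
  tr3$data[i_left, ] <- 2 * tr3$data[i_left, ]
  d3 <- power_differences(band_psd(tr3), schema)
  sel <- grepl("^Fp2-Fp1", names(d2))
  expect_equal(d2[sel], -d3[sel], tolerance = 1e-10)
  expect_gt(d2[["Fp2-Fp1.dpsd.alpha"]], 0)
  expect_error(power_differences(psd[1:10], schema), "5 \\* n_channels")
})

test_that("Hilbert-Huang features recover a pure tone's band, amplitude and frequency", {
  tr <- tone_trial(6, n_channels = 2)        # 6 Hz, unit amplitude -> theta
  h <- hhs_features(tr)
  expect_length(h, 10 * 2)
  expect_equal(h[["Fp1.hhs_amp.theta"]], 1, tolerance = 0.05)
  expect_equal(h[["Fp1.hhs_if.theta"]], 6, tolerance = 0.05 * 6)
  # >= 80% of squared-amplitude mass in the tone's band
  amps <- h[paste0("Fp1.hhs_amp.", c("delta", "theta", "alpha", "beta", "gamma"))]
  expect_gte(amps[["Fp1.hhs_amp.theta"]] / sum(amps), 0.8)
  zero <- eeg_trial(matrix(0, 2, 512), 128, c("Fp1", "AF3"), c(0, 0))
  expect_true(all(hhs_features(zero) == 0))
})

test_that("full extraction yields the 664-feature vector partitioned (128,160,56,160,160)", {
  schema <- feature_schema()
  cfg <- sim_config(n_subjects = 1, n_trials_per_subject = 1, duration = 4,
                    seed = 9)
  tr <- preprocess_trial(simulate_subject(cfg, 1)[[1]])
  v <- extract_features(tr, schema)
  expect_length(v, 664)
  expect_equal(vapply(schema$subset_index, length, integer(1)),
               c(F1 = 128, F2 = 160, F3 = 56, F4 = 160, F5 = 160))
  # subsets are disjoint and cover all indices exactly once
  idx <- unname(sort(unlist(schema$subset_index)))
  expect_identical(idx, 1:664)
  expect_identical(v, extract_features(tr, schema))   # deterministic
  expect_true(all(is.finite(v)))
})

test_that("scaling a trial scales means linearly, power quadratically, ZCR not at all", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_subject = 1, duration = 4,
                    seed = 10)
  tr <- preprocess_trial(simulate_subject(cfg, 1)[[1]])
  k <- 3
  trk <- tr; trk$data <- k * tr$data
  s1 <- time_stats(tr); sk <- time_stats(trk)
  pick <- function(s, stat) s[grepl(paste0("\\.", stat, "$"), names(s))]
  expect_equal(pick(sk, "mean"), k * pick(s1, "mean"), tolerance = 1e-10)
  expect_equal(pick(sk, "var"), k^2 * pick(s1, "var"), tolerance = 1e-10)
  expect_equal(pick(sk, "zcr"), pick(s1, "zcr"))
  expect_equal(band_psd(trk), k^2 * band_psd(tr), tolerance = 1e-10)
})

test_that("standardization z-scores per column and handles degenerate columns", {
  withr::with_seed(2, x <- cbind(matrix(rnorm(30), 10), const = rep(5, 10)))
  std <- standardize_features(x)
  expect_true(all(abs(colMeans(std$x)) < 1e-10))
  sds <- apply(std$x, 2, sd)
  expect_true(all(abs(sds[1:3] - 1) < 1e-10))
  expect_true(all(std$x[, 4] == 0))                    # constant column
  expect_error(standardize_features(x[1, , drop = FALSE]), "at least 2")
  # stored statistics reproduce the training transform on held-out rows
  toy <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2)
  st <- standardize_features(toy)
  held <- matrix(c(4, 40), ncol = 2)
  expect_equal(apply_standardization(held, st$center, st$scale),
               matrix(c((4 - 2) / 1, (40 - 20) / 10), ncol = 2))
})

test_that("feature matrices round-trip through delimited text", {
  d <- list(features = matrix(rnorm(12), 3,
                              dimnames = list(NULL, paste0("f", 1:4))),
            labels = cbind(arousal = c(0L, 1L, 0L), valence = c(1L, 1L, 0L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(d$features, d$labels, path)
  back <- read_feature_matrix(path)
  expect_equal(back$features, d$features, tolerance = 1e-10)
  expect_equal(unname(back$labels), unname(d$labels))
})
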