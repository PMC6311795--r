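# Shared fixtures, built in code and memoized for the session.

.fixtures <- new.env(parent = emptyenv())

# One-subject extracted feature dataset under the standard study conditions
# (40 trials, 128 Hz; 6 s trials keep entropy/EMD features stable while the
# suite stays fast).
eeg_feature_dataset <- function(effect_size, seed, n_trials = 40,
                                duration = 6, noise_sd = 0.2) {
  key <- paste("ds", effect_size, seed, n_trials, duration, noise_sd, sep = "_")
  if (is.null(.fixtures[[key]])) {
    cfg <- sim_config(n_subjects = 1, n_trials_per_subject = n_trials,
                      duration = duration, effect_size = effect_size,
                      noise_sd = noise_sd, seed = seed)
    .fixtures[[key]] <- extract_trials(simulate_subject(cfg, 1))
  }
  .fixtures[[key]]
}

# Reduced-width ensemble used for end-to-end recovery checks: same five-branch
# architecture, narrower layers suited to 36-instance training folds.
reduced_ensemble_config <- function(seed = 1) {
  ensemble_config(
    branch_sizes = list(F1 = c(32, 24, 16), F2 = c(32, 24, 16),
                        F3 = c(24, 16, 12), F4 = c(32, 24, 16),
                        F5 = c(32, 24, 16)),
    pretrain_hp = rbm_hyperparams(epochs = 10),
    finetune_hp = list(lr = 0.5, epochs = 60, batch_size = 8, momentum = 0.9),
    fusion = list(n_hidden = 20, lr = 0.1, epochs = 80, batch_size = 8,
                  momentum = 0.5),
    seed = seed)
}

# Independent band-power oracle: raw one-sided periodogram, mean power in
# [lo, hi). Deliberately avoids the package's Welch estimator.
periodogram_band_power <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f < band[2]
  mean(p[sel])
}

# A pure-tone trial on the standard montage.
tone_trial <- function(freq, fs = 128, duration = 6, amp = 1,
                       n_channels = 32) {
  tt <- (seq_len(duration * fs) - 1) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq * tt), n_channels),
              nrow = n_channels, byrow = TRUE)
  eeg_trial(x, fs, deap_channels()[seq_len(n_channels)], c(0, 1))
}

# Linearly separable 2-D toy set with margin, plus a glm() separability check.
separable_toy <- function(n = 100, seed = 5) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x1 <- ifelse(y == 1, stats::runif(n, 0.5, 2), stats::runif(n, -2, -0.5))
    x2 <- stats::rnorm(n)
    list(x = cbind(x1, x2), y = y)
  })
}
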