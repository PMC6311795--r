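# Synthetic labelled-EEG generator. Each channel is a sum of band-limited
# oscillators (theta 6 Hz, alpha 10 Hz, beta 20 Hz, gamma 35 Hz) whose
# amplitudes are drawn from class-conditional distributions, plus 1/f noise;
# channels are then mixed by a fixed per-subject matrix.

# 1/f ("pink") amplitude-shaped Gaussian noise, unit SD before scaling.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # guard DC
  f <- pmin(f, n - f + 1)            # mirror for negative frequencies
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Per-subject channel mixing matrix: (1-m) I + m S with S a fixed random
# row-stochastic non-negative matrix.
mixing_matrix <- function(n_channels, strength) {
  S <- matrix(abs(stats::rnorm(n_channels^2)), n_channels, n_channels)
  S <- S / rowSums(S)
  (1 - strength) * diag(n_channels) + strength * S
}

# SD of the per-trial, per-channel amplitude jitter around the
# class-conditional mean (fixed; 'noise_sd' governs the 1/f noise instead).
AMP_JITTER_SD <- 0.1
# Amplitude shift per unit effect size, applied with sign +/- by class.
AMP_EFFECT_SCALE <- 0.25

subject_seed <- function(cfg, subject_index) {
  as.integer((as.numeric(cfg$seed) * 10007 + subject_index * 97) %% 2147483629)
}

# Balanced binary labels: each class appears floor(n/2) or ceiling(n/2) times.
balanced_labels <- function(n) sample(rep(c(0L, 1L), length.out = n))

#' Simulate all trials for one subject
#'
#' Generates \code{cfg$n_trials_per_subject} labelled trials. High arousal
#' raises the beta and gamma oscillator amplitudes on all channels; pleasant
#' valence raises alpha amplitude on left-hemisphere channels and lowers it
#' on right-hemisphere channels (and vice versa), producing a left-minus-right
#' alpha asymmetry. Labels are balanced to within one trial per class and
#' dimension. Output is bit-reproducible from \code{cfg$seed} and
#' \code{subject_index}.
#'
#' @param cfg a [sim_config()].
#' @param subject_index subject number in \code{1..cfg$n_subjects}.
#' @return List of [eeg_trial()] objects.
#' @export
simulate_subject <- function(cfg, subject_index) {
  if (!inherits(cfg, "sim_config")) stop("'cfg' must be a sim_config")
  if (subject_index < 1 || subject_index > cfg$n_subjects)
    stop("subject_index must be in 1..n_subjects")
  nch <- cfg$n_channels
  nsamp <- round(cfg$duration * cfg$fs)
  side <- channel_sides(cfg$channels)
  osc_freq <- c(theta = 6, alpha = 10, beta = 20, gamma = 35)
  base <- cfg$base_amps
  es <- cfg$effect_size

  withr::with_seed(subject_seed(cfg, subject_index), {
    M <- mixing_matrix(nch, cfg$mixing_strength)
    lab_arousal <- balanced_labels(cfg$n_trials_per_subject)
    lab_valence <- balanced_labels(cfg$n_trials_per_subject)
    tt <- (seq_len(nsamp) - 1) / cfg$fs

    lapply(seq_len(cfg$n_trials_per_subject), function(tr) {
      sa <- 2 * lab_arousal[tr] - 1      # -1 / +1 arousal sign
      sv <- 2 * lab_valence[tr] - 1      # -1 / +1 valence sign
      X <- matrix(0, nch, nsamp)
      for (c_i in seq_len(nch)) {
        amp <- c(
          theta = base[["theta"]],
          alpha = base[["alpha"]] + AMP_EFFECT_SCALE * es * sv * side[c_i],
          beta  = base[["beta"]]  + AMP_EFFECT_SCALE * es * sa,
          gamma = base[["gamma"]] + AMP_EFFECT_SCALE * es * sa)
        jit <- stats::rnorm(4, 0, AMP_JITTER_SD)
        amp <- ifelse(base > 0, pmax(0, amp + jit), 0)
        ph <- stats::runif(4, 0, 2 * pi)
        sig <- numeric(nsamp)
        for (b in seq_along(osc_freq))
          if (amp[b] > 0)
            sig <- sig + amp[b] * sin(2 * pi * osc_freq[b] * tt + ph[b])
        X[c_i, ] <- sig + cfg$noise_sd * pink_noise(nsamp)
      }
      eeg_trial(M %*% X, cfg$fs, cfg$channels,
                c(lab_arousal[tr], lab_valence[tr]))
    })
  })
}

#' Simulate a full multi-subject dataset
#'
#' @param cfg a [sim_config()].
#' @return List of length \code{cfg$n_subjects}; element \code{s} is the list
#'   of trials returned by [simulate_subject()] for subject \code{s}.
#' @export
simulate_dataset <- function(cfg) {
  lapply(seq_len(cfg$n_subjects), function(s) simulate_subject(cfg, s))
}

#' Write one subject's trials to a single-file container
#'
#' Stores a \code{trials x channels x samples} array plus sampling rate,
#' channel names and the \code{trials x 2} label matrix in one serialized
#' container file (RDS).
#'
#' @param trials list of [eeg_trial()] with identical shape and montage.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_subject_trials <- function(trials, path) {
  stopifnot(length(trials) >= 1)
  nch <- nrow(trials[[1]]$data); nsamp <- ncol(trials[[1]]$data)
  arr <- array(NA_real_, c(length(trials), nch, nsamp))
  labels <- matrix(NA_integer_, length(trials), 2,
                   dimnames = list(NULL, c("arousal", "valence")))
  for (i in seq_along(trials)) {
    arr[i, , ] <- trials[[i]]$data
    labels[i, ] <- trials[[i]]$label
  }
  saveRDS(list(data = arr, fs = trials[[1]]$fs,
               channels = trials[[1]]$channels, labels = labels),
          path)
  invisible(path)
}

#' Read one subject's trials from a container written by
#' [write_subject_trials()]
#'
#' This is also the loader interface for real per-subject trial matrices:
#' any file holding the same layout (\code{data} trials x channels x samples,
#' \code{fs}, \code{channels}, \code{labels} trials x 2) is accepted.
#'
#' @param path container file path.
#' @return List of [eeg_trial()] objects.
#' @export
read_subject_trials <- function(path) {
  obj <- readRDS(path)
  lapply(seq_len(dim(obj$data)[1]), function(i)
    eeg_trial(obj$data[i, , , drop = TRUE], obj$fs, obj$channels,
              obj$labels[i, ]))
}
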