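#' Construct a single EEG trial
#'
#' An \code{eeg_trial} holds one trial's channels x samples matrix together
#' with its sampling rate, ordered channel names and a binary two-dimensional
#' emotion label \code{(arousal, valence)}. High arousal / pleasant valence
#' are coded 1, low / unpleasant 0 (self-assessment ratings above 5 map to 1).
#'
#' @param data numeric matrix, channels x samples.
#' @param fs sampling rate in Hz (> 0).
#' @param channels character vector of unique channel names, one per row of
#'   \code{data}.
#' @param label integer vector \code{c(arousal, valence)}, each in \{0, 1\}.
#' @return An object of class \code{eeg_trial}.
#' @export
eeg_trial <- function(data, fs, channels, label) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix (channels x samples)")
  if (anyDuplicated(channels))
    stop("'channels' must not contain duplicates")
  if (nrow(data) != length(channels))
    stop("row count of 'data' (", nrow(data), ") must equal number of channels (",
         length(channels), ")")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("'fs' must be a single positive number")
  if (length(label) != 2 || !all(label %in% c(0, 1)))
    stop("'label' must be a pair (arousal, valence) of values in {0, 1}")
  structure(list(data = data, fs = fs, channels = as.character(channels),
                 label = as.integer(label)),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> %d channels x %d samples @ %g Hz, label (arousal=%d, valence=%d)\n",
              nrow(x$data), ncol(x$data), x$fs, x$label[1], x$label[2]))
  invisible(x)
}

#' Simulation configuration for the synthetic EEG generator
#'
#' Defines the study conditions for the synthetic labelled-EEG generator:
#' number of subjects and trials, montage size, sampling rate and duration,
#' the class-conditional effect size, noise level and interchannel mixing.
#' Defaults mirror the acquisition protocol the pipeline targets: 32 subjects,
#' 40 one-minute trials each, 32 channels at 128 Hz.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_trials_per_subject trials per subject (>= 1).
#' @param n_channels number of channels (>= 1). For other than 32 channels an
#'   explicit \code{pair_list} must be supplied for asymmetry features.
#' @param fs sampling rate in Hz.
#' @param duration trial length in seconds (>= 4, so that entropy and
#'   empirical-mode features are meaningful).
#' @param effect_size dimensionless separation between class-conditional
#'   band-amplitude means (>= 0). Arousal shifts broadband beta+gamma
#'   amplitude; valence shifts the left-minus-right alpha amplitude of
#'   homologous channel pairs.
#' @param noise_sd standard deviation of the additive 1/f noise.
#' @param mixing_strength in [0, 1]; 0 leaves channels independent, larger
#'   values mix each channel with a fixed random combination of the others.
#' @param seed integer seed; together with the subject index it fully
#'   determines the generated data.
#' @param channels optional channel names; defaults to [deap_channels()] when
#'   \code{n_channels == 32}.
#' @param base_amps named base amplitudes of the four band-limited
#'   oscillators \code{c(theta, alpha, beta, gamma)}; set an entry to 0 to
#'   silence that oscillator.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_subjects = 32, n_trials_per_subject = 40,
                       n_channels = 32, fs = 128, duration = 60,
                       effect_size = 1.5, noise_sd = 0.5,
                       mixing_strength = 0.2, seed = 1,
                       channels = NULL,
                       base_amps = c(theta = 1, alpha = 1, beta = 1, gamma = 0.8)) {
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x))
      stop("invalid configuration field '", nm, "': must be an integer >= 1")
  }
  chk_count(n_subjects, "n_subjects")
  chk_count(n_trials_per_subject, "n_trials_per_subject")
  chk_count(n_channels, "n_channels")
  if (!is.numeric(fs) || fs <= 0)
    stop("invalid configuration field 'fs': must be > 0")
  if (!is.numeric(duration) || duration < 4)
    stop("invalid configuration field 'duration': must be >= 4 seconds")
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("invalid configuration field 'effect_size': must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("invalid configuration field 'noise_sd': must be >= 0")
  if (!is.numeric(mixing_strength) || mixing_strength < 0 || mixing_strength > 1)
    stop("invalid configuration field 'mixing_strength': must be in [0, 1]")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("invalid configuration field 'seed': must be an integer")
  if (is.null(channels)) {
    channels <- if (n_channels == 32) deap_channels()
                else sprintf("Ch%02d", seq_len(n_channels))
  }
  if (length(channels) != n_channels)
    stop("invalid configuration field 'channels': length must equal n_channels")
  req <- c("theta", "alpha", "beta", "gamma")
  if (!all(req %in% names(base_amps)) || any(base_amps < 0))
    stop("invalid configuration field 'base_amps': needs non-negative theta/alpha/beta/gamma entries")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 n_channels = as.integer(n_channels),
                 fs = fs, duration = duration,
                 effect_size = effect_size, noise_sd = noise_sd,
                 mixing_strength = mixing_strength, seed = as.integer(seed),
                 channels = as.character(channels),
                 base_amps = base_amps[req]),
            class = "sim_config")
}
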