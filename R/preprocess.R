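#' Downsample and band-pass filter a trial
#'
#' Anti-aliased decimation to \code{target_fs} followed by a zero-phase
#' band-pass (default 4--45 Hz, 4th-order Butterworth applied
#' forward-backward) per channel. Channel names and the label are unchanged.
#'
#' @param trial an [eeg_trial()].
#' @param target_fs target sampling rate in Hz; must divide \code{trial$fs}
#'   and exceed twice the band's upper edge.
#' @param band numeric \code{c(lo, hi)} pass band in Hz.
#' @return A preprocessed [eeg_trial()] at \code{target_fs}.
#' @export
preprocess_trial <- function(trial, target_fs = 128, band = c(4, 45)) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (target_fs > trial$fs)
    stop("target_fs (", target_fs, ") exceeds trial sampling rate (", trial$fs, ")")
  if (target_fs <= 2 * band[2])
    stop("target_fs must exceed twice the band upper edge (", 2 * band[2], " Hz)")
  factor <- trial$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9)
    stop("trial$fs must be an integer multiple of target_fs")
  factor <- round(factor)
  x <- trial$data
  if (factor > 1) {
    # anti-alias low-pass at 80% of the new Nyquist before subsampling
    aa <- signal::butter(8, 0.8 * (target_fs / 2) / (trial$fs / 2), type = "low")
    x <- t(apply(x, 1, function(ch) signal::filtfilt(aa, ch)))
    x <- x[, seq(1, ncol(x), by = factor), drop = FALSE]
  }
  if (ncol(x) < 2 * target_fs)
    stop("trial too short for filter warm-up (need >= 2 s at target_fs)")
  bp <- signal::butter(4, band / (target_fs / 2), type = "pass")
  x <- t(apply(x, 1, function(ch) signal::filtfilt(bp, ch)))
  eeg_trial(x, target_fs, trial$channels, trial$label)
}
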