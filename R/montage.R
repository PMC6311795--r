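#' Standard 32-channel EEG montage
#'
#' Ordered channel names of the 32-site recording montage used throughout the
#' package (the layout of the DEAP acquisition setup). The order is the
#' canonical acquisition order; left-hemisphere, midline and right-hemisphere
#' sites are interleaved as recorded.
#'
#' @return Character vector of 32 channel names.
#' @export
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Homologous left-right channel pairs
#'
#' The 14 right/left homologous electrode pairs used for hemispheric power
#' asymmetry features. Differences are taken as right minus left.
#'
#' @return A 14 x 2 character matrix with columns \code{right} and \code{left}.
#' @export
deap_pairs <- function() {
  m <- matrix(c(
    "Fp2", "Fp1",
    "AF4", "AF3",
    "F4",  "F3",
    "F8",  "F7",
    "FC6", "FC5",
    "FC2", "FC1",
    "C4",  "C3",
    "T8",  "T7",
    "CP6", "CP5",
    "CP2", "CP1",
    "P4",  "P3",
    "P8",  "P7",
    "PO4", "PO3",
    "O2",  "O1"), ncol = 2, byrow = TRUE)
  colnames(m) <- c("right", "left")
  m
}

#' EEG frequency bands
#'
#' Named frequency intervals (Hz) used by the feature pipeline. Band
#' membership is half-open: a frequency f belongs to band \code{[lo, hi)}.
#'
#' @return Named list of length-2 numeric vectors \code{c(lo, hi)}.
#' @export
eeg_bands <- function() {
  list(delta      = c(1, 4),
       theta      = c(4, 8),
       slow_alpha = c(8, 10),
       alpha      = c(8, 12),
       beta       = c(12, 30),
       gamma      = c(30, 45))
}

# Band subsets used by the three spectral feature families.
psd_band_names  <- function() c("theta", "slow_alpha", "alpha", "beta", "gamma")
diff_band_names <- function() c("theta", "alpha", "beta", "gamma")
hhs_band_names  <- function() c("delta", "theta", "alpha", "beta", "gamma")

# Hemisphere side of each channel: +1 left, -1 right, 0 midline.
channel_sides <- function(channels, pair_list = deap_pairs()) {
  side <- rep(0, length(channels))
  side[channels %in% pair_list[, "left"]]  <- 1
  side[channels %in% pair_list[, "right"]] <- -1
  side
}
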