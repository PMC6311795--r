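# Multi-domain EEG feature extraction producing the 664-dimensional vector.

#' Approximate entropy
#'
#' ApEn(m, r) of a univariate series with Chebyshev distance and
#' self-matches included; a constant series has ApEn 0.
#'
#' @param x numeric series.
#' @param m embedding dimension.
#' @param r tolerance; defaults to \code{r_frac * sd(x)}.
#' @param r_frac tolerance as a fraction of the series SD (used when
#'   \code{r} is NULL).
#' @return Approximate entropy (non-negative scalar).
#' @export
approx_entropy_ts <- function(x, m = 2, r = NULL, r_frac = 0.2) {
  if (length(x) < m + 2)
    stop("series too short for approximate entropy (need > m+1 samples)")
  s <- stats::sd(x)
  if (s == 0) return(0)
  if (is.null(r)) r <- r_frac * s
  apen_cpp(as.numeric(x), as.integer(m), r)
}

#' Per-channel time-domain statistics
#'
#' For each channel, in order: mean, variance (population convention by
#' default), zero-crossing rate of the mean-removed signal (sign changes
#' divided by N-1), and approximate entropy (m = 2, r = 0.2 SD).
#'
#' @param trial a preprocessed [eeg_trial()].
#' @param m,r_frac approximate-entropy parameters.
#' @param var_type \code{"population"} (divide by N) or \code{"sample"}.
#' @return Named numeric vector of length \code{4 * n_channels},
#'   channel-major.
#' @export
time_stats <- function(trial, m = 2, r_frac = 0.2,
                       var_type = c("population", "sample")) {
  var_type <- match.arg(var_type)
  if (ncol(trial$data) < m + 2)
    stop("trial too short for approximate entropy embedding")
  out <- lapply(seq_len(nrow(trial$data)), function(i) {
    x <- trial$data[i, ]
    n <- length(x)
    mu <- mean(x)
    v <- sum((x - mu)^2) / if (var_type == "population") n else n - 1
    s <- sign(x - mu); s[s == 0] <- 1
    zcr <- sum(diff(s) != 0) / (n - 1)
    c(mu, v, zcr, approx_entropy_ts(x, m = m, r_frac = r_frac))
  })
  out <- unlist(out)
  names(out) <- as.vector(t(outer(trial$channels,
                                  c("mean", "var", "zcr", "apen"),
                                  paste, sep = ".")))
  out
}

#' Per-channel average band power spectral density
#'
#' Welch PSD (2 s Hann segments, 50% overlap) averaged over the bins of each
#' of the five bands theta, slow-alpha, alpha, beta, gamma.
#'
#' @param trial a preprocessed [eeg_trial()].
#' @param nperseg Welch segment length in samples (default 2 s).
#' @return Named numeric vector of length \code{5 * n_channels},
#'   channel-major, band-minor.
#' @export
band_psd <- function(trial, nperseg = 2 * trial$fs) {
  bands <- eeg_bands()[psd_band_names()]
  if (max(vapply(bands, `[`, numeric(1), 2)) > trial$fs / 2)
    stop("band upper edge exceeds the Nyquist frequency")
  out <- lapply(seq_len(nrow(trial$data)), function(i) {
    w <- welch_psd(trial$data[i, ], trial$fs, nperseg = nperseg)
    vapply(bands, function(b) band_average(w$freq, w$psd, b), numeric(1))
  })
  out <- unlist(out)
  names(out) <- as.vector(t(outer(trial$channels,
                                  paste0("psd.", psd_band_names()),
                                  paste, sep = ".")))
  out
}

#' Right-minus-left band power differences
#'
#' For each homologous channel pair and each of theta, alpha, beta and gamma
#' (slow-alpha excluded): band PSD of the right channel minus that of the
#' left channel.
#'
#' @param psd_values output of [band_psd()] for the schema's montage.
#' @param schema a [feature_schema()].
#' @return Named numeric vector of length \code{4 * n_pairs}, pair-major.
#' @export
power_differences <- function(psd_values, schema) {
  nc <- length(schema$channels)
  if (length(psd_values) != 5 * nc)
    stop("psd_values length must be 5 * n_channels")
  pm <- matrix(psd_values, nrow = 5,
               dimnames = list(psd_band_names(), schema$channels))
  pairs <- schema$pair_list
  missing <- setdiff(as.vector(pairs), schema$channels)
  if (length(missing))
    stop("pair channel absent from schema: ", paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(pairs)), function(p)
    pm[diff_band_names(), pairs[p, "right"]] -
      pm[diff_band_names(), pairs[p, "left"]])
  out <- unlist(out)
  names(out) <- as.vector(t(outer(
    paste(pairs[, "right"], pairs[, "left"], sep = "-"),
    paste0("dpsd.", diff_band_names()), paste, sep = ".")))
  out
}

#' Hilbert-Huang spectrum band features
#'
#' Per channel the signal is decomposed into IMFs by [emd_sift()]; each IMF's
#' analytic signal yields instantaneous amplitude a(t) and frequency f(t).
#' For each band B over all (IMF, t) samples with f(t) in B (edges excluded):
#' the mean of a(t)^2, and the a^2-weighted mean of f(t); both 0 when the
#' band receives no samples. A flat (zero-variance) channel yields zeros.
#'
#' @param trial a preprocessed [eeg_trial()].
#' @param edge_frac fraction of samples excluded at each end of the trial
#'   before band averaging (edge effects of the analytic signal).
#' @param max_imf,sd_thresh EMD settings, see [emd_sift()].
#' @return Named numeric vector of length \code{10 * n_channels}: all
#'   squared-amplitude features (channel-major, band-minor) followed by all
#'   instantaneous-frequency features.
#' @export
hhs_features <- function(trial, edge_frac = 0.05, max_imf = 10,
                         sd_thresh = 0.2) {
  bands <- eeg_bands()[hhs_band_names()]
  nb <- length(bands)
  n <- ncol(trial$data)
  edge <- ceiling(edge_frac * n)
  keep <- (edge + 1):(n - edge)
  amp_feat <- matrix(0, nb, nrow(trial$data))
  if_feat <- matrix(0, nb, nrow(trial$data))
  for (ci in seq_len(nrow(trial$data))) {
    x <- trial$data[ci, ]
    if (stats::sd(x) == 0) next
    imfs <- emd_sift(x, max_imf = max_imf, sd_thresh = sd_thresh)
    if (length(imfs) == 0)
      stop("EMD produced no IMF for channel ", trial$channels[ci])
    a2 <- c(); fr <- c()
    for (imf in imfs) {
      af <- imf_amp_freq(imf, trial$fs)
      a2 <- c(a2, af$amp[keep]^2)
      fr <- c(fr, af$freq[keep])
    }
    for (b in seq_len(nb)) {
      sel <- fr >= bands[[b]][1] & fr < bands[[b]][2]
      if (any(sel)) {
        mass <- sum(a2[sel])
        amp_feat[b, ci] <- mass / sum(sel)
        if_feat[b, ci] <- if (mass > 0) sum(a2[sel] * fr[sel]) / mass else 0
      }
    }
  }
  out <- c(as.vector(amp_feat), as.vector(if_feat))
  names(out) <- c(
    as.vector(t(outer(trial$channels, paste0("hhs_amp.", hhs_band_names()),
                      paste, sep = "."))),
    as.vector(t(outer(trial$channels, paste0("hhs_if.", hhs_band_names()),
                      paste, sep = "."))))
  out
}

#' Extract the full multi-domain feature vector of one trial
#'
#' Concatenates [time_stats()], [band_psd()], [power_differences()] and
#' [hhs_features()] in schema order. For the 32-channel montage this is the
#' 664-dimensional vector partitioned (128, 160, 56, 160, 160) into subsets
#' F1..F5.
#'
#' @param trial a preprocessed [eeg_trial()].
#' @param schema a [feature_schema()] matching the trial's montage.
#' @return Named numeric vector of length \code{length(schema$names)} with
#'   attribute \code{label}.
#' @export
extract_features <- function(trial, schema = feature_schema()) {
  if (!identical(trial$channels, schema$channels))
    stop("trial channels do not match the feature schema montage")
  psd <- band_psd(trial)
  v <- c(time_stats(trial), psd, power_differences(psd, schema),
         hhs_features(trial))
  stopifnot(length(v) == length(schema$names))
  names(v) <- schema$names
  attr(v, "label") <- trial$label
  v
}

#' Extract a feature matrix from a list of trials
#'
#' @param trials list of raw [eeg_trial()] objects (preprocessing is applied
#'   when the sampling rate or \code{preprocess} demands it).
#' @param schema a [feature_schema()].
#' @param target_fs sampling rate used by [preprocess_trial()].
#' @param preprocess apply [preprocess_trial()] before extraction.
#' @return List with \code{features} (trials x n_features matrix) and
#'   \code{labels} (trials x 2 integer matrix, columns arousal/valence).
#' @export
extract_trials <- function(trials, schema = feature_schema(),
                           target_fs = 128, preprocess = TRUE) {
  rows <- lapply(trials, function(tr) {
    if (preprocess) tr <- preprocess_trial(tr, target_fs = target_fs)
    extract_features(tr, schema)
  })
  features <- do.call(rbind, lapply(rows, as.numeric))
  colnames(features) <- schema$names
  labels <- do.call(rbind, lapply(trials, function(tr) tr$label))
  colnames(labels) <- c("arousal", "valence")
  list(features = features, labels = labels)
}

#' Column-wise z-scoring of a subject's feature matrix
#'
#' Each column is centred and scaled by that subject's own statistics;
#' zero-variance columns map to all zeros.
#'
#' @param x instances x features numeric matrix with >= 2 rows.
#' @return List with the standardized matrix \code{x} and the per-column
#'   \code{center} and \code{scale} used (sample SD).
#' @export
standardize_features <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2)
    stop("standardization needs a matrix with at least 2 instances")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  list(x = apply_standardization(x, center, scale),
       center = center, scale = scale)
}

#' Apply stored standardization statistics to new rows
#'
#' @param x instances x features matrix.
#' @param center,scale per-column statistics from [standardize_features()].
#' @return Standardized matrix; columns with \code{scale == 0} become 0.
#' @export
apply_standardization <- function(x, center, scale) {
  z <- sweep(x, 2, center, "-")
  nz <- scale > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, scale[nz], "/")
  z[, !nz] <- 0
  z
}

#' Write a feature matrix with labels as delimited text
#'
#' @param features instances x features matrix.
#' @param labels instances x 2 label matrix.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_feature_matrix <- function(features, labels, path) {
  df <- data.frame(features, check.names = FALSE)
  df$arousal <- labels[, 1]
  df$valence <- labels[, 2]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path TSV path.
#' @return List with \code{features} and \code{labels} matrices.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  lab <- as.matrix(df[, c("arousal", "valence")])
  feat <- as.matrix(df[, setdiff(colnames(df), c("arousal", "valence"))])
  list(features = feat, labels = lab)
}
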