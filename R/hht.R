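# Hilbert-Huang spectrum machinery: empirical mode decomposition by standard
# sifting with cubic-spline envelopes, then analytic-signal amplitude and
# instantaneous frequency per intrinsic mode function (IMF).

find_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d); s[s == 0] <- 1
  ds <- diff(s)
  list(maxima = which(ds < 0) + 1L, minima = which(ds > 0) + 1L)
}

# Cubic-spline envelope through extrema, with the outermost extrema mirrored
# across both ends to suppress boundary overshoot.
envelope_through <- function(t, v, n) {
  k <- min(2, length(t))
  tt <- c(2 - rev(t[seq_len(k)]), t, 2 * n - rev(t[length(t) - seq_len(k) + 1]))
  vv <- c(rev(v[seq_len(k)]), v, rev(v[length(v) - seq_len(k) + 1]))
  stats::spline(tt, vv, xout = seq_len(n))$y
}

sift_once <- function(x, n) {
  ex <- find_extrema(x)
  if (length(ex$maxima) < 2 || length(ex$minima) < 2) return(NULL)
  up <- envelope_through(ex$maxima, x[ex$maxima], n)
  lo <- envelope_through(ex$minima, x[ex$minima], n)
  x - (up + lo) / 2
}

#' Empirical mode decomposition
#'
#' Standard sifting with cubic-spline envelopes through local extrema
#' (endpoints clamped), a Cauchy-type stop criterion
#' \eqn{\sum(h_{prev}-h_{new})^2 / \sum h_{prev}^2 < sd\_thresh}, and a cap
#' on the number of IMFs. Decomposition stops when the residue has fewer
#' than two maxima or minima.
#'
#' @param x numeric signal.
#' @param max_imf maximum number of IMFs.
#' @param sd_thresh Cauchy stop threshold per sift.
#' @param max_sift maximum sifting iterations per IMF.
#' @return List of numeric IMF vectors (possibly empty for a constant input).
#' @export
emd_sift <- function(x, max_imf = 10, sd_thresh = 0.2, max_sift = 50) {
  n <- length(x)
  imfs <- list()
  resid <- x
  e0 <- sum(x^2)
  for (k in seq_len(max_imf)) {
    if (sum(resid^2) < 1e-8 * e0) break     # residue energy exhausted
    h <- resid
    ok <- TRUE
    for (it in seq_len(max_sift)) {
      h_new <- sift_once(h, n)
      if (is.null(h_new)) { ok <- it > 1; break }
      num <- sum((h - h_new)^2); den <- sum(h^2)
      h <- h_new
      if (den == 0 || num / den < sd_thresh) break
    }
    if (!ok) break
    imfs[[k]] <- h
    resid <- resid - h
    ex <- find_extrema(resid)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
  }
  imfs
}

# Analytic signal via FFT: zero negative frequencies, double positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Instantaneous amplitude and frequency (Hz) of one IMF.
imf_amp_freq <- function(imf, fs) {
  z <- analytic_signal(imf)
  amp <- Mod(z)
  ph <- signal::unwrap(Arg(z))
  n <- length(ph)
  # central-difference phase derivative (one-sided at edges)
  dph <- numeric(n)
  dph[2:(n - 1)] <- (ph[3:n] - ph[1:(n - 2)]) / 2
  dph[1] <- ph[2] - ph[1]
  dph[n] <- ph[n] - ph[n - 1]
  list(amp = amp, freq = dph * fs / (2 * pi))
}
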