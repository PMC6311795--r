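# Welch power spectral density: Hann-windowed, mean-detrended segments with
# 50% overlap, one-sided density scaling (power per Hz).
welch_psd <- function(x, fs, nperseg = 2 * fs, overlap = 0.5) {
  n <- length(x)
  nperseg <- min(round(nperseg), n)
  step <- max(1, round(nperseg * (1 - overlap)))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nperseg - 1)) / (nperseg - 1)))
  u <- fs * sum(w^2)                      # density normalisation
  nfreq <- nperseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / u
    p <- p[seq_len(nfreq)]
    # one-sided: double everything except DC (and Nyquist when present)
    dbl <- seq(2, nfreq - if (nperseg %% 2 == 0) 1 else 0)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nperseg,
       psd = acc / length(starts))
}

# Mean PSD within half-open band [lo, hi).
band_average <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq < band[2]
  if (!any(sel)) 0 else mean(psd[sel])
}
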