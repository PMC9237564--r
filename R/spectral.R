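# Welch power/cross spectral machinery shared by bad-channel detection and
# coherence estimation.

# Split a length-n signal into Hann-windowed segments; returns the FFT of
# each segment (freq x segment matrix) and the frequency axis.
segment_ffts <- function(x, fs, seg_s = 1, overlap = 0.5) {
  nseg <- as.integer(round(seg_s * fs))
  if (length(x) < nseg)
    stop_invalid("signal shorter than one estimator segment (",
                 nseg, " samples)")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  X <- vapply(starts, function(s) {
    seg <- x[s:(s + nseg - 1L)]
    stats::fft((seg - mean(seg)) * w)
  }, complex(nseg))
  nf <- nseg %/% 2L + 1L
  list(fft = X[seq_len(nf), , drop = FALSE],
       freq = (seq_len(nf) - 1L) * fs / nseg,
       n_seg = length(starts))
}

# Welch PSD estimate (arbitrary scale; used for band-power ratios).
# agg = "median" aggregates segment periodograms robustly, so transient
# artifacts do not dominate a channel's spectral profile.
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5,
                      agg = c("mean", "median")) {
  agg <- match.arg(agg)
  sf <- segment_ffts(x, fs, seg_s, overlap)
  p2 <- Mod(sf$fft)^2
  pw <- if (agg == "median") apply(p2, 1, stats::median) else rowMeans(p2)
  list(freq = sf$freq, power = pw)
}

band_power <- function(psd, low_hz, high_hz) {
  sel <- psd$freq >= low_hz & psd$freq <= high_hz
  sum(psd$power[sel])
}
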