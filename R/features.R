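#' Magnitude-squared coherence between two signals in a band
#'
#' Welch-style estimate: Hann-windowed segments, per-frequency coherence
#' `|Sxy|^2 / (Sxx Syy)` averaged over the band's frequency bins. Symmetric
#' in its arguments and bounded in `[0, 1]`.
#'
#' @param x,y Equal-length signals.
#' @param band Band name or definition ([get_band()]).
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default 1).
#' @param overlap Segment overlap fraction (default 0.5).
#' @return Scalar coherence in `[0, 1]`.
#' @export
coherence <- function(x, y, band, fs, seg_s = 1, overlap = 0.5) {
  if (length(x) != length(y)) stop_invalid("signals must have equal length")
  b <- get_band(band)
  fx <- segment_ffts(x, fs, seg_s, overlap)
  fy <- segment_ffts(y, fs, seg_s, overlap)
  if (fx$n_seg < 2) stop_invalid("need >= 2 estimator segments")
  band_coherence(fx, fy, b)
}

# Coherence from precomputed segment FFTs (shared with the matrix extractor).
band_coherence <- function(fx, fy, b) {
  sel <- fx$freq >= b$low_hz & fx$freq <= b$high_hz
  Sxy <- rowMeans(fx$fft[sel, , drop = FALSE] * Conj(fy$fft[sel, , drop = FALSE]))
  Sxx <- rowMeans(Mod(fx$fft[sel, , drop = FALSE])^2)
  Syy <- rowMeans(Mod(fy$fft[sel, , drop = FALSE])^2)
  ok <- Sxx > 0 & Syy > 0
  if (!any(ok)) return(0)
  mean(Mod(Sxy[ok])^2 / (Sxx[ok] * Syy[ok]))
}

band_filter_if <- function(x, band, fs) {
  if (is.null(band)) return(x)
  b <- get_band(band)
  sos_filtfilt(butter_bandpass_sos(b$low_hz, b$high_hz, fs), x)
}

#' Phase lag index
#'
#' `|mean(sign(delta phi))|` over samples, where `delta phi` is the
#' instantaneous phase difference from the analytic signal; `sign(0) = 0`.
#' 0 for identical signals, 1 for a constant non-zero phase lag.
#'
#' @param x,y Equal-length band-limited signals (or pass `band` and `fs`
#'   to filter first).
#' @param band Optional band to filter into before phase extraction.
#' @param fs Sampling rate (required with `band`).
#' @param trim Samples to drop from each edge before averaging (filter
#'   transient suppression; default 0).
#' @return Scalar in `[0, 1]`.
#' @export
pli <- function(x, y, band = NULL, fs = NULL, trim = 0) {
  dphi <- phase_diff(x, y, band, fs, trim)
  abs(mean(sign(dphi)))
}

#' Directed phase lag index
#'
#' Mean Heaviside of the phase difference, with `H(0) = 0.5`; 0.5 means no
#' phase leadership and `dpli(x, y) + dpli(y, x) = 1` always.
#'
#' @inheritParams pli
#' @return Scalar in `[0, 1]`.
#' @export
dpli <- function(x, y, band = NULL, fs = NULL, trim = 0) {
  dphi <- phase_diff(x, y, band, fs, trim)
  mean((dphi > 0) + 0.5 * (dphi == 0))
}

phase_diff <- function(x, y, band, fs, trim) {
  if (length(x) != length(y)) stop_invalid("signals must have equal length")
  x <- band_filter_if(x, band, fs); y <- band_filter_if(y, band, fs)
  dphi <- wrap_pi(inst_phase(x) - inst_phase(y))
  if (trim > 0) dphi <- dphi[(trim + 1):(length(dphi) - trim)]
  dphi
}

wrap_pi <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  # map the boundary -pi (from exact pi differences) consistently to pi
  out[out == -pi & a > 0] <- pi
  out
}

#' Tort modulation index from phase and amplitude series
#'
#' Kullback-Leibler divergence of the phase-binned mean-amplitude
#' distribution from uniform, normalized by `log(n_bins)`: 0 for amplitude
#' independent of phase, 1 when all amplitude concentrates in one bin.
#'
#' @param phase Phase series in radians.
#' @param amplitude Non-negative amplitude series, same length.
#' @param n_bins Number of phase bins (default 18).
#' @return Modulation index in `[0, 1]`.
#' @export
tort_mi <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude))
    stop_invalid("phase and amplitude must have equal length")
  if (all(amplitude == 0)) stop_invalid("degenerate amplitude: all zeros")
  bins <- pmin(floor((wrap_pi(phase) + pi) / (2 * pi) * n_bins) + 1L, n_bins)
  m <- vapply(seq_len(n_bins), function(b) {
    v <- amplitude[bins == b]
    if (length(v) == 0) 0 else mean(v)
  }, 0)
  p <- m / sum(m)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(n_bins) - h) / log(n_bins)
}

#' Phase-amplitude coupling (Tort modulation index) between two signals
#'
#' Phase of the low-band-filtered first signal against the amplitude
#' envelope of the high-band-filtered second signal.
#'
#' @param low_sig,high_sig Signals (raw or broadband).
#' @param low_band,high_band Band names/definitions; the low band must lie
#'   entirely below the high band.
#' @param fs Sampling rate in Hz.
#' @param n_bins Phase bins (default 18).
#' @param trim Edge samples to drop (default 0).
#' @return Modulation index in `[0, 1]`.
#' @export
pac <- function(low_sig, high_sig, low_band, high_band, fs, n_bins = 18,
                trim = 0) {
  lb <- get_band(low_band); hb <- get_band(high_band)
  if (lb$high_hz >= hb$low_hz)
    stop_invalid("low band must lie below high band")
  ph <- inst_phase(band_filter_if(low_sig, lb, fs))
  am <- Mod(analytic_signal(band_filter_if(high_sig, hb, fs)))
  if (trim > 0) {
    keep <- (trim + 1):(length(ph) - trim)
    ph <- ph[keep]; am <- am[keep]
  }
  tort_mi(ph, am, n_bins)
}

#' Cross-frequency coupling synchronization index
#'
#' Phase-synchronization (mean resultant vector length) between the
#' low-band phase of `x` and the phase of the low-band-filtered amplitude
#' envelope of the high band of `y`.
#'
#' @inheritParams pac
#' @param x,y Signals.
#' @return Synchronization index in `[0, 1]`.
#' @export
cfc_sync_index <- function(x, y, low_band, high_band, fs, trim = 0) {
  lb <- get_band(low_band); hb <- get_band(high_band)
  if (lb$high_hz >= hb$low_hz)
    stop_invalid("low band must lie below high band")
  ph1 <- inst_phase(band_filter_if(x, lb, fs))
  env <- Mod(analytic_signal(band_filter_if(y, hb, fs)))
  env_f <- band_filter_if(env - mean(env), lb, fs)
  ph2 <- inst_phase(env_f)
  d <- ph1 - ph2
  if (trim > 0) d <- d[(trim + 1):(length(d) - trim)]
  Mod(mean(exp(1i * d)))
}
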