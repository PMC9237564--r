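#' Design a Butterworth band-pass filter as second-order sections
#'
#' Designs an order-`order` Butterworth band-pass filter (so 2 x `order`
#' poles after the band-pass transform) and returns it as a cascade of
#' biquad sections. Direct-form transfer functions of this order are
#' numerically singular in double precision for narrow EEG bands; the
#' cascade form is stable.
#'
#' @param low_hz,high_hz Band edges in Hz.
#' @param fs Sampling rate in Hz; must exceed `2 * high_hz`.
#' @param order Butterworth design order (default 12).
#' @return An object of class `sos_filter`: list with `sos` (n x 6 matrix,
#'   columns b0 b1 b2 a0 a1 a2) and the design parameters.
#' @export
butter_bandpass_sos <- function(low_hz, high_hz, fs, order = 12) {
  if (!(low_hz > 0 && high_hz > low_hz))
    stop_invalid("need 0 < low_hz < high_hz")
  if (fs <= 2 * high_hz)
    stop_invalid("sampling rate ", fs, " Hz must exceed twice the upper band edge (",
                 2 * high_hz, " Hz)")
  n <- as.integer(order)
  # analog lowpass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped analog band edges
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # lowpass -> bandpass: each prototype pole yields a conjugate-ish pair
  pb <- p_lp * bw / 2
  disc <- sqrt(pb^2 - w0^2)
  p_bp <- c(pb + disc, pb - disc)
  # bilinear transform
  zp <- (1 + p_bp / (2 * fs)) / (1 - p_bp / (2 * fs))
  if (any(Mod(zp) >= 1))
    stop_invalid("unstable filter design at fs = ", fs,
                 " Hz; widen the band or raise the sampling rate")
  # group into conjugate pairs: order by imaginary part magnitude then real
  zp <- zp[order(Re(zp), abs(Im(zp)))]
  pos <- zp[Im(zp) >= 0]
  pos <- pos[order(Mod(pos), decreasing = TRUE)]
  sos <- matrix(0, nrow = n, ncol = 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (i in seq_len(n)) {
    p <- pos[i]
    # digital band-pass zeros: one at z = +1 and one at z = -1 per section
    sos[i, ] <- c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
  }
  out <- structure(list(sos = sos, low_hz = low_hz, high_hz = high_hz,
                        fs = fs, order = n), class = "sos_filter")
  # normalise to unit gain at the band's geometric centre
  f0 <- sqrt(low_hz * high_hz)
  g <- Mod(sos_response(out, f0))
  out$sos[1, 1:3] <- out$sos[1, 1:3] / g
  out
}

#' Complex frequency response of a second-order-section cascade
#'
#' @param filt An `sos_filter`.
#' @param f Frequencies in Hz (vectorised).
#' @return Complex response at each frequency.
#' @export
sos_response <- function(filt, f) {
  z <- exp(-1i * 2 * pi * f / filt$fs)
  h <- rep(1 + 0i, length(z))
  for (i in seq_len(nrow(filt$sos))) {
    s <- filt$sos[i, ]
    h <- h * (s[1] + s[2] * z + s[3] * z^2) / (s[4] + s[5] * z + s[6] * z^2)
  }
  unname(h)
}

sos_filter_once <- function(filt, x) {
  sosfilt_cpp(filt$sos, x)
}

#' Zero-phase (forward-backward) filtering through an SOS cascade
#'
#' Applies the cascade forward and backward with odd-reflection edge padding,
#' giving zero net phase shift and squared magnitude response.
#'
#' @param filt An `sos_filter`.
#' @param x Numeric vector or channels-in-rows matrix.
#' @return Filtered data, same shape as `x`.
#' @export
sos_filtfilt <- function(filt, x) {
  vec <- !is.matrix(x)
  m <- if (vec) matrix(x, ncol = 1) else t(x)
  nx <- nrow(m)
  pad <- min(3L * 2L * nrow(filt$sos), nx - 1L)
  me <- rbind(
    2 * m[rep(1L, pad), , drop = FALSE] - m[(pad + 1):2, , drop = FALSE],
    m,
    2 * m[rep(nx, pad), , drop = FALSE] - m[(nx - 1):(nx - pad), , drop = FALSE]
  )
  y <- sos_filter_once(filt, me)
  y <- sos_filter_once(filt, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE][(pad + 1):(pad + nx), , drop = FALSE]
  if (vec) return(as.numeric(y))
  out <- t(y)
  dimnames(out) <- dimnames(x)
  out
}
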