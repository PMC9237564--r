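#' Network channel assignments for a montage
#'
#' Designates, per intrinsic network, the channel subset that carries its
#' state-gated coupling signature in the synthetic EEG. The first quarter of
#' the montage carries the DMN signature, the second the CEN, the third the
#' SN; remaining channels carry background noise only. The first channels
#' after the network sets form the "frontal" set for blink artifacts and
#' the last two the "edge" set for muscle artifacts, so artifacts land off
#' the signature channels when the montage allows it.
#'
#' @param n_channels Montage size.
#' @return List with integer vectors `dmn`, `cen`, `sn`, `frontal`, `edge`.
#' @export
network_channel_sets <- function(n_channels) {
  k <- max(2L, n_channels %/% 4L)
  rest <- setdiff(seq_len(n_channels), 1:(3 * k))
  frontal <- if (length(rest) >= 4) rest[1:4] else 1:min(4L, n_channels)
  list(dmn = 1:k, cen = (k + 1):(2 * k), sn = (2 * k + 1):(3 * k),
       frontal = frontal,
       edge = (n_channels - 1L):n_channels)
}

# Roughly uniform unit-sphere electrode positions (Fibonacci lattice),
# standing in for a real montage's 3-D coordinates.
fibonacci_positions <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Synthesize a multichannel EEG recording from latent network states
#'
#' Each network state imprints a band-limited coupling signature on its
#' designated channel subset: a common alpha (10 Hz) oscillator with a
#' fixed pi/4 inter-channel phase lag for the DMN, beta (20 Hz) plus gamma
#' (40 Hz) oscillators for the CEN, and a theta (6 Hz) oscillator with a
#' theta-phase-to-gamma-amplitude coupling motif for the SN. Signature
#' amplitude in each 5-s window scales with the window's ground-truth
#' activation level and with `sqrt(snr)` relative to unit-power 1/f-like
#' background noise. Optional blink and muscle artifacts and bad channels
#' are injected and recorded in the ground-truth sidecar.
#'
#' @param latent A `latent_state_series`.
#' @param spec A [cohort_spec()] (montage, snr, artifact parameters).
#' @param seed Integer seed.
#' @param schedule Optional `task_schedule` to attach to the recording.
#' @return An `eeg_recording`: list with `data` (channels x samples, uV
#'   scale), `fs`, `ch_names`, `ch_pos`, `schedule`, `ground_truth`.
#' @export
synthesize_eeg <- function(latent, spec = cohort_spec(), seed = NULL,
                           schedule = NULL) {
  fs <- spec$sampling_rate
  nch <- spec$n_channels
  if (fs < 100) stop_invalid("sampling rate ", fs, " Hz is below twice the ",
                             "gamma upper edge (100 Hz)")
  if (fs < 128) stop_invalid("sampling_rate must be >= 128 Hz")
  if (nch < 8) stop_invalid("need at least 8 channels")
  window_s <- 5
  dur <- max(latent$onset_s) + window_s
  n <- as.integer(round(dur * fs))
  sets <- network_channel_sets(nch)
  tt <- (seq_len(n) - 1) / fs

  local_seed(seed, {
    # background: AR(1) pink-ish noise, unit variance, independent channels
    e <- matrix(rnorm(n * nch), n, nch)
    bg <- stats::filter(e, 0.95, method = "recursive")
    bg <- matrix(as.numeric(bg), n, nch)
    bg <- sweep(bg, 2, apply(bg, 2, stats::sd), "/")
    data <- t(bg)

    # per-sample activation envelopes from the 5-s window levels
    env <- function(a) {
      v <- numeric(n)
      for (w in seq_len(nrow(latent))) {
        s0 <- as.integer(round(latent$onset_s[w] * fs)) + 1L
        s1 <- min(as.integer(round((latent$onset_s[w] + window_s) * fs)), n)
        v[s0:s1] <- a[w]
      }
      v
    }
    amp <- sqrt(2 * spec$snr)
    nch_all <- seq_len(nch)
    # Oscillator phases follow a drifting random walk (phase diffusion), so
    # two oscillators only stay phase-locked if they share the same walk.
    walk_sd <- 0.08
    osc_phase <- function(freq) 2 * pi * freq * tt +
      cumsum(rnorm(n, 0, walk_sd)) + runif(1, 0, 2 * pi)
    # Every channel carries every rhythm at constant power, so band spectra
    # are homogeneous across the montage and across states. A network's
    # activation level gates what FRACTION of its members' rhythm comes
    # from the shared oscillator (fixed pi/4 inter-channel lag) versus the
    # channel's own independent oscillator: activation is written into the
    # coupling structure, not the power, and snr sets the rhythm power
    # against the 1/f background.
    add_rhythm <- function(members, freq, envv, scale = 1) {
      common <- osc_phase(freq)
      for (ch in nch_all) {
        j <- match(ch, members)
        own <- osc_phase(freq)
        rhythm <- if (is.na(j)) sin(own)
        else sqrt(envv) * sin(common + (j - 1) * pi / 4) +
          sqrt(1 - envv) * sin(own)
        data[ch, ] <<- data[ch, ] + scale * amp * rhythm
      }
    }
    e_dmn <- env(latent$a_dmn); e_cen <- env(latent$a_cen)
    e_sn <- env(latent$a_sn)
    add_rhythm(sets$dmn, 10, e_dmn)
    add_rhythm(sets$cen, 20, e_cen, scale = 1 / sqrt(2))
    add_rhythm(sets$cen, 40, e_cen, scale = 1 / sqrt(2))
    # SN: theta plus a theta-phase-to-gamma-amplitude PAC motif, again with
    # the coupled fraction gated by the SN activation level
    th_common <- osc_phase(6)
    pac_rms <- sqrt(3 / 8)
    for (ch in nch_all) {
      j <- match(ch, sets$sn)
      th_own <- osc_phase(6)
      gph <- osc_phase(42)
      if (is.na(j)) {
        theta <- sin(th_own)
        genv <- pac_rms
      } else {
        th <- th_common + (j - 1) * pi / 4
        theta <- sqrt(e_sn) * sin(th) + sqrt(1 - e_sn) * sin(th_own)
        genv <- e_sn * 0.5 * (1 + cos(th)) + (1 - e_sn) * pac_rms
      }
      data[ch, ] <- data[ch, ] + amp * (theta + genv * sin(gph)) / sqrt(1.5)
    }

    # artifacts
    gt_blinks <- numeric(0); gt_muscle <- numeric(0)
    a <- spec$artifacts
    if ((a$blink_rate %||% 0) > 0) {
      nb <- rpois(1, a$blink_rate * dur)
      gt_blinks <- sort(runif(nb, 0.5, dur - 0.5))
      for (tc in gt_blinks) {
        idx <- which(abs(tt - tc) < 0.3)
        bump <- a$blink_amp * exp(-(tt[idx] - tc)^2 / (2 * 0.08^2))
        w <- seq(1, 0.5, length.out = length(sets$frontal))
        for (j in seq_along(sets$frontal))
          data[sets$frontal[j], idx] <- data[sets$frontal[j], idx] + w[j] * bump
      }
    }
    if ((a$muscle_rate %||% 0) > 0) {
      nm <- rpois(1, a$muscle_rate * dur)
      gt_muscle <- sort(runif(nm, 0.5, dur - 1.5))
      for (tc in gt_muscle) {
        idx <- which(tt >= tc & tt < tc + 1)
        for (ch in sets$edge) {
          hf <- diff(rnorm(length(idx) + 1))
          data[ch, idx] <- data[ch, idx] + a$muscle_amp * hf / stats::sd(hf)
        }
      }
    }
    # per-channel electrode gain variation (impedance differences)
    gains <- exp(rnorm(nch, 0, 0.15))
    data <- data * gains
    bad <- integer(0)
    if ((a$n_bad_channels %||% 0) > 0) {
      pool <- setdiff(seq_len(nch), c(sets$dmn, sets$cen, sets$sn))
      if (length(pool) < a$n_bad_channels) pool <- seq_len(nch)
      bad <- sort(sample(pool, a$n_bad_channels))
      for (ch in bad) data[ch, ] <- rnorm(n, 0, 10)
    }

    rec <- structure(list(
      data = data * 10,   # uV scale
      fs = fs,
      ch_names = sprintf("Ch%03d", seq_len(nch)),
      ch_pos = fibonacci_positions(nch),
      schedule = schedule,
      ground_truth = list(networks = sets[c("dmn", "cen", "sn")],
                          bad_channels = bad, blink_times = gt_blinks,
                          muscle_times = gt_muscle, channel_gains = gains)
    ), class = "eeg_recording")
    rec
  })
}

#' Construct an EEG recording from a data matrix
#'
#' @param data Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param ch_names Optional channel labels.
#' @param ch_pos Optional channels x 3 position matrix (unit sphere).
#' @param schedule Optional `task_schedule`.
#' @return An `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, ch_names = NULL, ch_pos = NULL,
                          schedule = NULL) {
  stopifnot(is.matrix(data), fs > 0)
  if (anyNA(data)) stop_invalid("EEG data contain NaN/NA")
  structure(list(data = data, fs = fs,
                 ch_names = ch_names %||% sprintf("Ch%03d", seq_len(nrow(data))),
                 ch_pos = ch_pos %||% fibonacci_positions(nrow(data)),
                 schedule = schedule,
                 ground_truth = NULL),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.null(x$schedule))
    cat(sprintf("  schedule: %d blocks (%s)\n", nrow(x$schedule),
                paste(x$schedule$label, collapse = " ")))
  invisible(x)
}
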