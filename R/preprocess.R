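#' Band-pass filter an EEG recording
#'
#' Zero-phase Butterworth filtering (design order 12, effective order 24
#' after the forward-backward pass) applied per channel as a cascade of
#' second-order sections. The input recording is not modified.
#'
#' @param rec An `eeg_recording`.
#' @param band Band name or definition accepted by [get_band()].
#' @param order Butterworth design order (default 12).
#' @return A new `eeg_recording` with filtered data.
#' @export
bandpass_filter <- function(rec, band, order = 12) {
  b <- get_band(band)
  filt <- butter_bandpass_sos(b$low_hz, b$high_hz, rec$fs, order)
  out <- rec
  out$data <- sos_filtfilt(filt, rec$data)
  out
}

#' Detect bad channels from spectral characteristics
#'
#' Flags channels whose log band power deviates from the montage in any of
#' the six analysis bands by more than `threshold` robust z-units
#' (median/MAD across channels).
#'
#' @param rec An `eeg_recording` (broadband, 1-50 Hz content).
#' @param threshold Robust z threshold (default 3).
#' @param min_log_ratio Absolute floor on the log band-power deviation from
#'   the montage median (default `log(2)`, i.e. a two-fold power
#'   deviation): keeps near-identical montages from flagging channels on
#'   vanishing MAD denominators.
#' @return Character vector of flagged channel labels (possibly empty),
#'   with integer indices in attribute `"index"`.
#' @export
detect_bad_channels <- function(rec, threshold = 3, min_log_ratio = log(2)) {
  nch <- nrow(rec$data)
  if (nch < 8)
    stop_invalid("bad-channel detection needs >= 8 channels (robust ",
                 "statistics are unreliable below that); got ", nch)
  bd <- band_definitions()
  psds <- apply(rec$data, 1, welch_psd, fs = rec$fs, agg = "median",
                simplify = FALSE)
  logp <- sapply(seq_len(nrow(bd)), function(b) {
    vapply(psds, function(p) log(band_power(p, bd$low_hz[b], bd$high_hz[b]) +
                                   1e-300), 0)
  })
  flag <- rep(FALSE, nch)
  for (b in seq_len(ncol(logp))) {
    v <- logp[, b]
    s <- stats::mad(v)
    z <- if (s == 0) rep(0, nch) else (v - stats::median(v)) / s
    flag <- flag | (abs(z) > threshold &
                      abs(v - stats::median(v)) > min_log_ratio)
  }
  idx <- which(flag)
  structure(rec$ch_names[idx], index = idx)
}

# Power fraction of a source in [low, high] Hz relative to the 0-50 Hz
# analysis band (the stage input is broadband 1-50 Hz filtered data).
power_fraction <- function(x, fs, low, high) {
  p <- welch_psd(x, fs)
  tot <- band_power(p, 0, 50)
  if (tot == 0) return(0)
  band_power(p, low, high) / tot
}

#' Remove artifactual independent components
#'
#' Decomposes the recording with FastICA and zeroes components matching
#' transparent artifact heuristics: blink components carry dominantly
#' low-frequency (< 3 Hz) source power with spatially focal loading;
#' muscle components carry a dominant gamma-band (> 30 Hz) power fraction.
#' Thresholds are explicit arguments.
#'
#' @param rec An `eeg_recording`.
#' @param blink_lowfreq_frac Minimum low-frequency power fraction for a
#'   blink component (default 0.6).
#' @param blink_focal_frac Minimum fraction of mixing-vector energy on the
#'   4 highest-loading channels for a blink component (default 0.6).
#' @param muscle_gamma_frac Minimum gamma power fraction for a muscle
#'   component (default 0.5).
#' @param n_comp,max_iter,seed Passed to [fast_ica()].
#' @param max_fit_samples Maximum samples used to estimate the unmixing
#'   (strided subsample; the cleaning operator applies to all samples).
#' @param on_fail Non-convergence handling, see [fast_ica()].
#' @return List with `recording` (cleaned), `n_removed`, `removed` (indices),
#'   `cleaning_matrix` (channels x channels linear operator, applicable to
#'   band-filtered copies of the same data).
#' @export
remove_artifact_components <- function(rec, blink_lowfreq_frac = 0.6,
                                       blink_focal_frac = 0.6,
                                       muscle_gamma_frac = 0.5,
                                       n_comp = NULL, max_iter = 500,
                                       seed = 1, max_fit_samples = 20000,
                                       on_fail = c("error", "warn")) {
  stride <- max(1L, ncol(rec$data) %/% max_fit_samples)
  fit_dat <- rec$data[, seq(1, ncol(rec$data), by = stride), drop = FALSE]
  ica <- fast_ica(fit_dat, n_comp = n_comp, max_iter = max_iter, seed = seed,
                  on_fail = match.arg(on_fail))
  ica$S <- ica$W %*% (rec$data - ica$center)
  r <- nrow(ica$S)
  nch <- nrow(rec$data)
  is_artifact <- vapply(seq_len(r), function(k) {
    src <- ica$S[k, ]
    lf <- power_fraction(src, rec$fs, 0, 3)
    gf <- power_fraction(src, rec$fs, 30, 50)
    a2 <- ica$A[, k]^2
    focal <- sum(sort(a2, decreasing = TRUE)[1:min(4, nch)]) / sum(a2)
    (lf >= blink_lowfreq_frac && focal >= blink_focal_frac) ||
      gf >= muscle_gamma_frac
  }, TRUE)
  keep <- which(!is_artifact)
  M <- ica$A[, keep, drop = FALSE] %*% ica$W[keep, , drop = FALSE]
  out <- rec
  out$data <- M %*% (rec$data - ica$center) + ica$center
  list(recording = out, n_removed = sum(is_artifact),
       removed = which(is_artifact), cleaning_matrix = M)
}

#' Average-reference an EEG recording
#'
#' Subtracts, per sample, the mean over the retained channels; the mean of
#' retained channels is exactly zero afterwards. Idempotent.
#'
#' @param rec An `eeg_recording`.
#' @param exclude Channel labels or indices excluded from the mean (bad
#'   channels); they are re-referenced with the same mean.
#' @return A new `eeg_recording`.
#' @export
rereference_average <- function(rec, exclude = NULL) {
  idx <- resolve_channels(rec, exclude)
  retained <- setdiff(seq_len(nrow(rec$data)), idx)
  ref <- colMeans(rec$data[retained, , drop = FALSE])
  out <- rec
  out$data <- sweep(rec$data, 2, ref)
  out
}

resolve_channels <- function(rec, chans) {
  if (is.null(chans) || length(chans) == 0) return(integer(0))
  if (is.character(chans)) {
    idx <- match(chans, rec$ch_names)
    if (anyNA(idx)) stop_invalid("unknown channel(s): ",
                                 paste(chans[is.na(idx)], collapse = ", "))
    idx
  } else as.integer(chans)
}

# Perrin-style spherical-spline basis: g(cos(angle)) with stiffness m,
# truncated Legendre series.
spline_g <- function(cosang, m = 4, n_terms = 20) {
  # Legendre polynomials by recurrence, evaluated at cosang (vectorized)
  p_prev <- rep(1, length(cosang))   # P_0
  p_cur <- cosang                    # P_1
  out <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_new <- ((2 * n - 1) * cosang * p_cur - (n - 1) * p_prev) / n
    out <- out + (2 * n + 1) / (n * (n + 1))^m * p_new
    p_prev <- p_cur; p_cur <- p_new
  }
  out / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces bad channels by spherical-spline interpolation from the
#' remaining channels, but only when fewer than 5% of channels are bad
#' (the study's interpolation rule); otherwise the recording is rejected
#' with a distinct status rather than silently truncated.
#'
#' @param rec An `eeg_recording` with channel positions.
#' @param bads Channel labels or indices to interpolate.
#' @param limit Maximum tolerated bad-channel fraction (default 0.05).
#' @param stiffness,n_terms Spline parameters.
#' @return An `interp_result`: list with `status` one of `"identity"`,
#'   `"interpolated"`, `"rejected"`; `recording` (NULL when rejected);
#'   `n_bad`; `limit_n` (strict upper bound).
#' @export
interpolate_bad <- function(rec, bads, limit = 0.05, stiffness = 4,
                            n_terms = 20) {
  idx <- resolve_channels(rec, bads)
  nch <- nrow(rec$data)
  lim <- limit * nch
  res <- function(status, recording)
    structure(list(status = status, recording = recording,
                   n_bad = length(idx), limit_n = lim),
              class = "interp_result")
  if (length(idx) == 0) return(res("identity", rec))
  if (length(idx) >= lim) return(res("rejected", NULL))
  if (is.null(rec$ch_pos)) stop_invalid("channel positions required")
  pos <- rec$ch_pos / sqrt(rowSums(rec$ch_pos^2))
  good <- setdiff(seq_len(nch), idx)
  G <- spline_g(tcrossprod(pos[good, , drop = FALSE]), stiffness, n_terms)
  diag(G) <- diag(G) + 1e-5
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  Gb <- spline_g(pos[idx, , drop = FALSE] %*% t(pos[good, , drop = FALSE]),
                 stiffness, n_terms)
  rhs <- rbind(rec$data[good, , drop = FALSE], 0)
  cw <- solve(A, rhs)
  interp <- cbind(Gb, 1) %*% cw
  out <- rec
  out$data[idx, ] <- interp
  res("interpolated", out)
}

#' Epoch band-filtered recordings into 5-s task-aligned windows
#'
#' Cuts six non-overlapping 5-s windows from each 30-s task block, aligned
#' to block onsets, labeling every window with its trial index, block label,
#' and half (windows 1-3 = first, 4-6 = second).
#'
#' @param recs A named list of band-filtered `eeg_recording`s (one per
#'   band), or a single `eeg_recording` (treated as band "full").
#' @param schedule A `task_schedule`.
#' @param window_s Window length in seconds (default 5).
#' @return An `epoch_set`: list with `bands` (per band: windows x channels x
#'   samples array), `index` (window, trial, half, label), `fs`, `ch_names`,
#'   `provenance`.
#' @export
epoch_recording <- function(recs, schedule, window_s = 5) {
  if (inherits(recs, "eeg_recording")) recs <- list(full = recs)
  r1 <- recs[[1]]
  fs <- r1$fs
  nsamp <- ncol(r1$data)
  validate_schedule(schedule)
  wl <- as.integer(round(window_s * fs))
  index <- list(); slices <- list()
  for (b in seq_len(nrow(schedule))) {
    nw <- as.integer(round(schedule$duration_s[b] / window_s))
    end_sample <- round((schedule$onset_s[b] + schedule$duration_s[b]) * fs)
    if (end_sample > nsamp)
      stop_invalid("block ", b, " (", schedule$label[b], " at ",
                   schedule$onset_s[b], " s) extends past the end of the recording")
    for (w in seq_len(nw)) {
      s0 <- as.integer(round((schedule$onset_s[b]) * fs)) + (w - 1L) * wl + 1L
      slices[[length(slices) + 1L]] <- s0
      index[[length(index) + 1L]] <- data.frame(
        trial = b, half = if (w <= nw / 2) "first" else "second",
        label = schedule$label[b], stringsAsFactors = FALSE)
    }
  }
  nwin <- length(slices)
  idx_df <- if (nwin > 0) {
    cbind(data.frame(window = seq_len(nwin)), do.call(rbind, index))
  } else data.frame(window = integer(0), trial = integer(0),
                    half = character(0), label = character(0))
  bands <- lapply(recs, function(rec) {
    arr <- array(0, dim = c(nwin, nrow(rec$data), wl))
    for (w in seq_len(nwin)) {
      s0 <- slices[[w]]
      arr[w, , ] <- rec$data[, s0:(s0 + wl - 1L)]
    }
    arr
  })
  structure(list(bands = bands, index = idx_df, fs = fs,
                 ch_names = r1$ch_names, window_s = window_s,
                 provenance = list()),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- if (length(x$bands)) dim(x$bands[[1]]) else c(0, 0, 0)
  cat(sprintf("Epoch set: %d windows x %d channels x %d samples, bands: %s\n",
              d[1], d[2], d[3], paste(names(x$bands), collapse = ", ")))
  invisible(x)
}

#' Run the full EEG preprocessing chain
#'
#' Stage order: band filtering (six bands), bad-channel detection on the
#' broadband (1-50 Hz) data, ICA artifact removal estimated on the
#' broadband data and applied to every band, average referencing excluding
#' bad channels, spherical-spline interpolation of bad channels (subject to
#' the < 5% rule), and block-aligned 5-s epoching.
#'
#' @param rec A raw `eeg_recording` with a schedule attached (or pass
#'   `schedule`).
#' @param schedule Optional `task_schedule` overriding `rec$schedule`.
#' @param bad_threshold Robust z threshold for bad channels.
#' @param ica Logical: run ICA artifact removal (default TRUE).
#' @param ica_seed Seed for the ICA initialization.
#' @param ica_max_iter Fixed-point iteration cap for the ICA fit.
#' @param ... Passed to [remove_artifact_components()].
#' @return An `epoch_set` (with `provenance` recording the stage order, bad
#'   channels and removed component count), or a `preprocess_rejected`
#'   object when more than 5% of channels are bad.
#' @export
preprocess_eeg <- function(rec, schedule = NULL, bad_threshold = 3,
                           ica = TRUE, ica_seed = 1, ica_max_iter = 75, ...) {
  schedule <- schedule %||% rec$schedule
  if (is.null(schedule)) stop_invalid("no task schedule available")
  stages <- character(0)
  bd <- band_definitions()
  filtered <- lapply(seq_len(nrow(bd)), function(i)
    bandpass_filter(rec, bd$name[i]))
  names(filtered) <- bd$name
  stages <- c(stages, "bandpass_filter")
  bads <- detect_bad_channels(filtered$full, threshold = bad_threshold)
  bad_idx <- attr(bads, "index")
  stages <- c(stages, "detect_bad_channels")
  n_removed <- 0L
  if (ica) {
    cleaned <- suppressWarnings(
      remove_artifact_components(filtered$full, seed = ica_seed,
                                 max_iter = ica_max_iter,
                                 on_fail = "warn", ...))
    n_removed <- cleaned$n_removed
    M <- cleaned$cleaning_matrix
    filtered <- lapply(filtered, function(f) {
      f$data <- M %*% f$data
      f
    })
    stages <- c(stages, "remove_artifact_components")
  }
  filtered <- lapply(filtered, rereference_average, exclude = bad_idx)
  stages <- c(stages, "rereference_average")
  if (length(bad_idx) > 0) {
    interp <- lapply(filtered, interpolate_bad, bads = bad_idx)
    if (interp$full$status == "rejected")
      return(structure(list(status = "rejected", bad_channels = bads,
                            n_bad = length(bad_idx)),
                       class = "preprocess_rejected"))
    filtered <- lapply(interp, `[[`, "recording")
  }
  stages <- c(stages, "interpolate_bad")
  ep <- epoch_recording(filtered, schedule)
  stages <- c(stages, "epoch")
  ep$provenance <- list(stage_order = stages, bad_channels = as.character(bads),
                        n_components_removed = n_removed)
  ep
}
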