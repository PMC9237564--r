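#' All channel pairs for a montage subset
#'
#' @param channels Integer channel indices.
#' @return Two-column matrix of channel pairs (`ch_a < ch_b`).
#' @export
all_pairs <- function(channels) {
  t(utils::combn(sort(unique(as.integer(channels))), 2))
}

segment_ffts_matrix <- function(X, fs, seg_s = 1, overlap = 0.5) {
  lapply(seq_len(nrow(X)), function(i) segment_ffts(X[i, ], fs, seg_s, overlap))
}

#' Extract the connectivity feature matrix from an epoch set
#'
#' Computes, per 5-s window, the five connectivity feature families:
#' coherence, phase lag index (PLI), and directed PLI for every configured
#' channel pair in every analysis band, plus the Tort phase-amplitude
#' coupling index and the cross-frequency synchronization index for every
#' pair in every configured (low band, high band) combination. The
#' descriptor ordering is deterministic (family, then pair, then band).
#'
#' @param epochs An `epoch_set` with per-band arrays.
#' @param pairs Two-column matrix of channel index pairs; default all pairs
#'   over all channels.
#' @param bands Within-band family bands (default the five narrow bands).
#' @param band_pairs List of `c(low, high)` band-name pairs for the
#'   cross-frequency families (default theta-gamma and alpha-gamma).
#' @param trim_s Edge trim per window for phase-based features, in seconds
#'   (default 0.25).
#' @return A `feature_matrix`: list with `X` (windows x features),
#'   `descriptor` (family, ch_a, ch_b, band_low, band_high), `index`
#'   (window index carried from the epoch set).
#' @export
extract_feature_matrix <- function(epochs,
                                   pairs = NULL,
                                   bands = c("delta", "theta", "alpha",
                                             "beta", "gamma"),
                                   band_pairs = list(c("theta", "gamma"),
                                                     c("alpha", "gamma")),
                                   trim_s = 0.25) {
  nwin <- nrow(epochs$index)
  if (nwin == 0) stop_invalid("epoch set is empty")
  nch <- dim(epochs$bands[[1]])[2]
  if (is.null(pairs)) pairs <- all_pairs(seq_len(nch))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  used <- sort(unique(as.integer(pairs)))
  fs <- epochs$fs
  trim <- as.integer(round(trim_s * fs))
  missing_bands <- setdiff(unique(c(bands, unlist(band_pairs))),
                           names(epochs$bands))
  if (length(missing_bands))
    stop_invalid("epoch set lacks band(s): ",
                 paste(missing_bands, collapse = ", "))

  desc <- build_descriptor(pairs, bands, band_pairs)
  nf <- nrow(desc)
  X <- matrix(NA_real_, nwin, nf)
  low_bands <- unique(vapply(band_pairs, `[`, "", 1))
  high_bands <- unique(vapply(band_pairs, `[`, "", 2))
  npair <- nrow(pairs)
  pa <- match(pairs[, 1], used); pb <- match(pairs[, 2], used)

  for (w in seq_len(nwin)) {
    ph <- list(); amp <- list(); sf <- list(); envph <- list()
    for (b in unique(c(bands, low_bands, high_bands))) {
      M <- matrix(epochs$bands[[b]][w, used, ], nrow = length(used))
      an <- t(apply(M, 1, analytic_signal))
      keep <- (trim + 1):(ncol(M) - trim)
      ph[[b]] <- Arg(an)[, keep, drop = FALSE]
      if (b %in% high_bands) amp[[b]] <- Mod(an)
      if (b %in% bands) sf[[b]] <- segment_ffts_matrix(M, fs)
    }
    # envelope phase of each high band, filtered into each low band
    for (bp in band_pairs) {
      key <- paste(bp, collapse = "_")
      lb <- get_band(bp[1])
      filt <- butter_bandpass_sos(lb$low_hz, lb$high_hz, fs)
      E <- amp[[bp[2]]]
      Ef <- sos_filtfilt(filt, E - rowMeans(E))
      envph[[key]] <- t(apply(Ef, 1, function(r) Arg(analytic_signal(r))))[, (trim + 1):(ncol(E) - trim), drop = FALSE]
    }
    col <- 0L
    for (b in bands) {                       # family: coherence
      bb <- get_band(b)
      for (p in seq_len(npair)) {
        col <- col + 1L
        X[w, col] <- band_coherence(sf[[b]][[pa[p]]], sf[[b]][[pb[p]]], bb)
      }
    }
    for (b in bands) {                       # family: pli, dpli
      D <- wrap_pi(ph[[b]][pa, , drop = FALSE] - ph[[b]][pb, , drop = FALSE])
      sgn <- sign(D)
      X[w, col + seq_len(npair)] <- abs(rowMeans(sgn))
      X[w, col + npair * length(bands) + seq_len(npair)] <-
        rowMeans((D > 0) + 0.5 * (D == 0))
      col <- col + npair
    }
    col <- col + npair * length(bands)       # skip the dpli block just filled
    for (bp in band_pairs) {                 # family: pac
      key <- paste(bp, collapse = "_")
      for (p in seq_len(npair)) {
        col <- col + 1L
        X[w, col] <- tort_mi(ph[[bp[1]]][pa[p], ],
                             amp[[bp[2]]][pb[p], (trim + 1):(ncol(amp[[bp[2]]]) - trim)])
      }
    }
    for (bp in band_pairs) {                 # family: cfc_sync
      key <- paste(bp, collapse = "_")
      for (p in seq_len(npair)) {
        col <- col + 1L
        X[w, col] <- Mod(mean(exp(1i * (ph[[bp[1]]][pa[p], ] -
                                          envph[[key]][pb[p], ]))))
      }
    }
  }
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("NaN feature: window ", bad[1], ", feature ",
         paste(desc[bad[2], ], collapse = "/"), call. = FALSE)
  }
  structure(list(X = X, descriptor = desc, index = epochs$index),
            class = "feature_matrix")
}

build_descriptor <- function(pairs, bands, band_pairs) {
  npair <- nrow(pairs)
  blocks <- list()
  for (fam in c("coherence", "pli", "dpli")) {
    for (b in bands) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        family = fam, ch_a = pairs[, 1], ch_b = pairs[, 2],
        band_low = b, band_high = b, stringsAsFactors = FALSE)
    }
  }
  for (fam in c("pac", "cfc_sync")) {
    for (bp in band_pairs) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        family = fam, ch_a = pairs[, 1], ch_b = pairs[, 2],
        band_low = bp[1], band_high = bp[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, blocks)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d windows x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(unique(x$descriptor$family), collapse = ", ")))
  invisible(x)
}

# Mutual information between a discretized feature and a binary label.
mi_binary <- function(xbin, y) {
  tab <- table(xbin, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  p <- tab / n
  e <- outer(px, py)
  sum(ifelse(p > 0, p * log(p / e), 0))
}

#' Rank features by one-vs-rest mutual information with state labels
#'
#' Each feature is discretized into equal-frequency bins (fixed quantile
#' scheme, so the estimator is deterministic); its score is the maximum
#' mutual information with any one-vs-rest binarization of the labels.
#' Selection should be computed on training windows only; the returned
#' object records the windows it was fitted on.
#'
#' @param X Feature matrix (windows x features) or a `feature_matrix`.
#' @param labels Per-window state labels (>= 2 classes).
#' @param K Number of features to keep.
#' @param n_bins Discretization bins (default 8).
#' @param train_idx Window indices the selection is computed on (default
#'   all rows).
#' @return A `feature_selection`: list with `indices` (ordered, length
#'   `min(K, n_features)`), `scores`, `K`, `train_idx`.
#' @export
select_features <- function(X, labels, K, n_bins = 8, train_idx = NULL) {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (K < 1) stop_invalid("K must be >= 1")
  labels <- as.character(labels)
  train_idx <- train_idx %||% seq_len(nrow(X))
  Xt <- X[train_idx, , drop = FALSE]
  lt <- labels[train_idx]
  classes <- sort(unique(lt))
  if (length(classes) < 2) stop_invalid("labels must cover >= 2 classes")
  scores <- vapply(seq_len(ncol(Xt)), function(j) {
    v <- Xt[, j]
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    xb <- if (length(br) < 2) rep(1L, length(v)) else
      findInterval(v, br[-c(1, length(br))]) + 1L
    max(vapply(classes, function(cl) mi_binary(xb, lt == cl), 0))
  }, 0)
  ord <- order(scores, decreasing = TRUE)
  k <- min(K, ncol(Xt))
  structure(list(indices = ord[seq_len(k)], scores = scores[ord[seq_len(k)]],
                 K = K, train_idx = train_idx),
            class = "feature_selection")
}
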