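#' Train one-vs-rest network-state classifiers
#'
#' Fits, for each class in `labels`, a ridge-regularized logistic
#' classifier (one-vs-rest) on the selected feature space. Probabilities
#' are deliberately not normalized across classes: each network's
#' activation is its own probability, which lets the salience network
#' co-activate with a task network.
#'
#' @param X Feature matrix (windows x features) or a `feature_matrix`.
#' @param labels Per-window class labels (>= 2 classes, >= 10 windows per
#'   class recommended).
#' @param selection Optional `feature_selection` restricting the feature
#'   space.
#' @param lambda Ridge penalty (default 0.05).
#' @param standardize Standardize features before fitting (default TRUE).
#' @param seed Seed (fit is deterministic; the seed is recorded in the
#'   training metadata).
#' @return A `network_model`: per-class glmnet fits plus feature-space
#'   metadata.
#' @export
train_network_classifier <- function(X, labels, selection = NULL,
                                     lambda = 0.05, standardize = TRUE,
                                     seed = 1) {
  desc <- NULL
  if (inherits(X, "feature_matrix")) { desc <- X$descriptor; X <- X$X }
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop_invalid("labels must cover >= 2 classes")
  if (nrow(X) < 10 * length(classes))
    warning("fewer than 10 windows per class; fit may be unstable")
  cols <- if (is.null(selection)) seq_len(ncol(X)) else selection$indices
  Xs <- X[, cols, drop = FALSE]
  fits <- local_seed(seed, lapply(classes, function(cl) {
    y <- as.integer(labels == cl)
    glmnet::glmnet(Xs, y, family = "binomial", alpha = 0, lambda = lambda,
                   standardize = standardize)
  }))
  names(fits) <- classes
  structure(list(fits = fits, classes = classes, feature_cols = cols,
                 n_features_total = ncol(X), descriptor = desc,
                 lambda = lambda, seed = seed),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("Network model: one-vs-rest ridge logistic (%s) on %d features\n",
              paste(x$classes, collapse = ", "), length(x$feature_cols)))
  invisible(x)
}

#' Predict per-window network activation probabilities
#'
#' @param model A `network_model`.
#' @param X Feature matrix (windows x features) or a `feature_matrix` with
#'   a descriptor matching the model's training space.
#' @param index Optional window index data frame (window, trial, half,
#'   label) carried onto the output.
#' @return A `network_prob_series` data frame with one `P_<class>` column
#'   per class, each in `[0, 1]`.
#' @export
predict_probabilities <- function(model, X, index = NULL) {
  if (inherits(X, "feature_matrix")) {
    if (!is.null(model$descriptor)) {
      if (nrow(model$descriptor) != nrow(X$descriptor))
        stop_invalid("descriptor mismatch: model trained on ",
                     nrow(model$descriptor), " features, input has ",
                     nrow(X$descriptor))
      diff <- which(!(model$descriptor$family == X$descriptor$family &
                        model$descriptor$ch_a == X$descriptor$ch_a &
                        model$descriptor$ch_b == X$descriptor$ch_b &
                        model$descriptor$band_low == X$descriptor$band_low &
                        model$descriptor$band_high == X$descriptor$band_high))
      if (length(diff))
        stop_invalid("descriptor mismatch at feature ", diff[1], ": ",
                     paste(X$descriptor[diff[1], ], collapse = "/"))
    }
    index <- index %||% X$index
    X <- X$X
  }
  if (ncol(X) != model$n_features_total)
    stop_invalid("feature count mismatch: model expects ",
                 model$n_features_total, ", got ", ncol(X))
  Xs <- X[, model$feature_cols, drop = FALSE]
  P <- vapply(model$classes, function(cl)
    as.numeric(predict(model$fits[[cl]], Xs, type = "response")),
    numeric(nrow(Xs)))
  P <- matrix(P, nrow = nrow(Xs),
              dimnames = list(NULL, paste0("P_", model$classes)))
  if (anyNA(P) || any(P < 0 | P > 1))
    stop("predicted probabilities out of [0,1] or NaN", call. = FALSE)
  out <- if (is.null(index)) data.frame(window = seq_len(nrow(P))) else index
  out <- cbind(out, as.data.frame(P))
  class(out) <- c("network_prob_series", "data.frame")
  out
}

#' Ground-truth window labels for classifier training
#'
#' Task-network state is the argmax of the DMN and CEN activation levels;
#' the salience network gets a separate active flag when its level exceeds
#' `sn_threshold` (it co-activates, so it is not part of the exclusive
#' state).
#'
#' @param latent A `latent_state_series`.
#' @param sn_threshold SN-active threshold (default 0.5).
#' @return List with `state` (factor "dmn"/"cen") and `sn_active` (logical).
#' @export
window_labels <- function(latent, sn_threshold = 0.5) {
  list(state = ifelse(latent$a_dmn >= latent$a_cen, "dmn", "cen"),
       sn_active = latent$a_sn > sn_threshold)
}

#' Fit the three-network model from labeled windows
#'
#' Trains the `dmn`/`cen` task-state classifiers (one-vs-rest on the state
#' label) and the `sn` classifier (on the SN-active flag) over a common
#' feature selection.
#'
#' @param fm A `feature_matrix`.
#' @param latent The matching `latent_state_series` (ground truth).
#' @param K Features kept by mutual-information selection (default 500).
#' @param train_idx Window indices used for selection and fitting.
#' @param ... Passed to [train_network_classifier()].
#' @return A `network_model` with classes `cen`, `dmn`, `sn_active`.
#' @export
fit_network_model <- function(fm, latent, K = 500, train_idx = NULL, ...) {
  lab <- window_labels(latent)
  combined <- paste0(lab$state, ifelse(lab$sn_active, "+sn", ""))
  train_idx <- train_idx %||% seq_len(nrow(fm$X))
  sel <- select_features(fm, combined, K = K, train_idx = train_idx)
  labels3 <- lab$state
  m_state <- train_network_classifier(
    structure(list(X = fm$X[train_idx, , drop = FALSE],
                   descriptor = fm$descriptor), class = "feature_matrix"),
    labels3[train_idx], selection = sel, ...)
  m_sn <- train_network_classifier(
    structure(list(X = fm$X[train_idx, , drop = FALSE],
                   descriptor = fm$descriptor), class = "feature_matrix"),
    ifelse(lab$sn_active[train_idx], "sn", "rest"), selection = sel, ...)
  m_state$fits$sn <- m_sn$fits$sn
  m_state$classes <- c(m_state$classes, "sn")
  m_state
}

#' Serialize / restore a network model
#'
#' Round-trips through a plain list so predictions are bit-identical after
#' reload.
#'
#' @param model A `network_model`.
#' @param path File path (.rds is not used; the model is written with
#'   [saveRDS()] semantics via [serialize()] to a connection-free raw
#'   vector stored as base64 text when `text = TRUE`).
#' @param text Write as base64 text (default TRUE).
#' @return `save_network_model` returns `path` invisibly;
#'   `load_network_model` returns the model.
#' @export
save_network_model <- function(model, path, text = TRUE) {
  raw <- serialize(model, NULL, version = 2)
  if (text) {
    writeLines(jsonlite::base64_enc(raw), path)
  } else {
    writeBin(raw, path)
  }
  invisible(path)
}

#' @rdname save_network_model
#' @export
load_network_model <- function(path, text = TRUE) {
  raw <- if (text) jsonlite::base64_dec(paste(readLines(path), collapse = ""))
  else readBin(path, "raw", file.size(path))
  unserialize(raw)
}
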