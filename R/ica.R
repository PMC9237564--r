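#' FastICA decomposition
#'
#' Symmetric fixed-point independent component analysis with the tanh
#' contrast function, after PCA whitening with automatic rank reduction
#' (eigenvalues below `rank_tol` times the largest are dropped, so
#' rank-deficient inputs such as duplicated channels are handled).
#'
#' @param X Channels x samples matrix.
#' @param n_comp Number of components (default: numerical rank).
#' @param max_iter Maximum fixed-point iterations.
#' @param tol Convergence tolerance on the unmixing update.
#' @param rank_tol Relative eigenvalue cutoff for rank reduction.
#' @param seed Seed for the random orthonormal initialization.
#' @param on_fail `"error"` (default) to raise on non-convergence, or
#'   `"warn"` to return the final iterate with a warning. Strongly
#'   narrowband signals contain quadrature source pairs whose joint
#'   distribution is circularly symmetric, so the unmixing rotation within
#'   such a pair is unidentifiable and the fixed-point update need not
#'   settle even when every identifiable component (artifacts included)
#'   has; `"warn"` is appropriate there.
#' @return List with `S` (components x samples sources), `A` (channels x
#'   components mixing), `W` (components x channels unmixing, applies to
#'   centered data), `center`, `n_iter`, `converged`.
#' @export
fast_ica <- function(X, n_comp = NULL, max_iter = 500, tol = 1e-4,
                     rank_tol = 1e-8, seed = 1,
                     on_fail = c("error", "warn")) {
  on_fail <- match.arg(on_fail)
  if (ncol(X) <= nrow(X))
    stop_invalid("ICA needs more samples than channels")
  center <- rowMeans(X)
  Xc <- X - center
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > rank_tol * eg$values[1]
  r <- sum(keep)
  if (!is.null(n_comp)) r <- min(r, n_comp)
  E <- eg$vectors[, seq_len(r), drop = FALSE]
  d <- eg$values[seq_len(r)]
  K <- diag(1 / sqrt(d), r) %*% t(E)          # whitening: r x channels
  Z <- K %*% Xc                                # whitened sources
  W <- local_seed(seed, {
    M <- matrix(rnorm(r * r), r)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0L
  n <- ncol(Z)
  while (it < max_iter) {
    it <- it + 1L
    U <- W %*% Z
    G <- tanh(U)
    Gp <- 1 - G^2
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(Gp), r) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    if (on_fail == "error")
      stop("ICA failed to converge after ", it, " iterations", call. = FALSE)
    warning("ICA not fully converged after ", it,
            " iterations; returning final iterate", call. = FALSE)
  }
  Wfull <- W %*% K                              # comps x channels
  A <- E %*% diag(sqrt(d), r) %*% t(W)          # channels x comps
  list(S = Wfull %*% Xc, A = A, W = Wfull, center = center,
       n_iter = it, converged = converged)
}
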