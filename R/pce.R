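#' Pairwise cross-entropy between two probability sequences
#'
#' The network-synchrony statistic: `-sum_i P_a[i] * log(P_b[i])` with the
#' natural logarithm, summed left to right in the given order. `P_b` is
#' clipped to `[eps, 1]` before the log so zero probabilities give a
#' finite, reproducible value. Lower values mean the second network's
#' activation tracks the first's high-activation windows more closely
#' (zero is maximal synchrony, reached when `P_b = 1` wherever `P_a > 0`).
#'
#' @param p_a,p_b Equal-length probability sequences in `[0, 1]`.
#' @param eps Clipping floor for `P_b` (default 1e-12).
#' @return Non-negative scalar, with per-window contributions in attribute
#'   `"contributions"`.
#' @examples
#' compute_pce(rep(0.5, 6), rep(0.5, 6))   # 3 * log(2)
#' @export
compute_pce <- function(p_a, p_b, eps = 1e-12) {
  if (length(p_a) != length(p_b))
    stop_invalid("probability sequences must have equal length")
  if (length(p_a) < 1) stop_invalid("need at least one window")
  if (any(!is.finite(p_a)) || any(!is.finite(p_b)) ||
      any(p_a < 0 | p_a > 1) || any(p_b < 0 | p_b > 1))
    stop_invalid("probabilities must be finite and in [0, 1]")
  contrib <- -p_a * log(pmin(pmax(p_b, eps), 1))
  total <- 0
  for (i in seq_along(contrib)) total <- total + contrib[i]
  structure(total, contributions = contrib)
}

#' Task- and segment-restricted PCE from a probability series
#'
#' Pools the windows of every trial of one task (optionally restricted to
#' the first or second half of each trial) in trial-then-window order and
#' applies [compute_pce()] to the chosen network pair: `P_dmn` vs `P_sn`
#' for the dmn-sn pair, `P_cen` vs `P_sn` for cen-sn.
#'
#' @param series A `network_prob_series` (needs `P_dmn`, `P_cen`, `P_sn`,
#'   `trial`, `half`, `label`).
#' @param pair `"dmn-sn"` or `"cen-sn"`.
#' @param task `"AM"` or `"WM"`.
#' @param segment `"full"`, `"first_half"`, or `"second_half"`.
#' @return A `pce_result`: list with `pair`, `task`, `segment`, `value`,
#'   `n_terms`, `mean_per_window`, `contributions`.
#' @export
compute_task_pce <- function(series, pair = c("dmn-sn", "cen-sn"),
                             task = c("WM", "AM"),
                             segment = c("full", "first_half", "second_half")) {
  pair <- match.arg(pair); task <- match.arg(task)
  segment <- match.arg(segment)
  sel <- series$label == task
  if (segment == "first_half") sel <- sel & series$half == "first"
  if (segment == "second_half") sel <- sel & series$half == "second"
  if (!any(sel))
    stop_invalid("empty selection: no windows for task ", task,
                 ", segment ", segment)
  sub <- series[sel, , drop = FALSE]
  sub <- sub[order(sub$trial, sub$window), , drop = FALSE]
  a <- if (pair == "dmn-sn") sub$P_dmn else sub$P_cen
  v <- compute_pce(a, sub$P_sn)
  structure(list(pair = pair, task = task, segment = segment,
                 value = as.numeric(v), n_terms = nrow(sub),
                 mean_per_window = as.numeric(v) / nrow(sub),
                 contributions = attr(v, "contributions")),
            class = "pce_result")
}

#' @export
print.pce_result <- function(x, ...) {
  cat(sprintf("PCE %s / %s / %s: %.4f over %d windows (%.4f per window)\n",
              x$pair, x$task, x$segment, x$value, x$n_terms,
              x$mean_per_window))
  invisible(x)
}

#' Full PCE panel for one participant
#'
#' All 12 PCE measures (2 network pairs x 2 tasks x 3 segments) at both
#' timepoints, in long format. The raw Eq.-style sum is the primary value;
#' a per-window mean is carried alongside for unequal-trial-count
#' comparisons.
#'
#' @param series_pre,series_post `network_prob_series` for the pre- and
#'   post-intervention scans.
#' @param participant Optional participant id attached to every row.
#' @return Data frame: `participant`, `session` ("Pre"/"Post"), `pair`,
#'   `task`, `segment`, `value`, `mean_per_window`, `n_terms` (24 rows).
#' @export
pce_panel <- function(series_pre, series_post, participant = NA_character_) {
  grid <- expand.grid(segment = c("full", "first_half", "second_half"),
                      task = c("WM", "AM"), pair = c("dmn-sn", "cen-sn"),
                      session = c("Pre", "Post"),
                      stringsAsFactors = FALSE)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    s <- if (grid$session[i] == "Pre") series_pre else series_post
    r <- compute_task_pce(s, grid$pair[i], grid$task[i], grid$segment[i])
    c(r$value, r$mean_per_window, r$n_terms)
  }, numeric(3))
  data.frame(participant = participant, session = grid$session,
             pair = grid$pair, task = grid$task, segment = grid$segment,
             value = vals[1, ], mean_per_window = vals[2, ],
             n_terms = as.integer(vals[3, ]), stringsAsFactors = FALSE)
}
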