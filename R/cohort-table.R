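#' Assemble the analysis table for a cohort
#'
#' Computes the per-participant PCE panel (from the probability series of
#' both scans), the responder labels, behavioral slopes and VO2-max change,
#' and merges them into the substrate of the statistical battery.
#'
#' @param cohort A `cohort` generated at `detail = "probs"`, or one whose
#'   participants already carry `pre$probs` / `post$probs` (e.g. filled in
#'   by the full EEG pipeline).
#' @param labels Optional precomputed `responder_labels`; computed from the
#'   cohort otherwise.
#' @return A `cohort_table`: list with `participants` (one row each: group,
#'   responder, vo2 and behavior summaries) and `pce` (long format:
#'   participant, group, responder, session, pair, task, segment, value).
#' @export
build_cohort_table <- function(cohort, labels = NULL) {
  labels <- labels %||% label_cohort(cohort)
  lab_idx <- match(names(cohort$participants), labels$participant)
  pce_rows <- list()
  prows <- list()
  for (i in seq_along(cohort$participants)) {
    p <- cohort$participants[[i]]
    if (is.null(p$pre$probs) || is.null(p$post$probs))
      stop_invalid("participant ", p$id, " lacks probability series; ",
                   "generate the cohort at detail = \"probs\" or run the ",
                   "EEG pipeline first")
    panel <- pce_panel(p$pre$probs, p$post$probs, participant = p$id)
    li <- lab_idx[i]
    panel$group <- p$group
    panel$responder <- labels$final[li]
    pce_rows[[i]] <- panel
    prows[[i]] <- data.frame(
      participant = p$id, group = p$group, responder = labels$final[li],
      responder_gt = p$responder_gt,
      calm_slope = labels$calm_slope[li],
      points_slope = labels$points_slope[li],
      vo2_pre = p$record$vo2_pre, vo2_post = p$record$vo2_post,
      vo2_delta = p$record$vo2_post - p$record$vo2_pre,
      stringsAsFactors = FALSE)
  }
  structure(list(participants = do.call(rbind, prows),
                 pce = do.call(rbind, pce_rows)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort table: %d participants, %d PCE rows\n",
              nrow(x$participants), nrow(x$pce)))
  invisible(x)
}

# Extract one PCE outcome as a wide (participant x session) data frame.
pce_outcome <- function(ct, pair, task, segment = "full",
                        subset_responder = NULL) {
  d <- ct$pce[ct$pce$pair == pair & ct$pce$task == task &
                ct$pce$segment == segment, ]
  if (!is.null(subset_responder))
    d <- d[!is.na(d$responder) & d$responder == subset_responder, ]
  d
}

#' Behavior slopes for all four groups (NFB effectiveness check input)
#'
#' @param ct A `cohort_table`.
#' @return Data frame with participant, group, calm_slope, points_slope.
#' @keywords internal
behavior_slopes <- function(ct) {
  ct$participants[, c("participant", "group", "calm_slope", "points_slope")]
}
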