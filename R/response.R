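#' Ordinary least-squares slope of a per-session measure
#'
#' @param values Per-session measurements.
#' @param sessions Session indices (default `1:length(values)`).
#' @return Slope per session unit.
#' @examples
#' fit_session_slope(c(2, 4, 6, 8), 1:4)   # 2
#' @export
fit_session_slope <- function(values, sessions = seq_along(values)) {
  ok <- is.finite(values) & is.finite(sessions)
  if (sum(ok) < 2)
    stop_invalid("insufficient data: need >= 2 sessions with values")
  x <- sessions[ok]; y <- values[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Neurofeedback responder rule
#'
#' Responder if either behavioral slope (calm-percentage or device points,
#' per session over the 8-week protocol) is strictly positive; zero or
#' negative slopes on both metrics mean non-responder.
#'
#' @param calm_slope,points_slope Fitted slopes.
#' @return Logical responder flag.
#' @export
label_nfb <- function(calm_slope, points_slope) {
  if (!is.finite(calm_slope) || !is.finite(points_slope))
    stop_invalid("slopes must be finite")
  max(calm_slope, points_slope) > 0
}

#' Aerobic-exercise responder rule
#'
#' Responder if post-intervention VO2-max strictly exceeds the
#' pre-intervention value; equal or lower means non-responder.
#'
#' @param vo2_pre,vo2_post VO2-max values (mL/kg/min, positive).
#' @return Logical responder flag.
#' @export
label_running <- function(vo2_pre, vo2_post) {
  if (!is.finite(vo2_pre) || !is.finite(vo2_post) ||
      vo2_pre <= 0 || vo2_post <= 0)
    stop_invalid("VO2-max values must be positive")
  vo2_post > vo2_pre
}

#' Label a cohort's responder status
#'
#' Dispatches the group-specific rules: NFB uses the behavioral-slope rule,
#' Running the VO2-max rule, Combined requires both, and Control is never
#' labeled. Per-participant failures (missing measurements) are reported in
#' the output rather than aborting the cohort.
#'
#' @param cohort A `cohort` from [generate_cohort()], or a list of
#'   `participant_record`s (named by participant id).
#' @return A `responder_labels` object: data frame with `participant`,
#'   `group`, `nfb_responder`, `running_responder`, `final`, `calm_slope`,
#'   `points_slope`, `vo2_delta`, `error`; summary counts in attribute
#'   `"counts"`.
#' @export
label_cohort <- function(cohort) {
  records <- if (inherits(cohort, "cohort")) {
    stats::setNames(lapply(cohort$participants, `[[`, "record"),
                    names(cohort$participants))
  } else cohort
  rows <- lapply(names(records), function(id) {
    r <- records[[id]]
    out <- data.frame(participant = id, group = r$group,
                      nfb_responder = NA, running_responder = NA,
                      final = NA_character_, calm_slope = NA_real_,
                      points_slope = NA_real_, vo2_delta = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      if (!is.null(r$sessions) && nrow(r$sessions) >= 2) {
        out$calm_slope <- fit_session_slope(r$sessions$calm_pct,
                                            r$sessions$session)
        out$points_slope <- fit_session_slope(r$sessions$points,
                                              r$sessions$session)
      }
      if (!is.null(r$vo2_pre) && !is.null(r$vo2_post))
        out$vo2_delta <- r$vo2_post - r$vo2_pre
      if (r$group %in% c("NFB", "Combined"))
        out$nfb_responder <- label_nfb(out$calm_slope, out$points_slope)
      if (r$group %in% c("Running", "Combined"))
        out$running_responder <- label_running(r$vo2_pre, r$vo2_post)
      out$final <- switch(r$group,
        Control = NA_character_,
        NFB = if (out$nfb_responder) "responder" else "non-responder",
        Running = if (out$running_responder) "responder" else "non-responder",
        Combined = if (out$nfb_responder && out$running_responder)
          "responder" else "non-responder")
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
    res
  })
  labels <- do.call(rbind, rows)
  counts <- table(labels$group[!is.na(labels$final)],
                  labels$final[!is.na(labels$final)])
  structure(labels, counts = counts, class = c("responder_labels",
                                               "data.frame"))
}

#' @export
print.responder_labels <- function(x, ...) {
  cat("Responder labels:\n")
  print(attr(x, "counts"))
  invisible(x)
}
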