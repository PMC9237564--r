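#' Write / read a task schedule as CSV
#'
#' Columns: `block_label`, `onset_s`, `duration_s`.
#'
#' @param schedule A `task_schedule`.
#' @param path CSV path.
#' @return `write_schedule_csv` returns `path` invisibly;
#'   `read_schedule_csv` returns a `task_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(data.frame(block_label = schedule$label,
                              onset_s = schedule$onset_s,
                              duration_s = schedule$duration_s),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  sched <- data.frame(label = d$block_label, onset_s = d$onset_s,
                      duration_s = d$duration_s, stringsAsFactors = FALSE)
  class(sched) <- c("task_schedule", "data.frame")
  validate_schedule(sched)
  sched
}

#' Write a probability series or PCE panel as CSV
#'
#' @param x A `network_prob_series` or PCE panel data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a probability series written by [write_table_csv()]
#'
#' @param path CSV path.
#' @return A `network_prob_series`.
#' @export
read_probs_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("window", "trial", "half", "label", "P_dmn", "P_cen", "P_sn")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop_invalid("probability CSV lacks column(s): ",
                 paste(missing, collapse = ", "))
  class(d) <- c("network_prob_series", "data.frame")
  d
}
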