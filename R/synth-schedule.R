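#' Generate a randomly interleaved AM/WM task schedule
#'
#' Builds a task schedule of 30-s blocks alternating, in seeded random order,
#' between autobiographical-memory recall (AM) and 2-back working-memory (WM)
#' blocks, balanced so half the blocks are of each type.
#'
#' @param n_blocks Total number of blocks; must be even and >= 2.
#' @param seed Integer seed; identical inputs give identical schedules.
#' @param block_s Block duration in seconds (default 30).
#' @param gap_s Inter-block gap in seconds (default 0: contiguous blocks).
#' @return A `task_schedule`: data frame with `label` ("AM"/"WM"), `onset_s`,
#'   `duration_s`.
#' @examples
#' generate_task_schedule(10, seed = 1)
#' @export
generate_task_schedule <- function(n_blocks, seed, block_s = 30, gap_s = 0) {
  n_blocks <- as.integer(n_blocks)
  if (is.na(n_blocks) || n_blocks < 2L || n_blocks %% 2L != 0L)
    stop_invalid("n_blocks must be an even integer >= 2, got ", n_blocks)
  labels <- local_seed(seed, sample(rep(c("AM", "WM"), n_blocks / 2)))
  sched <- data.frame(
    label = labels,
    onset_s = (seq_len(n_blocks) - 1) * (block_s + gap_s),
    duration_s = rep(block_s, n_blocks),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("task_schedule", "data.frame")
  sched
}

validate_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("label", "onset_s", "duration_s") %in% names(schedule)))
  if (!all(schedule$label %in% c("AM", "WM")))
    stop_invalid("schedule labels must be AM or WM")
  if (nrow(schedule) > 1) {
    ends <- schedule$onset_s + schedule$duration_s
    if (any(schedule$onset_s[-1] < ends[-nrow(schedule)] - 1e-9))
      stop_invalid("schedule blocks overlap")
  }
  invisible(schedule)
}
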