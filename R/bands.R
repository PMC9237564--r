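#' Canonical EEG frequency bands
#'
#' The six analysis bands used throughout the pipeline: full (1-50 Hz),
#' delta (1-4), theta (4-8), alpha (8-13), beta (13-30), gamma (30-50).
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz`.
#' @examples
#' band_definitions()
#' @export
band_definitions <- function() {
  data.frame(
    name    = c("full", "delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(1, 1, 4, 8, 13, 30),
    high_hz = c(50, 4, 8, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' Look up one band definition
#'
#' @param name One of `"full"`, `"delta"`, `"theta"`, `"alpha"`, `"beta"`,
#'   `"gamma"`, or a list/one-row data frame with `low_hz`/`high_hz` for a
#'   custom band.
#' @return A list with `name`, `low_hz`, `high_hz`.
#' @export
get_band <- function(name) {
  if (is.list(name) && !is.null(name$low_hz)) {
    return(list(name = as.character(name$name %||% "custom"),
                low_hz = as.numeric(name$low_hz),
                high_hz = as.numeric(name$high_hz)))
  }
  bd <- band_definitions()
  i <- match(name, bd$name)
  if (is.na(i)) stop_invalid("unknown band: ", name)
  list(name = bd$name[i], low_hz = bd$low_hz[i], high_hz = bd$high_hz[i])
}
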