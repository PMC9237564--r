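#' Default latent network dynamics parameters
#'
#' Ground-truth activation levels for the three intrinsic connectivity
#' networks across the 5-s windows of each 30-s task block. AM blocks show
#' the within-trial default-mode-to-executive transition (DMN-dominant
#' first half, CEN-dominant second half); WM blocks are CEN-dominant
#' throughout; salience-network activation tracks the task-appropriate
#' network's level with a configurable coupling weight.
#'
#' @param am_dmn Length-2 DMN level in AM blocks (first half, second half).
#' @param am_cen Length-2 CEN level in AM blocks.
#' @param wm_dmn,wm_cen DMN and CEN levels in WM blocks.
#' @param sn_base Salience-network baseline activation.
#' @param sn_coupling Weight pulling SN activation toward the
#'   task-appropriate network's level (0 = independent, 1 = identical).
#' @param noise_sd Gaussian jitter applied to every window's levels.
#' @return A named list of dynamics parameters.
#' @export
latent_dynamics <- function(am_dmn = c(0.85, 0.30), am_cen = c(0.25, 0.75),
                            wm_dmn = 0.20, wm_cen = 0.85,
                            sn_base = 0.40, sn_coupling = 0.70,
                            noise_sd = 0.12) {
  list(am_dmn = am_dmn, am_cen = am_cen, wm_dmn = wm_dmn, wm_cen = wm_cen,
       sn_base = sn_base, sn_coupling = sn_coupling, noise_sd = noise_sd)
}

#' Generate ground-truth latent network states for a task schedule
#'
#' Emits one window per 5 s of every block (six windows per 30-s block),
#' with ground-truth activation levels for DMN, CEN, and SN, the
#' window-to-trial/half mapping, and the derived window state label
#' (task-appropriate network) plus an SN-active flag.
#'
#' @param schedule A `task_schedule`.
#' @param dynamics Parameters from [latent_dynamics()].
#' @param seed Integer seed.
#' @param window_s Window length in seconds (default 5).
#' @return A `latent_state_series` data frame: `window`, `trial`, `half`,
#'   `label`, `onset_s`, `a_dmn`, `a_cen`, `a_sn`, `state`, `sn_active`.
#' @export
generate_latent_states <- function(schedule, dynamics = latent_dynamics(),
                                   seed = NULL, window_s = 5) {
  validate_schedule(schedule)
  rows <- local_seed(seed, {
    out <- vector("list", nrow(schedule))
    for (b in seq_len(nrow(schedule))) {
      nw <- as.integer(round(schedule$duration_s[b] / window_s))
      half <- ifelse(seq_len(nw) <= nw / 2, "first", "second")
      if (schedule$label[b] == "AM") {
        a_dmn <- ifelse(half == "first", dynamics$am_dmn[1], dynamics$am_dmn[2])
        a_cen <- ifelse(half == "first", dynamics$am_cen[1], dynamics$am_cen[2])
        a_task <- a_dmn   # SN tracks the task-appropriate (DMN) level in AM
      } else {
        a_dmn <- rep(dynamics$wm_dmn, nw)
        a_cen <- rep(dynamics$wm_cen, nw)
        a_task <- a_cen
      }
      a_dmn <- a_dmn + rnorm(nw, 0, dynamics$noise_sd)
      a_cen <- a_cen + rnorm(nw, 0, dynamics$noise_sd)
      a_sn <- (1 - dynamics$sn_coupling) * dynamics$sn_base +
        dynamics$sn_coupling * a_task + rnorm(nw, 0, dynamics$noise_sd)
      out[[b]] <- data.frame(
        trial = b,
        half = half,
        label = schedule$label[b],
        onset_s = schedule$onset_s[b] + (seq_len(nw) - 1) * window_s,
        a_dmn = clip01(a_dmn), a_cen = clip01(a_cen), a_sn = clip01(a_sn),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  rows$window <- seq_len(nrow(rows))
  rows$state <- ifelse(rows$a_dmn >= rows$a_cen, "dmn", "cen")
  rows$sn_active <- rows$a_sn > 0.5
  rows <- rows[, c("window", "trial", "half", "label", "onset_s",
                   "a_dmn", "a_cen", "a_sn", "state", "sn_active")]
  class(rows) <- c("latent_state_series", "data.frame")
  rows
}
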