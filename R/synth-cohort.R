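COHORT_GROUPS <- c("Control", "Running", "NFB", "Combined")

#' Specify a synthetic intervention cohort
#'
#' Parameterizes the synthetic-cohort generator: group sizes, responder
#' fractions, montage and sampling rate, signal-to-noise ratio of the
#' state-locked EEG coupling signatures, the network-coupling effect shifts
#' that create the study's subgroup differences in pairwise cross-entropy
#' (PCE), and the behavioral/fitness distributions. Defaults follow the
#' study conditions: 15/20/14/20 participants per Control/Running/NFB/
#' Combined group, 16 sessions, and NFB/Combined responder fractions
#' matching the reported responder counts (11 of 14, 5 of 20); the montage
#' defaults to 32 channels at 256 Hz for desk-scale runtime.
#'
#' @param n_per_group Named counts for Control, Running, NFB, Combined.
#' @param responder_fraction Named fractions in `[0,1]` per group (Control is
#'   never labeled, so its entry only fixes ground truth for bookkeeping).
#' @param n_channels Montage size (>= 8).
#' @param sampling_rate Sampling rate in Hz (>= 128).
#' @param n_blocks Task blocks per scan (even, default 10).
#' @param snr Ratio of state-locked coupled signal power to background noise
#'   power in the synthetic EEG (> 0).
#' @param pce_effect List with coupling shifts in `[0,1]`, each pulling SN
#'   activation toward its co-activation ceiling in the affected windows:
#'   `cen_sn_responder` (second half of WM trials, both timepoints, all
#'   responders in the NFB-training arms, i.e. NFB and Combined groups),
#'   `cen_sn_combined_responder` (same windows, Combined-group responders,
#'   superseding the former), `dmn_sn_nonresponder_post` (all WM windows at
#'   the post timepoint, every labeled non-responder: a cohort-wide
#'   post-intervention drift toward task-inappropriate synchrony), and
#'   `dmn_sn_nfb_nonresponder_post` (same windows, NFB-group
#'   non-responders, superseding the former). Set all to 0 for a null
#'   cohort.
#' @param prob_noise_sd Gaussian noise on window activation probabilities.
#' @param sn_coupling_sd Between-participant SD of the SN coupling weight.
#' @param dynamics Latent dynamics, see [latent_dynamics()].
#' @param behavior,vo2,artifacts Distribution parameters; see Details.
#' @param n_sessions Behavioral sessions (default 16: two weekly for 8 weeks).
#' @param seed Master seed; all child seeds derive from it.
#'
#' @details `behavior` controls the per-session neurofeedback metrics
#' (percent time in the "calm" state and device points): responders draw a
#' positive underlying slope on at least one metric, non-responders
#' non-positive slopes on both. `vo2` controls pre/post maximal oxygen
#' uptake (mL/kg/min): Running/Combined responders draw strictly positive
#' deltas centred near +4, non-responders non-positive deltas, and
#' non-exercising groups draw deltas centred at 0.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = c(Control = 15, Running = 20,
                                        NFB = 14, Combined = 20),
                        responder_fraction = c(Control = 0, Running = 0.6,
                                               NFB = 11 / 14, Combined = 0.25),
                        n_channels = 32, sampling_rate = 256, n_blocks = 10,
                        snr = 1,
                        pce_effect = list(cen_sn_responder = 0.35,
                                          cen_sn_combined_responder = 0.8,
                                          dmn_sn_nonresponder_post = 0.35,
                                          dmn_sn_nfb_nonresponder_post = 0.8),
                        prob_noise_sd = 0.10, sn_coupling_sd = 0.08,
                        dynamics = latent_dynamics(),
                        behavior = list(calm_start = 50, calm_sd = 3,
                                        points_start = 1500, points_sd = 80,
                                        calm_slope_responder = c(0.3, 1.5),
                                        points_slope_responder = c(10, 60),
                                        slope_nonresponder = c(-1.5, -0.25)),
                        vo2 = list(pre_mean = 40, pre_sd = 6,
                                   responder_delta = c(4, 1.5),
                                   nonresponder_delta = c(-1, 0.75),
                                   null_delta_sd = 1),
                        artifacts = list(blink_rate = 0.2, blink_amp = 5,
                                         muscle_rate = 0.05, muscle_amp = 3,
                                         n_bad_channels = 0),
                        n_sessions = 16, seed = 20220614) {
  n_per_group <- n_per_group[COHORT_GROUPS]
  responder_fraction <- responder_fraction[COHORT_GROUPS]
  if (anyNA(n_per_group) || any(n_per_group < 0))
    stop_invalid("n_per_group must give a non-negative count for each of ",
                 paste(COHORT_GROUPS, collapse = ", "))
  if (anyNA(responder_fraction) ||
      any(responder_fraction < 0 | responder_fraction > 1))
    stop_invalid("responder_fraction entries must lie in [0, 1]")
  if (snr <= 0) stop_invalid("snr must be > 0")
  if (n_channels < 8) stop_invalid("n_channels must be >= 8")
  pe <- utils::modifyList(list(cen_sn_responder = 0,
                               cen_sn_combined_responder = 0,
                               dmn_sn_nonresponder_post = 0,
                               dmn_sn_nfb_nonresponder_post = 0), pce_effect)
  structure(list(n_per_group = n_per_group,
                 responder_fraction = responder_fraction,
                 n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 n_blocks = as.integer(n_blocks), snr = snr,
                 pce_effect = pe, prob_noise_sd = prob_noise_sd,
                 sn_coupling_sd = sn_coupling_sd, dynamics = dynamics,
                 behavior = behavior, vo2 = vo2, artifacts = artifacts,
                 n_sessions = as.integer(n_sessions),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat("  groups: ", paste(sprintf("%s=%d", names(x$n_per_group),
                                  x$n_per_group), collapse = ", "), "\n")
  cat(sprintf("  montage: %d channels @ %g Hz, %d blocks/scan, snr = %g\n",
              x$n_channels, x$sampling_rate, x$n_blocks, x$snr))
  cat(sprintf("  pce effects: cen-sn(Combined responders) = %g, dmn-sn(NFB non-responders, post) = %g\n",
              x$pce_effect$cen_sn_combined_responder,
              x$pce_effect$dmn_sn_nfb_nonresponder_post))
  invisible(x)
}

# Shift SN activation toward its co-activation ceiling in the windows a
# subgroup effect targets. Each delta in [0,1]; 0 leaves the series alone.
apply_pce_effects <- function(latent, group, responder, session, pce_effect) {
  ceiling_ <- 0.97
  bump <- function(sel, d)
    latent$a_sn[sel] <<- latent$a_sn[sel] + d * (ceiling_ - latent$a_sn[sel])
  # baseline CEN-SN co-activation advantage of NFB-arm responders,
  # strongest in the Combined group (second half of WM trials)
  if (isTRUE(responder) && group %in% c("NFB", "Combined")) {
    d <- if (group == "Combined") pce_effect$cen_sn_combined_responder
    else pce_effect$cen_sn_responder
    if (d > 0) bump(latent$label == "WM" & latent$half == "second", d)
  }
  # post-intervention drift toward task-inappropriate DMN-SN synchrony in
  # non-responders, strongest in the NFB-only group (all WM windows)
  if (!isTRUE(responder) && session == "Post" &&
      group %in% c("Running", "NFB", "Combined")) {
    d <- if (group == "NFB") pce_effect$dmn_sn_nfb_nonresponder_post
    else pce_effect$dmn_sn_nonresponder_post
    if (d > 0) bump(latent$label == "WM", d)
  }
  latent$sn_active <- latent$a_sn > 0.5
  latent
}

# Window activation probabilities straight from latent levels plus noise.
latent_to_probs <- function(latent, prob_noise_sd, seed = NULL) {
  local_seed(seed, {
    n <- nrow(latent)
    probs <- data.frame(
      window = latent$window, trial = latent$trial, half = latent$half,
      label = latent$label,
      P_dmn = clip01(latent$a_dmn + rnorm(n, 0, prob_noise_sd), 0.01),
      P_cen = clip01(latent$a_cen + rnorm(n, 0, prob_noise_sd), 0.01),
      P_sn  = clip01(latent$a_sn  + rnorm(n, 0, prob_noise_sd), 0.01),
      stringsAsFactors = FALSE
    )
    class(probs) <- c("network_prob_series", "data.frame")
    probs
  })
}

#' Generate per-session behavior and fitness for one participant
#'
#' Draws the 16-session neurofeedback metrics (calm percentage and device
#' points) and pre/post VO2-max consistent with the participant's group and
#' ground-truth responder flag: NFB/Combined responders carry at least one
#' positive underlying behavioral slope, non-responders non-positive slopes
#' on both metrics; Running/Combined responders a strictly positive VO2-max
#' delta, non-responders a non-positive one; other groups draw deltas
#' centred at zero.
#'
#' @param group One of Control, Running, NFB, Combined.
#' @param responder Ground-truth responder flag.
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A `participant_record`: list with `group`, `responder_gt`,
#'   `sessions` (data frame: session, calm_pct, points), `vo2_pre`,
#'   `vo2_post`.
#' @export
generate_behavior <- function(group, responder, spec = cohort_spec(), seed = NULL) {
  group <- match.arg(group, COHORT_GROUPS)
  b <- spec$behavior; v <- spec$vo2; ns <- spec$n_sessions
  local_seed(seed, {
    nfb_arm <- group %in% c("NFB", "Combined")
    nfb_resp <- nfb_arm && isTRUE(responder)
    if (group == "Combined" && !isTRUE(responder)) {
      # a Combined non-responder fails the NFB rule, the exercise rule, or both
      fail_mode <- sample(c("nfb", "vo2", "both"), 1)
    } else fail_mode <- NA_character_
    nfb_pass <- nfb_resp || (group == "Combined" && !isTRUE(responder) &&
                               fail_mode == "vo2")
    if (nfb_arm && nfb_pass) {
      slope_calm <- runif(1, b$calm_slope_responder[1], b$calm_slope_responder[2])
      slope_pts <- if (runif(1) < 0.7)
        runif(1, b$points_slope_responder[1], b$points_slope_responder[2])
      else runif(1, -b$points_slope_responder[2] / 2, 0)
    } else if (nfb_arm) {
      slope_calm <- runif(1, b$slope_nonresponder[1], b$slope_nonresponder[2])
      slope_pts <- runif(1, b$slope_nonresponder[1] * 20, 0)
    } else {
      slope_calm <- rnorm(1, 0, 0.1)
      slope_pts <- rnorm(1, 0, 2)
    }
    s <- seq_len(ns)
    calm <- clip01((b$calm_start + slope_calm * s + rnorm(ns, 0, b$calm_sd)) / 100) * 100
    pts <- pmax(b$points_start + slope_pts * s + rnorm(ns, 0, b$points_sd), 0)
    vo2_pre <- max(rnorm(1, v$pre_mean, v$pre_sd), 20)
    run_arm <- group %in% c("Running", "Combined")
    vo2_pass <- (run_arm && isTRUE(responder)) ||
      (group == "Combined" && !isTRUE(responder) && fail_mode == "nfb")
    delta <- if (run_arm && vo2_pass) {
      abs(rnorm(1, v$responder_delta[1], v$responder_delta[2]))
    } else if (run_arm) {
      -abs(rnorm(1, -v$nonresponder_delta[1], v$nonresponder_delta[2]))
    } else rnorm(1, 0, v$null_delta_sd)
    structure(list(group = group, responder_gt = isTRUE(responder),
                   sessions = data.frame(session = s, calm_pct = calm,
                                         points = pts),
                   vo2_pre = vo2_pre, vo2_post = vo2_pre + delta),
              class = "participant_record")
  })
}

#' Generate a full synthetic cohort
#'
#' Produces, for every participant, a pre- and post-intervention scan plus
#' the behavioral/fitness record and ground-truth responder flag. At
#' `detail = "probs"` each scan carries the window-level network activation
#' probability series derived directly from the latent states (the substrate
#' of the PCE and statistics stages); at `detail = "eeg"` each scan carries
#' a synthesized multichannel EEG recording for the full pipeline.
#'
#' @param spec A [cohort_spec()].
#' @param detail `"probs"` (default) or `"eeg"`.
#' @return A `cohort` object: list with `spec`, `detail`, and `participants`
#'   (each with `id`, `group`, `responder_gt`, `record`, `pre`, `post`).
#' @export
generate_cohort <- function(spec = cohort_spec(), detail = c("probs", "eeg")) {
  detail <- match.arg(detail)
  participants <- list()
  idx <- 0L
  for (g in COHORT_GROUPS) {
    n <- spec$n_per_group[[g]]
    if (n == 0) next
    n_resp <- round(spec$responder_fraction[[g]] * n)
    resp <- local_seed(child_seed(spec$seed, "resp", g),
                       sample(c(rep(TRUE, n_resp), rep(FALSE, n - n_resp))))
    for (i in seq_len(n)) {
      idx <- idx + 1L
      id <- sprintf("P%03d", idx)
      record <- generate_behavior(g, resp[i], spec,
                                  seed = child_seed(spec$seed, "beh", id))
      scans <- lapply(c(Pre = "Pre", Post = "Post"), function(sess) {
        sseed <- child_seed(spec$seed, "scan", id, sess)
        sched <- generate_task_schedule(spec$n_blocks, seed = sseed)
        dyn <- spec$dynamics
        dyn$sn_coupling <- clip01(dyn$sn_coupling +
          local_seed(child_seed(spec$seed, "coup", id),
                     rnorm(1, 0, spec$sn_coupling_sd)), 0.05)
        latent <- generate_latent_states(sched, dyn, seed = sseed + 1L)
        latent <- apply_pce_effects(latent, g, resp[i], sess, spec$pce_effect)
        out <- list(schedule = sched, latent = latent)
        if (detail == "probs") {
          out$probs <- latent_to_probs(latent, spec$prob_noise_sd,
                                       seed = sseed + 2L)
        } else {
          out$eeg <- synthesize_eeg(latent, spec, seed = sseed + 3L,
                                    schedule = sched)
        }
        out
      })
      participants[[id]] <- list(id = id, group = g, responder_gt = resp[i],
                                 record = record,
                                 pre = scans$Pre, post = scans$Post)
    }
  }
  structure(list(spec = spec, detail = detail, participants = participants),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- vapply(x$participants, `[[`, "", "group")
  cat(sprintf("Synthetic cohort: %d participants (%s), detail = %s\n",
              length(x$participants),
              paste(sprintf("%s=%d", names(table(groups)), table(groups)),
                    collapse = ", "),
              x$detail))
  invisible(x)
}
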