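test_that("task schedules are balanced, 30 s, and seed-deterministic", {
  s <- generate_task_schedule(10, seed = 1)
  expect_equal(sum(s$label == "AM"), 5)
  expect_equal(sum(s$label == "WM"), 5)
  expect_true(all(s$duration_s == 30))
  expect_equal(sum(s$duration_s), 300)
  s2 <- generate_task_schedule(2, seed = 7)
  expect_setequal(s2$label, c("AM", "WM"))
  expect_identical(generate_task_schedule(10, seed = 3),
                   generate_task_schedule(10, seed = 3))
  expect_error(generate_task_schedule(7, seed = 1), "even")
  expect_error(generate_task_schedule(0, seed = 1), "even|>= 2")
})

test_that("latent states encode the within-trial DMN-to-CEN transition", {
  am <- data.frame(label = "AM", onset_s = 0, duration_s = 30)
  class(am) <- c("task_schedule", "data.frame")
  lat <- generate_latent_states(am, seed = 1)
  expect_equal(nrow(lat), 6)
  expect_gt(mean(lat$a_dmn[1:3]), mean(lat$a_dmn[4:6]))
  wm <- data.frame(label = "WM", onset_s = 0, duration_s = 30)
  class(wm) <- c("task_schedule", "data.frame")
  dyn0 <- latent_dynamics(noise_sd = 0)
  lat_wm <- generate_latent_states(wm, dyn0, seed = 1)
  expect_true(all(lat_wm$a_cen > lat_wm$a_dmn))
  # window-to-trial map: 4 blocks -> 4 trials x 6 windows
  sched <- generate_task_schedule(4, seed = 2)
  lat4 <- generate_latent_states(sched, seed = 3)
  expect_equal(length(unique(lat4$trial)), 4)
  expect_true(all(table(lat4$trial) == 6))
  expect_equal(lat4$half, rep(rep(c("first", "second"), each = 3), 4))
})

test_that("SN activation tracks the task-appropriate network", {
  sched <- generate_task_schedule(20, seed = 4)
  lat <- generate_latent_states(sched, seed = 5)
  task_level <- ifelse(lat$label == "AM", lat$a_dmn, lat$a_cen)
  expect_gt(stats::cor(lat$a_sn, task_level), 0.5)
})

test_that("synthetic EEG has the right shape and is seed-deterministic", {
  sc <- mini_scan(seed = 21, n_blocks = 2, n_channels = 32)
  expect_equal(dim(sc$eeg$data), c(32, 2 * 30 * 256))
  sc2 <- mini_scan(seed = 21, n_blocks = 2, n_channels = 32)
  expect_identical(sc$eeg$data, sc2$eeg$data)
  expect_error(
    synthesize_eeg(sc$lat, cohort_spec(seed = 1, sampling_rate = 90)),
    "gamma upper edge")
})

test_that("coupled-channel coherence collapses to the noise floor as snr -> 0", {
  hi <- mini_scan(seed = 31, snr = 2, n_blocks = 2)
  lo <- mini_scan(seed = 31, snr = 1e-6, n_blocks = 2)
  sets <- network_channel_sets(16)
  coh <- function(sc) {
    d <- bandpass_filter(sc$eeg, "alpha")
    coherence(d$data[sets$dmn[1], 1:1280], d$data[sets$dmn[2], 1:1280],
              "alpha", 256)
  }
  # surrogate null: coherence of window-shuffled channel pairs at snr ~ 0
  null_coh <- withr::with_seed(99, {
    d <- bandpass_filter(lo$eeg, "alpha")
    vapply(1:50, function(i) {
      a <- sample(16, 1); b <- sample(16, 1)
      off <- sample(1280, 1)
      coherence(d$data[a, 1:1280], d$data[b, off + (1:1280)], "alpha", 256)
    }, 0)
  })
  expect_gt(coh(hi), stats::quantile(null_coh, 0.95))
  expect_lt(coh(lo), stats::quantile(null_coh, 0.99) + 0.1)
})

test_that("behavior generation respects responder construction", {
  spec <- cohort_spec(seed = 2)
  nfb_r <- generate_behavior("NFB", TRUE, spec, seed = 11)
  sl <- c(fit_session_slope(nfb_r$sessions$calm_pct),
          fit_session_slope(nfb_r$sessions$points))
  expect_gt(max(sl), 0)
  run_n <- generate_behavior("Running", FALSE, spec, seed = 12)
  expect_lte(run_n$vo2_post, run_n$vo2_pre)
  run_r <- generate_behavior("Running", TRUE, spec, seed = 13)
  expect_gt(run_r$vo2_post, run_r$vo2_pre)
  ctl <- generate_behavior("Control", FALSE, spec, seed = 14)
  expect_equal(nrow(ctl$sessions), 16)
})

test_that("cohorts match requested sizes and are reproducible", {
  co <- generate_cohort(mini_spec(seed = 9))
  expect_equal(length(co$participants), 11)
  groups <- vapply(co$participants, `[[`, "", "group")
  expect_equal(unname(table(groups)[c("Control", "Running", "NFB",
                                      "Combined")]),
               c(2L, 3L, 3L, 3L), ignore_attr = TRUE)
  co2 <- generate_cohort(mini_spec(seed = 9))
  expect_identical(co$participants$P001$pre$probs,
                   co2$participants$P001$pre$probs)
  # responder_fraction = 1 labels every NFB participant a responder
  spec1 <- cohort_spec(n_per_group = c(Control = 0, Running = 0, NFB = 4,
                                       Combined = 0),
                       responder_fraction = c(Control = 0, Running = 0,
                                              NFB = 1, Combined = 0),
                       seed = 17)
  lab <- label_cohort(generate_cohort(spec1))
  expect_true(all(lab$final[lab$group == "NFB"] == "responder"))
})

test_that("study-sized default cohort has 69 participants", {
  spec <- cohort_spec()
  expect_equal(sum(spec$n_per_group), 69)
})
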