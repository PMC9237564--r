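# Small factories shared across tests; sizes chosen for fast unit runs.

mini_spec <- function(seed = 1, ...) {
  cohort_spec(n_per_group = c(Control = 2, Running = 3, NFB = 3,
                              Combined = 3),
              responder_fraction = c(Control = 0, Running = 2 / 3,
                                     NFB = 2 / 3, Combined = 1 / 3),
              n_channels = 16, n_blocks = 4, seed = seed, ...)
}

mini_scan <- function(seed = 1, snr = 1, n_blocks = 4, n_channels = 16,
                      artifacts = list(blink_rate = 0, muscle_rate = 0,
                                       n_bad_channels = 0)) {
  spec <- cohort_spec(seed = seed, snr = snr, n_channels = n_channels,
                      n_blocks = n_blocks, artifacts = artifacts)
  sched <- generate_task_schedule(n_blocks, seed = seed)
  lat <- generate_latent_states(sched, seed = seed + 1)
  eeg <- synthesize_eeg(lat, spec, seed = seed + 2, schedule = sched)
  list(spec = spec, sched = sched, lat = lat, eeg = eeg)
}

fake_cohort_table <- function(seed = 1, n = 4, ...) {
  spec <- cohort_spec(n_per_group = c(Control = 2, Running = n, NFB = n,
                                      Combined = n),
                      responder_fraction = c(Control = 0, Running = 0.5,
                                             NFB = 0.5, Combined = 0.5),
                      seed = seed, ...)
  build_cohort_table(generate_cohort(spec))
}

# A band-limited noisy sinusoid for connectivity tests.
sine_plus_noise <- function(freq, n = 1280, fs = 256, snr = 10, seed = 1,
                            phase = 0) {
  withr::with_seed(seed, {
    t <- (seq_len(n) - 1) / fs
    sqrt(2 * snr) * sin(2 * pi * freq * t + phase) + rnorm(n)
  })
}
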