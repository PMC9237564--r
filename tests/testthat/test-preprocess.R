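make_rec <- function(nch = 32, n = 5120, fs = 256, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(nch * n), nch)
    eeg_recording(X, fs)
  })
}

test_that("bad-channel detection flags constructed outliers only", {
  rec <- make_rec(seed = 2)
  noisy <- rec
  noisy$data[17, ] <- 10 * noisy$data[17, ]   # 100x broadband variance
  expect_equal(as.character(detect_bad_channels(noisy)), "Ch017")
  flat <- rec
  flat$data[5, ] <- 0
  expect_true("Ch005" %in% detect_bad_channels(flat))
  same <- rec
  for (i in 2:32) same$data[i, ] <- same$data[1, ]
  expect_length(detect_bad_channels(same), 0)
  expect_error(detect_bad_channels(make_rec(nch = 4)), ">= 8 channels")
})

test_that("ICA artifact removal recovers clean channels, removes the blink", {
  fs <- 256; n <- 5120
  withr::with_seed(3, {
    t <- (0:(n - 1)) / fs
    src <- matrix(runif(10 * n, -1.8, 1.8), 10)   # sub-Gaussian sources
    blink <- numeric(n)
    for (tc in seq(1, 19, by = 4))
      blink <- blink + 12 * exp(-(t - tc)^2 / (2 * 0.08^2))
    A <- matrix(rnorm(100), 10)
    X <- A %*% src
    topo <- c(8, 6, rep(0.1, 8))   # blink focal on channels 1-2
    X <- X + outer(topo, blink)
    rec <- eeg_recording(X, fs)
    res <- remove_artifact_components(rec, seed = 4)
    expect_gte(res$n_removed, 1)
    blink_idx <- which(blink > 1)
    raw_rms <- sqrt(mean(X[1, blink_idx]^2))
    clean_rms <- sqrt(mean(res$recording$data[1, blink_idx]^2))
    expect_lt(clean_rms / raw_rms, 0.3)
    clean_cors <- vapply(3:10, function(ch)
      stats::cor(res$recording$data[ch, ], X[ch, ]), 0)
    expect_true(all(clean_cors > 0.95))
  })
})

test_that("artifact-free data with strict thresholds passes through", {
  rec <- withr::with_seed(5, {
    A <- matrix(rnorm(100), 10)
    eeg_recording(A %*% matrix(runif(10 * 5120, -1.8, 1.8), 10), 256)
  })
  res <- remove_artifact_components(rec, blink_lowfreq_frac = 0.99,
                                    blink_focal_frac = 0.99,
                                    muscle_gamma_frac = 0.99, seed = 6)
  expect_equal(res$n_removed, 0)
  cors <- vapply(1:10, function(ch)
    stats::cor(res$recording$data[ch, ], rec$data[ch, ]), 0)
  expect_true(all(cors > 0.99))
})

test_that("rank-deficient input is handled by rank reduction", {
  rec <- withr::with_seed(7, {
    A <- matrix(rnorm(64), 8)
    eeg_recording(A %*% matrix(runif(8 * 5120, -1.8, 1.8), 8), 256)
  })
  rec$data <- rbind(rec$data, rec$data[1, ])   # duplicated channel
  res <- remove_artifact_components(rec, seed = 8)
  expect_true(is.matrix(res$cleaning_matrix))
})

test_that("average reference zeroes the channel mean and is idempotent", {
  rec <- make_rec(nch = 8, seed = 9)
  rec$data <- rec$data + 5                      # constant offset
  rr <- rereference_average(rec)
  expect_lt(max(abs(colMeans(rr$data))), 1e-10)
  rr2 <- rereference_average(rr)
  expect_equal(rr$data, rr2$data, tolerance = 1e-12)
})

test_that("the 5% interpolation rule gates spherical-spline interpolation", {
  rec128 <- make_rec(nch = 128, n = 512, seed = 10)
  r <- interpolate_bad(rec128, bads = 1:6)      # 6 < 6.4
  expect_equal(r$status, "interpolated")
  rec32 <- make_rec(nch = 32, n = 512, seed = 11)
  r2 <- interpolate_bad(rec32, bads = 1:2)      # 2 >= 1.6
  expect_equal(r2$status, "rejected")
  expect_null(r2$recording)
  r3 <- interpolate_bad(rec32, bads = integer(0))
  expect_equal(r3$status, "identity")
  expect_equal(r3$recording$data, rec32$data)
})

test_that("spherical splines reconstruct a smooth scalp field", {
  # low-order spherical-harmonic field sampled on the montage
  rec <- make_rec(nch = 64, n = 200, seed = 12)
  pos <- rec$ch_pos
  field <- function(w) 2 * pos[, 1] + pos[, 2] - 1.5 * pos[, 3] +
    pos[, 1] * pos[, 3] + 0.1 * w
  for (s in 1:200) rec$data[, s] <- field(s / 200)
  r <- interpolate_bad(rec, bads = 10)
  truth <- rec$data[10, ]
  est <- r$recording$data[10, ]
  expect_lt(sqrt(mean((est - truth)^2)) / stats::sd(truth), 0.2)
})

test_that("epoching yields six labeled windows per block", {
  sc <- mini_scan(seed = 51, n_blocks = 4)
  ep <- epoch_recording(sc$eeg, sc$sched)
  expect_equal(nrow(ep$index), 24)
  expect_equal(sum(ep$index$half == "first"), 12)
  expect_equal(ep$index$half[4], "second")
  expect_equal(dim(ep$bands$full), c(24, 16, 1280))
  empty <- sc$sched[0, ]
  ep0 <- epoch_recording(sc$eeg, empty)
  expect_equal(nrow(ep0$index), 0)
  long <- sc$sched
  long$onset_s[4] <- 1e5
  expect_error(epoch_recording(sc$eeg, long), "block 4")
})

test_that("the orchestrator runs the stages in the documented order", {
  sc <- mini_scan(seed = 53, n_blocks = 2)
  ep <- preprocess_eeg(sc$eeg, bad_threshold = 6)
  expect_equal(ep$provenance$stage_order,
               c("bandpass_filter", "detect_bad_channels",
                 "remove_artifact_components", "rereference_average",
                 "interpolate_bad", "epoch"))
  expect_named(ep$bands, band_definitions()$name)
})

test_that("a recording with too many bad channels is rejected outright", {
  sc <- mini_scan(seed = 55, n_blocks = 2)
  bad <- sc$eeg
  bad$data[3, ] <- 100 * bad$data[3, ]
  bad$data[9, ] <- 100 * bad$data[9, ]
  res <- preprocess_eeg(bad, ica = FALSE)
  expect_s3_class(res, "preprocess_rejected")
  expect_gte(res$n_bad, 2)
})
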