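test_that("compute_pce matches hand-derived values", {
  expect_equal(as.numeric(compute_pce(c(1, 1, 1), c(1, 1, 1))), 0)
  expect_equal(as.numeric(compute_pce(rep(0.5, 6), rep(0.5, 6))),
               3 * log(2), tolerance = 1e-9)   # 2.079442
  expect_equal(as.numeric(compute_pce(c(0.9, 0.9), c(0.1, 0.1))),
               1.8 * log(10), tolerance = 1e-9) # 4.144653
})

test_that("compute_pce equals the per-element oracle loop", {
  oracle <- function(a, b, eps = 1e-12) {
    s <- 0
    for (i in seq_along(a)) s <- s - a[i] * log(min(max(b[i], eps), 1))
    s
  }
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(1:40, 1)
      a <- runif(n); b <- runif(n)
      expect_equal(as.numeric(compute_pce(a, b)), oracle(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("compute_pce validates its inputs", {
  expect_error(compute_pce(c(0.5, 0.5), 0.5), "equal length")
  expect_error(compute_pce(numeric(0), numeric(0)), "at least one")
  expect_error(compute_pce(c(0.5, 1.2), c(0.5, 0.5)), "\\[0, 1\\]")
  expect_error(compute_pce(c(0.5, NA), c(0.5, 0.5)), "finite")
})

test_that("PCE is monotone in its arguments and zero only at synchrony", {
  a <- c(0.3, 0.6, 0.9); b <- c(0.5, 0.4, 0.8)
  base <- as.numeric(compute_pce(a, b))
  b_up <- b; b_up[2] <- b[2] + 0.1
  expect_lt(as.numeric(compute_pce(a, b_up)), base)
  a_up <- a; a_up[1] <- a[1] + 0.05
  expect_gt(as.numeric(compute_pce(a_up, b)), base)
  expect_gt(base, 0)
  expect_equal(as.numeric(compute_pce(c(0, 0.4), c(0.2, 1))), 0)
  # synchronized high-probability windows beat anti-phase at fixed marginals
  sync <- as.numeric(compute_pce(c(0.9, 0.1), c(0.9, 0.1)))
  anti <- as.numeric(compute_pce(c(0.9, 0.1), c(0.1, 0.9)))
  expect_lt(sync, anti)
})

make_probs <- function(n_blocks = 10, seed = 1) {
  sched <- generate_task_schedule(n_blocks, seed = seed)
  lat <- generate_latent_states(sched, seed = seed + 1)
  icnsync:::latent_to_probs(lat, 0.1, seed = seed + 2)
}

test_that("task/segment selection pools the expected windows", {
  probs <- make_probs(10, seed = 3)   # 5 WM trials
  full <- compute_task_pce(probs, "dmn-sn", "WM", "full")
  expect_equal(full$n_terms, 30)
  fh <- compute_task_pce(probs, "dmn-sn", "WM", "first_half")
  expect_equal(fh$n_terms, 15)
  expect_equal(full$value, sum(full$contributions), tolerance = 1e-12)
  # P_sn == 1 makes every contribution vanish
  p1 <- probs; p1$P_sn <- 1
  expect_equal(compute_task_pce(p1, "dmn-sn", "WM", "full")$value, 0)
  # brute-force oracle over the same windows
  sel <- probs[probs$label == "WM", ]
  sel <- sel[order(sel$trial, sel$window), ]
  s <- 0
  for (i in seq_len(nrow(sel)))
    s <- s - sel$P_dmn[i] * log(max(sel$P_sn[i], 1e-12))
  expect_equal(full$value, s, tolerance = 1e-12)
  empty <- probs[probs$label == "AM", ]
  empty$label <- "WM"
  expect_error(compute_task_pce(probs[0, ], "dmn-sn", "WM"), "empty")
})

test_that("pce_panel emits the full 24-row participant panel", {
  pre <- make_probs(4, seed = 5)
  post <- make_probs(4, seed = 6)
  pan <- pce_panel(pre, post, participant = "P1")
  expect_equal(nrow(pan), 24)
  expect_equal(sort(unique(pan$segment)),
               c("first_half", "full", "second_half"))
  same <- pce_panel(pre, pre)
  v <- stats::reshape(same[, c("session", "pair", "task", "segment",
                               "value")],
                      idvar = c("pair", "task", "segment"),
                      timevar = "session", direction = "wide")
  expect_equal(v$value.Pre, v$value.Post)
})

test_that("injected WM coupling lowers dmn-sn WM PCE across participants", {
  delta <- withr::with_seed(77, vapply(1:20, function(i) {
    sched <- generate_task_schedule(6, seed = i)
    lat <- generate_latent_states(sched, seed = i + 100)
    coupled <- lat
    sel <- coupled$label == "WM"
    coupled$a_sn[sel] <- coupled$a_sn[sel] + 0.5 * (0.97 - coupled$a_sn[sel])
    p0 <- icnsync:::latent_to_probs(lat, 0.1, seed = i + 200)
    p1 <- icnsync:::latent_to_probs(coupled, 0.1, seed = i + 200)
    compute_task_pce(p1, "dmn-sn", "WM")$value -
      compute_task_pce(p0, "dmn-sn", "WM")$value
  }, 0))
  expect_lt(stats::t.test(delta, alternative = "less")$p.value, 0.05)
})
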