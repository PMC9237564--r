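fake_participants <- function(deltas, seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(names(deltas), function(g) {
      n <- deltas[[g]]$n
      data.frame(participant = paste0(g, seq_len(n)), group = g,
                 responder = NA_character_,
                 calm_slope = rnorm(n), points_slope = rnorm(n),
                 vo2_pre = 40, vo2_post = 40,
                 vo2_delta = rnorm(n, deltas[[g]]$mu, 1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

test_that("VO2 manipulation check detects the exercise-arm effect", {
  hits <- vapply(1:25, function(i) {
    d <- fake_participants(list(Control = list(n = 15, mu = 0),
                                Running = list(n = 15, mu = 4),
                                NFB = list(n = 15, mu = 0),
                                Combined = list(n = 15, mu = 4)), seed = i)
    res <- vo2_manipulation_check(d)
    res$p[1] < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  res <- vo2_manipulation_check(
    fake_participants(list(Control = list(n = 15, mu = 0),
                           Running = list(n = 15, mu = 4),
                           NFB = list(n = 15, mu = 0),
                           Combined = list(n = 15, mu = 4)), seed = 3))
  expect_equal(nrow(res), 5)            # omnibus + 4 planned t-tests
  expect_equal(attr(res, "alpha_bonferroni"), 0.0125)
  expect_true(all(res$p_corrected[-1] >= res$p[-1]))
})

test_that("degenerate constant groups return statistic 0 / p 1", {
  d <- fake_participants(list(Control = list(n = 5, mu = 0),
                              Running = list(n = 5, mu = 0)), seed = 4)
  d$vo2_delta <- 1
  res <- vo2_manipulation_check(d)
  expect_equal(res$statistic[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("omnibus ANOVA type-I rate is nominal under the null", {
  pvals <- vapply(1:400, function(i) {
    d <- fake_participants(list(Control = list(n = 8, mu = 0),
                                Running = list(n = 8, mu = 0),
                                NFB = list(n = 8, mu = 0),
                                Combined = list(n = 8, mu = 0)), seed = i)
    vo2_manipulation_check(d)$p[1]
  }, 0)
  expect_gte(mean(pvals < 0.05), 0.03)
  expect_lte(mean(pvals < 0.05), 0.07)
})

test_that("multivariate NFB check is calibrated and powered", {
  null_p <- vapply(1:200, function(i) {
    d <- fake_participants(list(Control = list(n = 10, mu = 0),
                                NFB = list(n = 10, mu = 0)), seed = i + 500)
    nfb_effect_check(d)$p
  }, 0)
  expect_gte(mean(null_p < 0.05), 0.02)
  expect_lte(mean(null_p < 0.05), 0.08)
  d <- fake_participants(list(Control = list(n = 12, mu = 0),
                              NFB = list(n = 12, mu = 0)), seed = 9)
  d$calm_slope <- d$calm_slope + ifelse(d$group == "NFB", 3, 0)
  d$points_slope <- d$points_slope + ifelse(d$group == "NFB", 3, 0)
  expect_lt(nfb_effect_check(d)$p, 0.001)
  expect_error(nfb_effect_check(d[d$group == "NFB", ]), ">= 2 groups")
})

test_that("pairwise post-hocs: count, power, and null calibration", {
  withr::with_seed(21, {
    v <- c(rnorm(10), rnorm(10, 2), rnorm(10))
    g <- rep(c("A", "B", "C"), each = 10)
  })
  res <- posthoc_pairwise(v, g)
  expect_equal(nrow(res), 3)
  expect_lt(res$p_corrected[res$test == "A vs B"], 0.05)
  hits <- vapply(1:60, function(i) {
    withr::with_seed(1000 + i, {
      v <- c(rnorm(10), rnorm(10, 2))
      g <- rep(c("A", "B"), each = 10)
    })
    posthoc_pairwise(v, g)$p_corrected[1] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  null_rate <- mean(vapply(1:400, function(i) {
    withr::with_seed(3000 + i, {
      v <- rnorm(20); g <- rep(c("A", "B"), each = 10)
    })
    posthoc_pairwise(v, g)$p[1] < 0.05
  }, TRUE))
  expect_gte(null_rate, 0.03); expect_lte(null_rate, 0.07)
  small <- posthoc_pairwise(c(1, 2, 3), c("A", "A", "B"))
  expect_match(small$status[1], "skipped")
})

test_that("BH correction preserves p-value ordering and dominates raw p", {
  withr::with_seed(22, p <- runif(30)^2)
  adj <- stats::p.adjust(p, method = "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12))
  expect_true(all(adj <= pmin(p * length(p) / rank(p) + 1e-12, 1)))
})

test_that("Spearman correlation: monotone pairs and tie handling", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(unname(suppressWarnings(
    stats::cor.test(x, x^3, method = "spearman")$estimate)), 1)
  ct <- fake_cohort_table(seed = 31)
  res <- fitness_synchrony_correlation(ct)
  expect_equal(nrow(res), 2)
  expect_true(all(is.finite(res$statistic)))
  # tied values do not crash
  ct$participants$vo2_pre <- rep(40, nrow(ct$participants))
  expect_silent(fitness_synchrony_correlation(ct))
})

test_that("null Spearman magnitude matches its sampling distribution", {
  rhos <- vapply(1:400, function(i) {
    withr::with_seed(5000 + i,
                     stats::cor(rnorm(16), rnorm(16), method = "spearman"))
  }, 0)
  q95 <- stats::quantile(rhos, 0.95)
  expect_gte(q95, 0.38); expect_lte(q95, 0.48)
})

test_that("SVM cross-validation: separable, chance, and Bayes-rate cases", {
  withr::with_seed(23, {
    X <- matrix(c(rnorm(20, -4, 0.3), rnorm(20, 4, 0.3)), ncol = 1)
    y <- rep(c("a", "b"), each = 20)
  })
  expect_equal(svm_cv_accuracy(X, y, k = 10, seed = 1)$mean, 1)
  accs <- vapply(1:30, function(i) {
    withr::with_seed(6000 + i, {
      X <- matrix(rnorm(40), ncol = 1)
      y <- rep(c("a", "b"), each = 20)
    })
    svm_cv_accuracy(X, y, k = 10, seed = i)$mean
  }, 0)
  expect_gte(mean(accs), 0.35); expect_lte(mean(accs), 0.65)
  # Gaussian classes at d' = 2: accuracy near Phi(1) = 0.841
  accs2 <- vapply(1:10, function(i) {
    withr::with_seed(7000 + i, {
      X <- matrix(c(rnorm(100, 0), rnorm(100, 2)), ncol = 1)
      y <- rep(c("a", "b"), each = 100)
    })
    svm_cv_accuracy(X, y, k = 10, seed = i)$mean
  }, 0)
  expect_lt(abs(mean(accs2) - stats::pnorm(1)), 0.05)
  expect_error(svm_cv_accuracy(matrix(rnorm(8), ncol = 1),
                               rep(c("a", "b"), 4), k = 10), "at least k")
})

test_that("three-way factorial and RM-ANOVA run on a minimal balanced table", {
  ct <- fake_cohort_table(seed = 41)
  res3 <- pce_three_way(ct)
  expect_true(all(is.finite(res3$statistic[res3$status == "ok"])))
  expect_true(any(grepl("group:session:responder", res3$test)))
  rm <- rm_anova_bootstrap(ct, subset = "non-responder", n_boot = 20,
                           seed = 2)
  expect_equal(nrow(rm), 6)   # 2 outcomes x 3 terms
  expect_true(all(rm$correction == "FDR-BH"))
  expect_true(all(is.finite(rm$ci_low) | rm$status != "ok"))
  rm1 <- rm_anova_bootstrap(ct, subset = "responder", n_boot = 1, seed = 3)
  expect_true(all(rm1$status == "degenerate-ci"))
})

test_that("RM-ANOVA bootstrap excludes participants missing a session", {
  ct <- fake_cohort_table(seed = 43)
  drop_id <- ct$pce$participant[!is.na(ct$pce$responder) &
                                  ct$pce$responder == "non-responder"][1]
  ct$pce <- ct$pce[!(ct$pce$participant == drop_id &
                       ct$pce$session == "Post"), ]
  rm <- rm_anova_bootstrap(ct, subset = "non-responder", n_boot = 5,
                           seed = 4)
  expect_true(drop_id %in% attr(rm, "excluded"))
})
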