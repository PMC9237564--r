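test_row <- function(test, statistic = NA_real_, df1 = NA_real_,
                     df2 = NA_real_, p = NA_real_, p_corrected = NA_real_,
                     correction = "none", effect_size = NA_real_,
                     n_boot = NA_integer_, status = "ok",
                     ci_low = NA_real_, ci_high = NA_real_) {
  data.frame(test = test, statistic = statistic, df1 = df1, df2 = df2,
             p = p, p_corrected = p_corrected, correction = correction,
             effect_size = effect_size, ci_low = ci_low, ci_high = ci_high,
             n_boot = n_boot, status = status, stringsAsFactors = FALSE)
}

# Cohen's d: mean difference over pooled SD (independent samples).
cohens_d <- function(a, b) {
  sp <- sqrt(((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Aerobic-intervention manipulation check
#'
#' One-way ANOVA of the VO2-max change from baseline across the four
#' groups, followed by the four planned independent-samples Welch t-tests
#' (Running vs Control, Combined vs Control, Running vs NFB, Combined vs
#' NFB) at the Bonferroni-corrected threshold 0.0125 (0.05 / 4), with
#' Cohen's d effect sizes.
#'
#' @param ct A `cohort_table` (or data frame with `group` and `vo2_delta`).
#' @return A data frame of test results (omnibus first), with the
#'   Bonferroni alpha in attribute `"alpha_bonferroni"`.
#' @export
vo2_manipulation_check <- function(ct) {
  d <- if (inherits(ct, "cohort_table")) ct$participants else ct
  d <- d[is.finite(d$vo2_delta), ]
  groups <- unique(d$group)
  if (length(groups) < 2 || any(table(d$group) < 2))
    stop_invalid("need >= 2 groups with >= 2 participants each")
  if (stats::var(d$vo2_delta) == 0) {
    omni <- test_row("vo2_delta ~ group (omnibus)", 0, length(groups) - 1,
                     nrow(d) - length(groups), 1, status = "degenerate")
  } else {
    fit <- stats::aov(vo2_delta ~ factor(group), data = d)
    a <- summary(fit)[[1]]
    eta2 <- a[1, "Sum Sq"] / sum(a[, "Sum Sq"])
    omni <- test_row("vo2_delta ~ group (omnibus)", a[1, "F value"],
                     a[1, "Df"], a[2, "Df"], a[1, "Pr(>F)"],
                     effect_size = eta2)
  }
  planned <- list(c("Running", "Control"), c("Combined", "Control"),
                  c("Running", "NFB"), c("Combined", "NFB"))
  rows <- lapply(planned, function(pr) {
    if (!all(pr %in% groups)) return(NULL)
    a <- d$vo2_delta[d$group == pr[1]]
    b <- d$vo2_delta[d$group == pr[2]]
    tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
    if (is.null(tt))
      return(test_row(paste(pr, collapse = " vs "), status = "degenerate"))
    test_row(paste(pr, collapse = " vs "), unname(tt$statistic),
             df2 = unname(tt$parameter), p = tt$p.value,
             p_corrected = min(tt$p.value * 4, 1), correction = "Bonferroni",
             effect_size = cohens_d(a, b))
  })
  out <- rbind(omni, do.call(rbind, rows))
  attr(out, "alpha_bonferroni") <- 0.0125
  out
}

#' Neurofeedback-intervention effectiveness check
#'
#' Multivariate one-way ANOVA (Pillai's trace) of the two neurofeedback
#' performance metrics (calm-percentage slope, points slope) across groups.
#'
#' @param ct A `cohort_table` (or data frame with `group`, `calm_slope`,
#'   `points_slope`).
#' @return One-row test-result data frame.
#' @export
nfb_effect_check <- function(ct) {
  d <- if (inherits(ct, "cohort_table")) behavior_slopes(ct) else ct
  d <- d[is.finite(d$calm_slope) & is.finite(d$points_slope), ]
  if (length(unique(d$group)) < 2)
    stop_invalid("need >= 2 groups with both NFB metrics")
  fit <- stats::manova(cbind(calm_slope, points_slope) ~ factor(group),
                       data = d)
  s <- summary(fit, test = "Pillai")$stats
  test_row("(calm_slope, points_slope) ~ group (Pillai)",
           s[1, "approx F"], s[1, "num Df"], s[1, "den Df"],
           s[1, "Pr(>F)"], effect_size = s[1, "Pillai"] / nrow(s))
}

#' Three-way factorial tests on the PCE panel
#'
#' For each of the four PCE outcomes of interest (dmn-sn and cen-sn during
#' WM and AM, full trials), a Group x Session x Responder factorial ANOVA
#' including the three-way interaction, with partial eta squared per term.
#' Control participants (no responder label) are excluded.
#'
#' @param ct A `cohort_table`.
#' @param segment Trial segment (default "full").
#' @return Data frame of test results, one row per outcome x term.
#' @export
pce_three_way <- function(ct, segment = "full") {
  grid <- expand.grid(pair = c("dmn-sn", "cen-sn"), task = c("WM", "AM"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- pce_outcome(ct, grid$pair[i], grid$task[i], segment)
    d <- d[!is.na(d$responder), ]
    if (nrow(d) == 0) return(NULL)
    d$group <- factor(d$group); d$session <- factor(d$session)
    d$responder <- factor(d$responder)
    fit <- tryCatch(stats::aov(value ~ group * session * responder, data = d),
                    error = function(e) NULL)
    if (is.null(fit))
      return(test_row(sprintf("pce %s %s: model failure", grid$pair[i],
                              grid$task[i]), status = "dropped"))
    a <- summary(fit)[[1]]
    terms <- trimws(rownames(a))
    res_i <- which(terms == "Residuals")
    out <- lapply(setdiff(seq_len(nrow(a)), res_i), function(r) {
      peta <- a[r, "Sum Sq"] / (a[r, "Sum Sq"] + a[res_i, "Sum Sq"])
      test_row(sprintf("pce %s %s [%s]", grid$pair[i], grid$task[i],
                       terms[r]),
               a[r, "F value"], a[r, "Df"], a[res_i, "Df"], a[r, "Pr(>F)"],
               effect_size = peta,
               status = if (is.na(a[r, "F value"])) "dropped" else "ok")
    })
    do.call(rbind, out)
  })
  do.call(rbind, rows)
}

# Two-way mixed ANOVA (Group between, Session within) on a wide
# participant x session outcome; returns F/p/partial eta^2 per term.
rm_anova_fit <- function(d) {
  d$group <- factor(d$group); d$session <- factor(d$session,
                                                  levels = c("Pre", "Post"))
  d$participant <- factor(d$participant)
  fit <- stats::aov(value ~ group * session + Error(participant), data = d)
  s <- summary(fit)
  between <- s[["Error: participant"]][[1]]
  within <- s[["Error: Within"]][[1]]
  g <- trimws(rownames(between)); w <- trimws(rownames(within))
  gres <- which(g == "Residuals"); wres <- which(w == "Residuals")
  peta <- function(tab, r, res) tab[r, "Sum Sq"] /
    (tab[r, "Sum Sq"] + tab[res, "Sum Sq"])
  list(
    group = c(F = between[1, "F value"], df1 = between[1, "Df"],
              df2 = between[gres, "Df"], p = between[1, "Pr(>F)"],
              peta = peta(between, 1, gres)),
    session = c(F = within[which(w == "session"), "F value"],
                df1 = within[which(w == "session"), "Df"],
                df2 = within[wres, "Df"],
                p = within[which(w == "session"), "Pr(>F)"],
                peta = peta(within, which(w == "session"), wres)),
    interaction = c(F = within[which(w == "group:session"), "F value"],
                    df1 = within[which(w == "group:session"), "Df"],
                    df2 = within[wres, "Df"],
                    p = within[which(w == "group:session"), "Pr(>F)"],
                    peta = peta(within, which(w == "group:session"), wres)))
}

#' Bootstrapped two-way repeated-measures ANOVA on PCE outcomes
#'
#' Group (between) x Session (within) repeated-measures ANOVA for each
#' requested PCE outcome, restricted to responders or non-responders.
#' Percentile confidence intervals for each term's partial eta squared come
#' from `n_boot` replicates resampling participants within group;
#' Benjamini-Hochberg correction is applied per effect term across the
#' outcome family. Participants missing a session are excluded (logged in
#' the `status` column of an attribute).
#'
#' @param ct A `cohort_table`.
#' @param outcomes Data frame with columns `pair`, `task`, `segment` (one
#'   row per outcome; default the two WM outcomes, full trials).
#' @param subset `"responder"` or `"non-responder"`.
#' @param n_boot Bootstrap replicates (default 1000; values < 2 skip CIs
#'   and are flagged degenerate).
#' @param seed Seed for the bootstrap resampling.
#' @return Data frame of test results (outcome x term rows).
#' @export
rm_anova_bootstrap <- function(ct,
                               outcomes = data.frame(
                                 pair = c("dmn-sn", "cen-sn"),
                                 task = "WM", segment = "full",
                                 stringsAsFactors = FALSE),
                               subset = c("non-responder", "responder"),
                               n_boot = 1000, seed = 1) {
  subset <- match.arg(subset)
  per_outcome <- lapply(seq_len(nrow(outcomes)), function(i) {
    d <- pce_outcome(ct, outcomes$pair[i], outcomes$task[i],
                     outcomes$segment[i], subset_responder = subset)
    cnt <- table(d$participant)
    excluded <- names(cnt)[cnt < 2]
    d <- d[!(d$participant %in% excluded), ]
    if (nrow(d) < 4 || length(unique(d$group)) < 2)
      return(list(rows = test_row(
        sprintf("pce %s %s %s (%s): insufficient data", outcomes$pair[i],
                outcomes$task[i], outcomes$segment[i], subset),
        status = "insufficient-data"), excluded = excluded))
    est <- rm_anova_fit(d)
    cis <- boot_cis(d, n_boot, seed + i)
    rows <- do.call(rbind, lapply(names(est), function(term) {
      e <- est[[term]]
      test_row(sprintf("pce %s %s %s (%s) [%s]", outcomes$pair[i],
                       outcomes$task[i], outcomes$segment[i], subset, term),
               e["F"], e["df1"], e["df2"], e["p"], effect_size = e["peta"],
               n_boot = n_boot, ci_low = cis[[term]][1],
               ci_high = cis[[term]][2],
               status = if (n_boot < 2) "degenerate-ci" else "ok")
    }))
    list(rows = rows, excluded = excluded)
  })
  out <- do.call(rbind, lapply(per_outcome, `[[`, "rows"))
  # BH per term family across outcomes
  for (term in c("group", "session", "interaction")) {
    sel <- grepl(sprintf("\\[%s\\]$", term), out$test)
    if (any(sel)) {
      out$p_corrected[sel] <- stats::p.adjust(out$p[sel], method = "BH")
      out$correction[sel] <- "FDR-BH"
    }
  }
  attr(out, "excluded") <- unique(unlist(lapply(per_outcome, `[[`,
                                                "excluded")))
  out
}

boot_cis <- function(d, n_boot, seed) {
  empty <- list(group = c(NA, NA), session = c(NA, NA),
                interaction = c(NA, NA))
  if (n_boot < 2) return(empty)
  ids_by_group <- lapply(split(d$participant, d$group), unique)
  ids_by_group <- ids_by_group[vapply(ids_by_group, length, 0L) > 0]
  stats_mat <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      picks <- unlist(lapply(names(ids_by_group), function(g) {
        ids <- ids_by_group[[g]]
        sample(ids, length(ids), replace = TRUE)
      }))
      reps <- lapply(seq_along(picks), function(j) {
        rows <- d[d$participant == picks[j], ]
        rows$participant <- sprintf("b%04d", j)
        rows
      })
      db <- do.call(rbind, reps)
      est <- tryCatch(rm_anova_fit(db), error = function(e) NULL)
      if (is.null(est)) return(c(NA_real_, NA_real_, NA_real_))
      c(est$group["peta"], est$session["peta"], est$interaction["peta"])
    }, numeric(3))
  })
  list(group = stats::quantile(stats_mat[1, ], c(0.025, 0.975), na.rm = TRUE),
       session = stats::quantile(stats_mat[2, ], c(0.025, 0.975), na.rm = TRUE),
       interaction = stats::quantile(stats_mat[3, ], c(0.025, 0.975),
                                     na.rm = TRUE))
}

#' Post-hoc pairwise group comparisons
#'
#' Welch t-tests between every pair of groups on one outcome, with Cohen's
#' d and Benjamini-Hochberg correction across the pair family. One-tailed
#' tests use the fixed alternative "first group lower" in the pair's
#' (alphabetical) order, so the test is directional, not data-driven.
#'
#' @param values Outcome values.
#' @param groups Group labels, same length.
#' @param tail `"two"` (default) or `"one"`.
#' @return Data frame of test results (one row per pair; pairs with a
#'   group of n < 2 are reported with a skipped status).
#' @export
posthoc_pairwise <- function(values, groups, tail = c("two", "one")) {
  tail <- match.arg(tail)
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) < 2) stop_invalid("need >= 2 groups")
  prs <- utils::combn(gl, 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    a <- values[groups == pr[1]]; b <- values[groups == pr[2]]
    nm <- paste(pr, collapse = " vs ")
    if (length(a) < 2 || length(b) < 2)
      return(test_row(nm, status = "skipped: group n < 2"))
    alt <- if (tail == "one") "less" else "two.sided"
    tt <- stats::t.test(a, b, alternative = alt)
    test_row(nm, unname(tt$statistic), df2 = unname(tt$parameter),
             p = tt$p.value, effect_size = cohens_d(a, b))
  })
  out <- do.call(rbind, rows)
  ok <- out$status == "ok"
  out$p_corrected[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out$correction[ok] <- "FDR-BH"
  out
}

#' Spearman correlation of synchrony change with aerobic fitness
#'
#' Correlates the change (post minus pre) in dmn-sn PCE during WM trials
#' with VO2-max at the pre- and post-intervention timepoints, over the
#' exercising participants (Running and Combined groups).
#'
#' @param ct A `cohort_table`.
#' @param pair,task,segment Outcome selector (defaults dmn-sn, WM, full).
#' @return Data frame with two rows (Pre, Post): Spearman's rho and p.
#' @export
fitness_synchrony_correlation <- function(ct, pair = "dmn-sn", task = "WM",
                                          segment = "full") {
  d <- pce_outcome(ct, pair, task, segment)
  d <- d[d$group %in% c("Running", "Combined"), ]
  wide <- stats::reshape(d[, c("participant", "session", "value")],
                         idvar = "participant", timevar = "session",
                         direction = "wide")
  delta <- wide$value.Post - wide$value.Pre
  pt <- ct$participants[match(wide$participant, ct$participants$participant), ]
  out <- lapply(c(Pre = "vo2_pre", Post = "vo2_post"), function(v) {
    ok <- is.finite(delta) & is.finite(pt[[v]])
    if (sum(ok) < 5)
      return(test_row(paste0("delta-PCE vs ", v),
                      status = "insufficient-data"))
    ct_ <- suppressWarnings(stats::cor.test(delta[ok], pt[[v]][ok],
                                            method = "spearman"))
    test_row(paste0("delta-PCE vs ", v), unname(ct_$estimate),
             p = ct_$p.value, effect_size = unname(ct_$estimate))
  })
  do.call(rbind, out)
}

#' Stratified k-fold cross-validated linear-SVM accuracy
#'
#' Generic engine for response prediction: stratified fold assignment
#' (seeded), a linear support vector machine per training fold, and the
#' per-fold held-out accuracies.
#'
#' @param X Predictor matrix (participants x predictors).
#' @param y Binary class labels.
#' @param k Folds (default 10).
#' @param seed Fold-assignment seed.
#' @param cost SVM cost parameter (default 1).
#' @return List with `fold_accuracy`, `mean`, `sd`, `k`.
#' @export
svm_cv_accuracy <- function(X, y, k = 10, seed = 1, cost = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop_invalid("both classes must be present")
  if (nrow(X) < k) stop_invalid("need at least k labeled cases")
  folds <- local_seed(seed, {
    f <- integer(nrow(X))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  acc <- vapply(seq_len(k), function(fi) {
    tr <- folds != fi; te <- !tr
    if (length(unique(y[tr])) < 2)
      stop("stratification failure: a training fold lacks a class",
           call. = FALSE)
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = cost, scale = apply(X[tr, , drop = FALSE], 2,
                                                 stats::sd) > 0)
    mean(predict(fit, X[te, , drop = FALSE]) == y[te])
  }, 0)
  list(fold_accuracy = acc, mean = mean(acc), sd = stats::sd(acc), k = k)
}

#' Predict neurofeedback response from baseline PCE
#'
#' Classifies NFB response (responder vs non-responder, NFB and Combined
#' groups) from the pre-intervention PCE during WM trials, using a linear
#' SVM with stratified k-fold cross-validation. The predictor set defaults
#' to the cen-sn PCE alone; `predictors = c("cen-sn", "dmn-sn")` uses both.
#'
#' @param ct A `cohort_table`.
#' @param predictors Subset of `c("cen-sn", "dmn-sn")`.
#' @param k Folds (default 10).
#' @param seed Fold seed.
#' @param groups Groups whose participants enter the classification.
#' @return List with `fold_accuracy`, `mean`, `sd`, `k`, `n`.
#' @export
predict_nfb_response <- function(ct, predictors = "cen-sn", k = 10, seed = 1,
                                 groups = c("NFB", "Combined")) {
  stopifnot(all(predictors %in% c("cen-sn", "dmn-sn")))
  pt <- ct$participants[ct$participants$group %in% groups &
                          !is.na(ct$participants$responder), ]
  X <- vapply(predictors, function(pr) {
    d <- pce_outcome(ct, pr, "WM", "full")
    d <- d[d$session == "Pre", ]
    d$value[match(pt$participant, d$participant)]
  }, numeric(nrow(pt)))
  X <- matrix(X, nrow = nrow(pt),
              dimnames = list(NULL, predictors))
  res <- svm_cv_accuracy(X, pt$responder, k = k, seed = seed)
  res$n <- nrow(pt)
  res
}
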