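default_config <- function() {
  list(
    detail = "probs",
    cohort = list(),               # cohort_spec() arguments
    preprocess = list(bad_threshold = 3, ica = FALSE),
    features = list(pairs = "within_network", K = 200,
                    band_pairs = list(c("theta", "gamma"),
                                      c("alpha", "gamma"))),
    classifier = list(lambda = 0.05, train_frac = 0.5),
    stats = list(n_boot = 1000, k_folds = 10),
    bands = NULL,                  # optional band redefinitions
    seed = NULL,                   # overrides cohort$seed when given
    out_dir = NULL
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults, checks vocabulary (stage names, groups, bands) and value
#' ranges, and returns the normalized configuration. Unknown keys and bad
#' ranges are reported together in one error. Redefining a canonical band
#' is accepted with a warning.
#'
#' @param config A named list, or path to a YAML/JSON file.
#' @return The normalized configuration (class `run_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  def <- default_config()
  problems <- character(0)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    problems <- c(problems, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(def, config[intersect(names(config), names(def))])
  if (!cfg$detail %in% c("probs", "eeg"))
    problems <- c(problems, "detail must be 'probs' or 'eeg'")
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || cfg$seed < 0)
      problems <- c(problems, "seed must be a non-negative integer")
    else cfg$cohort$seed <- as.integer(cfg$seed)
  }
  if (!is.null(cfg$cohort$n_per_group)) {
    npg <- cfg$cohort$n_per_group
    if (is.null(names(npg)) || !all(names(npg) %in% COHORT_GROUPS))
      problems <- c(problems, paste0("n_per_group names must be drawn from: ",
                                     paste(COHORT_GROUPS, collapse = ", ")))
  }
  if (!is.null(cfg$bands)) {
    canon <- band_definitions()
    for (nm in names(cfg$bands)) {
      if (!nm %in% canon$name) {
        problems <- c(problems, paste0("unknown band: ", nm))
      } else {
        b <- cfg$bands[[nm]]
        i <- match(nm, canon$name)
        if (!isTRUE(all.equal(as.numeric(b),
                              c(canon$low_hz[i], canon$high_hz[i]))))
          warning("band '", nm, "' redefined to ", b[1], "-", b[2],
                  " Hz (non-canonical)", call. = FALSE)
      }
    }
  }
  if (length(problems))
    stop_invalid("invalid configuration:\n  - ",
                 paste(problems, collapse = "\n  - "))
  spec_args <- cfg$cohort
  cfg$cohort_spec <- do.call(cohort_spec, spec_args)
  class(cfg) <- "run_config"
  cfg
}

file_hash <- function(path) unname(tools::md5sum(path))

#' Run the full analysis pipeline
#'
#' Orchestrates simulate, (for EEG detail) preprocess / feature extraction /
#' classifier training / probability prediction, then PCE, responder
#' labeling and the statistical battery, writing tabular artifacts and a
#' hashed manifest when `out_dir` is set.
#'
#' @param config A configuration accepted by [validate_config()].
#' @return A `pipeline_run`: list with `config`, `cohort_table`, `labels`,
#'   `stats` (named list of test-result tables), `prediction`, `manifest`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  t0 <- Sys.time()
  stages <- character(0)
  timings <- numeric(0)
  tick <- function(name, start) {
    stages <<- c(stages, name)
    timings <<- c(timings, as.numeric(difftime(Sys.time(), start,
                                               units = "secs")))
  }

  s <- Sys.time()
  cohort <- generate_cohort(cfg$cohort_spec, detail = cfg$detail)
  tick("simulate", s)

  if (cfg$detail == "eeg") {
    s <- Sys.time()
    cohort <- eeg_to_probabilities(cohort, cfg)
    tick("preprocess+features+classify", s)
  }

  s <- Sys.time()
  labels <- label_cohort(cohort)
  tick("label", s)

  s <- Sys.time()
  ct <- build_cohort_table(cohort, labels)
  tick("pce", s)

  s <- Sys.time()
  nb <- cfg$stats$n_boot
  # small cohorts can fail a test's preconditions; report, don't abort
  try_stat <- function(name, expr) tryCatch(expr, error = function(e)
    test_row(name, status = paste0("error: ", conditionMessage(e))))
  stat_results <- list(
    vo2_manipulation = try_stat("vo2 manipulation check",
                                vo2_manipulation_check(ct)),
    nfb_effect = try_stat("nfb effect check", nfb_effect_check(ct)),
    pce_three_way = try_stat("pce three-way", pce_three_way(ct)),
    rm_nonresponders = try_stat("rm non-responders",
      rm_anova_bootstrap(ct, subset = "non-responder", n_boot = nb,
                         seed = cfg$cohort_spec$seed + 1L)),
    rm_responders = try_stat("rm responders",
      rm_anova_bootstrap(ct, subset = "responder", n_boot = nb,
                         seed = cfg$cohort_spec$seed + 2L)),
    fitness_correlation = try_stat("fitness correlation",
                                   fitness_synchrony_correlation(ct))
  )
  prediction <- tryCatch(
    predict_nfb_response(ct, k = min(cfg$stats$k_folds,
                                     sum(!is.na(ct$participants$responder))),
                         seed = cfg$cohort_spec$seed + 3L),
    error = function(e) list(error = conditionMessage(e)))
  tick("stats", s)

  manifest <- list(stages = stages, timings_s = round(timings, 3),
                   seed = cfg$cohort_spec$seed, detail = cfg$detail,
                   started = format(t0), artifacts = list())
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      pce = write_table_csv(ct$pce, file.path(cfg$out_dir, "pce.csv")),
      participants = write_table_csv(ct$participants,
                                     file.path(cfg$out_dir,
                                               "participants.csv")),
      labels = write_table_csv(labels, file.path(cfg$out_dir, "labels.csv"))
    )
    for (nm in names(stat_results))
      paths[nm] <- write_table_csv(stat_results[[nm]],
                                   file.path(cfg$out_dir,
                                             paste0("stats_", nm, ".csv")))
    manifest$artifacts <- lapply(paths, function(p)
      list(path = p, md5 = file_hash(p)))
    jsonlite::write_json(manifest,
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(config = cfg, cohort_table = ct, labels = labels,
                 stats = stat_results, prediction = prediction,
                 manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (", x$manifest$detail, " detail), stages: ",
      paste(x$manifest$stages, collapse = " -> "), "\n", sep = "")
  cat(sprintf("  %d participants\n", nrow(x$cohort_table$participants)))
  invisible(x)
}

# Channel-pair universe for feature extraction from a config keyword.
resolve_pairs <- function(pairs, n_channels) {
  if (is.matrix(pairs)) return(pairs)
  sets <- network_channel_sets(n_channels)
  switch(as.character(pairs),
    all = all_pairs(seq_len(n_channels)),
    within_network = {
      wn <- rbind(all_pairs(sets$dmn), all_pairs(sets$cen),
                  all_pairs(sets$sn))
      cross <- cbind(c(sets$dmn[1:2], sets$cen[1:2], sets$sn[1:2]),
                     c(sets$cen[1:2], sets$sn[1:2], sets$dmn[1:2]))
      rbind(wn, cross)
    },
    stop_invalid("unknown pair specification: ", pairs))
}

# EEG-level path: preprocess every scan, extract features, train the
# network classifiers on a participant split, and attach predicted
# probability series to every scan.
eeg_to_probabilities <- function(cohort, cfg) {
  spec <- cohort$spec
  prs <- resolve_pairs(cfg$features$pairs, spec$n_channels)
  scans <- list()
  for (id in names(cohort$participants)) {
    for (sess in c("pre", "post")) {
      sc <- cohort$participants[[id]][[sess]]
      ep <- preprocess_eeg(sc$eeg, schedule = sc$schedule,
                           bad_threshold = cfg$preprocess$bad_threshold,
                           ica = isTRUE(cfg$preprocess$ica))
      if (inherits(ep, "preprocess_rejected"))
        stop("preprocess stage rejected participant ", id, " (", sess,
             " scan): ", ep$n_bad, " bad channels exceed the 5% rule",
             call. = FALSE)
      fm <- extract_feature_matrix(ep, pairs = prs,
                                   band_pairs = cfg$features$band_pairs)
      scans[[paste(id, sess)]] <- list(id = id, sess = sess, fm = fm,
                                       latent = sc$latent)
    }
  }
  ids <- names(cohort$participants)
  n_train <- max(1L, floor(cfg$classifier$train_frac * length(ids)))
  train_ids <- local_seed(spec$seed, sample(ids, n_train))
  tr <- unlist(lapply(scans, function(s) s$id %in% train_ids))
  Xall <- do.call(rbind, lapply(scans, function(s) s$fm$X))
  latall <- do.call(rbind, lapply(scans, function(s)
    as.data.frame(s$latent)))
  fm_all <- structure(list(X = Xall, descriptor = scans[[1]]$fm$descriptor,
                           index = NULL), class = "feature_matrix")
  row_train <- rep(tr, times = vapply(scans, function(s) nrow(s$fm$X), 0L))
  model <- fit_network_model(fm_all, latall, K = cfg$features$K,
                             train_idx = which(row_train),
                             lambda = cfg$classifier$lambda)
  for (s in scans) {
    probs <- predict_probabilities(model, s$fm)
    cohort$participants[[s$id]][[s$sess]]$probs <- probs
  }
  cohort$model <- model
  cohort$train_ids <- train_ids
  cohort
}
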