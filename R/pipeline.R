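#' Build a validated pipeline run configuration
#'
#' Collects every tunable number used by the end-to-end run: cohort sizes
#' and generating effects, task structure, EEG simulation and preprocessing
#' parameters, and the group-statistics settings. A persisted config plus
#' the package version fully determines a run; all stage randomness is
#' derived deterministically from the single `seed`.
#'
#' @param seed Integer master seed.
#' @param group_sizes Cohort sizes (directly/indirectly/non-exposed).
#' @param n_trials Trials per block.
#' @param covariate_config See [default_covariate_config()].
#' @param behavior_effect See [behavior_effect_config()].
#' @param eeg_effect See [eeg_effect_config()].
#' @param eeg_missing Named per-group counts of subjects without usable EEG
#'   (the acquisition loss pattern: 8/7/3).
#' @param montage See [default_montage()].
#' @param bands,periods See [default_bands()], [default_periods()].
#' @param summary Period summary mode (`"envelope"` or `"mean"`).
#' @param srate Sampling rate of simulated epochs (Hz).
#' @param epoch_window Epoch window in ms.
#' @param broadband Broadband filter range (Hz).
#' @param amp_criterion,sd_thresh,max_iter Trial rejection parameters.
#' @param baseline Baseline window (ms).
#' @param mask_sd Cross-subject outlier masking threshold (SD).
#' @param n_perm Permutations for cluster tests.
#' @param cluster_alpha,sig_alpha,mark_alpha Cluster test thresholds.
#' @param fdr_q FDR level across the 9 scalp maps.
#' @param out_dir Output directory (created if needed).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       group_sizes = c(directly_exposed = 27,
                                       indirectly_exposed = 21,
                                       non_exposed = 27),
                       n_trials = 40L,
                       covariate_config = default_covariate_config(),
                       behavior_effect = behavior_effect_config(),
                       eeg_effect = eeg_effect_config(),
                       eeg_missing = c(directly_exposed = 8,
                                       indirectly_exposed = 7,
                                       non_exposed = 3),
                       montage = default_montage(),
                       bands = default_bands(),
                       periods = default_periods(),
                       summary = "envelope",
                       srate = 250, epoch_window = c(-500, 1500),
                       broadband = c(1, 45),
                       amp_criterion = 100, sd_thresh = 5, max_iter = 8,
                       baseline = c(-250, -50), mask_sd = 5,
                       n_perm = 10000,
                       cluster_alpha = 0.05, sig_alpha = 0.05,
                       mark_alpha = 1e-4, fdr_q = 0.05,
                       out_dir = tempfile("luckydoor_run_")) {
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
    stop("`n_perm` must be >= 1")
  }
  if (any(eeg_missing < 0) || any(eeg_missing >= group_sizes[names(eeg_missing)])) {
    stop("`eeg_missing` must leave at least one EEG subject per group")
  }
  validate_montage(montage, eeg_effect$target_channels)
  structure(as.list(environment()), class = "run_config")
}

child_seed <- function(seed, k) (as.integer(seed) + 104729L * k) %% 2147483647L

model_to_list <- function(m) {
  list(outcome = m$outcome, n = m$n, n_dropped = m$n_dropped,
       adj_r2 = m$adj_r2, fstat = m$fstat, model_p = m$model_p,
       df_residual = m$df_residual, terms = m$terms)
}

map_to_list <- function(m) {
  list(t = as.list(m$t), map_p = m$map_p,
       clusters = lapply(m$clusters, function(cl) names(m$t)[cl]),
       cluster_p = m$cluster_p, mask = as.list(m$mask),
       n_perm = m$n_perm)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Executes, in order: synthetic cohort generation (covariates + task
#' behavior), behavioral metrics and robust group models, synthetic epoched
#' EEG for the subjects with usable recordings, the channel-space
#' preprocessing chain, cross-subject outlier masking, the nine
#' permutation-cluster scalp maps (3 bands x 3 periods) with FDR across
#' maps, parietal alpha cluster t-tests per period, the neurobehavioral
#' interaction model family, within-group Spearman follow-up, and
#' demographic comparisons. All intermediate tables are written under
#' `config$out_dir` together with a plain-text log and an md5 manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results plus `manifest`
#'   (`data.frame` of file names and md5 checksums).
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(...) writeLines(paste0(format(Sys.time(), "%H:%M:%S "),
                                            sprintf(...)), log_con)
  stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    logmsg("stage %s: done", name)
    out
  }

  covariates <- stage("cohort_covariates",
    generate_covariates(config$group_sizes, config$covariate_config,
                        seed = child_seed(config$seed, 1L)))
  behavior <- stage("cohort_behavior",
    generate_cohort_behavior(covariates, config$behavior_effect,
                             config$n_trials,
                             seed = child_seed(config$seed, 2L)))
  metrics <- stage("behavior_metrics", compute_behavior_metrics(behavior))
  behavior_models <- stage("behavior_models", {
    lapply(c(win_stay_expt = "win_stay_expt",
             win_stay_baseline = "win_stay_baseline",
             gain_freq_bias = "gain_freq_bias"),
           function(o) fit_group_model(metrics, covariates, o))
  })

  # subjects with usable EEG: drop the configured per-group counts
  set.seed(child_seed(config$seed, 3L))
  eeg_ids <- unlist(lapply(names(config$group_sizes), function(g) {
    ids <- covariates$subject_id[covariates$group == g]
    n_miss <- config$eeg_missing[[g]]
    if (n_miss > 0) ids <- setdiff(ids, sample(ids, n_miss))
    ids
  }))
  cov_eeg <- covariates[covariates$subject_id %in% eeg_ids, ]

  scalars <- list(); cluster_scalars <- list(); rejection_logs <- list()
  stage("eeg_simulate_preprocess", {
    set.seed(child_seed(config$seed, 4L))
    for (i in seq_len(nrow(cov_eeg))) {
      id <- cov_eeg$subject_id[i]
      sub <- behavior[behavior$subject_id == id &
                      behavior$block == "experimental" &
                      behavior$choice == "RareG", ]
      if (nrow(sub) < 2L) next
      amp <- max(0, stats::rnorm(1,
        config$eeg_effect$group_amp_mean[[cov_eeg$group[i]]],
        config$eeg_effect$amp_sd))
      ep <- simulate_subject_epochs(id, nrow(sub), amp, config$eeg_effect,
                                    config$montage, config$srate,
                                    config$epoch_window)
      pp <- preprocess_subject(ep, config$bands, config$periods,
                               config$summary, config$srate,
                               config$broadband, config$amp_criterion,
                               config$sd_thresh, config$max_iter,
                               config$baseline)
      scalars[[id]] <- pp$scalars
      cluster_scalars[[id]] <- pp$cluster
      rejection_logs[[id]] <- pp$rejection_log
    }
    invisible(NULL)
  })
  eeg_ids <- names(scalars)
  cov_eeg <- cov_eeg[cov_eeg$subject_id %in% eeg_ids, ]

  # subjects x (band, channel, period) matrix, outlier-masked
  stats_input <- stage("mask_outliers", {
    tidy <- scalars_to_tidy(scalars)
    key <- paste(tidy$band, tidy$channel, tidy$period, sep = "|")
    wide <- stats::reshape(
      data.frame(subject_id = tidy$subject_id, key = key,
                 value = tidy$value, stringsAsFactors = FALSE),
      idvar = "subject_id", timevar = "key", direction = "wide")
    rownames(wide) <- wide$subject_id
    m <- as.matrix(wide[, -1, drop = FALSE])
    colnames(m) <- sub("^value\\.", "", colnames(m))
    mask_group_outliers(m[eeg_ids, , drop = FALSE], config$mask_sd)
  })

  contrast <- exposure_contrast(cov_eeg$group)
  channels <- config$montage$channels$label
  maps <- list()
  stage("permutation_maps", {
    set.seed(child_seed(config$seed, 5L))
    for (bn in names(config$bands)) {
      for (pn in names(config$periods)) {
        cols <- paste(bn, channels, pn, sep = "|")
        x <- stats_input[, cols, drop = FALSE]
        colnames(x) <- channels
        maps[[paste(bn, pn, sep = ".")]] <-
          permutation_cluster_map(x, contrast, config$montage,
                                  n_perm = config$n_perm,
                                  cluster_alpha = config$cluster_alpha,
                                  sig_alpha = config$sig_alpha,
                                  mark_alpha = config$mark_alpha)
      }
    }
    invisible(NULL)
  })
  map_fdr <- fdr_across_maps(vapply(maps, `[[`, numeric(1), "map_p"),
                             q = config$fdr_q)

  alpha_cluster <- stage("cluster_ttests", {
    res <- list()
    for (pn in names(config$periods)) {
      cols <- paste("alpha", c("Pz", "P3", "P4", "POz"), pn, sep = "|")
      vals <- rowMeans(stats_input[, cols, drop = FALSE], na.rm = TRUE)
      res[[pn]] <- cluster_ttest(vals, contrast)
      res[[pn]]$values <- vals
    }
    res
  })

  neuro <- stage("neurobehavioral_models", {
    rows <- list()
    for (pn in names(config$periods)) {
      cl_vals <- alpha_cluster[[pn]]$values
      rows[[paste("cluster", pn)]] <- data.frame(
        subject_id = eeg_ids, electrode = "cluster", period = pn,
        value = unname(cl_vals), stringsAsFactors = FALSE)
      for (el in c("Pz", "P3", "P4", "POz")) {
        rows[[paste(el, pn)]] <- data.frame(
          subject_id = eeg_ids, electrode = el, period = pn,
          value = unname(stats_input[, paste("alpha", el, pn, sep = "|")]),
          stringsAsFactors = FALSE)
      }
    }
    neurobehavioral_family(metrics, cov_eeg, do.call(rbind, rows))
  })

  spearman <- stage("spearman_followup", {
    pz <- stats_input[, "alpha|Pz|choice"]
    ws <- metrics$win_stay_expt[match(eeg_ids, metrics$subject_id)]
    g2 <- as.character(contrast)
    list(other = within_group_spearman(pz, ws, g2, "other"),
         directly_exposed = within_group_spearman(pz, ws, g2,
                                                  "directly_exposed"))
  })

  demographics <- stage("demographics", demographic_comparison(covariates))

  stage("write_outputs", {
    od <- config$out_dir
    write_covariates_csv(covariates, file.path(od, "covariates.csv"))
    write_behavior_csv(behavior, file.path(od, "behavior.csv"))
    utils::write.csv(metrics, file.path(od, "behavior_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(scalars_to_tidy(scalars),
                     file.path(od, "band_scalars.csv"), row.names = FALSE)
    utils::write.csv(demographics, file.path(od, "demographics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(behavior_models, model_to_list),
                         file.path(od, "behavior_models.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(maps = lapply(maps, map_to_list),
                              fdr = map_fdr,
                              cluster_ttests = lapply(alpha_cluster,
                                function(x) x[c("t", "df", "p", "d", "n")]),
                              spearman = spearman),
                         file.path(od, "neural_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(neuro, file.path(od, "neurobehavioral_models.csv"),
                     row.names = FALSE)
    invisible(NULL)
  })

  files <- setdiff(list.files(config$out_dir, full.names = TRUE),
                   file.path(config$out_dir, c("run_log.txt", "manifest.csv")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  logmsg("pipeline complete: %d files", nrow(manifest))

  invisible(list(config = config, covariates = covariates,
                 behavior = behavior, metrics = metrics,
                 behavior_models = behavior_models,
                 eeg_subjects = eeg_ids, scalars = stats_input,
                 rejection_logs = rejection_logs, maps = maps,
                 map_fdr = map_fdr, alpha_cluster = alpha_cluster,
                 neurobehavioral = neuro, spearman = spearman,
                 demographics = demographics, manifest = manifest))
}
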