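# YAML persistence of a run configuration: every tunable number appears in
# the file; the montage is stored as its layout table + neighbor radius and
# the adjacency graph is recomputed on read.

#' Persist a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path Destination `.yaml` file.
#' @return The path, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ser <- unclass(config)
  ser$montage <- list(
    channels = as.list(config$montage$channels),
    neighbor_radius = config$montage$neighbor_radius)
  ser$eeg_effect <- unclass(config$eeg_effect)
  ser$eeg_effect$group_amp_mean <- as.list(config$eeg_effect$group_amp_mean)
  ser$behavior_effect$means <- as.list(config$behavior_effect$means)
  ser$group_sizes <- as.list(config$group_sizes)
  ser$eeg_missing <- as.list(config$eeg_missing)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Load a run configuration from YAML
#'
#' @param path A file written by [write_run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  montage <- make_montage(as.data.frame(raw$montage$channels),
                          raw$montage$neighbor_radius)
  eff <- raw$eeg_effect
  eeg_effect <- eeg_effect_config(
    target_channels = unlist(eff$target_channels),
    carrier_freq = eff$carrier_freq,
    group_amp_mean = unlist(eff$group_amp_mean),
    amp_sd = eff$amp_sd, target_window = unlist(eff$target_window),
    noise_sd = eff$noise_sd, noise_gamma = eff$noise_gamma,
    leakage = eff$leakage, blink_rate = eff$blink_rate,
    big_amp_rate = eff$big_amp_rate)
  behavior_effect <- list(means = unlist(raw$behavior_effect$means),
                          sd = raw$behavior_effect$sd,
                          baseline_mean = raw$behavior_effect$baseline_mean)
  cov_cfg <- lapply(raw$covariate_config, function(g) {
    g$ethnicity_levels <- unlist(g$ethnicity_levels)
    g$ethnicity_probs <- unlist(g$ethnicity_probs)
    g
  })
  run_config(
    seed = raw$seed, group_sizes = unlist(raw$group_sizes),
    n_trials = raw$n_trials, covariate_config = cov_cfg,
    behavior_effect = behavior_effect, eeg_effect = eeg_effect,
    eeg_missing = unlist(raw$eeg_missing), montage = montage,
    bands = lapply(raw$bands, unlist),
    periods = lapply(raw$periods, unlist),
    summary = raw$summary, srate = raw$srate,
    epoch_window = unlist(raw$epoch_window),
    broadband = unlist(raw$broadband),
    amp_criterion = raw$amp_criterion, sd_thresh = raw$sd_thresh,
    max_iter = raw$max_iter, baseline = unlist(raw$baseline),
    mask_sd = raw$mask_sd, n_perm = raw$n_perm,
    cluster_alpha = raw$cluster_alpha, sig_alpha = raw$sig_alpha,
    mark_alpha = raw$mark_alpha, fdr_q = raw$fdr_q,
    out_dir = raw$out_dir)
}
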