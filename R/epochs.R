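#' Construct an epoched EEG container
#'
#' @param subject_id Subject identifier.
#' @param data Numeric array `trials x channels x samples`, in microvolts.
#' @param srate Sampling rate (Hz).
#' @param window Epoch window in ms relative to chosen-door onset,
#'   `c(start, end)`; the sample count must equal
#'   `(end - start) / 1000 * srate`.
#' @param channels Channel labels (length = dim 2).
#' @param trial_info `data.frame` with one row per trial (at least a
#'   `trial` column; generator artifact flags live here too).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(subject_id, data, srate, window, channels,
                      trial_info = NULL) {
  stopifnot(length(dim(data)) == 3L)
  n_expected <- round((window[2] - window[1]) / 1000 * srate)
  if (dim(data)[3] != n_expected) {
    stop("sample count ", dim(data)[3], " != window duration x rate (",
         n_expected, ")")
  }
  if (dim(data)[2] != length(channels)) {
    stop("channel dimension does not match `channels`")
  }
  if (is.null(trial_info)) {
    trial_info <- data.frame(trial = seq_len(dim(data)[1]))
  }
  if (nrow(trial_info) != dim(data)[1]) {
    stop("`trial_info` rows must match trial dimension")
  }
  structure(list(subject_id = subject_id, data = data, srate = srate,
                 window = window, channels = channels,
                 trial_info = trial_info),
            class = "epoch_set")
}

#' Sample times of an epoch window
#'
#' @param x An `epoch_set` or `band_activity` object.
#' @return Times in ms (left edge of each sample).
#' @export
epoch_times <- function(x) {
  n <- if (inherits(x, "epoch_set")) dim(x$data)[3] else ncol(x$waveform)
  seq(x$window[1], by = 1000 / x$srate, length.out = n)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set %s: %d trials x %d channels x %d samples @ %g Hz, %d..%d ms>\n",
              x$subject_id, d[1], d[2], d[3], x$srate,
              x$window[1], x$window[2]))
  invisible(x)
}

#' EEG effect configuration for the synthetic generator
#'
#' Ground-truth parameters of the simulated group effect: a phase-locked
#' alpha-band (10 Hz carrier) burst on the posterior channels whose
#' subject-level amplitude is drawn from the subject's group distribution.
#' The defaults place the directly exposed group 1.5 uV above the other two
#' groups with a 2 uV between-subject SD, i.e. a configured standardized
#' difference (Cohen's d) of 0.75 — the magnitude of the parietal alpha
#' effect this pipeline is designed to detect. The broadband background is
#' 1/f-shaped noise of 10 uV SD; a configurable fraction of trials carry
#' frontal blink transients or are forced past the 100 uV rejection bound.
#'
#' @param target_channels Channels carrying the burst at unit weight.
#' @param carrier_freq Burst carrier frequency (Hz).
#' @param group_amp_mean Named per-group mean burst amplitudes (uV).
#' @param amp_sd Between-subject amplitude SD (uV).
#' @param target_window Burst extent in ms.
#' @param noise_sd Background noise SD (uV).
#' @param noise_gamma Background spectral exponent.
#' @param leakage Burst weight on channels adjacent to a target channel.
#' @param blink_rate Fraction of trials with a blink transient.
#' @param big_amp_rate Fraction of trials forced to exceed 100 uV.
#' @return A list of class `eeg_effect_config`.
#' @export
eeg_effect_config <- function(target_channels = c("Pz", "P3", "P4", "POz"),
                              carrier_freq = 10,
                              group_amp_mean = c(directly_exposed = 5.5,
                                                 indirectly_exposed = 4,
                                                 non_exposed = 4),
                              amp_sd = 2,
                              target_window = c(0, 1500),
                              noise_sd = 10,
                              noise_gamma = 1,
                              leakage = 0.4,
                              blink_rate = 0.05,
                              big_amp_rate = 0.02) {
  if (any(group_amp_mean < 0) || amp_sd < 0) stop("amplitudes must be >= 0")
  if (blink_rate < 0 || blink_rate > 1 || big_amp_rate < 0 || big_amp_rate > 1) {
    stop("artifact rates must be in [0, 1]")
  }
  structure(list(target_channels = target_channels,
                 carrier_freq = carrier_freq,
                 group_amp_mean = group_amp_mean, amp_sd = amp_sd,
                 target_window = target_window, noise_sd = noise_sd,
                 noise_gamma = noise_gamma, leakage = leakage,
                 blink_rate = blink_rate, big_amp_rate = big_amp_rate),
            class = "eeg_effect_config")
}

# raised-cosine-ramped plateau envelope over [a, b] ms with 100-ms ramps
burst_envelope <- function(times, a, b, ramp = 100) {
  env <- numeric(length(times))
  inside <- times >= a & times <= b
  env[inside] <- 1
  up <- inside & times < a + ramp
  dn <- inside & times > b - ramp
  env[up] <- 0.5 * (1 - cos(pi * (times[up] - a) / ramp))
  env[dn] <- 0.5 * (1 - cos(pi * (b - times[dn]) / ramp))
  env
}

blink_weights <- function(channels) {
  w <- c(Fp1 = 1, Fp2 = 1, F7 = 0.6, F8 = 0.6, F3 = 0.5, F4 = 0.5,
         Fz = 0.45, FC1 = 0.25, FC2 = 0.25)
  out <- w[channels]
  out[is.na(out)] <- 0
  unname(out)
}

#' Simulate epoched EEG for one subject
#'
#' Each epoch is 1/f background noise plus (on target channels and, at
#' reduced weight, their montage neighbors) a phase-consistent alpha burst
#' whose amplitude is the subject's ground-truth value. Blink trials add a
#' large frontal low-frequency transient; "big amplitude" trials are scaled
#' to a 150 uV peak to exercise the amplitude rejection rule. Artifact
#' trials are flagged in `trial_info`.
#'
#' @param subject_id Subject identifier.
#' @param n_trials Number of epochs.
#' @param alpha_amp Subject-level burst amplitude (uV).
#' @param effect An [eeg_effect_config()].
#' @param montage A [default_montage()] montage.
#' @param srate Sampling rate (default 250 Hz).
#' @param window Epoch window in ms (default `c(-500, 1500)`).
#' @return An `epoch_set` with `trial_info` columns `trial`, `blink`,
#'   `big_amp`, `alpha_amp`.
#' @export
simulate_subject_epochs <- function(subject_id, n_trials, alpha_amp,
                                    effect = eeg_effect_config(),
                                    montage = default_montage(),
                                    srate = 250, window = c(-500, 1500)) {
  validate_montage(montage, effect$target_channels)
  labels <- montage$channels$label
  n_ch <- length(labels)
  n_samp <- round((window[2] - window[1]) / 1000 * srate)
  times <- seq(window[1], by = 1000 / srate, length.out = n_samp)

  # spatial weights: 1 on targets, `leakage` on their neighbors
  wt <- numeric(n_ch)
  tgt <- match(effect$target_channels, labels)
  wt[tgt] <- 1
  nb <- which(colSums(montage$adjacency[tgt, , drop = FALSE]) > 0)
  wt[setdiff(nb, tgt)] <- effect$leakage

  env <- burst_envelope(times, effect$target_window[1], effect$target_window[2])
  carrier <- cos(2 * pi * effect$carrier_freq * (times - effect$target_window[1]) / 1000)
  burst <- alpha_amp * env * carrier              # phase-locked across trials

  noise <- colored_noise(n_samp, n_trials * n_ch, srate,
                         gamma = effect$noise_gamma, sd = effect$noise_sd)
  data <- array(aperm(array(noise, c(n_samp, n_trials, n_ch)), c(2, 3, 1)),
                c(n_trials, n_ch, n_samp))
  add <- outer(wt, burst)                          # channels x samples
  for (tr in seq_len(n_trials)) data[tr, , ] <- data[tr, , ] + add

  blink <- stats::runif(n_trials) < effect$blink_rate
  bw <- blink_weights(labels)
  for (tr in which(blink)) {
    center <- stats::runif(1, times[1] + 200, times[n_samp] - 200)
    pulse <- stats::runif(1, 110, 160) * exp(-(times - center)^2 / (2 * 80^2))
    data[tr, , ] <- data[tr, , ] + outer(bw, pulse)
  }

  # in-band (5 Hz) transient so the violation survives broadband filtering
  big_amp <- stats::runif(n_trials) < effect$big_amp_rate & !blink
  for (tr in which(big_amp)) {
    ch <- sample(n_ch, 1L)
    center <- stats::runif(1, times[1] + 300, times[n_samp] - 300)
    pulse <- stats::runif(1, 130, 170) *
      exp(-(times - center)^2 / (2 * 100^2)) *
      cos(2 * pi * 5 * (times - center) / 1000)
    data[tr, ch, ] <- data[tr, ch, ] + pulse
  }

  epoch_set(subject_id, data, srate, window, labels,
            data.frame(trial = seq_len(n_trials), blink = blink,
                       big_amp = big_amp, alpha_amp = alpha_amp))
}

#' Simulate epoched EEG for a cohort
#'
#' One epoch per analyzed behavioral trial (experimental-block trials on
#' which the higher-EV RareG door was chosen, matching the trials entering
#' the neural analysis). Subject burst amplitudes are drawn from the
#' subject's group distribution in `effect`.
#'
#' @param behavior Long behavior table from [generate_cohort_behavior()].
#' @param covariates Covariate table (supplies the group of each subject).
#' @param effect An [eeg_effect_config()].
#' @param montage A montage.
#' @param srate,window As in [simulate_subject_epochs()].
#' @param seed Optional integer seed.
#' @return Named list of `epoch_set`, one per subject with at least one
#'   analyzable trial.
#' @export
simulate_epochs <- function(behavior, covariates,
                            effect = eeg_effect_config(),
                            montage = default_montage(),
                            srate = 250, window = c(-500, 1500),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_montage(montage, effect$target_channels)
  out <- list()
  for (i in seq_len(nrow(covariates))) {
    id <- covariates$subject_id[i]
    g <- covariates$group[i]
    sub <- behavior[behavior$subject_id == id &
                    behavior$block == "experimental" &
                    behavior$choice == "RareG", ]
    if (nrow(sub) == 0L) next
    amp <- max(0, stats::rnorm(1, effect$group_amp_mean[[g]], effect$amp_sd))
    out[[id]] <- simulate_subject_epochs(id, nrow(sub), amp, effect,
                                         montage, srate, window)
    out[[id]]$trial_info$trial <- sub$trial
  }
  out
}
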