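#' Frequency band definitions
#'
#' Canonical EEG bands used by the analysis: theta 4-8 Hz, alpha 8-13 Hz,
#' beta 13-30 Hz. Gamma is deliberately excluded (it requires shielded
#' acquisition).
#'
#' @return Named list of `c(low, high)` Hz intervals.
#' @export
default_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Trial period definitions
#'
#' The three 500-ms post-choice analysis windows: choice presentation
#' 0-500 ms, immediate reward 500-1000 ms, cumulative reward 1000-1500 ms,
#' relative to chosen-door onset. Windows are half-open `[a, b)` so they
#' tile 0-1500 ms without gap or overlap.
#'
#' @return Named list of `c(start, end)` ms intervals.
#' @export
default_periods <- function() {
  list(choice = c(0, 500), immediate_reward = c(500, 1000),
       cumulative_reward = c(1000, 1500))
}

window_samples <- function(times, window, closed_right = FALSE) {
  if (closed_right) which(times >= window[1] & times <= window[2])
  else which(times >= window[1] & times < window[2])
}

#' Resample and broadband-filter epochs
#'
#' Polyphase resampling to the target rate followed by a zero-phase
#' 1-45 Hz FIR band-pass, removing ultraslow drift and high-frequency
#' muscle/line noise.
#'
#' @param epochs An `epoch_set`.
#' @param target_rate Target sampling rate (default 250 Hz).
#' @param band Broadband pass-band in Hz (default `c(1, 45)`).
#' @return A filtered `epoch_set` at `target_rate`.
#' @export
resample_and_filter <- function(epochs, target_rate = 250, band = c(1, 45)) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (epochs$srate < 2 * band[2]) {
    stop("input rate ", epochs$srate, " Hz is below twice the upper band edge")
  }
  d <- dim(epochs$data)
  if (epochs$srate != target_rate) {
    frac <- frac_ratio(target_rate, epochs$srate)
    n_new <- round(d[3] * target_rate / epochs$srate)
    new <- array(0, c(d[1], d[2], n_new))
    for (tr in seq_len(d[1])) {
      for (ch in seq_len(d[2])) {
        y <- signal::resample(epochs$data[tr, ch, ], frac[1], frac[2])
        new[tr, ch, ] <- y[seq_len(n_new)]
      }
    }
    epochs$data <- new
    epochs$srate <- target_rate
  }
  filter_epochs(epochs, band)
}

frac_ratio <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

# zero-phase FIR band-pass applied to all trials x channels at once
filter_epochs <- function(epochs, band) {
  d <- dim(epochs$data)
  kernel <- design_fir(band[1], band[2], epochs$srate)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  flat <- filter_zero_phase(flat, kernel)
  epochs$data <- aperm(array(flat, c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Reject artifact trials
#'
#' Two rules, applied in order: (a) amplitude criterion — any trial whose
#' absolute value exceeds `amp_criterion` (default 100 uV) on any channel is
#' removed; (b) iterative outlier criterion — a per-trial deviation summary
#' (default: maximum absolute amplitude) is computed over the remaining
#' trials and trials deviating more than `sd_thresh` SDs from the mean of
#' the remaining distribution are removed, recomputing mean and SD each
#' pass, until no trial is removed or `max_iter` passes (default 8).
#'
#' @param epochs An `epoch_set` (>= 2 trials).
#' @param amp_criterion Absolute amplitude bound in uV.
#' @param sd_thresh SD multiple for the iterative rule.
#' @param max_iter Maximum iterations of the iterative rule.
#' @param stat Per-trial deviation summary: `"maxabs"` or `"var"`.
#' @return List with `epochs` (retained trials) and `log` (`data.frame`
#'   `trial`, `reason`, `iteration`); errors if every trial is rejected.
#' @export
reject_trials <- function(epochs, amp_criterion = 100, sd_thresh = 5,
                          max_iter = 8, stat = c("maxabs", "var")) {
  stopifnot(inherits(epochs, "epoch_set"))
  stat <- match.arg(stat)
  n <- dim(epochs$data)[1]
  if (n < 2L) stop("need >= 2 trials")
  peak <- apply(abs(epochs$data), 1, max)
  log <- data.frame(trial = integer(), reason = character(),
                    iteration = integer(), stringsAsFactors = FALSE)
  bad_amp <- which(peak > amp_criterion)
  if (length(bad_amp)) {
    log <- rbind(log, data.frame(trial = epochs$trial_info$trial[bad_amp],
                                 reason = "amplitude", iteration = 0L))
  }
  keep <- setdiff(seq_len(n), bad_amp)
  dev <- switch(stat,
    maxabs = peak,
    var = apply(epochs$data, 1, stats::var)
  )
  for (it in seq_len(max_iter)) {
    if (length(keep) < 3L) break
    m <- mean(dev[keep]); s <- stats::sd(dev[keep])
    if (is.na(s) || s == 0) break
    bad <- keep[abs(dev[keep] - m) > sd_thresh * s]
    if (!length(bad)) break
    log <- rbind(log, data.frame(trial = epochs$trial_info$trial[bad],
                                 reason = "sd_outlier", iteration = it))
    keep <- setdiff(keep, bad)
  }
  if (!length(keep)) {
    stop("all trials rejected for subject ", epochs$subject_id)
  }
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$trial_info <- epochs$trial_info[keep, , drop = FALSE]
  rownames(epochs$trial_info) <- NULL
  list(epochs = epochs, log = log)
}

#' Band-filter trials and average into evoked band activity
#'
#' Zero-phase FIR band-pass of every retained trial followed by the
#' arithmetic mean across trials per channel and sample: the evoked
#' (phase-locked) band-limited waveform in uV.
#'
#' @param epochs A cleaned `epoch_set`.
#' @param band `c(low, high)` Hz (must lie within the 1-45 Hz broadband
#'   envelope), or a name from [default_bands()].
#' @param band_name Optional label stored in the result.
#' @return An object of class `band_activity`: `subject_id`, `band`,
#'   `band_range`, `waveform` (channels x samples matrix), `srate`,
#'   `window`, `channels`, `n_trials`.
#' @export
band_decompose_and_average <- function(epochs, band, band_name = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.character(band)) {
    band_name <- band
    band <- default_bands()[[band]]
    if (is.null(band)) stop("unknown band name")
  }
  if (band[1] < 1 || band[2] > 45) {
    stop("band must lie within the 1-45 Hz broadband envelope")
  }
  filtered <- filter_epochs(epochs, band)
  wf <- apply(filtered$data, c(2, 3), mean)
  rownames(wf) <- epochs$channels
  structure(list(subject_id = epochs$subject_id,
                 band = if (is.null(band_name)) paste(band, collapse = "-")
                        else band_name,
                 band_range = band, waveform = wf, srate = epochs$srate,
                 window = epochs$window, channels = epochs$channels,
                 n_trials = dim(epochs$data)[1]),
            class = "band_activity")
}

#' Baseline-correct a band-activity waveform
#'
#' Subtracts, per channel, the mean over the pre-choice fixation window
#' (default -250 to -50 ms) from the whole waveform.
#'
#' @param activity A `band_activity` object.
#' @param window Baseline window in ms (closed interval).
#' @return The corrected `band_activity`.
#' @export
baseline_correct <- function(activity, window = c(-250, -50)) {
  stopifnot(inherits(activity, "band_activity"))
  times <- epoch_times(activity)
  idx <- window_samples(times, window, closed_right = TRUE)
  if (!length(idx) || window[1] < activity$window[1] ||
      window[2] > activity$window[2]) {
    stop("baseline window outside the epoch")
  }
  mu <- rowMeans(activity$waveform[, idx, drop = FALSE])
  activity$waveform <- activity$waveform - mu
  activity$baseline_window <- window
  activity
}

#' Summarize band activity into per-period scalars
#'
#' For each channel and trial period, reduces the trial-averaged band
#' waveform to one value in uV. The default summary is the mean Hilbert
#' envelope of the evoked waveform over the period, referenced to the mean
#' envelope over the baseline window — a magnitude measure that carries
#' oscillatory amplitude differences. `summary = "mean"` instead takes the
#' signed time-mean of the waveform (near zero for narrowband oscillations
#' spanning whole cycles). The parietal cluster scalar is the mean of the
#' four cluster channel scalars.
#'
#' @param activity A baseline-corrected `band_activity`.
#' @param periods Named list of ms windows (default [default_periods()]).
#' @param summary `"envelope"` (default) or `"mean"`.
#' @param baseline Baseline window for the envelope reference.
#' @param cluster_channels Channels averaged into the cluster scalar.
#' @return List with `scalars` (channels x periods matrix, uV) and
#'   `cluster` (named vector, one value per period).
#' @export
summarize_periods <- function(activity, periods = default_periods(),
                              summary = c("envelope", "mean"),
                              baseline = c(-250, -50),
                              cluster_channels = c("Pz", "P3", "P4", "POz")) {
  stopifnot(inherits(activity, "band_activity"))
  summary <- match.arg(summary)
  times <- epoch_times(activity)
  missing_ch <- setdiff(cluster_channels, activity$channels)
  if (length(missing_ch)) {
    stop("missing cluster channel(s): ", paste(missing_ch, collapse = ", "))
  }
  base_mat <- if (summary == "envelope") {
    env <- t(analytic_envelope(t(activity$waveform)))
    ref <- rowMeans(env[, window_samples(times, baseline, TRUE), drop = FALSE])
    env - ref
  } else {
    activity$waveform
  }
  scal <- vapply(periods, function(w) {
    rowMeans(base_mat[, window_samples(times, w), drop = FALSE])
  }, numeric(nrow(base_mat)))
  rownames(scal) <- activity$channels
  cluster <- colMeans(scal[cluster_channels, , drop = FALSE])
  list(scalars = scal, cluster = cluster)
}

#' Mask cross-subject outliers with NaN
#'
#' For each column of a subjects-by-measures matrix, values more than
#' `sd_thresh` SDs from the cross-subject mean are set to `NaN`; downstream
#' statistics exclude them. Nothing is masked when a column's SD is zero.
#'
#' @param x Numeric matrix (subjects in rows).
#' @param sd_thresh SD multiple (default 5).
#' @return `x` with outliers replaced by `NaN`.
#' @export
mask_group_outliers <- function(x, sd_thresh = 5) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need >= 3 subjects")
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    m <- mean(v, na.rm = TRUE); s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    x[which(abs(v - m) > sd_thresh * s), j] <- NaN
  }
  x
}

#' Run the channel-space preprocessing chain for one subject
#'
#' Resample/broadband filter, reject artifact trials, then for each band:
#' band-filter, trial-average, baseline-correct and summarize the three
#' trial periods.
#'
#' @param epochs An `epoch_set`.
#' @param bands Named list of band intervals (default [default_bands()]).
#' @param periods Named list of period windows.
#' @param summary Period summary mode, see [summarize_periods()].
#' @param target_rate,broadband,amp_criterion,sd_thresh,max_iter Chain
#'   parameters; see the stage functions.
#' @param baseline Baseline window in ms.
#' @return List with `scalars` (named list per band of channels x periods
#'   matrices), `cluster` (per band named period vectors), `activity`
#'   (per band `band_activity`), `rejection_log`, `n_trials_retained`.
#' @export
preprocess_subject <- function(epochs, bands = default_bands(),
                               periods = default_periods(),
                               summary = "envelope",
                               target_rate = 250, broadband = c(1, 45),
                               amp_criterion = 100, sd_thresh = 5,
                               max_iter = 8, baseline = c(-250, -50)) {
  ep <- resample_and_filter(epochs, target_rate, broadband)
  rej <- reject_trials(ep, amp_criterion, sd_thresh, max_iter)
  out <- list(scalars = list(), cluster = list(), activity = list(),
              rejection_log = rej$log,
              n_trials_retained = dim(rej$epochs$data)[1])
  for (bn in names(bands)) {
    act <- band_decompose_and_average(rej$epochs, bands[[bn]], bn)
    act <- baseline_correct(act, baseline)
    sm <- summarize_periods(act, periods, summary = summary,
                            baseline = baseline)
    out$scalars[[bn]] <- sm$scalars
    out$cluster[[bn]] <- sm$cluster
    out$activity[[bn]] <- act
  }
  out
}
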