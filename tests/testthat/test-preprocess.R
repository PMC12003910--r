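test_that("resampling halves the sample count from 500 to 250 Hz", {
  set.seed(1)
  mon <- mini_montage()
  n_samp <- 1000  # 2 s at 500 Hz
  data <- array(rnorm(4 * 8 * n_samp, sd = 3), c(4, 8, n_samp))
  ep <- epoch_set("s", data, 500, c(-500, 1500), mon$channels$label)
  out <- resample_and_filter(ep, target_rate = 250)
  expect_equal(dim(out$data)[3], 500)
  expect_equal(out$srate, 250)
  expect_error(resample_and_filter(ep, target_rate = 250, band = c(1, 300)),
               "Nyquist|twice")
})

test_that("the broadband filter passes 10 Hz and suppresses slow drift", {
  srate <- 250
  t <- seq(1 / srate, 12, by = 1 / srate)
  k <- design_fir(1, 45, srate)
  mid <- seq(2 * srate, 10 * srate)   # central region clear of edges
  s10 <- sin(2 * pi * 10 * t)
  g10 <- sqrt(mean(filter_zero_phase(s10, k)[mid]^2)) /
         sqrt(mean(s10[mid]^2))
  expect_lt(abs(g10 - 1), 0.05)
  s02 <- sin(2 * pi * 0.2 * t)
  g02 <- sqrt(mean(filter_zero_phase(s02, k)[mid]^2)) /
         sqrt(mean(s02[mid]^2))
  expect_lte(20 * log10(g02), -20)
})

test_that("filtering is zero-phase: burst peak latency preserved within one sample", {
  srate <- 250
  t <- seq(1 / srate, 8, by = 1 / srate)
  sig <- exp(-(t - 4)^2 / (2 * 0.3^2)) * sin(2 * pi * 10 * (t - 4))
  out <- filter_zero_phase(sig, design_fir(8, 13, srate))
  expect_lte(abs(which.max(abs(out)) - which.max(abs(sig))), 1)
})

test_that("amplitude rule removes exactly the violating trials", {
  set.seed(2)
  ep <- clean_epochs(n_trials = 10, sd = 5)     # peaks well under 100 uV
  res <- reject_trials(ep)
  expect_equal(nrow(res$log), 0L)
  expect_equal(dim(res$epochs$data)[1], 10L)
  # force one trial to a 150 uV peak
  ep$data[4, 2, 100] <- 150
  res <- reject_trials(ep)
  expect_equal(res$log$trial, 4L)
  expect_equal(res$log$reason, "amplitude")
  expect_equal(dim(res$epochs$data)[1], 9L)
})

test_that("the iterative 5 SD rule catches a high-variance trial within 8 passes", {
  set.seed(3)
  ep <- clean_epochs(n_trials = 30, sd = 4)
  ep$data[17, , ] <- ep$data[17, , ] * sqrt(10)   # 10x variance artifact
  # disable the amplitude rule so only the SD rule can act
  res <- reject_trials(ep, amp_criterion = Inf)
  expect_true(17L %in% res$log$trial)
  expect_true(all(res$log$reason == "sd_outlier"))
  expect_lte(max(res$log$iteration), 8L)
})

test_that("rejection logs account for every dropped trial exactly once", {
  set.seed(4)
  ep <- clean_epochs(n_trials = 20, sd = 5)
  ep$data[3, 1, 50] <- 120
  ep$data[9, 2, 10] <- -140
  res <- reject_trials(ep)
  dropped <- setdiff(1:20, res$epochs$trial_info$trial)
  expect_setequal(res$log$trial, dropped)
  expect_equal(anyDuplicated(res$log$trial), 0L)
  expect_equal(dim(res$epochs$data)[1] + nrow(res$log), 20L)
})

test_that("all-rejected subjects raise an explicit error", {
  set.seed(5)
  ep <- clean_epochs(n_trials = 3, sd = 5)
  ep$data <- ep$data + 200
  expect_error(reject_trials(ep), "all trials rejected")
})

test_that("trial averaging of identical trials equals one filtered trial", {
  set.seed(6)
  mon <- mini_montage()
  one <- matrix(rnorm(8 * 500, sd = 5), 8, 500)
  data <- array(0, c(4, 8, 500))
  for (i in 1:4) data[i, , ] <- one
  ep <- epoch_set("s", data, 250, c(-500, 1500), mon$channels$label)
  avg <- band_decompose_and_average(ep, "alpha")
  single <- band_decompose_and_average(
    epoch_set("s", data[1, , , drop = FALSE], 250, c(-500, 1500),
              mon$channels$label), "alpha")
  expect_equal(avg$waveform, single$waveform, tolerance = 1e-10)
})

test_that("phase-randomized oscillations cancel in the trial average while phase-locked bursts survive", {
  mon <- mini_montage()
  srate <- 250
  times <- seq(-500, by = 1000 / srate, length.out = 500) / 1000
  n_trials <- 100
  set.seed(7)
  rand <- array(0, c(n_trials, 8, 500))
  lock <- array(0, c(n_trials, 8, 500))
  for (i in seq_len(n_trials)) {
    phi <- runif(1, 0, 2 * pi)
    rand[i, , ] <- matrix(10 * sin(2 * pi * 10 * times + phi), 8, 500,
                          byrow = TRUE)
    lock[i, , ] <- matrix(10 * sin(2 * pi * 10 * times), 8, 500,
                          byrow = TRUE)
  }
  ep_r <- epoch_set("r", rand, srate, c(-500, 1500), mon$channels$label)
  ep_l <- epoch_set("l", lock, srate, c(-500, 1500), mon$channels$label)
  avg_r <- band_decompose_and_average(ep_r, "alpha")
  avg_l <- band_decompose_and_average(ep_l, "alpha")
  mid <- 100:400
  rms_r <- sqrt(mean(avg_r$waveform[1, mid]^2))
  rms_l <- sqrt(mean(avg_l$waveform[1, mid]^2))
  single_rms <- 10 / sqrt(2)
  expect_lt(rms_r, 0.25 * single_rms)          # induced-only: cancels
  expect_gt(rms_l, 0.95 * single_rms)          # evoked: retained
})

test_that("baseline correction zeroes the fixation window and is shift-invariant", {
  mon <- mini_montage()
  set.seed(8)
  wf <- matrix(rnorm(8 * 500, sd = 2), 8, 500)
  act <- structure(list(subject_id = "s", band = "alpha",
                        band_range = c(8, 13), waveform = wf, srate = 250,
                        window = c(-500, 1500),
                        channels = mon$channels$label, n_trials = 1),
                   class = "band_activity")
  corr <- baseline_correct(act)
  times <- epoch_times(corr)
  base_idx <- times >= -250 & times <= -50
  expect_lt(max(abs(rowMeans(corr$waveform[, base_idx]))), 1e-9)
  # constant signal maps to zero
  const <- act; const$waveform <- matrix(5, 8, 500)
  expect_equal(max(abs(baseline_correct(const)$waveform)), 0)
  # adding any offset leaves the corrected waveform unchanged
  shifted <- act; shifted$waveform <- act$waveform + 11.3
  expect_equal(baseline_correct(shifted)$waveform,
               corr$waveform, tolerance = 1e-10)
  expect_error(baseline_correct(act, c(-900, -600)), "outside")
})

test_that("period summaries reduce indicator waveforms correctly and the cluster scalar is the channel mean", {
  mon <- mini_montage()
  times <- seq(-500, by = 4, length.out = 500)
  wf <- matrix(0, 8, 500)
  wf[, times >= 0 & times < 500] <- 1     # 1 uV during the choice period only
  act <- structure(list(subject_id = "s", band = "alpha",
                        band_range = c(8, 13), waveform = wf, srate = 250,
                        window = c(-500, 1500),
                        channels = mon$channels$label, n_trials = 1),
                   class = "band_activity")
  sm <- summarize_periods(act, summary = "mean")
  expect_equal(unname(sm$scalars[, "choice"]), rep(1, 8))
  expect_equal(unname(sm$scalars[, "immediate_reward"]), rep(0, 8))
  expect_equal(unname(sm$scalars[, "cumulative_reward"]), rep(0, 8))
  expect_equal(sm$cluster,
               colMeans(sm$scalars[c("Pz", "P3", "P4", "POz"), ]))
  # flat zero waveform: all scalars zero in both summary modes
  act$waveform <- matrix(0, 8, 500)
  expect_true(all(summarize_periods(act, summary = "mean")$scalars == 0))
  expect_true(all(summarize_periods(act, summary = "envelope")$scalars == 0))
  expect_error(summarize_periods(act, cluster_channels = c("Pz", "CPz")),
               "CPz")
})

test_that("the three trial periods tile 0-1500 ms without gap or overlap", {
  times <- seq(-500, by = 4, length.out = 500)
  post <- which(times >= 0 & times < 1500)
  assigned <- unlist(lapply(default_periods(), function(w) {
    luckydoor:::window_samples(times, w)
  }))
  expect_setequal(assigned, post)
  expect_equal(anyDuplicated(assigned), 0L)
})

test_that("cross-subject outlier masking flags only genuine outliers", {
  set.seed(9)
  x <- matrix(rnorm(50 * 6), 50, 6)
  expect_equal(sum(is.nan(mask_group_outliers(x))), 0L)  # ~0 expected at 5 SD
  x[7, 3] <- 10 * sd(x[, 3])
  masked <- mask_group_outliers(x)
  expect_true(is.nan(masked[7, 3]))
  expect_equal(sum(is.nan(masked)), 1L)
  # degenerate zero-SD column: nothing masked
  x2 <- matrix(1, 10, 2)
  expect_false(any(is.nan(mask_group_outliers(x2))))
  expect_error(mask_group_outliers(x[1:2, ]), "3 subjects")
})

test_that("the preprocessing chain is deterministic given its input", {
  set.seed(10)
  ep <- clean_epochs(n_trials = 6, sd = 5)
  a <- preprocess_subject(ep)
  b <- preprocess_subject(ep)
  expect_identical(a$scalars, b$scalars)
  expect_identical(a$cluster, b$cluster)
})
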