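# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (loops, enumeration) and never call the
# package functions they are used to check.

# Brute-force Win-Stay: enumerate every (win, next-choice) pair with a loop.
oracle_win_stay <- function(choice, outcome, target = "RareG") {
  num <- 0L; den <- 0L
  n <- length(choice)
  if (n >= 2L) {
    for (t in seq_len(n - 1L)) {
      if (choice[t] == target && outcome[t] > 0) {
        den <- den + 1L
        if (choice[t + 1L] == target) num <- num + 1L
      }
    }
  }
  if (den == 0L) NA_real_ else num / den
}

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  reject <- logical(m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, ps[i] * m / i)
    adj[o[i]] <- prev
  }
  list(adjusted = adj, reject = reject)
}

# Random choice/outcome sequence; outcome sign carries the win information.
random_sequence <- function(len) {
  choice <- sample(c("RareG", "RareL"), len, replace = TRUE)
  outcome <- sample(c(60, -20, 20, -60), len, replace = TRUE)
  list(choice = choice, outcome = outcome)
}

# All choice x win-status sequences of a given length (4 symbols/trial).
enumerate_sequences <- function(len) {
  symbols <- list(c("RareG", 60), c("RareG", -20), c("RareL", 20),
                  c("RareL", -60))
  grid <- do.call(expand.grid, rep(list(1:4), len))
  lapply(seq_len(nrow(grid)), function(i) {
    sel <- unlist(grid[i, ])
    list(choice = vapply(symbols[sel], `[`, character(1), 1),
         outcome = as.numeric(vapply(symbols[sel], `[`, character(1), 2)))
  })
}

# Compact montage (8 channels, includes the parietal cluster) for fast
# preprocessing tests.
mini_montage <- function() {
  ch <- data.frame(
    label = c("Fz", "Cz", "P3", "Pz", "P4", "POz", "O1", "O2"),
    x = c(0, 0, -0.45, 0, 0.45, 0, -0.31, 0.31),
    y = c(0.52, 0, -0.55, -0.52, -0.55, -0.78, -0.95, -0.95))
  make_montage(ch, neighbor_radius = 0.65)
}

# Gaussian epochs with controllable peak amplitude, no structured signal.
clean_epochs <- function(n_trials = 8, montage = mini_montage(),
                         srate = 250, window = c(-500, 1500), sd = 5) {
  n_ch <- nrow(montage$channels)
  n_samp <- round((window[2] - window[1]) / 1000 * srate)
  data <- array(stats::rnorm(n_trials * n_ch * n_samp, sd = sd),
                c(n_trials, n_ch, n_samp))
  # keep honestly below the 100 uV bound for "clean" fixtures
  data <- pmin(pmax(data, -8 * sd), 8 * sd)
  epoch_set("test", data, srate, window, montage$channels$label)
}

expect_rate_within <- function(rate, nominal, n_rep, n_se = 3) {
  se <- sqrt(nominal * (1 - nominal) / n_rep)
  expect_gte(rate, nominal - n_se * se)
  expect_lte(rate, nominal + n_se * se)
}
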