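#' Define a reward deck
#'
#' A deck (door) in the two-choice probabilistic reward task delivers a gain
#' of `gain` coins with probability `p_gain` and a loss of `loss` coins
#' otherwise. The two canonical decks are `RareG` (rare gains, frequent small
#' losses) and `RareL` (rare losses, frequent small gains).
#'
#' @param label One of `"RareG"`, `"RareL"`.
#' @param p_gain Probability of a gain on any trial, in `[0, 1]`.
#' @param gain Coins won on a gain trial (positive integer).
#' @param loss Coins lost on a loss trial (negative integer).
#' @return An object of class `deck_spec`.
#' @examples
#' deck_spec("RareG", p_gain = 0.3, gain = 60, loss = -20)
#' @export
deck_spec <- function(label, p_gain, gain, loss) {
  label <- match.arg(label, c("RareG", "RareL"))
  if (!is.numeric(p_gain) || length(p_gain) != 1L || is.na(p_gain) ||
      p_gain < 0 || p_gain > 1) {
    stop("`p_gain` must be a single probability in [0, 1], got ", p_gain)
  }
  if (!is.numeric(gain) || length(gain) != 1L || gain <= 0) {
    stop("`gain` must be a single positive number of coins")
  }
  if (!is.numeric(loss) || length(loss) != 1L || loss >= 0) {
    stop("`loss` must be a single negative number of coins")
  }
  structure(
    list(label = label, p_gain = p_gain, gain = gain, loss = loss),
    class = "deck_spec"
  )
}

#' @export
print.deck_spec <- function(x, ...) {
  cat(sprintf("<deck %s> P(gain)=%.2f: %+d coins; P(loss)=%.2f: %+d coins\n",
              x$label, x$p_gain, x$gain, 1 - x$p_gain, x$loss))
  invisible(x)
}

#' Expected cumulative value of a deck
#'
#' The probability-weighted mean payoff of a deck, accumulated over a playing
#' horizon. The task's printed EV labels (+40 / -40 / 0 coins) correspond to
#' a 10-trial horizon of the per-trial expectation, which is the default.
#'
#' @param deck A [deck_spec()].
#' @param horizon Number of trials over which to accumulate (default 10).
#' @return Expected cumulative coins (numeric scalar).
#' @examples
#' deck_ev(deck_spec("RareG", 0.3, 60, -20))   # +40
#' deck_ev(deck_spec("RareL", 0.7, 20, -60))   # -40
#' @export
deck_ev <- function(deck, horizon = 10) {
  stopifnot(inherits(deck, "deck_spec"))
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1) {
    stop("`horizon` must be a single count >= 1")
  }
  horizon * (deck$p_gain * deck$gain + (1 - deck$p_gain) * deck$loss)
}

#' Sample one trial outcome from a deck
#'
#' Draws the Bernoulli payoff: `gain` coins with probability `p_gain`,
#' otherwise `loss` coins. Uses R's global RNG stream, so outcomes are
#' reproducible under `set.seed()`.
#'
#' @param deck A [deck_spec()].
#' @param n Number of outcomes to draw (default 1).
#' @return Integer vector of signed coin outcomes.
#' @export
sample_outcome <- function(deck, n = 1L) {
  stopifnot(inherits(deck, "deck_spec"))
  ifelse(stats::runif(n) < deck$p_gain, deck$gain, deck$loss)
}

#' Construct a task block
#'
#' The experimental block opposes a higher-EV rare-gain door (RareG:
#' P = 0.3 gain +60, P = 0.7 loss -20; EV label +40) to a lower-EV rare-loss
#' door (RareL: P = 0.7 gain +20, P = 0.3 loss -60; EV label -40). In the
#' baseline block both doors have EV 0 (RareG: 0.3/+70 vs 0.7/-30; RareL:
#' 0.7/+30 vs 0.3/-70), isolating gain-frequency bias from EV-based choice.
#' Each block has 40 trials.
#'
#' @param block_kind `"experimental"` or `"baseline"`.
#' @param n_trials Trials per block (default 40).
#' @return An object of class `block_spec` with elements `block_kind`,
#'   `decks` (named list `RareG`, `RareL`) and `n_trials`.
#' @export
make_block <- function(block_kind = c("experimental", "baseline"),
                       n_trials = 40L) {
  block_kind <- match.arg(block_kind)
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1) {
    stop("`n_trials` must be >= 1")
  }
  decks <- if (block_kind == "experimental") {
    list(
      RareG = deck_spec("RareG", p_gain = 0.3, gain = 60, loss = -20),
      RareL = deck_spec("RareL", p_gain = 0.7, gain = 20, loss = -60)
    )
  } else {
    list(
      RareG = deck_spec("RareG", p_gain = 0.3, gain = 70, loss = -30),
      RareL = deck_spec("RareL", p_gain = 0.7, gain = 30, loss = -70)
    )
  }
  structure(
    list(block_kind = block_kind, decks = decks, n_trials = as.integer(n_trials)),
    class = "block_spec"
  )
}

#' @export
print.block_spec <- function(x, ...) {
  cat(sprintf("<%s block, %d trials>\n", x$block_kind, x$n_trials))
  print(x$decks$RareG); print(x$decks$RareL)
  invisible(x)
}

#' Assemble a trial table from choices and outcomes
#'
#' Builds the per-trial record used throughout the behavioral analysis:
#' 1-based trial index, chosen door, signed coin outcome, win flag
#' (outcome > 0) and running cumulative total.
#'
#' @param choice Character vector of `"RareG"` / `"RareL"` choices.
#' @param outcome Signed coin outcomes, same length.
#' @return A `data.frame` with columns `trial`, `choice`, `outcome`,
#'   `is_win`, `cumulative`.
#' @export
trial_table <- function(choice, outcome) {
  if (length(choice) != length(outcome)) {
    stop("`choice` and `outcome` must have equal length")
  }
  if (!all(choice %in% c("RareG", "RareL"))) {
    stop("`choice` values must be 'RareG' or 'RareL'")
  }
  data.frame(
    trial = seq_along(choice),
    choice = as.character(choice),
    outcome = as.numeric(outcome),
    is_win = as.numeric(outcome) > 0,
    cumulative = cumsum(as.numeric(outcome)),
    stringsAsFactors = FALSE
  )
}

#' Validate a trial table
#'
#' Checks ordering, uniqueness of trial indices and internal consistency of
#' the win flag and cumulative total.
#'
#' @param trials A trial `data.frame` as produced by [trial_table()].
#' @return Invisibly `TRUE`; errors otherwise.
#' @export
validate_trials <- function(trials) {
  req <- c("trial", "choice", "outcome")
  if (!all(req %in% names(trials))) {
    stop("trial table must have columns: ", paste(req, collapse = ", "))
  }
  idx <- trials$trial
  if (anyDuplicated(idx) || is.unsorted(idx, strictly = TRUE)) {
    stop("trial indices must be strictly increasing and unique")
  }
  if ("is_win" %in% names(trials) &&
      !identical(trials$is_win, trials$outcome > 0)) {
    stop("`is_win` inconsistent with `outcome > 0`")
  }
  if ("cumulative" %in% names(trials) && nrow(trials) > 0L &&
      max(abs(trials$cumulative - cumsum(trials$outcome))) > 1e-9) {
    stop("`cumulative` is not the running sum of `outcome`")
  }
  invisible(TRUE)
}
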