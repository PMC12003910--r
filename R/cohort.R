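#' Default covariate effect configuration
#'
#' Group-wise generating parameters for the synthetic covariate table. The
#' default directions follow the study design this package emulates: the
#' exposed groups carry elevated anxiety (GAD7), depression (PHQ9) and
#' recent-trauma endorsement, groups are age- and gender-matched, and the
#' exposed groups skew more Caucasian while controls include more Asian
#' participants. Magnitudes are configuration, not empirical claims.
#'
#' @return A nested list of per-group means/SDs/rates keyed by
#'   `directly_exposed`, `indirectly_exposed`, `non_exposed`.
#' @export
default_covariate_config <- function() {
  base <- list(
    age_mean = 24.5, age_sd = 6, ses_mean = 4.5, ses_sd = 1.8,
    p_female = 0.84,
    ethnicity_levels = c("Caucasian", "Asian", "MoreThanOne", "Other")
  )
  list(
    directly_exposed = c(base, list(
      gad7_mean = 10, gad7_sd = 6, phq9_mean = 9, phq9_sd = 6,
      p_trauma = 0.67, ethnicity_probs = c(0.78, 0.02, 0.15, 0.05)
    )),
    indirectly_exposed = c(base, list(
      gad7_mean = 9.5, gad7_sd = 5, phq9_mean = 11, phq9_sd = 6,
      p_trauma = 0.15, ethnicity_probs = c(0.57, 0.10, 0.24, 0.09)
    )),
    non_exposed = c(base, list(
      gad7_mean = 3, gad7_sd = 2.5, phq9_mean = 3, phq9_sd = 2.5,
      p_trauma = 0.0, ethnicity_probs = c(0.30, 0.41, 0.22, 0.07)
    ))
  )
}

#' Null (no group difference) covariate configuration
#'
#' All three groups share identical generating distributions; useful for
#' type-I calibration of downstream models.
#' @return Same structure as [default_covariate_config()].
#' @export
null_covariate_config <- function() {
  cfg <- default_covariate_config()
  pooled <- cfg$indirectly_exposed
  pooled$gad7_mean <- 6; pooled$phq9_mean <- 6
  pooled$p_trauma <- 0.2
  pooled$ethnicity_probs <- c(0.5, 0.2, 0.2, 0.1)
  list(directly_exposed = pooled, indirectly_exposed = pooled,
       non_exposed = pooled)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic covariate table
#'
#' Draws per-subject demographics and mental-health scores for a three-group
#' cohort (directly exposed / indirectly exposed / non-exposed; default sizes
#' 27/21/27). Continuous scores are truncated to instrument ranges: GAD7
#' 0-21, PHQ9 0-27, SES family-affluence 0-9.
#'
#' @param group_sizes Integer vector of length 3, named or in the order
#'   directly_exposed, indirectly_exposed, non_exposed.
#' @param effect_config Per-group generating parameters, see
#'   [default_covariate_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return A `data.frame` with columns `subject_id`, `group`, `age`,
#'   `gender`, `ethnicity`, `ses`, `gad7`, `phq9`, `recent_trauma`.
#' @export
generate_covariates <- function(group_sizes = c(directly_exposed = 27,
                                                indirectly_exposed = 21,
                                                non_exposed = 27),
                                effect_config = default_covariate_config(),
                                seed = NULL) {
  if (length(group_sizes) != 3L || any(group_sizes < 1)) {
    stop("`group_sizes` must be three counts >= 1")
  }
  groups <- c("directly_exposed", "indirectly_exposed", "non_exposed")
  if (is.null(names(group_sizes))) names(group_sizes) <- groups
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(groups, function(g) {
    n <- group_sizes[[g]]
    cfg <- effect_config[[g]]
    if (any(c(cfg$age_sd, cfg$gad7_sd, cfg$phq9_sd, cfg$ses_sd) < 0)) {
      stop("negative SD in effect_config for group ", g)
    }
    data.frame(
      group = g,
      age = round(rtrunc_norm(n, cfg$age_mean, cfg$age_sd, 18, 60)),
      gender = sample(c("female", "male"), n, replace = TRUE,
                      prob = c(cfg$p_female, 1 - cfg$p_female)),
      ethnicity = sample(cfg$ethnicity_levels, n, replace = TRUE,
                         prob = cfg$ethnicity_probs),
      ses = round(rtrunc_norm(n, cfg$ses_mean, cfg$ses_sd, 0, 9)),
      gad7 = round(rtrunc_norm(n, cfg$gad7_mean, cfg$gad7_sd, 0, 21)),
      phq9 = round(rtrunc_norm(n, cfg$phq9_mean, cfg$phq9_sd, 0, 27)),
      recent_trauma = stats::runif(n) < cfg$p_trauma,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(out))), out)
  out$subject_id <- as.character(out$subject_id)
  rownames(out) <- NULL
  out
}

#' Agent parameters for behavior simulation
#'
#' Two simple generative families stand in for participant behavior:
#' `wsls` (win-stay/lose-shift with tunable stay and shift probabilities)
#' and `delta_rule` (incremental value learning with softmax choice and a
#' multiplicative loss-aversion weight on negative outcomes).
#'
#' @param agent_kind `"wsls"` or `"delta_rule"`.
#' @param p_stay_win_rareG Probability of repeating a RareG choice after a
#'   RareG win (wsls).
#' @param p_stay_win_rarel Probability of repeating a RareL choice after a
#'   RareL win (wsls); the stay/shift rule after frequent-gain wins is not
#'   constrained by the task design, so it defaults to indifference.
#' @param p_shift_loss Probability of switching door after any loss (wsls).
#' @param learning_rate Delta-rule step size in `[0, 1]`.
#' @param inverse_temperature Softmax choice sharpness, `>= 0`.
#' @param loss_aversion_weight Multiplier applied to losses before the value
#'   update, `>= 0`.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(agent_kind = c("wsls", "delta_rule"),
                         p_stay_win_rareG = 0.65,
                         p_stay_win_rarel = 0.5,
                         p_shift_loss = 0.5,
                         learning_rate = 0.3,
                         inverse_temperature = 5,
                         loss_aversion_weight = 1) {
  agent_kind <- match.arg(agent_kind)
  probs <- c(p_stay_win_rareG, p_stay_win_rarel, p_shift_loss)
  if (any(probs < 0 | probs > 1)) stop("agent probabilities must be in [0, 1]")
  if (learning_rate < 0 || learning_rate > 1) stop("`learning_rate` must be in [0, 1]")
  if (inverse_temperature < 0) stop("`inverse_temperature` must be >= 0")
  if (loss_aversion_weight < 0) stop("`loss_aversion_weight` must be >= 0")
  structure(list(agent_kind = agent_kind,
                 p_stay_win_rareG = p_stay_win_rareG,
                 p_stay_win_rarel = p_stay_win_rarel,
                 p_shift_loss = p_shift_loss,
                 learning_rate = learning_rate,
                 inverse_temperature = inverse_temperature,
                 loss_aversion_weight = loss_aversion_weight),
            class = "agent_params")
}

#' Simulate one agent playing one block
#'
#' The first-trial choice is uniform random. A `wsls` agent then stays on
#' RareG after a RareG win with probability `p_stay_win_rareG`, stays on
#' RareL after a RareL win with probability `p_stay_win_rarel`, and switches
#' door after any loss with probability `p_shift_loss`. A `delta_rule` agent
#' maintains per-door values `V <- V + alpha * (r - V)` (losses scaled by
#' `loss_aversion_weight`) and chooses by softmax with the configured inverse
#' temperature. Outcomes are i.i.d. Bernoulli draws from the chosen deck.
#'
#' @param block A [make_block()] block.
#' @param params An [agent_params()] object.
#' @return A trial `data.frame` as from [trial_table()].
#' @export
simulate_agent <- function(block, params) {
  stopifnot(inherits(block, "block_spec"), inherits(params, "agent_params"))
  n <- block$n_trials
  choice <- character(n)
  outcome <- numeric(n)
  doors <- c("RareG", "RareL")
  V <- c(RareG = 0, RareL = 0)
  for (t in seq_len(n)) {
    if (t == 1L) {
      choice[t] <- sample(doors, 1L)
    } else if (params$agent_kind == "wsls") {
      prev <- choice[t - 1L]
      won <- outcome[t - 1L] > 0
      p_stay <- if (won) {
        if (prev == "RareG") params$p_stay_win_rareG else params$p_stay_win_rarel
      } else {
        1 - params$p_shift_loss
      }
      stay <- stats::runif(1) < p_stay
      choice[t] <- if (stay) prev else setdiff(doors, prev)
    } else {
      p_g <- 1 / (1 + exp(-params$inverse_temperature * (V[["RareG"]] - V[["RareL"]])))
      choice[t] <- if (stats::runif(1) < p_g) "RareG" else "RareL"
    }
    outcome[t] <- sample_outcome(block$decks[[choice[t]]])
    if (params$agent_kind == "delta_rule") {
      r <- outcome[t]
      if (r < 0) r <- r * params$loss_aversion_weight
      V[[choice[t]]] <- V[[choice[t]]] + params$learning_rate * (r - V[[choice[t]]])
    }
  }
  trial_table(choice, outcome)
}

#' Default behavior effect configuration
#'
#' Per-group mean stay-after-RareG-win probabilities and the between-subject
#' SD used by [generate_cohort_behavior()]. The default injects the
#' experimental-block deficit in the directly exposed group (mean 0.45 vs
#' 0.65 in the other two groups, SD 0.1); the baseline block always has a
#' common mean (no group effect), mirroring the design's expectation that
#' Win-Stay differences arise only under EV differences.
#'
#' @param direct_mean,indirect_mean,control_mean Group means of the stay
#'   probability in the experimental block.
#' @param sd Between-subject SD of the stay probability.
#' @param baseline_mean Common stay-probability mean in the baseline block.
#' @return A list used as `behavior_effect` downstream.
#' @export
behavior_effect_config <- function(direct_mean = 0.45, indirect_mean = 0.65,
                                   control_mean = 0.65, sd = 0.1,
                                   baseline_mean = 0.65) {
  list(means = c(directly_exposed = direct_mean,
                 indirectly_exposed = indirect_mean,
                 non_exposed = control_mean),
       sd = sd, baseline_mean = baseline_mean)
}

#' Simulate task behavior for a whole cohort
#'
#' Each subject plays one experimental and one baseline block of 40 trials
#' with a win-stay/lose-shift agent whose stay-after-RareG-win probability is
#' drawn from the subject's group distribution (experimental block) or from
#' the common baseline distribution (baseline block). Block order alternates
#' with subject index parity, emulating counterbalancing.
#'
#' @param covariates A covariate table from [generate_covariates()].
#' @param behavior_effect A [behavior_effect_config()] list.
#' @param n_trials Trials per block (default 40).
#' @param seed Optional integer seed.
#' @return A long `data.frame` with columns `subject_id`, `group`, `block`,
#'   `block_order`, `trial`, `choice`, `outcome`, `is_win`, `cumulative`,
#'   `p_stay_true`.
#' @export
generate_cohort_behavior <- function(covariates,
                                     behavior_effect = behavior_effect_config(),
                                     n_trials = 40L,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- list(experimental = make_block("experimental", n_trials),
                 baseline = make_block("baseline", n_trials))
  out <- vector("list", 2L * nrow(covariates))
  k <- 0L
  for (i in seq_len(nrow(covariates))) {
    g <- covariates$group[i]
    order_i <- if (i %% 2L == 1L) c("experimental", "baseline")
               else c("baseline", "experimental")
    for (j in seq_along(order_i)) {
      bk <- order_i[j]
      mu <- if (bk == "experimental") behavior_effect$means[[g]]
            else behavior_effect$baseline_mean
      p_stay <- rtrunc_norm(1, mu, behavior_effect$sd, 0, 1)
      tr <- simulate_agent(blocks[[bk]],
                           agent_params("wsls", p_stay_win_rareG = p_stay))
      tr$subject_id <- covariates$subject_id[i]
      tr$group <- g
      tr$block <- bk
      tr$block_order <- j
      tr$p_stay_true <- p_stay
      k <- k + 1L
      out[[k]] <- tr
    }
  }
  res <- do.call(rbind, out)
  cols <- c("subject_id", "group", "block", "block_order", "trial",
            "choice", "outcome", "is_win", "cumulative", "p_stay_true")
  res <- res[, cols]
  rownames(res) <- NULL
  res
}
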