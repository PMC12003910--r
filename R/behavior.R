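#' Win-Stay statistic
#'
#' The proportion of post-win trials on which the subject repeated the
#' previously rewarded target-door choice: the numerator counts trials `t`
#' (excluding the final trial) where the target door was chosen, won, and
#' was chosen again at `t + 1`; the denominator counts all non-final trials
#' where the target door was chosen and won. Final-trial wins have no
#' follow-up trial and are excluded from the denominator. With no qualifying
#' wins the statistic is undefined and `NA` is returned (never 0).
#'
#' @param trials A trial `data.frame` (columns `trial`, `choice`, `outcome`)
#'   ordered by trial index.
#' @param target_deck Door whose post-win repetition is scored (default
#'   `"RareG"`, the higher-EV door in the experimental block).
#' @return Ratio in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' tr <- trial_table(c("RareG", "RareG", "RareG", "RareL", "RareG"),
#'                   c(60, -20, 60, 20, -20))
#' win_stay(tr)  # wins at t1 and t3; followers RareG, RareL -> 0.5
#' @export
win_stay <- function(trials, target_deck = "RareG") {
  validate_trials(trials)
  n <- nrow(trials)
  if (n < 2L) return(NA_real_)
  idx <- seq_len(n - 1L)
  qualifying <- trials$choice[idx] == target_deck & trials$outcome[idx] > 0
  denom <- sum(qualifying)
  if (denom == 0L) return(NA_real_)
  stays <- qualifying & trials$choice[idx + 1L] == target_deck
  sum(stays) / denom
}

#' Gain-frequency bias
#'
#' The fraction of trials on which the frequent-gain door (RareL) was chosen.
#' Computed on the baseline block, where both doors have equal expected
#' value, this isolates a preference for frequent small gains from EV-based
#' choice.
#'
#' @param trials A trial `data.frame` for one subject's baseline block.
#' @return Ratio in `[0, 1]`.
#' @export
gain_frequency_bias <- function(trials) {
  validate_trials(trials)
  if (nrow(trials) == 0L) stop("empty trial list")
  mean(trials$choice == "RareL")
}

#' Per-subject behavior metrics
#'
#' Computes Win-Stay in the experimental and baseline blocks and the
#' baseline-block gain-frequency bias for every subject in a long cohort
#' behavior table.
#'
#' @param behavior A long behavior table from [generate_cohort_behavior()]
#'   (or the same schema read from CSV).
#' @return A `data.frame` with one row per subject: `subject_id`, `group`,
#'   `win_stay_expt`, `win_stay_baseline`, `gain_freq_bias`.
#' @export
compute_behavior_metrics <- function(behavior) {
  req <- c("subject_id", "block", "trial", "choice", "outcome")
  if (!all(req %in% names(behavior))) {
    stop("behavior table must have columns: ", paste(req, collapse = ", "))
  }
  ids <- unique(behavior$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- behavior[behavior$subject_id == id, ]
    expt <- sub[sub$block == "experimental", ]
    base <- sub[sub$block == "baseline", ]
    expt <- expt[order(expt$trial), ]
    base <- base[order(base$trial), ]
    data.frame(
      subject_id = id,
      group = if ("group" %in% names(sub)) sub$group[1] else NA_character_,
      win_stay_expt = if (nrow(expt)) win_stay(expt) else NA_real_,
      win_stay_baseline = if (nrow(base)) win_stay(base) else NA_real_,
      gain_freq_bias = if (nrow(base)) gain_frequency_bias(base) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("cannot z-score a constant variable")
  (x - mean(x)) / s
}

check_full_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Robust group regression of a behavior metric
#'
#' Fits an iteratively-reweighted least-squares regression (bisquare
#' weights, tuning constant 4.685 by default) of a behavioral outcome on
#' group plus demographic and mental-health covariates. The outcome and all
#' continuous covariates are z-scored before fitting so coefficients are
#' standardized betas; categorical terms are reference-coded with
#' `non_exposed` as the reference group. Subjects with an undefined outcome
#' are dropped with a message. Term p-values come from the t distribution
#' with residual degrees of freedom; model-level adjusted R-squared, F and p
#' are computed from the robust-weighted fit.
#'
#' @param metrics Behavior metric table from [compute_behavior_metrics()].
#' @param covariates Covariate table from [generate_covariates()].
#' @param outcome_name Column of `metrics` to model (default
#'   `"win_stay_expt"`).
#' @param terms Character vector of covariate terms to include alongside
#'   `group`.
#' @param tuning Bisquare tuning constant (default 4.685).
#' @return An object of class `ld_model`: list with `terms` (data.frame of
#'   term, beta, se, t, p), `adj_r2`, `fstat`, `model_p`, `n`, `df_residual`,
#'   `n_dropped`, `outcome`.
#' @export
fit_group_model <- function(metrics, covariates,
                            outcome_name = "win_stay_expt",
                            terms = c("group", "age", "gender", "ethnicity",
                                      "ses", "gad7", "phq9"),
                            tuning = 4.685) {
  dat <- merge(metrics[, c("subject_id", outcome_name)], covariates,
               by = "subject_id")
  y_raw <- dat[[outcome_name]]
  keep <- !is.na(y_raw)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " subject(s) dropped: undefined ", outcome_name)
  }
  dat <- dat[keep, ]
  if (nrow(dat) < 10L) stop("need >= 10 complete cases, have ", nrow(dat))

  dat$group <- stats::relevel(factor(dat$group), ref = "non_exposed")
  for (v in intersect(terms, names(dat))) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (is.numeric(dat[[v]]) && v != "group") dat[[v]] <- zscore(dat[[v]])
  }
  dat$.y <- zscore(dat[[outcome_name]])

  fml <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = dat)
  check_full_rank(X)

  fit <- MASS::rlm(fml, data = dat, psi = MASS::psi.bisquare, c = tuning,
                   maxit = 100)
  ld_model_from_rlm(fit, n = nrow(dat), n_dropped = n_dropped,
                    outcome = outcome_name)
}

# Shared extraction of standardized-beta term table and robust-weighted
# model-level statistics from a MASS::rlm fit.
ld_model_from_rlm <- function(fit, n, n_dropped, outcome) {
  sm <- summary(fit)
  coefs <- sm$coefficients
  p_terms <- nrow(coefs)
  df_res <- n - p_terms
  tvals <- coefs[, "t value"]
  terms_df <- data.frame(
    term = rownames(coefs),
    beta = coefs[, "Value"],
    se = coefs[, "Std. Error"],
    t = tvals,
    p = 2 * stats::pt(abs(tvals), df = df_res, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(terms_df) <- NULL

  # model-level stats from the final IRLS weights
  w <- fit$w
  y <- fit$model[[1L]]
  res <- stats::residuals(fit)
  ybar <- sum(w * y) / sum(w)
  sse <- sum(w * res^2)
  sst <- sum(w * (y - ybar)^2)
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / df_res
  fstat <- (r2 / (p_terms - 1)) / ((1 - r2) / df_res)
  model_p <- stats::pf(fstat, p_terms - 1, df_res, lower.tail = FALSE)

  structure(list(terms = terms_df, adj_r2 = adj_r2, fstat = fstat,
                 model_p = model_p, n = n, df_residual = df_res,
                 n_dropped = n_dropped, outcome = outcome),
            class = "ld_model")
}

#' @export
print.ld_model <- function(x, ...) {
  cat(sprintf("Robust regression of %s (n = %d, %d dropped)\n",
              x$outcome, x$n, x$n_dropped))
  cat(sprintf("adj R2 = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
              x$adj_r2, nrow(x$terms) - 1L, x$df_residual, x$fstat,
              x$model_p))
  tf <- x$terms
  tf$beta <- sprintf("% .3f", tf$beta)
  tf$se <- sprintf("%.3f", tf$se)
  tf$t <- sprintf("% .2f", tf$t)
  tf$p <- sprintf("%.4g", tf$p)
  print(tf, row.names = FALSE)
  invisible(x)
}
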