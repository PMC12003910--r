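test_that("Win-Stay matches hand enumeration on the worked example", {
  # RareG wins at t1 and t3; followers are RareG (stay) and RareL (shift)
  tr <- trial_table(c("RareG", "RareG", "RareG", "RareL", "RareG"),
                    c(60, -20, 60, 20, -20))
  expect_equal(win_stay(tr), 0.5)
  # every RareG win followed by RareG
  all_stay <- trial_table(rep("RareG", 6), rep(60, 6))
  expect_equal(win_stay(all_stay), 1)
  # no RareG wins: undefined, not zero
  no_win <- trial_table(c("RareG", "RareL", "RareL"), c(-20, 20, 20))
  expect_true(is.na(win_stay(no_win)))
  # a win on the final trial has no follow-up and is excluded
  final_win <- trial_table(c("RareG", "RareG"), c(-20, 60))
  expect_true(is.na(win_stay(final_win)))
})

test_that("Win-Stay agrees with the brute-force oracle on random sequences", {
  set.seed(14)
  for (i in 1:500) {
    len <- sample(2:12, 1)
    s <- random_sequence(len)
    expect_identical(win_stay(trial_table(s$choice, s$outcome)),
                     oracle_win_stay(s$choice, s$outcome))
  }
})

test_that("Win-Stay depends only on the win/stay pattern, not payoff magnitudes", {
  set.seed(15)
  for (i in 1:50) {
    s <- random_sequence(10)
    ws1 <- win_stay(trial_table(s$choice, s$outcome))
    ws2 <- win_stay(trial_table(s$choice, s$outcome * 7))
    expect_identical(ws1, ws2)
  }
})

test_that("gain-frequency bias is the RareL choice proportion", {
  all_l <- trial_table(rep("RareL", 10), rep(30, 10))
  expect_equal(gain_frequency_bias(all_l), 1)
  alt <- trial_table(rep(c("RareG", "RareL"), 20), rep(c(-30, 30), 20))
  expect_equal(gain_frequency_bias(alt), 0.5)
  mix <- trial_table(c(rep("RareL", 28), rep("RareG", 12)),
                     c(rep(30, 28), rep(-30, 12)))
  expect_equal(gain_frequency_bias(mix), 0.7)
  expect_error(gain_frequency_bias(trial_table(character(0), numeric(0))),
               "empty")
})

make_fit_fixture <- function(n = 60, seed = 1) {
  set.seed(seed)
  cov <- generate_covariates(c(n / 3, n / 3, n / 3),
                             null_covariate_config())
  metrics <- data.frame(subject_id = cov$subject_id,
                        win_stay_expt = NA_real_)
  list(cov = cov, metrics = metrics)
}

test_that("an outcome tracking a single covariate gets standardized beta 1", {
  fx <- make_fit_fixture(60, seed = 4)
  fx$metrics$win_stay_expt <- fx$cov$age          # perfect dependence
  fit <- fit_group_model(fx$metrics, fx$cov, terms = c("group", "age"))
  beta_age <- fit$terms$beta[fit$terms$term == "age"]
  expect_equal(beta_age, 1, tolerance = 1e-8)
  expect_lt(max(abs(fit$terms$beta[fit$terms$term != "age"])), 1e-8)
})

test_that("robust fit matches ordinary least squares on clean data", {
  fx <- make_fit_fixture(60, seed = 6)
  # near-noiseless linear outcome: robust and OLS solutions coincide
  fx$metrics$win_stay_expt <- 0.5 * scale(fx$cov$age)[, 1] +
    0.3 * scale(fx$cov$gad7)[, 1] + rnorm(60, 0, 1e-7)
  fit <- fit_group_model(fx$metrics, fx$cov,
                         terms = c("group", "age", "gad7"))
  dat <- data.frame(y = scale(fx$metrics$win_stay_expt)[, 1],
                    group = relevel(factor(fx$cov$group), "non_exposed"),
                    age = scale(fx$cov$age)[, 1],
                    gad7 = scale(fx$cov$gad7)[, 1])
  ols <- coef(lm(y ~ group + age + gad7, dat))
  expect_equal(unname(fit$terms$beta), unname(ols), tolerance = 1e-6)
})

test_that("a gross outlier moves robust betas less than OLS betas", {
  fx <- make_fit_fixture(60, seed = 7)
  age_z <- scale(fx$cov$age)[, 1]
  y <- 0.5 * age_z + rnorm(60, 0, 0.3)
  # corrupt the highest-leverage subject so OLS is dragged hard
  y_out <- y
  y_out[which.max(abs(age_z))] <- y_out[which.max(abs(age_z))] + 25
  fx$metrics$win_stay_expt <- y
  clean <- fit_group_model(fx$metrics, fx$cov, terms = c("group", "age"))
  fx$metrics$win_stay_expt <- y_out
  robust <- fit_group_model(fx$metrics, fx$cov, terms = c("group", "age"))
  # compare on the raw outcome scale (standardized betas de-standardized by
  # the outcome SD, which the outlier itself inflates)
  raw_beta <- function(fit, y_used) {
    fit$terms$beta[fit$terms$term == "age"] * sd(y_used)
  }
  dat <- data.frame(group = relevel(factor(fx$cov$group), "non_exposed"),
                    age = age_z)
  ols_clean <- coef(lm(y ~ group + age, dat))[["age"]]
  ols_out <- coef(lm(y_out ~ group + age, dat))[["age"]]
  shift_robust <- abs(raw_beta(robust, y_out) - raw_beta(clean, y))
  shift_ols <- abs(ols_out - ols_clean)
  expect_lt(shift_robust, shift_ols)
})

test_that("rank-deficient designs fail with the collinear term named", {
  fx <- make_fit_fixture(60, seed = 8)
  fx$metrics$win_stay_expt <- rnorm(60)
  fx$cov$gad7_copy <- fx$cov$gad7
  expect_error(
    fit_group_model(fx$metrics, fx$cov,
                    terms = c("group", "gad7", "gad7_copy")),
    "gad7_copy")
})

test_that("subjects with undefined outcomes are dropped with a message", {
  fx <- make_fit_fixture(60, seed = 9)
  fx$metrics$win_stay_expt <- rnorm(60)
  fx$metrics$win_stay_expt[c(2, 5)] <- NA
  expect_message(
    fit <- fit_group_model(fx$metrics, fx$cov, terms = c("group", "age")),
    "2 subject")
  expect_equal(fit$n, 58)
  expect_equal(fit$n_dropped, 2)
})
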