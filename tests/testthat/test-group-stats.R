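test_that("BH-FDR agrees with the brute-force step-up oracle", {
  set.seed(1)
  # random vectors of every length up to 6, plus permutations of one set
  for (len in 1:6) {
    for (rep in 1:20) {
      p <- round(runif(len), 3)
      got <- fdr_across_maps(p, q = 0.05)
      want <- oracle_bh(p, q = 0.05)
      expect_equal(got$p_adjusted, pmin(want$adjusted, 1))
      expect_identical(got$reject, want$reject)
    }
  }
  base <- c(0.01, 0.02, 0.04, 0.2, 0.6, 0.9)
  for (rep in 1:30) {
    p <- sample(base)
    got <- fdr_across_maps(p, q = 0.05)
    want <- oracle_bh(p, q = 0.05)
    expect_identical(got$reject, want$reject)
  }
})

test_that("BH-FDR reproduces the hand-computed 9-map family decisions", {
  # all nine maps at p = 0.01: adjusted p = 0.01 * 9 / 9 = 0.01, all rejected
  res <- fdr_across_maps(rep(0.01, 9), q = 0.05)
  expect_true(all(res$reject))
  expect_equal(res$p_adjusted, rep(0.01, 9))
  # only the smallest survives in a sparse family
  p <- c(0.001, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
  res <- fdr_across_maps(p, q = 0.05)
  expect_identical(res$reject, c(TRUE, rep(FALSE, 8)))
  # single test: adjusted equals raw
  res1 <- fdr_across_maps(0.04, q = 0.05)
  expect_equal(res1$p_adjusted, 0.04)
  expect_true(res1$reject)
  expect_error(fdr_across_maps(c(0.5, 1.2)), "0, 1")
})

test_that("cluster t-test reports the textbook effect size", {
  # equal means: t = 0, p = 1, d = 0
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- cluster_ttest(x, g)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_equal(res$d, 0)
  # means 1 vs 0 with pooled SD exactly 1: d = 1
  s <- 1 / sqrt(2)
  res <- cluster_ttest(c(1 - s, 1 + s, -s, s), rep(c("a", "b"), each = 2))
  expect_equal(res$d, 1)
  expect_equal(res$df, 2)
  # NaN values are excluded before testing
  res <- cluster_ttest(c(1 - s, 1 + s, NaN, -s, s),
                       c("a", "a", "a", "b", "b"))
  expect_equal(res$n, c(2L, 2L))
  expect_error(cluster_ttest(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)),
               "zero pooled SD")
})

test_that("cluster t on z-scored input matches the correlation equivalent", {
  set.seed(2)
  x <- rnorm(40); g <- rep(c("a", "b"), 20)
  z <- (x - mean(x)) / sd(x)
  res <- cluster_ttest(z, g)
  r <- cor.test(z, as.numeric(factor(g)))
  expect_equal(unname(res$t), -unname(r$statistic), tolerance = 1e-10)
  expect_equal(res$p, r$p.value, tolerance = 1e-10)
})

test_that("permutation clustering finds a planted parietal effect and respects sign", {
  set.seed(3)
  mon <- default_montage()
  g <- rep(c("directly_exposed", "other"), c(20, 36))
  x <- matrix(rnorm(56 * 24), 56, 24,
              dimnames = list(NULL, mon$channels$label))
  cl_ch <- c("Pz", "P3", "P4", "POz")
  x[1:20, cl_ch] <- x[1:20, cl_ch] + 1.5
  res <- permutation_cluster_map(x, g, mon, n_perm = 500)
  expect_true(res$mask["Pz"])
  hit <- which(vapply(res$clusters, function(cl) {
    "Pz" %in% names(res$t)[cl]
  }, logical(1)))
  expect_true(all(cl_ch %in% names(res$t)[res$clusters[[hit[1]]]]))
  # same-sign clustering: all member t-values share a sign
  for (cl in res$clusters) {
    expect_true(all(sign(res$t[cl]) == sign(res$t[cl][1])))
  }
})

test_that("zero-variance electrodes are excluded rather than crashing the map", {
  set.seed(4)
  mon <- default_montage()
  g <- rep(c("directly_exposed", "other"), c(10, 12))
  x <- matrix(rnorm(22 * 24), 22, 24,
              dimnames = list(NULL, mon$channels$label))
  x[, "Fz"] <- 1
  res <- permutation_cluster_map(x, g, mon, n_perm = 200)
  expect_true(is.na(res$t["Fz"]))
  expect_false(any(vapply(res$clusters, function(cl) {
    "Fz" %in% names(res$t)[cl]
  }, logical(1))))
})

test_that("permutation p-values are exchangeable under label reshuffling", {
  set.seed(5)
  mon <- default_montage()
  g <- rep(c("directly_exposed", "other"), c(12, 14))
  x <- matrix(rnorm(26 * 24), 26, 24,
              dimnames = list(NULL, mon$channels$label))
  set.seed(99); p1 <- permutation_cluster_map(x, g, mon, n_perm = 300)$map_p
  idx <- sample(26)
  set.seed(99)
  p2 <- permutation_cluster_map(x[idx, ], g[idx], mon, n_perm = 300)$map_p
  # identical data under a relabeling that respects group sizes:
  # observed cluster masses are identical, p differs only by MC error
  expect_lt(abs(p1 - p2), 0.15)
})

test_that("within-group Spearman handles monotone, reversed and constant input", {
  g <- rep("other", 8)
  x <- 1:8
  expect_equal(within_group_spearman(x, x^3, g, "other")$rho, 1)
  expect_equal(within_group_spearman(x, rev(x), g, "other")$rho, -1)
  res <- within_group_spearman(x, rep(2, 8), g, "other")
  expect_true(is.na(res$rho))
  expect_error(within_group_spearman(1:3, 1:3, rep("other", 3), "other"),
               ">= 5 pairs")
})

test_that("null Spearman correlations reject at the nominal rate", {
  set.seed(6)
  n_rep <- 400
  hits <- 0; rhos <- numeric(n_rep)
  g <- rep("other", 30)
  for (i in seq_len(n_rep)) {
    res <- within_group_spearman(rnorm(30), rnorm(30), g, "other")
    rhos[i] <- res$rho
    if (res$p < 0.05) hits <- hits + 1
  }
  expect_lt(abs(mean(rhos)), 0.03)
  expect_rate_within(hits / n_rep, 0.05, n_rep)
})

test_that("demographic comparisons use the right tests and star coding", {
  # hand-computed uncorrected chi-square for a 2x2 table (20,10 / 10,20):
  # X2 = n (ad - bc)^2 / (r1 r2 c1 c2) = 60 * 300^2 / 30^4 = 6.667
  cov <- data.frame(
    subject_id = sprintf("S%02d", 1:60),
    group = rep(c("directly_exposed", "non_exposed"), each = 30),
    gender = c(rep("female", 20), rep("male", 10),
               rep("female", 10), rep("male", 20)),
    age = rep(25, 60) + rep(c(0, 1), 30))
  res <- demographic_comparison(cov)
  chi <- res[res$variable == "gender", ]
  expect_equal(chi$statistic, 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30),
               tolerance = 1e-10)
  expect_identical(chi$test, "chisq")
  # fully separated rank-sum at n = 4 vs 4 attains exactly p = 2/choose(8,4)
  cov2 <- data.frame(subject_id = sprintf("S%d", 1:8),
                     group = rep(c("directly_exposed", "non_exposed"),
                                 each = 4),
                     gad7 = c(10, 11, 12, 13, 1, 2, 3, 4))
  res2 <- demographic_comparison(cov2)
  expect_equal(res2$p[res2$variable == "gad7"], 2 / choose(8, 4))
  # star coding thresholds
  expect_identical(res2$stars[res2$variable == "gad7"], "")
})

test_that("the interaction model recovers a planted group-specific coupling", {
  set.seed(7)
  n <- 60
  cov <- generate_covariates(c(n / 2, 0, n / 2) + c(0, 1, 0),
                             null_covariate_config())
  alpha <- rnorm(nrow(cov))
  other <- cov$group != "directly_exposed"
  ws <- ifelse(other, 0.5 * alpha, 0) + rnorm(nrow(cov), 0, 0.5)
  metrics <- data.frame(subject_id = cov$subject_id, win_stay_expt = ws)
  neural <- data.frame(subject_id = cov$subject_id, value = alpha)
  fit <- neurobehavioral_model(metrics, cov, neural)
  inter <- fit$terms[grepl(":neural", fit$terms$term), ]
  # directly-exposed contrast removes the coupling: negative interaction
  expect_lt(inter$beta, 0)
  expect_lt(inter$p, 0.05)
})

test_that("duplicate neural regressors are reported as rank deficiency", {
  set.seed(8)
  cov <- generate_covariates(c(20, 10, 20), null_covariate_config())
  metrics <- data.frame(subject_id = cov$subject_id,
                        win_stay_expt = rnorm(50))
  neural <- data.frame(subject_id = cov$subject_id,
                       value = cov$gad7)   # identical to the gad7 covariate
  expect_error(neurobehavioral_model(metrics, cov, neural), "collinear")
})
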