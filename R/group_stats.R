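#' Two-level exposure contrast
#'
#' The neural analyses contrast the directly exposed group against all
#' other participants ("other" = indirectly exposed + non-exposed,
#' combined because they do not differ behaviorally).
#'
#' @param group Character/factor vector of three-level group labels.
#' @return Factor with levels `other`, `directly_exposed` (reference
#'   `other`).
#' @export
exposure_contrast <- function(group) {
  factor(ifelse(group == "directly_exposed", "directly_exposed", "other"),
         levels = c("other", "directly_exposed"))
}

# pooled-variance two-sample t statistics per electrode, NA-aware and
# vectorized over an indicator matrix G (subjects x n_contrasts)
pooled_t_matrix <- function(x, G) {
  M <- !is.na(x)
  X0 <- ifelse(M, x, 0)
  nA <- crossprod(M, G)              # electrodes x n_contrasts
  SA <- crossprod(X0, G)
  SA2 <- crossprod(X0^2, G)
  n_e <- colSums(M); S <- colSums(X0); S2 <- colSums(X0^2)
  nB <- n_e - nA; SB <- S - SA; SB2 <- S2 - SA2
  mA <- SA / nA; mB <- SB / nB
  vA <- (SA2 - nA * mA^2) / (nA - 1)
  vB <- (SB2 - nB * mB^2) / (nB - 1)
  df <- nA + nB - 2
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / df
  tt <- (mA - mB) / sqrt(sp2 * (1 / nA + 1 / nB))
  tt[!is.finite(tt)] <- NA
  list(t = tt, df = df)
}

# connected components of same-sign suprathreshold electrodes
find_clusters <- function(tvals, supra, adj) {
  idx <- which(supra & !is.na(tvals))
  if (!length(idx)) return(list())
  visited <- logical(length(tvals))
  out <- list()
  for (s in idx) {
    if (visited[s]) next
    sgn <- sign(tvals[s])
    comp <- integer(0)
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- which(adj[v, ] & supra & !visited)
      nb <- nb[!is.na(tvals[nb]) & sign(tvals[nb]) == sgn]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

#' Cluster-based permutation test of a scalp map
#'
#' Per-electrode pooled-variance two-sample t statistics are thresholded at
#' a two-sided cluster-forming level; spatially adjacent suprathreshold
#' electrodes of the same sign form clusters whose mass (sum of |t|) is
#' compared against the permutation null of the maximum cluster mass under
#' random relabeling of subjects, giving family-wise control over
#' electrodes. Electrodes with `NaN` values are excluded per electrode;
#' zero-variance electrodes get an undefined t and never enter clusters.
#'
#' @param x Subjects-by-electrodes numeric matrix (colnames = labels).
#' @param groups Two-level factor/character vector along rows of `x`.
#' @param montage A montage supplying adjacency for every electrode.
#' @param n_perm Number of label permutations (default 10000).
#' @param cluster_alpha Two-sided per-electrode cluster-forming p threshold
#'   (default 0.05).
#' @param sig_alpha Cluster-level significance threshold (default 0.05).
#' @param mark_alpha Stricter map-marking threshold (default 1e-4).
#' @return Object of class `map_stat`: per-electrode `t`, `df`, `clusters`
#'   (list of electrode index vectors), `cluster_mass`, `cluster_p`,
#'   `mask` (electrodes in clusters with p <= sig_alpha), `mark_mask`
#'   (p < mark_alpha), `map_p` (smallest cluster p, 1 if none),
#'   `null_max_mass`.
#' @export
permutation_cluster_map <- function(x, groups, montage, n_perm = 10000,
                                    cluster_alpha = 0.05, sig_alpha = 0.05,
                                    mark_alpha = 1e-4) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("`groups` must have exactly two levels")
  if (min(table(groups)) < 2L) stop("need >= 2 subjects per side")
  labels <- colnames(x)
  if (is.null(labels)) stop("`x` must have electrode column names")
  miss <- setdiff(labels, montage$channels$label)
  if (length(miss)) stop("montage lacks electrode(s): ",
                         paste(miss, collapse = ", "))
  adj <- montage$adjacency[labels, labels]
  if (any(rowSums(adj) == 0)) {
    warning("disconnected montage node(s): ",
            paste(labels[rowSums(adj) == 0], collapse = ", "))
  }
  n <- nrow(x)
  g_obs <- as.numeric(groups == levels(groups)[2L])
  obs <- pooled_t_matrix(x, matrix(g_obs, ncol = 1L))
  t_obs <- drop(obs$t); df_obs <- drop(obs$df)
  t_crit <- stats::qt(1 - cluster_alpha / 2, df_obs)
  supra_obs <- !is.na(t_obs) & abs(t_obs) > t_crit
  clusters <- find_clusters(t_obs, supra_obs, adj)
  mass <- vapply(clusters, function(cl) sum(abs(t_obs[cl])), numeric(1))

  nA <- sum(g_obs)
  G <- vapply(seq_len(n_perm), function(i) {
    g <- numeric(n); g[sample.int(n, nA)] <- 1; g
  }, numeric(n))
  perm <- pooled_t_matrix(x, G)
  null_max <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    tp <- perm$t[, i]
    supra <- !is.na(tp) & abs(tp) > t_crit
    if (!any(supra)) next
    cls <- find_clusters(tp, supra, adj)
    if (length(cls)) {
      null_max[i] <- max(vapply(cls, function(cl) sum(abs(tp[cl])),
                                numeric(1)))
    }
  }
  cluster_p <- vapply(mass, function(m2) {
    (1 + sum(null_max >= m2)) / (n_perm + 1)
  }, numeric(1))
  mask <- mark <- logical(length(labels))
  for (k in seq_along(clusters)) {
    if (cluster_p[k] <= sig_alpha) mask[clusters[[k]]] <- TRUE
    if (cluster_p[k] < mark_alpha) mark[clusters[[k]]] <- TRUE
  }
  names(t_obs) <- names(mask) <- names(mark) <- labels
  structure(list(t = t_obs, df = df_obs, clusters = clusters,
                 cluster_mass = mass, cluster_p = cluster_p,
                 mask = mask, mark_mask = mark,
                 map_p = if (length(cluster_p)) min(cluster_p) else 1,
                 null_max_mass = null_max, n_perm = n_perm,
                 groups = levels(groups)),
            class = "map_stat")
}

#' @export
print.map_stat <- function(x, ...) {
  cat(sprintf("<map_stat: %d electrodes, %d cluster(s), %d permutations>\n",
              length(x$t), length(x$clusters), x$n_perm))
  if (length(x$clusters)) {
    for (k in seq_along(x$clusters)) {
      cat(sprintf("  cluster %d: {%s} mass = %.2f, p = %.4g\n", k,
                  paste(names(x$t)[x$clusters[[k]]], collapse = ", "),
                  x$cluster_mass[k], x$cluster_p[k]))
    }
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR across a family of map p-values
#'
#' Step-up FDR control over the family of scalp-map comparisons (by
#' default 9 maps: 3 bands x 3 periods).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `reject`.
#' @export
fdr_across_maps <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, reject = adj <= q)
}

#' Two-sample cluster t-test with Cohen's d
#'
#' Pooled-variance two-sample t-test of a per-subject scalar (e.g. the
#' parietal alpha cluster mean) between contrast sides, with the
#' standardized mean difference d = (mean difference) / (pooled SD).
#' `NaN`/`NA` values are excluded.
#'
#' @param values Per-subject numeric scalar.
#' @param groups Two-level factor along `values`; the difference is
#'   level 1 minus level 2.
#' @return List with `t`, `df`, `p`, `d`, `means`, `n`.
#' @export
cluster_ttest <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("`groups` must have exactly two levels")
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  x1 <- values[groups == levels(groups)[1L]]
  x2 <- values[groups == levels(groups)[2L]]
  if (length(x1) < 2L || length(x2) < 2L) stop("need >= 2 per side")
  sp2 <- ((length(x1) - 1) * stats::var(x1) + (length(x2) - 1) * stats::var(x2)) /
         (length(x1) + length(x2) - 2)
  if (sp2 == 0) stop("zero pooled SD")
  tt <- stats::t.test(x1, x2, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(x1) - mean(x2)) / sqrt(sp2),
       means = c(mean(x1), mean(x2)),
       n = c(length(x1), length(x2)))
}

#' Robust group-by-neural interaction model of behavior
#'
#' Fits Win-Stay ~ group + neural + group:neural + age + ethnicity +
#' anxiety by iteratively-reweighted least squares (bisquare weights),
#' where `group` is the directly-exposed-vs-other contrast and `neural`
#' is a per-subject alpha scalar (cluster mean or a single parietal
#' electrode in one trial period). Continuous variables are z-scored so
#' betas are standardized.
#'
#' @param metrics Behavior metric table (needs `win_stay_expt`).
#' @param covariates Covariate table.
#' @param neural `data.frame` with `subject_id` and `value` columns.
#' @param outcome_name Behavior outcome column (default `win_stay_expt`).
#' @param covariate_terms Covariates entered alongside the interaction
#'   (default age + ethnicity + gad7, the terms that differ between the
#'   contrast sides).
#' @param tuning Bisquare tuning constant.
#' @return An `ld_model` object; the interaction term is
#'   `groupdirectly_exposed:neural`.
#' @export
neurobehavioral_model <- function(metrics, covariates, neural,
                                  outcome_name = "win_stay_expt",
                                  covariate_terms = c("age", "ethnicity", "gad7"),
                                  tuning = 4.685) {
  dat <- merge(metrics[, c("subject_id", outcome_name)],
               covariates, by = "subject_id")
  dat <- merge(dat, neural[, c("subject_id", "value")], by = "subject_id")
  keep <- !is.na(dat[[outcome_name]]) & is.finite(dat$value)
  n_dropped <- sum(!keep)
  dat <- dat[keep, ]
  if (nrow(dat) < 10L) stop("need >= 10 complete cases, have ", nrow(dat))
  dat$group <- exposure_contrast(dat$group)
  dat$neural <- zscore(dat$value)
  for (v in intersect(covariate_terms, names(dat))) {
    if (is.character(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    if (is.numeric(dat[[v]])) dat[[v]] <- zscore(dat[[v]])
  }
  dat$.y <- zscore(dat[[outcome_name]])
  fml <- stats::as.formula(paste(
    ".y ~ group * neural +", paste(covariate_terms, collapse = " + ")))
  X <- stats::model.matrix(fml, data = dat)
  dup <- duplicated(t(X)) & colnames(X) != "(Intercept)"
  if (any(dup)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(colnames(X)[dup], collapse = ", "))
  }
  check_full_rank(X)
  fit <- MASS::rlm(fml, data = dat, psi = MASS::psi.bisquare, c = tuning,
                   maxit = 100)
  ld_model_from_rlm(fit, n = nrow(dat), n_dropped = n_dropped,
                    outcome = outcome_name)
}

#' Fit the neurobehavioral model family with FDR correction
#'
#' Fits one interaction model per electrode (the four parietal electrodes)
#' and trial period — a family of 12 — plus the three cluster-mean models,
#' and applies Benjamini-Hochberg correction to the interaction p-values
#' across the 12 electrode models.
#'
#' @param metrics,covariates As in [neurobehavioral_model()].
#' @param neural_scalars `data.frame` with columns `subject_id`,
#'   `electrode` (including `"cluster"` rows), `period`, `value`.
#' @param q FDR level.
#' @param ... Passed to [neurobehavioral_model()].
#' @return `data.frame` with one row per fitted model: `electrode`,
#'   `period`, interaction `beta`, `se`, `t`, `p`, `p_fdr` (NA for cluster
#'   rows), `model_p`; the fitted models are attached as the `"models"`
#'   attribute.
#' @export
neurobehavioral_family <- function(metrics, covariates, neural_scalars,
                                   q = 0.05, ...) {
  combos <- unique(neural_scalars[, c("electrode", "period")])
  fits <- vector("list", nrow(combos))
  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- neural_scalars$electrode == combos$electrode[i] &
           neural_scalars$period == combos$period[i]
    fit <- neurobehavioral_model(metrics, covariates,
                                 neural_scalars[sel, ], ...)
    term <- fit$terms[grepl(":neural", fit$terms$term), ]
    rows[[i]] <- data.frame(electrode = combos$electrode[i],
                            period = combos$period[i],
                            beta = term$beta, se = term$se, t = term$t,
                            p = term$p, model_p = fit$model_p,
                            stringsAsFactors = FALSE)
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  elec <- out$electrode != "cluster"
  out$p_fdr[elec] <- stats::p.adjust(out$p[elec], method = "BH")
  attr(out, "models") <- fits
  out
}

#' Within-group Spearman correlation
#'
#' Rank correlation between a behavior metric and a neural scalar within
#' one group only (the follow-up to a significant group-by-neural
#' interaction).
#'
#' @param x,y Paired numeric vectors.
#' @param group Group labels along the pairs.
#' @param which_group Group to correlate within.
#' @return List with `rho`, `p`, `n`; `rho` is `NA` for constant input.
#' @export
within_group_spearman <- function(x, y, group, which_group) {
  sel <- group == which_group & is.finite(x) & is.finite(y)
  if (sum(sel) < 5L) stop("need >= 5 pairs in group ", which_group)
  xs <- x[sel]; ys <- y[sel]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = sum(sel),
                note = "constant input; rho undefined"))
  }
  ct <- suppressWarnings(stats::cor.test(xs, ys, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(sel))
}

#' Demographic and mental-health group comparisons
#'
#' Compares covariates between the two contrast sides: Wilcoxon rank-sum
#' tests for ordinal/continuous variables and chi-square tests on
#' contingency tables for gender and ethnicity, with the conventional
#' star coding (`**` p < 0.01, `***` p < 0.001). Empty category levels are
#' dropped with a warning.
#'
#' @param covariates Covariate table.
#' @param contrast Optional two-level factor; defaults to the
#'   directly-exposed-vs-other contrast.
#' @return `data.frame` with `variable`, `test`, `statistic`, `p`, `stars`.
#' @export
demographic_comparison <- function(covariates, contrast = NULL) {
  if (is.null(contrast)) contrast <- exposure_contrast(covariates$group)
  contrast <- factor(contrast)
  ranksum_vars <- intersect(c("age", "ses", "gad7", "phq9", "recent_trauma"),
                            names(covariates))
  chisq_vars <- intersect(c("gender", "ethnicity"), names(covariates))
  rows <- list()
  for (v in ranksum_vars) {
    w <- suppressWarnings(
      stats::wilcox.test(as.numeric(covariates[[v]]) ~ contrast))
    rows[[v]] <- data.frame(variable = v, test = "ranksum",
                            statistic = unname(w$statistic), p = w$p.value)
  }
  for (v in chisq_vars) {
    f <- factor(covariates[[v]])
    if (any(table(f) == 0)) {
      warning("dropping empty level(s) of ", v)
      f <- droplevels(f)
    }
    tab <- table(f, contrast)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[v]] <- data.frame(variable = v, test = "chisq",
                            statistic = unname(ct$statistic), p = ct$p.value)
  }
  out <- do.call(rbind, rows)
  out$stars <- ifelse(out$p < 0.001, "***", ifelse(out$p < 0.01, "**", ""))
  rownames(out) <- NULL
  out
}
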