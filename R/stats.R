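#' Holm-Bonferroni step-down adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, order-preserving, monotone, capped at 1.
#' @export
holm_bonferroni <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1L) * p[o]))
  out <- numeric(m); out[o] <- adj
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted p-values, order-preserving, monotone, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  out <- numeric(m); out[o] <- adj
  out
}

# internal: pooled ranks and tie bookkeeping for rank tests
rank_groups <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(!vapply(groups, length, 1L))) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(x))) stop("non-finite observation")
  r <- rank(x)
  idx <- rep(seq_along(groups), vapply(groups, length, 1L))
  ties <- table(x)
  list(r = r, idx = idx, n = vapply(groups, length, 1L), N = length(x),
       tie_term = sum(ties^3 - ties))
}

#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' `k - 1` degrees of freedom. When every observation is identical the tie
#' correction degenerates and H is defined as 0.
#'
#' @param groups named list of numeric vectors, one per group.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  rg <- rank_groups(groups)
  if (rg$N < 3L) stop("need at least 3 observations in total")
  mean_ranks <- tapply(rg$r, rg$idx, mean)
  H <- 12 / (rg$N * (rg$N + 1)) * sum(rg$n * (mean_ranks - (rg$N + 1) / 2)^2)
  corr <- 1 - rg$tie_term / (rg$N^3 - rg$N)
  H <- if (corr > 0) H / corr else 0
  df <- length(groups) - 1L
  list(H = H, p = stats::pchisq(H, df, lower.tail = FALSE), df = df)
}

#' Dunn's post hoc test with Holm-Bonferroni correction
#'
#' All pairwise mean-rank comparisons after a Kruskal-Wallis test. The
#' standard error uses the standard tie correction,
#' `SE = sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t)` over tied values. Two-sided normal p-values, Holm
#' adjusted across all pairs.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with `group1`, `group2`, `z`, `p_raw`, `p_holm`.
#' @export
dunn_posthoc <- function(groups) {
  rg <- rank_groups(groups)
  nms <- names(groups) %||% as.character(seq_along(groups))
  mean_ranks <- tapply(rg$r, rg$idx, mean)
  tie_adj <- rg$tie_term / (12 * (rg$N - 1))
  pairs <- utils::combn(length(groups), 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    se2 <- unname((rg$N * (rg$N + 1) / 12 - tie_adj) * (1 / rg$n[i] + 1 / rg$n[j]))
    diff <- unname(mean_ranks[i] - mean_ranks[j])
    z <- if (se2 > 0) diff / sqrt(se2) else 0
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  out <- data.frame(group1 = nms[pairs[1, ]], group2 = nms[pairs[2, ]],
                    z = res["z", ], p_raw = res["p", ])
  out$p_holm <- holm_bonferroni(out$p_raw)
  out
}

# internal: all permutations of 1..n as a matrix (n! rows); n <= 8
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# internal: run expr with a private, restored RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Spearman correlation with permutation test
#'
#' Spearman's rho (average ranks for ties) with a two-sided permutation
#' p-value. When `factorial(n) <= n_perm` all permutations are enumerated
#' and `p = #\{|rho_perm| >= |rho_obs|\} / n!`; otherwise `n_perm` Monte
#' Carlo draws give `p = (1 + #exceed) / (1 + n_perm)`, so p is never 0.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, neither constant.
#' @param n_perm permutation budget.
#' @param seed RNG seed for the Monte Carlo branch (recorded in the result).
#' @return list of class `correlation_result`: `rho`, `p_perm`, `n`,
#'   `n_permutations`, `exhaustive`, `seed`.
#' @export
spearman_perm <- function(x, y, n_perm = 10000L, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need n >= 3")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  if (n < 3L) stop("need n >= 3 complete cases")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  exhaustive <- n <= 8L && factorial(n) <= n_perm
  if (exhaustive) {
    perms <- all_permutations(n)
    rho_p <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- sum(abs(rho_p) >= abs(rho) - 1e-12) / nrow(perms)
    np <- nrow(perms)
  } else {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12
      }, logical(1)))
    })
    p <- (1 + exceed) / (1 + n_perm)
    np <- n_perm
  }
  structure(list(rho = rho, p_perm = p, n = n, n_permutations = np,
                 exhaustive = exhaustive, seed = seed),
            class = "correlation_result")
}

#' Feature-clinical correlation matrix
#'
#' Spearman permutation correlations between per-patient median spectral
#' features and (a) the baseline motor BFMDRS score and (b) its percent
#' change after surgery, with Benjamini-Hochberg FDR across the whole
#' matrix.
#'
#' @param tab feature table (one row per recording).
#' @param clinical data.frame with `patient_id`, `bfmdrs_pre`,
#'   `percent_change` (see [patient_clinical()] and [clinical_table()]).
#' @param features feature columns to use.
#' @param n_perm,seed permutation settings.
#' @return data.frame with `feature`, `clinical`, `rho`, `p_perm`, `p_fdr`, `n`.
#' @export
clinical_correlations <- function(tab, clinical, features = feature_names(),
                                  n_perm = 10000L, seed = 1L) {
  med <- stats::aggregate(tab[features], by = list(patient_id = tab$patient_id),
                          FUN = stats::median, na.rm = TRUE)
  d <- merge(med, clinical, by = "patient_id")
  if (nrow(d) < 3L) stop("fewer than 3 patients with both features and clinical scores")
  targets <- c(baseline_bfmdrs = "bfmdrs_pre", percent_change = "percent_change")
  rows <- list()
  k <- 0L
  for (f in features) for (ti in seq_along(targets)) {
    k <- k + 1L
    r <- tryCatch(
      spearman_perm(d[[f]], d[[targets[ti]]], n_perm = n_perm, seed = seed + k),
      error = function(e) NULL)   # constant column -> cell flagged missing
    rows[[k]] <- data.frame(feature = f, clinical = names(targets)[ti],
                            rho = if (is.null(r)) NA_real_ else r$rho,
                            p_perm = if (is.null(r)) NA_real_ else r$p_perm,
                            n = nrow(d))
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_perm)
  out$p_fdr[ok] <- bh_fdr(out$p_perm[ok])
  out
}

#' Per-group depth-feature correlation heatmap
#'
#' Spearman permutation correlation between normalized depth and each
#' spectral feature, within each genetic group, restricted to in-GPi
#' recordings; BH-FDR across all computed cells. Cells with fewer than
#' `min_n` recordings are returned with `NA` values.
#'
#' @param tab feature table with `normalized_depth`, `in_gpi`, `group`.
#' @param features feature columns.
#' @param min_n minimum in-GPi recordings per (group, feature) cell.
#' @param n_perm,seed permutation settings.
#' @return data.frame with `group`, `feature`, `rho`, `p_perm`, `p_fdr`, `n`.
#' @export
depth_correlations <- function(tab, features = feature_names(), min_n = 3L,
                               n_perm = 10000L, seed = 1L) {
  if (!is.null(tab$in_gpi)) tab <- tab[tab$in_gpi, , drop = FALSE]
  rows <- list(); k <- 0L
  for (g in unique(tab$group)) {
    sub <- tab[tab$group == g, , drop = FALSE]
    for (f in features) {
      k <- k + 1L
      ok <- stats::complete.cases(sub$normalized_depth, sub[[f]])
      if (sum(ok) < min_n || stats::sd(sub[[f]][ok]) == 0) {
        rows[[k]] <- data.frame(group = g, feature = f, rho = NA_real_,
                                p_perm = NA_real_, n = sum(ok))
      } else {
        r <- spearman_perm(sub$normalized_depth[ok], sub[[f]][ok],
                           n_perm = n_perm, seed = seed + k)
        rows[[k]] <- data.frame(group = g, feature = f, rho = r$rho,
                                p_perm = r$p_perm, n = r$n)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  ok <- !is.na(out$p_perm)
  out$p_fdr[ok] <- bh_fdr(out$p_perm[ok])
  out
}

#' Mixed-model depth effect for one feature
#'
#' Fits `feature ~ 1 + normalized_depth` with crossed random intercepts for
#' genetic group and patient (restricted to in-GPi recordings) and tests
#' the fixed depth slope with a Wald z test. A singular or non-converged
#' fit is reported with `converged = FALSE`; the slope is still returned.
#'
#' @param tab feature table.
#' @param feature feature column name.
#' @return list of class `lmm_result`: `feature`, `slope`, `se`, `wald_z`,
#'   `p`, `var_group`, `var_patient`, `var_residual`, `converged`.
#' @export
lmm_depth_effect <- function(tab, feature) {
  if (!is.null(tab$in_gpi)) tab <- tab[tab$in_gpi, , drop = FALSE]
  d <- data.frame(y = tab[[feature]], depth = tab$normalized_depth,
                  group = factor(tab$group), patient = factor(tab$patient_id))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 4L) stop("too few in-GPi rows for a mixed model")
  form <- if (nlevels(d$group) > 1L)
    y ~ depth + (1 | group) + (1 | patient) else y ~ depth + (1 | patient)
  ok <- TRUE
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    warning = function(w) { ok <<- FALSE; invokeRestart("muffleWarning") })
  if (lme4::isSingular(fit, tol = 1e-5)) ok <- FALSE
  co <- summary(fit)$coefficients
  slope <- co["depth", "Estimate"]; se <- co["depth", "Std. Error"]
  z <- slope / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(nm) { v <- vc$vcov[vc$grp == nm]; if (length(v)) v else 0 }
  structure(list(feature = feature, slope = slope, se = se, wald_z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 var_group = getv("group"), var_patient = getv("patient"),
                 var_residual = getv("Residual"), converged = ok),
            class = "lmm_result")
}

#' Mixed-model depth effects across the feature family
#'
#' Runs [lmm_depth_effect()] per feature and Holm-adjusts the Wald
#' p-values across the family.
#'
#' @param tab feature table.
#' @param features feature columns.
#' @return data.frame with one row per feature incl. `p_holm`.
#' @export
lmm_depth_effects <- function(tab, features = feature_names()) {
  res <- lapply(features, function(f) lmm_depth_effect(tab, f))
  out <- do.call(rbind, lapply(res, function(r)
    data.frame(feature = r$feature, slope = r$slope, se = r$se,
               wald_z = r$wald_z, p = r$p, var_group = r$var_group,
               var_patient = r$var_patient, var_residual = r$var_residual,
               converged = r$converged)))
  out$p_holm <- holm_bonferroni(out$p)
  out
}
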