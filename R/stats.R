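#' Univariate outlier screening by standardized scores
#'
#' Flags observations whose z score (sample mean/SD) exceeds the limit in
#' absolute value. The conventional limit 3.29 corresponds to two-sided
#' p < .001 under normality.
#'
#' @param values Numeric vector, n >= 3.
#' @param limit Absolute z limit.
#' @return Logical vector of flags (all `FALSE`, with a message attribute,
#'   when the sample is degenerate).
#' @export
zscore_screen <- function(values, limit = 3.29) {
  if (length(values) < 3) stop_oxy("oxydrift_short", "need n >= 3")
  s <- sd(values)
  if (s == 0) {
    flags <- rep(FALSE, length(values))
    attr(flags, "degenerate") <- TRUE
    return(flags)
  }
  abs((values - mean(values)) / s) > limit
}

#' Iterative winsorization to a z-score limit
#'
#' The most extreme flagged value is replaced by the nearest boundary value
#' (mean +/- limit * SD at the current iteration, clamped so the sample's
#' ordering is never reversed), z scores are recomputed, and the procedure
#' repeats until every |z| <= limit.
#'
#' @param values Numeric vector, n >= 3.
#' @param limit Absolute z limit (default 3.29).
#' @return Adjusted vector with attribute `n_adjusted` (number of
#'   replacements performed).
#' @export
winsorize_to_limit <- function(values, limit = 3.29) {
  if (length(values) < 3) stop_oxy("oxydrift_short", "need n >= 3")
  v <- values
  n_adj <- 0L
  for (iter in seq_len(10L * length(v))) {
    m <- mean(v); s <- sd(v)
    if (s == 0) break
    z <- (v - m) / s
    if (all(abs(z) <= limit)) break
    i <- which.max(abs(z))
    if (z[i] > 0) {
      repl <- m + limit * s
      below <- v[-i][v[-i] < v[i]]
      if (length(below)) repl <- max(repl, max(below))
    } else {
      repl <- m - limit * s
      above <- v[-i][v[-i] > v[i]]
      if (length(above)) repl <- min(repl, min(above))
    }
    v[i] <- repl
    n_adj <- n_adj + 1L
  }
  attr(v, "n_adjusted") <- n_adj
  v
}

#' Ordered quantile normalization
#'
#' Rank-based inverse normal transform: mid-ranks (ties averaged) are mapped
#' through `qnorm(r / (n + 1))`. Strictly rank-preserving; an inverse map
#' (linear interpolation between the sorted transformed/original pairs) is
#' returned for back-transformation.
#'
#' @param values Numeric vector, n >= 3, not all tied.
#' @return List with `values` (transformed) and `inverse` (a function).
#' @export
orq_transform <- function(values) {
  n <- length(values)
  if (n < 3) stop_oxy("oxydrift_short", "need n >= 3")
  if (length(unique(values)) == 1L)
    stop_oxy("oxydrift_degenerate", "all values tied: no ordering information")
  r <- rank(values, ties.method = "average")
  z <- qnorm(r / (n + 1))
  o <- order(values)
  xs <- values[o]; zs <- z[o]
  keep <- !duplicated(zs)
  inv <- stats::approxfun(zs[keep], xs[keep], rule = 2)
  list(values = z, inverse = inv)
}

# Long (participant, condition, value) -> wide matrix, complete cases only.
cohort_wide <- function(table) {
  stopifnot(all(c("participant", "condition", "value") %in% names(table)))
  conds <- unique(table$condition)
  cnt <- table(table$participant)
  complete <- names(cnt)[cnt == length(conds)]
  dropped <- setdiff(names(cnt), complete)
  tab <- table[table$participant %in% complete, ]
  Y <- matrix(NA_real_, length(complete), length(conds),
              dimnames = list(complete, conds))
  Y[cbind(match(as.character(tab$participant), complete),
          match(tab$condition, conds))] <- tab$value
  if (anyNA(Y)) stop_oxy("oxydrift_format", "duplicated or missing cells")
  attr(Y, "dropped") <- dropped
  Y
}

# Orthonormal contrast basis (k x (k-1)) orthogonal to the unit vector.
ortho_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

#' One-way repeated-measures ANOVA with sphericity handling
#'
#' Balanced one-way within-subject F test with partial eta squared.
#' Mauchly's test of sphericity is computed on the orthonormalized contrast
#' covariance; when it rejects at `sphericity_alpha`, Greenhouse-Geisser
#' epsilon-corrected degrees of freedom are used for the p value. Pairwise
#' paired t tests with Bonferroni-adjusted p values and Cohen's d (of the
#' paired differences) accompany the omnibus test.
#'
#' @param table Long data frame with columns `participant`, `condition`,
#'   `value`; must be complete after dropping incomplete participants.
#' @param alpha Decision level for the omnibus test (default .02).
#' @param sphericity_alpha Level of Mauchly's gate (default .05).
#' @return Object of class `oxy_test`: `method`, `statistic` (F), `df`,
#'   `df_corrected`, `p`, `effect_size` (partial eta squared), `mauchly_w`,
#'   `mauchly_p`, `gg_epsilon`, `gg_applied`, `pairwise` (data frame),
#'   `decision`, `dropped`.
#' @export
rm_anova <- function(table, alpha = 0.02, sphericity_alpha = 0.05) {
  Y <- cohort_wide(table)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2) stop_oxy("oxydrift_format", "need >= 2 conditions")
  if (n < 3) stop_oxy("oxydrift_short", "need >= 3 complete participants")
  grand <- mean(Y)
  cm <- colMeans(Y); rm_ <- rowMeans(Y)
  ss_cond <- n * sum((cm - grand)^2)
  ss_subj <- k * sum((rm_ - grand)^2)
  ss_err <- sum((Y - grand)^2) - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fst <- (ss_cond / df1) / (ss_err / df2)
  eta_p2 <- ss_cond / (ss_cond + ss_err)
  mauchly_w <- NA_real_; mauchly_p <- NA_real_
  eps <- 1; gg <- FALSE
  if (k > 2) {
    S <- stats::cov(Y %*% ortho_contrasts(k))
    p_ <- k - 1
    mauchly_w <- det(S) / (sum(diag(S)) / p_)^p_
    f <- 1 - (2 * p_^2 + p_ + 2) / (6 * p_ * (n - 1))
    chi2 <- -(n - 1) * f * log(mauchly_w)
    dfm <- p_ * (p_ + 1) / 2 - 1
    mauchly_p <- pchisq(chi2, dfm, lower.tail = FALSE)
    eps <- sum(diag(S))^2 / (p_ * sum(S^2))
    gg <- mauchly_p < sphericity_alpha
  }
  d1c <- if (gg) eps * df1 else df1
  d2c <- if (gg) eps * df2 else df2
  p <- pf(Fst, d1c, d2c, lower.tail = FALSE)
  prs <- utils::combn(colnames(Y), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(prs, function(pr) {
    d <- Y[, pr[1]] - Y[, pr[2]]
    tt <- t.test(d)
    data.frame(a = pr[1], b = pr[2], t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value,
               cohens_d = mean(d) / sd(d))
  }))
  pw$p_bonf <- pmin(1, pw$p_raw * nrow(pw))
  structure(list(method = "rm_anova", statistic = Fst,
                 df = c(df1, df2), df_corrected = c(d1c, d2c), p = p,
                 effect_size = eta_p2, effect_size_name = "partial_eta2",
                 mauchly_w = mauchly_w, mauchly_p = mauchly_p,
                 gg_epsilon = eps, gg_applied = gg, pairwise = pw,
                 decision = p < alpha, alpha = alpha,
                 dropped = attr(Y, "dropped")),
            class = "oxy_test")
}

#' Friedman rank-sum test with Kendall's W
#'
#' Friedman chi-squared statistic (tie-corrected, as in
#' [stats::friedman.test()]) with Kendall's coefficient of concordance
#' `W = chi2 / (n (k - 1))`. On tiny tie-free designs (n <= 6 blocks, k = 3
#' conditions) the p value is computed exactly by enumerating all within-
#' block rank permutations; otherwise the chi-squared approximation is used.
#'
#' @inheritParams rm_anova
#' @return Object of class `oxy_test` with `statistic` (chi2), `df`, `p`,
#'   `effect_size` (Kendall's W), `p_exact` flag.
#' @export
friedman_w <- function(table, alpha = 0.02) {
  Y <- cohort_wide(table)
  n <- nrow(Y); k <- ncol(Y)
  ft <- friedman.test(Y)
  chi2 <- unname(ft$statistic)
  if (is.nan(chi2)) chi2 <- 0   # every block fully tied: no concordance signal
  W <- chi2 / (n * (k - 1))
  no_ties <- all(apply(Y, 1, function(r) length(unique(r)) == k))
  exact <- FALSE
  p <- if (chi2 == 0) 1 else ft$p.value
  if (n <= 6 && k == 3 && no_ties) {
    p <- friedman_exact_p(Y)
    exact <- TRUE
  }
  structure(list(method = "friedman", statistic = chi2,
                 df = unname(ft$parameter), p = p, p_exact = exact,
                 effect_size = W, effect_size_name = "kendalls_w",
                 decision = p < alpha, alpha = alpha,
                 dropped = attr(Y, "dropped")),
            class = "oxy_test")
}

# Exact null distribution of the Friedman statistic for k = 3 by full
# enumeration of the 6^n equally likely within-block rank assignments.
friedman_exact_p <- function(Y) {
  n <- nrow(Y); k <- 3L
  obs <- unname(friedman.test(Y)$statistic)
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  grid <- as.matrix(expand.grid(rep(list(1:6), n)))
  R1 <- matrix(perms[grid, 1], nrow(grid), n)
  R2 <- matrix(perms[grid, 2], nrow(grid), n)
  R3 <- matrix(perms[grid, 3], nrow(grid), n)
  S1 <- rowSums(R1); S2 <- rowSums(R2); S3 <- rowSums(R3)
  chi_all <- 12 / (n * k * (k + 1)) * (S1^2 + S2^2 + S3^2) - 3 * n * (k + 1)
  mean(chi_all >= obs - 1e-9)
}

#' @export
print.oxy_test <- function(x, ...) {
  if (x$method == "rm_anova") {
    cat(sprintf("RM ANOVA: F(%.2f, %.2f) = %.3f, p = %.4g, eta_p^2 = %.3f%s\n",
                x$df_corrected[1], x$df_corrected[2], x$statistic, x$p,
                x$effect_size,
                if (x$gg_applied) sprintf(" [GG eps = %.3f]", x$gg_epsilon) else ""))
  } else if (x$method == "friedman") {
    cat(sprintf("Friedman: chi2(%d) = %.3f, p = %.4g%s, W = %.3f\n",
                x$df, x$statistic, x$p, if (isTRUE(x$p_exact)) " (exact)" else "",
                x$effect_size))
  } else {
    cat(sprintf("%s: stat = %.3f, p = %.4g\n", x$method, x$statistic, x$p))
  }
  invisible(x)
}

#' Paired equivalence test (TOST)
#'
#' Two one-sided paired t tests against equivalence bounds expressed in
#' Cohen's d units and converted to raw units through the SD of the paired
#' differences. Equivalence is claimed only when both one-sided tests are
#' significant at `alpha`. Hedges' g (small-sample corrected d of the paired
#' difference) is reported.
#'
#' @param x,y Paired samples (equal length, n >= 3).
#' @param d_bound Symmetric equivalence bound in Cohen's d units (> 0).
#' @param alpha One-sided level for each test (default .02).
#' @return List with `t_lower`, `t_upper`, `p_lower`, `p_upper`,
#'   `equivalent`, `hedges_g`, `bound_raw`, `df`.
#' @export
tost_paired <- function(x, y, d_bound, alpha = 0.02) {
  stopifnot(length(x) == length(y), length(x) >= 3, d_bound > 0)
  d <- x - y
  sdd <- sd(d)
  if (sdd == 0)
    stop_oxy("oxydrift_degenerate", "zero-variance differences")
  n <- length(d)
  se <- sdd / sqrt(n)
  bound <- d_bound * sdd
  t_lower <- (mean(d) + bound) / se     # H0: mean <= -bound
  t_upper <- (mean(d) - bound) / se     # H0: mean >= +bound
  p_lower <- pt(t_lower, n - 1, lower.tail = FALSE)
  p_upper <- pt(t_upper, n - 1, lower.tail = TRUE)
  dz <- mean(d) / sdd
  g <- dz * (1 - 3 / (4 * (n - 1) - 1))
  list(t_lower = t_lower, t_upper = t_upper,
       p_lower = p_lower, p_upper = p_upper,
       equivalent = max(p_lower, p_upper) < alpha,
       hedges_g = g, bound_raw = bound, df = n - 1)
}

#' Pearson correlation with confidence interval
#'
#' r, two-sided p from the t transform, and a Fisher-z confidence interval.
#'
#' @param x,y Numeric vectors, n >= 4, nonzero variance.
#' @param conf Confidence level.
#' @return List with `r`, `p`, `ci` (length 2), `n`.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  if (length(x) < 4) stop_oxy("oxydrift_short", "need n >= 4")
  if (sd(x) == 0 || sd(y) == 0)
    stop_oxy("oxydrift_degenerate", "zero variance")
  ct <- cor.test(x, y, conf.level = conf)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int), n = length(x))
}

#' Standard univariate analysis pipeline for one outcome
#'
#' Screening and testing in the order used for cohort outcomes:
#' z-score screening with winsorization of flagged values, per-condition
#' Shapiro-Wilk normality checks, ordered quantile normalization when
#' normality is violated, and finally the omnibus test — repeated-measures
#' ANOVA when (possibly transformed) cells look normal, the Friedman test
#' when the violation resists the transformation. Every branch decision is
#' logged.
#'
#' @param table Long data frame (`participant`, `condition`, `value`).
#' @param alpha Omnibus decision level (default .02).
#' @param shapiro_alpha Per-cell normality level (default .05).
#' @param z_limit Winsorization limit.
#' @return List with `result` (an `oxy_test`), `method`, `transformed`,
#'   `n_winsorized`, `log` (character vector), `table` (the analyzed data).
#' @export
run_univariate_pipeline <- function(table, alpha = 0.02,
                                    shapiro_alpha = 0.05, z_limit = 3.29) {
  log <- character(0)
  flags <- zscore_screen(table$value, z_limit)
  n_w <- 0L
  if (any(flags)) {
    adj <- winsorize_to_limit(table$value, z_limit)
    n_w <- attr(adj, "n_adjusted")
    table$value <- as.numeric(adj)
    log <- c(log, sprintf("winsorized %d outlier(s) beyond |z| = %g", n_w, z_limit))
  } else log <- c(log, "no univariate outliers")
  cell_normal <- function(tab) {
    ps <- vapply(split(tab$value, tab$condition),
                 function(v) shapiro.test(v)$p.value, numeric(1))
    all(ps >= shapiro_alpha)
  }
  transformed <- FALSE
  if (!cell_normal(table)) {
    log <- c(log, "normality violated; ordered quantile normalization applied")
    table$value <- orq_transform(table$value)$values
    transformed <- TRUE
    if (!cell_normal(table)) {
      log <- c(log, "violation resistant to transformation; Friedman branch")
      res <- friedman_w(table, alpha)
      return(list(result = res, method = "friedman", transformed = TRUE,
                  n_winsorized = n_w, log = log, table = table))
    }
  } else log <- c(log, "normality satisfied in every cell")
  res <- rm_anova(table, alpha)
  if (res$gg_applied)
    log <- c(log, sprintf("sphericity violated (Mauchly p = %.3g); GG correction",
                          res$mauchly_p))
  list(result = res, method = "rm_anova", transformed = transformed,
       n_winsorized = n_w, log = log, table = table)
}
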