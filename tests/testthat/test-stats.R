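test_that("z-score screening flags constructed outliers only", {
  v <- withr::with_seed(1, c(rnorm(35, 0, 0.5), 10))
  flags <- zscore_screen(v)
  expect_true(flags[36])
  expect_equal(sum(flags), 1)
  expect_false(any(zscore_screen(rep(2, 10))))
  expect_error(zscore_screen(c(1, 2)), class = "oxydrift_short")
})

test_that("false-flag rate of the 3.29 screen matches the normal closed form", {
  cnt <- vapply(1:2000, function(s)
    sum(zscore_screen(withr::with_seed(s, rnorm(36)))), numeric(1))
  # E[count] ~ 36 * 2 * pnorm(-3.29) ~ 0.036 (slightly less with sample mean/SD)
  expect_lt(mean(cnt), 0.08)
})

test_that("winsorization caps every z at the limit and preserves order", {
  v <- withr::with_seed(2, c(rnorm(34), 8, -9))
  w <- winsorize_to_limit(v)
  z <- (w - mean(w)) / sd(w)
  expect_lte(max(abs(z)), 3.29 + 1e-9)
  expect_equal(rank(w, ties.method = "min"), rank(v, ties.method = "min"))
  expect_gte(attr(w, "n_adjusted"), 1)
  # clean data pass through untouched
  v0 <- withr::with_seed(3, rnorm(36))
  w0 <- winsorize_to_limit(v0)
  expect_equal(as.numeric(w0), v0)
  expect_equal(attr(w0, "n_adjusted"), 0L)
  # symmetric extremes stay symmetric
  vs <- c(seq(-1, 1, length.out = 30), 20, -20)
  ws <- winsorize_to_limit(vs)
  expect_equal(mean(ws), mean(vs[1:30]) * 30 / 32 + 0, tolerance = 1e-9)
  expect_equal(ws[31], -ws[32], tolerance = 1e-9)
})

test_that("ordered quantile normalization is rank-preserving and invertible", {
  x <- withr::with_seed(4, rlnorm(36))
  tr <- orq_transform(x)
  expect_equal(order(tr$values), order(x))
  expect_equal(tr$inverse(tr$values), x, tolerance = 1e-9)
  # ties map to identical outputs
  xt <- c(1, 2, 2, 3)
  trt <- orq_transform(xt)
  expect_equal(trt$values[2], trt$values[3])
  expect_error(orq_transform(rep(1, 5)), class = "oxydrift_degenerate")
  # the transform of a sorted sample is strictly increasing
  expect_true(all(diff(orq_transform(sort(x))$values) > 0))
})

test_that("RM ANOVA reduces to the squared paired t for two conditions", {
  Y <- withr::with_seed(5, matrix(rnorm(40), 20, 2,
                                  dimnames = list(NULL, c("a", "b"))))
  r <- rm_anova(long_table(Y))
  tt <- t.test(Y[, 1], Y[, 2], paired = TRUE)
  expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(r$p, tt$p.value, tolerance = 1e-9)
})

test_that("RM ANOVA agrees with the base-R mlm machinery", {
  Y <- withr::with_seed(6, {
    m <- matrix(rnorm(60), 20, 3)
    m[, 2] <- m[, 2] * 2 + 0.5 * m[, 1]   # break sphericity
    colnames(m) <- c("a", "b", "c")
    m
  })
  r <- rm_anova(long_table(Y))
  fit <- lm(Y ~ 1)
  mt <- stats::mauchly.test(fit, X = ~1)
  expect_equal(r$mauchly_w, unname(mt$statistic), tolerance = 1e-9)
  expect_equal(r$mauchly_p, mt$p.value, tolerance = 1e-9)
  df <- data.frame(y = as.vector(Y), s = factor(rep(1:20, 3)),
                   c = factor(rep(1:3, each = 20)))
  av <- summary(stats::aov(y ~ c + Error(s / c), df))[[2]][[1]]
  expect_equal(r$statistic, av[1, "F value"], tolerance = 1e-9)
  expect_equal(pf(r$statistic, r$df[1], r$df[2], lower.tail = FALSE),
               av[1, "Pr(>F)"], tolerance = 1e-9)
  # partial eta squared from the same table
  expect_equal(r$effect_size,
               av[1, "Sum Sq"] / (av[1, "Sum Sq"] + av[2, "Sum Sq"]),
               tolerance = 1e-9)
})

test_that("Greenhouse-Geisser correction is gated on Mauchly", {
  # strongly heteroscedastic contrasts -> GG applied, p computed on eps-df
  Y <- withr::with_seed(7, {
    m <- matrix(rnorm(90), 30, 3)
    m[, 3] <- m[, 3] * 6
    colnames(m) <- c("a", "b", "c")
    m
  })
  r <- rm_anova(long_table(Y))
  expect_true(r$gg_applied)
  expect_lt(r$gg_epsilon, 1)
  expect_equal(r$p, pf(r$statistic, r$gg_epsilon * r$df[1],
                       r$gg_epsilon * r$df[2], lower.tail = FALSE),
               tolerance = 1e-12)
  # near-spherical data -> no correction
  Y2 <- withr::with_seed(8, matrix(rnorm(90), 30, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  expect_false(rm_anova(long_table(Y2))$gg_applied)
})

test_that("pairwise comparisons carry Bonferroni adjustment and d", {
  Y <- withr::with_seed(9, matrix(rnorm(60), 20, 3,
                                  dimnames = list(NULL, c("a", "b", "c"))))
  r <- rm_anova(long_table(Y))
  expect_equal(nrow(r$pairwise), 3)
  expect_equal(r$pairwise$p_bonf, pmin(1, r$pairwise$p_raw * 3))
  d12 <- Y[, "a"] - Y[, "b"]
  expect_equal(r$pairwise$cohens_d[1], mean(d12) / sd(d12), tolerance = 1e-12)
})

test_that("incomplete participants are dropped before the within-subject fit", {
  Y <- withr::with_seed(10, matrix(rnorm(30), 10, 3,
                                   dimnames = list(NULL, c("a", "b", "c"))))
  tab <- long_table(Y)
  tab <- tab[!(tab$participant == 3 & tab$condition == "b"), ]
  r <- rm_anova(tab)
  expect_equal(r$dropped, "3")
  r_ref <- rm_anova(long_table(Y[-3, ]))
  expect_equal(r$statistic, r_ref$statistic, tolerance = 1e-12)
})

test_that("Friedman matches brute-force rank computation and exact enumeration", {
  for (s in 1:5) {
    n <- sample(4:6, 1)
    Y <- withr::with_seed(s, matrix(rnorm(n * 3), n, 3,
                                    dimnames = list(NULL, c("a", "b", "c"))))
    r <- friedman_w(long_table(Y))
    # brute-force statistic from the rank definition (tie-free data)
    R <- t(apply(Y, 1, rank))
    chi_bf <- 12 / (n * 3 * 4) * sum(colSums(R)^2) - 3 * n * 4
    expect_equal(r$statistic, chi_bf, tolerance = 1e-9)
    expect_true(r$p_exact)
    # Monte-Carlo permutation oracle for the exact p value
    mc <- withr::with_seed(100 + s, {
      reps <- vapply(1:4000, function(i) {
        Rp <- t(apply(matrix(runif(n * 3), n, 3), 1, rank))
        12 / (n * 3 * 4) * sum(colSums(Rp)^2) - 3 * n * 4
      }, numeric(1))
      mean(reps >= chi_bf - 1e-9)
    })
    expect_lt(abs(r$p - mc), 0.035)
  }
})

test_that("Kendall's W hits its bounds for perfect and absent concordance", {
  # identical ranking in every block
  Y <- matrix(rep(c(1, 2, 3), each = 6), 6, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  r <- friedman_w(long_table(Y + withr::with_seed(11, matrix(runif(18, 0, 0.1), 6, 3)) * 0))
  expect_equal(r$effect_size, 1, tolerance = 1e-9)
  # fully tied blocks carry no concordance signal
  Yt <- matrix(5, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  rt <- friedman_w(long_table(Yt))
  expect_equal(rt$statistic, 0)
  expect_equal(rt$effect_size, 0)
  expect_equal(rt$p, 1)
})

test_that("paired TOST follows its definition and is monotone in the bound", {
  x <- withr::with_seed(12, rnorm(36))
  y <- x + withr::with_seed(13, rnorm(36, 0, 1))
  r <- tost_paired(x, y, d_bound = 0.62)
  d <- x - y
  se <- sd(d) / sqrt(36)
  expect_equal(r$t_lower, (mean(d) + 0.62 * sd(d)) / se, tolerance = 1e-12)
  expect_equal(r$p_upper, pt((mean(d) - 0.62 * sd(d)) / se, 35), tolerance = 1e-12)
  dz <- mean(d) / sd(d)
  expect_equal(r$hedges_g, dz * (1 - 3 / (4 * 35 - 1)), tolerance = 1e-12)
  # widening the bound never flips equivalent -> not equivalent
  eqs <- vapply(c(0.1, 0.3, 0.62, 1, 2, 4),
                function(b) tost_paired(x, y, b)$equivalent, logical(1))
  expect_true(all(diff(eqs) >= 0))
  expect_error(tost_paired(x, x, 0.62), class = "oxydrift_degenerate")
})

test_that("Pearson correlation wraps the t test and Fisher interval", {
  x <- 1:20
  expect_equal(pearson_ci(x, 2 * x + 1)$r, 1, tolerance = 1e-9)
  xy <- withr::with_seed(14, {
    a <- rnorm(108)
    list(a = a, b = 0.5 * a + rnorm(108, 0, sqrt(0.75)))
  })
  r <- pearson_ci(xy$a, xy$b)
  z <- atanh(r$r); se <- 1 / sqrt(108 - 3)
  expect_equal(r$ci, tanh(c(z - qnorm(0.975) * se, z + qnorm(0.975) * se)),
               tolerance = 1e-6)
  expect_error(pearson_ci(1:3, 2:4), class = "oxydrift_short")
  expect_error(pearson_ci(rep(1, 10), 1:10), class = "oxydrift_degenerate")
})

test_that("the univariate pipeline takes the documented branches", {
  # clean normal data -> RM ANOVA branch, no transformation
  tab <- generate_cohort(cohort_spec(n_subjects = 36, seed = 15))
  out <- run_univariate_pipeline(tab)
  expect_equal(out$method, "rm_anova")
  expect_false(out$transformed)
  # boundary pile-up resistant to normalization -> Friedman branch
  pile <- withr::with_seed(16, c(pmin(100, 100 - abs(rnorm(36, 0, 0.1))),
                                 runif(36, 40, 100),
                                 pmin(100, 100 - abs(rnorm(36, 0, 0.5)))))
  tabp <- data.frame(participant = rep(1:36, 3),
                     condition = rep(c("a", "b", "c"), each = 36),
                     value = pile)
  outp <- run_univariate_pipeline(tabp)
  expect_equal(outp$method, "friedman")
  expect_true(outp$transformed)
  # a single gross outlier is winsorized before testing and logged
  tab2 <- tab
  tab2$value[1] <- 50
  out2 <- run_univariate_pipeline(tab2)
  expect_gte(out2$n_winsorized, 1)
  expect_true(any(grepl("winsorized", out2$log)))
  expect_lte(max(abs(scale(out2$table$value))), 3.29 + 1e-6)
})
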