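toy_oneway <- function(seed = 1, n = 3, k = 3, effects = c(0, 1, 2)) {
  if (!is.null(seed)) set.seed(seed)
  expand <- expand.grid(subject = factor(seq_len(n)),
                        condition = letters[seq_len(k)])
  expand$value <- stats::rnorm(nrow(expand)) +
    effects[as.integer(expand$condition)] +
    stats::rnorm(n)[as.integer(expand$subject)]
  expand
}

test_that("one-way RM F matches the longhand sums-of-squares oracle", {
  for (seed in 1:4) {
    tab <- toy_oneway(seed)
    fit <- rm_anova_oneway(tab)
    oracle <- rm_oneway_oracle(tab$value, tab$subject, tab$condition)
    expect_equal(fit$effects$F, oracle$F, tolerance = 1e-8)
    expect_equal(c(fit$effects$df_num, fit$effects$df_den), oracle$df)
  }
})

test_that("one-way RM F agrees with aov's within-subject stratum", {
  tab <- toy_oneway(7, n = 6)
  fit <- rm_anova_oneway(tab)
  a <- summary(stats::aov(value ~ condition + Error(subject / condition),
                          data = tab))
  f_aov <- a[["Error: subject:condition"]][[1]]["condition", "F value"]
  expect_equal(fit$effects$F, f_aov, tolerance = 1e-8)
})

test_that("degenerate one-way cases behave", {
  tab <- toy_oneway(1)
  tab$value <- 5
  expect_equal(rm_anova_oneway(tab)$effects$F, 0)
  expect_error(rm_anova_oneway(toy_oneway(1)[-1, ]), "unbalanced")
})

test_that("two-condition RM F equals the squared paired t", {
  set.seed(9)
  tab <- expand.grid(subject = factor(1:10), condition = c("a", "b"))
  tab$value <- stats::rnorm(20) + (tab$condition == "b") * 0.8
  fit <- rm_anova_oneway(tab)
  d <- tab$value[tab$condition == "b"] - tab$value[tab$condition == "a"]
  tt <- stats::t.test(d)
  expect_equal(fit$effects$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(fit$effects$p, tt$p.value, tolerance = 1e-8)
})

test_that("two-way RM ANOVA has the pooled error df and matches its oracle", {
  set.seed(12)
  n <- 35
  tab <- expand.grid(subject = factor(1:n),
                     condition = c("harmonic", "inharmonic", "changing"),
                     deviance = c("standard", "deviant"))
  tab$value <- stats::rnorm(nrow(tab))
  fit <- rm_anova_twoway(tab)
  expect_equal(unique(fit$effects$df_den), 170)  # n*k*m - n - 2 - 1 - 2 - 1
  expect_equal(fit$effects$df_num, c(2, 1, 2))

  # longhand decomposition on a small table
  set.seed(3)
  small <- expand.grid(subject = factor(1:3), condition = c("a", "b", "c"),
                       deviance = c("s", "d"))
  small$value <- stats::rnorm(18)
  f2 <- rm_anova_twoway(small)
  cell <- tapply(small$value,
                 list(small$subject, small$condition, small$deviance), mean)
  g <- mean(cell)
  ss_cond <- 3 * 2 * sum((apply(cell, 2, mean) - g)^2)
  ss_dev <- 3 * 3 * sum((apply(cell, 3, mean) - g)^2)
  cd <- apply(cell, c(2, 3), mean)
  ss_int <- 3 * sum((cd - outer(apply(cell, 2, mean), apply(cell, 3, mean),
                                `+`) + g)^2)
  ss_subj <- 6 * sum((apply(cell, 1, mean) - g)^2)
  ss_err <- sum((cell - g)^2) - ss_cond - ss_dev - ss_int - ss_subj
  df_err <- (18 - 1) - (3 - 1) - 2 - 1 - 2
  expect_equal(f2$effects$F[1], (ss_cond / 2) / (ss_err / df_err),
               tolerance = 1e-8)
  expect_equal(f2$effects$F[2], (ss_dev / 1) / (ss_err / df_err),
               tolerance = 1e-8)
  expect_equal(f2$effects$F[3], (ss_int / 2) / (ss_err / df_err),
               tolerance = 1e-8)
})

test_that("additive noise-free two-way table has zero interaction F", {
  tab <- expand.grid(subject = factor(1:5), condition = c("a", "b", "c"),
                     deviance = c("s", "d"))
  tab$value <- as.integer(tab$condition) + 2 * (tab$deviance == "d") +
    0.3 * as.integer(tab$subject)
  fit <- rm_anova_twoway(tab)
  expect_lt(fit$effects$F[3], 1e-20)
})

test_that("Tukey contrasts are antisymmetric and null on equal means", {
  tab <- toy_oneway(2, n = 8, effects = c(0, 0, 0))
  # remove condition means exactly: estimates 0 while the error term stays
  cm <- tapply(tab$value, tab$condition, mean)
  tab$value <- tab$value - cm[tab$condition]
  ct <- tukey_contrasts(tab)
  expect_true(all(abs(ct$estimate) < 1e-12))
  expect_true(all(ct$p_adjusted > 0.999))

  tab2 <- toy_oneway(4, n = 10, effects = c(0, 1.5, 3))
  ct2 <- tukey_contrasts(tab2)
  means <- tapply(tab2$value, tab2$condition, mean)
  expect_equal(ct2$estimate[ct2$pair == "a - b"],
               unname(means["a"] - means["b"]), tolerance = 1e-10)
  # Tukey-adjusted p never below the unadjusted pairwise p
  for (i in seq_len(nrow(ct2))) {
    p_unadj <- 2 * stats::pt(abs(ct2$t[i]), ct2$df[i], lower.tail = FALSE)
    expect_gte(ct2$p_adjusted[i] + 1e-12, p_unadj)
  }
})

test_that("Tukey contrasts agree with emmeans on a balanced table", {
  skip_if_not_installed("emmeans")
  skip_if_not_installed("lme4")
  tab <- toy_oneway(11, n = 12, effects = c(0, 0.8, 1.6))
  ct <- tukey_contrasts(tab)
  fit <- lme4::lmer(value ~ condition + (1 | subject), data = tab)
  em <- as.data.frame(emmeans::emmeans(fit, pairwise ~ condition)$contrasts)
  for (i in seq_len(nrow(em))) {
    pair <- gsub(" ", "", em$contrast[i])
    mine <- ct[gsub(" ", "", ct$pair) == pair, ]
    expect_equal(mine$estimate, em$estimate[i], tolerance = 1e-6)
    expect_equal(mine$SE, em$SE[i], tolerance = 1e-6)
    expect_equal(mine$p_adjusted, em$p.value[i], tolerance = 1e-5)
  }
})

test_that("model comparison statistic is null-calibrated and monotone", {
  # ~ chi-squared(2) under the null
  set.seed(77)
  stats_null <- vapply(1:1000, function(i) {
    tab <- toy_oneway(seed = NULL, n = 20, effects = c(0, 0, 0))
    model_comparison(tab)$statistic
  }, numeric(1))
  ks <- stats::ks.test(stats_null, "pchisq", 2)
  expect_gt(ks$p.value, 0.01)

  # grows with the injected effect under a fixed seed
  grow <- vapply(c(0, 0.5, 1, 2), function(e) {
    model_comparison(toy_oneway(5, n = 12, effects = c(0, e, e)))$statistic
  }, numeric(1))
  expect_true(all(diff(grow) > 0))

  # identical model fits (zero condition sum of squares) -> statistic 0
  tab <- toy_oneway(2, n = 6, effects = c(0, 0, 0))
  cm <- tapply(tab$value, tab$condition, mean)
  tab$value <- tab$value - cm[tab$condition]
  expect_equal(model_comparison(tab)$statistic, 0, tolerance = 1e-12)
})

test_that("power simulation is sized, monotone, and calibrated near N = 33", {
  pw0 <- power_simulation(effect_uv = 0, n_range = c(25, 33, 40),
                          n_sims = 600, seed = 42)
  mc_se <- sqrt(0.05 * 0.95 / 600)
  expect_true(all(abs(pw0$power - 0.05) < 3 * mc_se + 0.01))

  pw <- power_simulation(effect_uv = 1, n_range = seq(25, 40, by = 3),
                         n_sims = 600, seed = 43)
  fit <- stats::isoreg(pw$n, pw$power)
  expect_lt(mean(abs(fit$yf - pw$power)), 0.03)  # near-isotone in N
  expect_gt(pw$power[length(pw$power)], pw$power[1])
})

test_that("count error is the absolute difference and symmetric", {
  expect_equal(count_error(3, 3), 0)
  expect_equal(count_error(1, 5), 4)
  expect_equal(count_error(5, 1), count_error(1, 5))
  expect_equal(count_error(c(2, 7), c(4, 7)), c(2, 0))
})
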