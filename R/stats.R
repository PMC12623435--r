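#' One-way repeated-measures ANOVA (balanced)
#'
#' Classical within-subject decomposition for a balanced subject x
#' condition table: `F = MS_condition / MS_(condition x subject)` with
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom. For balanced data this is
#' exactly the condition test of the random-intercept linear mixed model;
#' unbalanced tables are rejected.
#'
#' @param table data.frame with columns `subject`, `condition`, `value`.
#' @return an object of class `rm_anova`: list with `effects` data.frame
#'   (`effect`, `F`, `df_num`, `df_den`, `p`), `means` (condition means),
#'   `mse` and `df_err` (error term used for contrasts), `n_subjects`,
#'   `rss_null`, `rss_full`.
#' @export
rm_anova_oneway <- function(table) {
  table <- check_balanced(table, c("subject", "condition"))
  n <- length(unique(table$subject))
  k <- length(unique(table$condition))
  cell <- tapply(table$value, list(table$subject, table$condition), mean)
  g <- mean(cell)
  ss_subj <- k * sum((rowMeans(cell) - g)^2)
  ss_cond <- n * sum((colMeans(cell) - g)^2)
  ss_tot <- sum((cell - g)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df_num <- k - 1
  df_den <- (k - 1) * (n - 1)
  ms_cond <- ss_cond / df_num
  mse <- ss_err / df_den
  Fv <- if (mse > 0) ms_cond / mse else 0
  structure(
    list(
      effects = data.frame(
        effect = "condition", F = Fv, df_num = df_num, df_den = df_den,
        p = stats::pf(Fv, df_num, df_den, lower.tail = FALSE)
      ),
      means = colMeans(cell), mse = mse, df_err = df_den, n_subjects = n,
      k = k, rss_null = ss_cond + ss_err, rss_full = ss_err
    ),
    class = "rm_anova"
  )
}

#' Two-way repeated-measures ANOVA with a pooled error term (balanced)
#'
#' Balanced subject x condition x deviance decomposition in which the three
#' fixed effects (condition, deviance, their interaction) share one pooled
#' within-subject error term, matching the reporting shape `F(2, 170)` for
#' 35 subjects in a 3 x 2 design: pooled error df
#' `= (n*k*m - 1) - (n-1) - (k-1) - (m-1) - (k-1)(m-1)`.
#'
#' @param table data.frame with columns `subject`, `condition`, `deviance`,
#'   `value`.
#' @return an `rm_anova` object; `effects` has one row per fixed effect.
#' @export
rm_anova_twoway <- function(table) {
  table <- check_balanced(table, c("subject", "condition", "deviance"))
  n <- length(unique(table$subject))
  k <- length(unique(table$condition))
  m <- length(unique(table$deviance))
  cell <- tapply(table$value,
                 list(table$subject, table$condition, table$deviance), mean)
  g <- mean(cell)
  subj_m <- apply(cell, 1, mean)
  cond_m <- apply(cell, 2, mean)
  dev_m <- apply(cell, 3, mean)
  cd_m <- apply(cell, c(2, 3), mean)
  ss_subj <- k * m * sum((subj_m - g)^2)
  ss_cond <- n * m * sum((cond_m - g)^2)
  ss_dev <- n * k * sum((dev_m - g)^2)
  ss_int <- n * sum((sweep(sweep(cd_m, 1, cond_m), 2, dev_m) + g)^2)
  ss_tot <- sum((cell - g)^2)
  ss_err <- ss_tot - ss_subj - ss_cond - ss_dev - ss_int
  df_err <- (n * k * m - 1) - (n - 1) - (k - 1) - (m - 1) - (k - 1) * (m - 1)
  mse <- ss_err / df_err
  eff <- data.frame(
    effect = c("condition", "deviance", "condition:deviance"),
    F = c(ss_cond / (k - 1), ss_dev / (m - 1),
          ss_int / ((k - 1) * (m - 1))) / mse,
    df_num = c(k - 1, m - 1, (k - 1) * (m - 1)),
    df_den = df_err
  )
  eff$p <- stats::pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  structure(
    list(effects = eff, means = cond_m, cell_means = cd_m, mse = mse,
         df_err = df_err, n_subjects = n, k = k, m = m,
         rss_null = ss_err + ss_cond + ss_dev + ss_int, rss_full = ss_err),
    class = "rm_anova"
  )
}

check_balanced <- function(table, factors) {
  stopifnot(all(c(factors, "value") %in% names(table)))
  counts <- table(table[factors])
  if (any(counts != 1)) {
    stop("unbalanced table: every subject must contribute every ",
         paste(factors[-1], collapse = " x "),
         " cell exactly once (no general mixed-model fit is attempted)")
  }
  table
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("<rm_anova>", x$n_subjects, "subjects\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %s: F(%d, %d) = %.2f, p = %.4g\n", eff$effect[i],
                eff$df_num[i], eff$df_den[i], eff$F[i], eff$p[i]))
  }
  invisible(x)
}

#' Tukey HSD contrasts of condition marginal means
#'
#' All pairwise differences of condition means with the standard error taken
#' from the ANOVA error term (`SE = sqrt(2 * MSE / n_per_mean)`) and
#' p-values from the studentized-range distribution with the error degrees
#' of freedom.
#'
#' @param table a balanced one-way table (see [rm_anova_oneway()]) or an
#'   `rm_anova` result from it.
#' @return data.frame of class `contrast_result`: `pair`, `estimate`, `SE`,
#'   `t`, `df`, `p_adjusted`.
#' @export
tukey_contrasts <- function(table) {
  fit <- if (inherits(table, "rm_anova")) table else rm_anova_oneway(table)
  means <- fit$means
  k <- length(means)
  n_per <- fit$n_subjects * (if (!is.null(fit$m)) fit$m else 1)
  se <- sqrt(2 * fit$mse / n_per)
  pairs <- utils::combn(names(means), 2)
  out <- data.frame(
    pair = apply(pairs, 2, paste, collapse = " - "),
    estimate = means[pairs[1, ]] - means[pairs[2, ]],
    SE = se, df = fit$df_err, stringsAsFactors = FALSE
  )
  out$t <- out$estimate / se
  out$p_adjusted <- stats::ptukey(abs(out$t) * sqrt(2), k, fit$df_err,
                                  lower.tail = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Compare the condition model against the null model
#'
#' Balanced-design analogue of a likelihood-ratio model comparison: the
#' statistic is `df_err * log(RSS_null / RSS_full)` (a Bartlett-style
#' df-corrected log RSS ratio), approximately chi-squared with `k - 1`
#' degrees of freedom under the null.
#'
#' @param table a balanced one-way table or `rm_anova` fit.
#' @return list with `statistic`, `df`, `p`, `rss_null`, `rss_full`.
#' @export
model_comparison <- function(table) {
  fit <- if (inherits(table, "rm_anova")) table else rm_anova_oneway(table)
  df <- fit$k - 1
  stat <- if (fit$rss_full > 0) {
    fit$df_err * log(fit$rss_null / fit$rss_full)
  } else {
    Inf
  }
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       rss_null = fit$rss_null, rss_full = fit$rss_full)
}

#' A-priori power simulation for the condition effect
#'
#' Simulates, for each candidate sample size, balanced one-way
#' within-subject datasets in which subject condition means are
#' `subject intercept + condition effect + residual`, tests the condition
#' effect with [rm_anova_oneway()], and reports the rejection fraction. The
#' effect enters as a difference between the harmonic and the other two
#' conditions (the working assumption being that the changing condition
#' does not differ from the inharmonic one).
#'
#' @param effect_uv condition effect in µV.
#' @param n_range integer vector of sample sizes to scan.
#' @param n_sims simulations per sample size.
#' @param subject_sd SD of the subject intercept (µV).
#' @param residual_sd SD of the residual per subject-condition mean (µV).
#' @param alpha test level.
#' @param target target power defining the minimal sample size.
#' @param seed optional RNG seed.
#' @return an object of class `power_curve`: data.frame (`n`, `power`,
#'   `n_sims`) with attributes `minimal_n`, `target`, `seed`.
#' @export
power_simulation <- function(effect_uv = 1, n_range = 25:40, n_sims = 2000,
                             subject_sd = 1.5, residual_sd = 1.5,
                             alpha = 0.05, target = 0.8, seed = NULL) {
  stopifnot(n_sims >= 1)
  cond_means <- c(harmonic = 0, inharmonic = effect_uv, changing = effect_uv)
  k <- length(cond_means)
  crit <- function(n) stats::qf(1 - alpha, k - 1, (k - 1) * (n - 1))
  power <- with_seed(seed, vapply(n_range, function(n) {
    cv <- crit(n)
    hits <- 0L
    for (b in seq_len(n_sims)) {
      subj <- stats::rnorm(n, 0, subject_sd)
      y <- outer(subj, cond_means, `+`) +
        matrix(stats::rnorm(n * k, 0, residual_sd), n, k)
      # inline balanced one-way RM F (identical to rm_anova_oneway)
      g <- mean(y)
      ss_subj <- k * sum((rowMeans(y) - g)^2)
      ss_cond <- n * sum((colMeans(y) - g)^2)
      ss_err <- sum((y - g)^2) - ss_subj - ss_cond
      Fv <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
      if (Fv > cv) hits <- hits + 1L
    }
    hits / n_sims
  }, numeric(1)))
  out <- data.frame(n = n_range, power = power, n_sims = n_sims)
  reached <- out$n[out$power >= target]
  attr(out, "minimal_n") <- if (length(reached)) min(reached) else NA_integer_
  attr(out, "target") <- target
  attr(out, "seed") <- seed
  class(out) <- c("power_curve", "data.frame")
  out
}

#' Absolute deviant-count error
#'
#' `|reported - truth|`, the counting-error metric of the behavioral task.
#'
#' @param reported,truth non-negative integer counts.
#' @return non-negative integer (vectorized).
#' @export
count_error <- function(reported, truth) {
  stopifnot(all(reported >= 0), all(truth >= 0))
  abs(reported - truth)
}
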