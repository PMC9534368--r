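# Reporting statistics: Pearson chi-squared, gender-controlled one-way
# ANOVA with omega-squared, Scheffe and Fisher LSD pairwise comparisons,
# Spearman correlation with a Fisher-z confidence interval.

#' Pearson chi-squared test on a contingency table
#'
#' Classic `sum((O - E)^2 / E)` with expected counts from the product of
#' the margins; no continuity correction at any table size, so printed
#' 2 x k statistics are reproduced exactly. Zero row or column margins
#' are rejected with the offending label named.
#'
#' @param counts Integer matrix, at least 2 x 2, ideally with dimnames.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0)) stop("negative counts")
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0))
    stop("zero row margin: ",
         paste(if (is.null(rownames(counts))) which(rs == 0) else
           rownames(counts)[rs == 0], collapse = ", "))
  if (any(cs == 0))
    stop("zero column margin: ",
         paste(if (is.null(colnames(counts))) which(cs == 0) else
           colnames(counts)[cs == 0], collapse = ", "))
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

magnitude_label <- function(omega_sq) {
  if (omega_sq >= 0.14) "LARGE"
  else if (omega_sq >= 0.06) "MEDIUM"
  else if (omega_sq >= 0.01) "SMALL"
  else "NEGLIGIBLE"
}

#' One-way ANOVA controlling for gender
#'
#' Fits the additive linear model `value ~ group + gender` and reports the
#' group effect from Type II sums of squares (the group SS is the residual
#' SS of `value ~ gender` minus that of the full model), with the error
#' term from the full model. The effect size is
#' `omega^2 = (SS_group - df_group * MS_error) / (SS_total + MS_error)`,
#' labelled small/medium/large at the 0.01/0.06/0.14 thresholds.
#'
#' @param values Numeric response.
#' @param group Factor (or coercible) with >= 2 non-empty levels.
#' @param gender Binary factor; must not be confounded with `group`.
#' @return List of class `cpm_anova`: `F_group`, `df_group`, `df_error`,
#'   `p_value`, `ss_group`, `ms_error`, `omega_sq`, `magnitude`, `model`.
#' @export
anova_gender_controlled <- function(values, group, gender) {
  group <- droplevels(as.factor(group))
  gender <- droplevels(as.factor(gender))
  stopifnot(length(values) == length(group),
            length(values) == length(gender))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (nlevels(gender) != 2L) stop("gender must be binary")
  full <- stats::lm(values ~ group + gender)
  if (anyNA(stats::coef(full)))
    stop("group and gender are confounded: model is rank deficient")
  reduced <- stats::lm(values ~ gender)
  ss_group <- stats::deviance(reduced) - stats::deviance(full)
  df_group <- nlevels(group) - 1L
  df_error <- stats::df.residual(full)
  ms_error <- stats::deviance(full) / df_error
  F_group <- (ss_group / df_group) / ms_error
  ss_total <- sum((values - mean(values))^2)
  omega_sq <- (ss_group - df_group * ms_error) / (ss_total + ms_error)
  structure(list(F_group = F_group, df_group = df_group,
                 df_error = df_error,
                 p_value = stats::pf(F_group, df_group, df_error,
                                     lower.tail = FALSE),
                 ss_group = ss_group, ms_error = ms_error,
                 omega_sq = omega_sq,
                 magnitude = magnitude_label(omega_sq),
                 model = full),
            class = "cpm_anova")
}

#' @export
print.cpm_anova <- function(x, ...) {
  cat(sprintf("Gender-controlled one-way ANOVA: F(%d, %d) = %.2f, p = %.4g, omega^2 = %.3f (%s)\n",
              x$df_group, x$df_error, x$F_group, x$p_value, x$omega_sq,
              tolower(x$magnitude)))
  invisible(x)
}

# Gender-adjusted group means: model predictions per group averaged over
# the observed gender distribution.
adjusted_group_means <- function(model, group, gender) {
  group <- droplevels(as.factor(group))
  gender <- droplevels(as.factor(gender))
  w <- table(gender) / length(gender)
  grid <- expand.grid(group = levels(group), gender = levels(gender))
  pred <- stats::predict(model, newdata = grid)
  means <- tapply(pred * w[as.character(grid$gender)], grid$group, sum)
  means[levels(group)]
}

#' Scheffe post hoc comparisons after the gender-controlled ANOVA
#'
#' For each pair of groups the statistic is
#' `S = diff^2 / (MS_error * (1/n_a + 1/n_b))` with `diff` the
#' gender-adjusted mean difference and `MS_error` from the full model;
#' `p = 1 - F_cdf(S / (k - 1); k - 1, df_error)`. Valid simultaneously
#' for all contrasts, hence conservative relative to Fisher LSD.
#'
#' @inheritParams anova_gender_controlled
#' @return Data frame with columns `group_a`, `group_b`, `diff`,
#'   `p_value`; attribute `method = "SCHEFFE"`.
#' @export
scheffe_pairwise <- function(values, group, gender) {
  group <- droplevels(as.factor(group))
  fit <- anova_gender_controlled(values, group, gender)
  means <- adjusted_group_means(fit$model, group, gender)
  n_by <- table(group)
  k <- nlevels(group)
  pairs <- utils::combn(levels(group), 2)
  res <- apply(pairs, 2, function(p) {
    diff <- unname(means[p[1]] - means[p[2]])
    S <- diff^2 / (fit$ms_error * (1 / n_by[[p[1]]] + 1 / n_by[[p[2]]]))
    c(diff = diff,
      p_value = stats::pf(S / (k - 1), k - 1, fit$df_error,
                          lower.tail = FALSE))
  })
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    diff = res["diff", ], p_value = res["p_value", ],
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "SCHEFFE"
  out
}

#' Fisher LSD pairwise comparisons
#'
#' Unadjusted pairwise t tests using the pooled mean squared error of the
#' one-way model.
#'
#' @param values Numeric response.
#' @param group Factor with >= 2 levels, none singleton.
#' @return Data frame with columns `group_a`, `group_b`, `diff`,
#'   `p_value`; attribute `method = "FISHER_LSD"`.
#' @export
fisher_lsd_pairwise <- function(values, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  n_by <- table(group)
  if (any(n_by < 2L))
    stop("singleton group(s): ",
         paste(names(n_by)[n_by < 2L], collapse = ", "))
  fit <- stats::lm(values ~ group)
  mse <- stats::deviance(fit) / stats::df.residual(fit)
  df_error <- stats::df.residual(fit)
  means <- tapply(values, group, mean)
  pairs <- utils::combn(levels(group), 2)
  res <- apply(pairs, 2, function(p) {
    diff <- unname(means[p[1]] - means[p[2]])
    se <- sqrt(mse * (1 / n_by[[p[1]]] + 1 / n_by[[p[2]]]))
    tt <- diff / se
    c(diff = diff, p_value = 2 * stats::pt(-abs(tt), df_error))
  })
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    diff = res["diff", ], p_value = res["p_value", ],
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "FISHER_LSD"
  out
}

#' Spearman correlation with a 95% confidence interval
#'
#' Rank correlation (average ranks for ties) with a Fieller-Hartley-
#' Pearson interval: Fisher z transform of rho with standard error
#' `sqrt(1.06 / (n - 3))`, back-transformed. Two-sided p via the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @param alpha Two-sided significance level (default 0.05).
#' @return List with `rho`, `ci95` (low, high), `p_value`, `n`.
#' @export
spearman_ci <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rho <- stats::cor(rank(x), rank(y))
  z <- atanh(rho)
  se <- sqrt(1.06 / (n - 3))
  q <- stats::qnorm(1 - alpha / 2)
  ci <- tanh(c(z - q * se, z + q * se))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, ci95 = ci, p_value = p, n = n)
}
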