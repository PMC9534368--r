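# Closed-form one-way ANOVA decomposition used as an independent oracle.
oneway_decomp <- function(values, group) {
  group <- as.factor(group)
  gm <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  list(ssb = ssb, ssw = ssw, k = nlevels(group), n = length(values))
}

test_that("Pearson chi-squared matches a brute-force double loop", {
  set.seed(21)
  for (i in 1:20) {
    tab <- matrix(stats::rpois(9, 12) + 1, 3, 3)
    res <- pearson_chi2(tab)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    brute <- 0
    for (r in 1:3) for (c in 1:3)
      brute <- brute + (tab[r, c] - expected[r, c])^2 / expected[r, c]
    expect_equal(res$statistic, brute, tolerance = 1e-10)
    expect_equal(res$df, 4)
  }
})

test_that("chi-squared is zero under exact independence and invariant to layout", {
  prop <- outer(c(10, 20, 30), c(1, 2)) # proportional rows
  expect_equal(pearson_chi2(prop)$statistic, 0, tolerance = 1e-12)
  set.seed(22)
  tab <- matrix(stats::rpois(12, 9) + 1, 3, 4)
  s <- pearson_chi2(tab)$statistic
  expect_equal(pearson_chi2(tab[c(2, 3, 1), c(4, 1, 3, 2)])$statistic, s)
  expect_equal(pearson_chi2(t(tab))$statistic, s)
  # zero margins are rejected with the offending label named
  bad <- matrix(c(0, 5, 0, 7), 2, 2, dimnames = list(c("u", "v"), NULL))
  expect_error(pearson_chi2(bad), "u")
})

test_that("gender-controlled ANOVA reduces to the one-way decomposition under balance", {
  # mirrored genders within each group: fitted gender effect is exactly 0,
  # so the Type II group SS equals the classical between-group SS and the
  # F statistic equals the one-way F evaluated with the adjusted model's
  # error df
  set.seed(31)
  g <- rep(c("a", "b", "c"), each = 20)
  per_group <- split(stats::rnorm(30), rep(1:3, each = 10))
  values <- unlist(lapply(per_group, function(v) c(v, v))) # F copy + M copy
  gender <- rep(rep(c("F", "M"), each = 10), times = 3)
  fit <- anova_gender_controlled(values, g, gender)
  o <- oneway_decomp(values, g)
  F_oracle <- (o$ssb / (o$k - 1)) / (o$ssw / (o$n - o$k - 1))
  expect_equal(fit$F_group, F_oracle, tolerance = 1e-8)
  expect_equal(fit$ss_group, o$ssb, tolerance = 1e-8)
  expect_equal(fit$df_error, o$n - o$k - 1)
})

test_that("ANOVA handles null effects, confounding, and unbalanced Type II SS", {
  set.seed(32)
  # equal group means, balanced: F near zero, omega^2 non-positive
  v <- rep(c(1, 2, 3, 4), times = 3)
  g <- rep(c("a", "b", "c"), each = 4)
  gender <- rep(c("F", "M"), 6)
  fit <- anova_gender_controlled(v, g, gender)
  expect_lt(fit$F_group, 1e-20)
  expect_lte(fit$omega_sq, 0)
  expect_equal(fit$magnitude, "NEGLIGIBLE")
  # group coincident with gender is confounded
  expect_error(anova_gender_controlled(stats::rnorm(10),
                                       rep(c("a", "b"), each = 5),
                                       rep(c("F", "M"), each = 5)),
               "confounded")
  # unbalanced fixture: Type II SS equals the nested-model RSS difference
  # computed independently via explicit least squares
  n <- c(7, 12, 9)
  g <- rep(c("a", "b", "c"), times = n)
  gender <- c(rep(c("F", "M"), c(5, 2)), rep(c("F", "M"), c(4, 8)),
              rep(c("F", "M"), c(6, 3)))
  v <- stats::rnorm(sum(n), mean = c(a = 0, b = 1, c = 3)[g] +
                      ifelse(gender == "F", 0, 0.7))
  proj_rss <- function(X, y) {
    beta <- qr.solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% beta)^2)
  }
  Xg <- cbind(1, gender == "M")
  Xf <- cbind(Xg, g == "b", g == "c")
  ss_oracle <- proj_rss(Xg, v) - proj_rss(Xf, v)
  fit <- anova_gender_controlled(v, g, gender)
  expect_equal(fit$ss_group, ss_oracle, tolerance = 1e-8)
  expect_equal(fit$ms_error, proj_rss(Xf, v) / (sum(n) - 4),
               tolerance = 1e-8)
})

test_that("omega squared never exceeds eta squared", {
  set.seed(33)
  for (i in 1:25) {
    g <- sample(c("a", "b", "c"), 40, replace = TRUE)
    gender <- sample(c("F", "M"), 40, replace = TRUE)
    v <- stats::rnorm(40, mean = match(g, c("a", "b", "c")) * runif(1, 0, 1))
    if (min(table(g, gender)) == 0) next
    fit <- anova_gender_controlled(v, g, gender)
    eta <- fit$ss_group / sum((v - mean(v))^2)
    expect_lte(fit$omega_sq, eta + 1e-12)
  }
})

test_that("Scheffe comparisons are conservative and null-calibrated", {
  set.seed(34)
  # identical groups: p = 1 for the zero-difference pair
  v <- rep(stats::rnorm(10), 2)
  g <- rep(c("a", "b"), each = 10)
  gender <- rep(rep(c("F", "M"), each = 5), 2)
  sch <- scheffe_pairwise(v, g, gender)
  expect_equal(sch$p_value, 1.0)
  expect_equal(sch$diff, 0)
  # Scheffe p >= Fisher LSD p across fixtures where gender is balanced
  # within groups and carries no effect (so both procedures address the
  # same mean differences and the dominance is the Scheffe guarantee, not
  # an artifact of differing adjustments)
  for (i in 1:30) {
    g <- rep(c("a", "b", "c"), each = 10)
    per <- lapply(1:3, function(j) stats::rnorm(5, mean = j * runif(1, 0, 2)))
    v <- unlist(lapply(per, function(x) c(x, x)))  # F copy + M copy
    gender <- rep(rep(c("F", "M"), each = 5), 3)
    sch <- scheffe_pairwise(v, g, gender)
    lsd <- fisher_lsd_pairwise(v, g)
    expect_true(all(sch$p_value >= lsd$p_value - 1e-12))
    # equal group sizes: p decreases as |adjusted difference| grows
    o <- order(abs(sch$diff))
    expect_true(all(diff(sch$p_value[o]) <= 1e-12))
  }
})

test_that("Fisher LSD equals the pooled two-sample t test with two groups", {
  set.seed(35)
  v <- stats::rnorm(25, mean = rep(c(0, 1), c(12, 13)))
  g <- rep(c("a", "b"), c(12, 13))
  lsd <- fisher_lsd_pairwise(v, g)
  tt <- stats::t.test(v[g == "a"], v[g == "b"], var.equal = TRUE)
  expect_equal(lsd$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(lsd$diff, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
  expect_error(fisher_lsd_pairwise(v, rep(c("a", "b", "c"), c(12, 12, 1))),
               "singleton")
})

test_that("Spearman correlation and its Fisher-z interval behave at the extremes", {
  x <- c(1, 4, 9, 16, 25, 36)
  expect_equal(spearman_ci(x, sqrt(x))$rho, 1.0)
  expect_equal(spearman_ci(x, -x)$rho, -1.0)
  set.seed(36)
  a <- stats::rnorm(50)
  b <- 0.4 * a + stats::rnorm(50)
  res <- spearman_ci(a, b)
  expect_equal(res$rho, stats::cor(a, b, method = "spearman"),
               tolerance = 1e-12)
  expect_true(res$ci95[1] <= res$rho && res$rho <= res$ci95[2])
  expect_true(all(res$ci95 >= -1 & res$ci95 <= 1))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_error(spearman_ci(rep(1, 10), stats::rnorm(10)), "constant")
})
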