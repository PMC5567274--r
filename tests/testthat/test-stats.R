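test_that("Grubbs screen removes a gross outlier and only then", {
  x <- c(1, 1.1, 0.9, 1.05, 9)
  # longhand check that G exceeds the two-sided critical value at n = 5
  G <- max(abs(x - mean(x))) / sd(x)
  tc <- qt(1 - 0.05 / (2 * 5), 3)
  Gcrit <- (4 / sqrt(5)) * sqrt(tc^2 / (3 + tc^2))
  expect_gt(G, Gcrit)

  out <- grubbs_screen(x)
  expect_equal(out$removed, 5L)
  expect_equal(out$kept, x[1:4])

  # tight sample: nothing removed
  out <- grubbs_screen(c(1, 1.1, 0.9, 1.05, 0.95))
  expect_equal(length(out$removed), 0)

  # all-equal values: sd = 0 handled as no outlier
  out <- grubbs_screen(rep(2, 5))
  expect_equal(length(out$removed), 0)

  expect_warning(out <- grubbs_screen(c(1, 2)), "fewer than 3")
  expect_equal(out$kept, c(1, 2))
})

test_that("Grubbs removal rate under the null is near alpha", {
  set.seed(91)
  removed <- vapply(1:2000, function(i) {
    length(grubbs_screen(rnorm(10))$removed) > 0
  }, logical(1))
  rate <- mean(removed)
  # Monte Carlo check: removal prob of the first pass is ~alpha
  expect_lt(abs(rate - 0.05), 0.02)
})

test_that("pooled t-test matches closed form", {
  r <- compare_means_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  a <- c(1, 2, 3); b <- c(4, 5, 6)
  r <- compare_means_ttest(a, b)
  # closed-form pooled computation
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$t, t_manual)
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$p, 2 * pt(t_manual, 4))
  expect_equal(r$p, 0.0213, tolerance = 1e-3)
  expect_equal(r$df, 4)

  # degenerate identical constants
  r <- compare_means_ttest(c(2, 2), c(2, 2))
  expect_equal(r$p, 1)
  expect_error(compare_means_ttest(1, c(1, 2)), "at least 2")
})

test_that("t-test Grubbs screening drops outliers per group", {
  a <- c(rnorm(10), 50)
  b <- rnorm(10)
  r <- compare_means_ttest(a, b, grubbs = TRUE)
  expect_equal(r$n_a, 10)
})

test_that("Fisher exact matches full enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  p <- fisher_exact_2x2(matrix(c(1, 9, 9, 1), 2))
  expect_equal(p, oracle_fisher_2x2(matrix(c(1, 9, 9, 1), 2)),
    tolerance = 1e-9)
  expect_equal(p, 202 / 184756)  # enumerated by hand: 2*(1 + 100)/C(20,10)
  # empty margin
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")

  set.seed(17)
  for (i in 1:100) {
    m <- matrix(sample(0:20, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_2x2(m), oracle_fisher_2x2(m), tolerance = 1e-8)
  }
})

test_that("ANOVA and Tukey behave on degenerate and shifted groups", {
  g <- rep(c("a", "b", "c"), each = 5)
  v <- rep(c(1, 2, 3, 4, 5), 3)  # identical groups
  r <- anova_tukey(v, g)
  expect_equal(r$anova$f, 0)
  expect_equal(r$anova$p, 1)
  expect_true(all(r$pairwise$p_adj == 1))

  # all values constant
  r0 <- anova_tukey(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(r0$anova$p, 1)

  set.seed(3)
  v <- c(rnorm(10), rnorm(10), rnorm(10, mean = 5))
  r <- anova_tukey(v, g <- rep(c("a", "b", "c"), each = 10))
  expect_lt(r$anova$p, 0.001)
  expect_lt(r$pairwise$p_adj[r$pairwise$contrast == "c-a"], 0.001)

  expect_error(anova_tukey(rnorm(4), rep(c("a", "b"), 2)), "3 groups")
  expect_error(anova_tukey(rnorm(5), c("a", "a", "b", "b", "c")), "n >= 2")
})

test_that("Tukey adjusted p never undercuts the pooled pairwise t", {
  set.seed(19)
  for (i in 1:20) {
    v <- rnorm(24, mean = rep(runif(3, 0, 2), each = 8))
    g <- rep(c("a", "b", "c"), each = 8)
    r <- anova_tukey(v, g)
    an <- anova(lm(v ~ g))
    mse <- an[2, "Mean Sq"]
    df2 <- an[2, "Df"]
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      # pairwise t using the same single-pooled variance as Tukey
      d <- mean(v[g == pair[2]]) - mean(v[g == pair[1]])
      t_stat <- d / sqrt(mse * (1 / 8 + 1 / 8))
      p_t <- 2 * pt(-abs(t_stat), df2)
      contrast <- paste(pair[2], pair[1], sep = "-")
      p_adj <- r$pairwise$p_adj[r$pairwise$contrast == contrast]
      expect_gte(p_adj + 1e-10, p_t)
    }
  }
})

test_that("log-rank matches longhand observed-minus-expected arithmetic", {
  # identical groups
  rec <- tibble::tibble(
    time = rep(c(5, 10, 15), 2), event = rep(1, 6),
    group = rep(c("A", "B"), each = 3)
  )
  r <- km_logrank(rec)
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  # hand-worked six-subject example: all A events precede all B events
  rec <- tibble::tibble(
    time = c(1, 2, 3, 4, 5, 6), event = 1,
    group = rep(c("A", "B"), each = 3)
  )
  r <- km_logrank(rec)
  o <- oracle_logrank(rec$time, rec$event, rec$group)
  expect_equal(r$chi2, o$chi2, tolerance = 1e-9)
  expect_equal(r$p, o$p, tolerance = 1e-9)

  # randomized censored data still matches the longhand oracle
  set.seed(23)
  for (i in 1:10) {
    rec <- tibble::tibble(
      time = round(rexp(40, 0.05), 1),
      event = rbinom(40, 1, 0.7),
      group = rep(c("A", "B"), each = 20)
    )
    if (sum(rec$event[rec$group == "A"]) == 0 ||
        sum(rec$event[rec$group == "B"]) == 0) next
    r <- km_logrank(rec)
    o <- oracle_logrank(rec$time, rec$event, rec$group)
    expect_equal(r$chi2, o$chi2, tolerance = 1e-8)
  }
})

test_that("KM tidy/glance/autoplot expose curves and the test summary", {
  set.seed(29)
  rec <- tibble::tibble(time = rexp(40, 0.02), event = rbinom(40, 1, 0.8),
    group = rep(c("A", "B"), each = 20))
  r <- km_logrank(rec)
  td <- tidy(r)
  expect_setequal(unique(td$group), c("A", "B"))
  expect_true(all(td$survival >= 0 & td$survival <= 1))
  expect_true(all(diff(td$survival[td$group == "A"]) <= 1e-12))
  gl <- glance(r)
  expect_equal(gl$n, 40)
  expect_equal(gl$p, r$p)
  expect_s3_class(autoplot(r), "ggplot")
  expect_error(km_logrank(dplyr::mutate(rec, group = "A")), "2 groups")
})

test_that("Cox adjustment recovers simulated hazard ratios", {
  set.seed(37)
  # null covariate: CI covers 1
  n <- 300
  rec <- tibble::tibble(
    time = rexp(n, 0.05), event = 1L,
    x = rbinom(n, 1, 0.5)
  )
  fit <- cox_adjust(rec, "x")
  td <- tidy(fit)
  expect_true(td$conf_low < 1 && td$conf_high > 1)

  # true HR = 2 recovered on average within 10%
  est <- vapply(1:60, function(i) {
    x <- rbinom(200, 1, 0.5)
    t <- rexp(200, 0.05 * 2^x)
    cens <- runif(200, 10, 60)
    rec <- tibble::tibble(time = pmin(t, cens),
      event = as.integer(t <= cens), x = x)
    tidy(cox_adjust(rec, "x"))$hr
  }, numeric(1))
  expect_lt(abs(mean(est) - 2) / 2, 0.1)

  expect_error(cox_adjust(dplyr::mutate(rec, x = 1), "x"), "constant")
  expect_error(cox_adjust(rec, "nope"), "missing covariate")
  gl <- glance(fit)
  expect_equal(gl$n, n)
  expect_true(gl$concordance >= 0 && gl$concordance <= 1)
})
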