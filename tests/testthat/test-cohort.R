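test_that("quartile dichotomization follows the <25th percentile rule", {
  lab <- quartile_dichotomize(1:8)
  expect_equal(attr(lab, "threshold"), 2.75)   # type-7 interpolation
  expect_equal(as.character(lab[1:2]), c("low", "low"))
  expect_true(all(lab[3:8] == "high"))
  # four distinct values: exactly one low
  expect_equal(sum(quartile_dichotomize(c(10, 20, 30, 40)) == "low"), 1)
  # invariant to input order
  set.seed(4)
  x <- rnorm(40)
  p <- sample(40)
  expect_equal(as.character(quartile_dichotomize(x)[p]),
               as.character(quartile_dichotomize(x[p])))
  # a value equal to the threshold goes to high
  lab2 <- quartile_dichotomize(c(1, 2, 2, 2, 5, 6, 7, 8))
  expect_equal(as.character(lab2[2]), "high")
  expect_warning(quartile_dichotomize(rep(3, 8)), "identical")
  expect_error(quartile_dichotomize(1:3), "at least 4")
  # |low| within 1 of n/4 for tie-free data
  expect_lte(abs(sum(quartile_dichotomize(rnorm(101)) == "low") - 101 / 4), 1)
})

test_that("Kaplan-Meier estimator matches hand and brute-force values", {
  km <- km_estimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
  expect_equal(km$survival, c(2 / 3, 2 / 3 * 1 / 2, 0))
  # survival after t = 2 is (2/3) * (1/2) = 1/3
  expect_equal(km$survival[km$time == 2], 1 / 3)
  # no events: no steps, survival stays at 1
  expect_equal(nrow(km_estimate(c(1, 2, 3), c(FALSE, FALSE, FALSE))), 0)
  # brute-force tabulation oracle on random censored cohorts
  set.seed(6)
  for (i in 1:5) {
    tt <- round(rexp(25, 0.1), 1) + 0.1
    ev <- runif(25) < 0.7
    km2 <- km_estimate(tt, ev)
    orc <- oracle_km(tt, ev)
    expect_equal(km2$survival, orc$survival)
    expect_true(all(diff(km2$survival) <= 1e-12))
    expect_true(all(km2$survival >= 0 & km2$survival <= 1))
  }
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)), "> 0")
})

test_that("log-rank test matches a hand tabulation and is symmetric", {
  # six-subject worked case, tabulated per event time in the oracle loop
  tt <- c(2, 4, 5, 7, 9, 12)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  gg <- c("a", "b", "a", "b", "a", "b")
  o_minus_e <- 0; v <- 0
  for (t0 in sort(unique(tt[ev]))) {
    at <- tt >= t0
    n <- sum(at); n1 <- sum(at & gg == "a")
    d <- sum(tt == t0 & ev); d1 <- sum(tt == t0 & ev & gg == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  res <- logrank_test(tt, ev, gg)
  expect_equal(res$statistic, o_minus_e^2 / v)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
  # symmetric in group order
  expect_equal(logrank_test(tt, ev, factor(gg, levels = c("b", "a")))$statistic,
               res$statistic)
  # identical groups give statistic 0
  res0 <- logrank_test(rep(tt, 2), rep(ev, 2), rep(c("x", "y"), each = 6))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)
  # invariant to monotone time rescaling
  res_sq <- logrank_test(tt^2 / 10, ev, gg)
  expect_equal(res_sq$statistic, res$statistic)
  expect_warning(r_noev <- logrank_test(tt, rep(FALSE, 6), gg), "no events")
  expect_equal(r_noev$p_value, 1)
  expect_error(logrank_test(tt, ev, rep("a", 6)), "two group")
})

test_that("log-rank agrees with the survival package on simulated cohorts", {
  set.seed(17)
  for (i in 1:5) {
    d <- simulate_cohort(80, sample(c(1, 2, 3), 1), 0.25, seed = NULL)
    mine <- logrank_test(d$time, d$event, d$arm)
    ref <- survival::survdiff(survival::Surv(time, event) ~ arm, data = d)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-10)
  }
})

test_that("Fisher exact test matches full hypergeometric enumeration", {
  tb <- matrix(c(5, 1, 1, 5), 2, 2)
  res <- fisher_exact_2x2(tb)
  expect_equal(res$p_value, oracle_fisher_p(tb))
  expect_equal(res$p_value, stats::fisher.test(tb)$p.value)
  expect_equal(res$odds_ratio, unname(stats::fisher.test(tb)$estimate),
               tolerance = 1e-4)
  # independence gives p = 1
  expect_equal(fisher_exact_2x2(matrix(2, 2, 2))$p_value, 1)
  # transpose invariance
  tb2 <- matrix(c(7, 2, 3, 9), 2, 2)
  expect_equal(fisher_exact_2x2(tb2)$p_value, fisher_exact_2x2(t(tb2))$p_value)
  expect_equal(fisher_exact_2x2(tb2)$p_value, oracle_fisher_p(tb2))
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, 2)), "margins")
  # extreme table: conditional MLE odds ratio degenerates to infinity
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))$odds_ratio, Inf)
})

test_that("response contingency wraps the exact test", {
  resp <- c(rep(TRUE, 6), rep(FALSE, 6))
  grp <- factor(c(rep("low", 5), "high", "low", rep("high", 5)),
                levels = c("low", "high"))
  out <- response_contingency(resp, grp)
  expect_equal(sum(out$table), 12)
  expect_equal(out$table["responder", "low"], 5)
  expect_equal(out$p_value, fisher_exact_2x2(out$table)$p_value)
  expect_error(response_contingency(resp, rep("low", 12)), "two levels")
})

test_that("cohort survival analysis composes split, KM and log-rank", {
  d <- simulate_cohort(200, 3, 0.2, seed = 8)
  res <- cohort_survival_analysis(d)
  expect_equal(levels(res$labels), c("low", "high"))
  expect_equal(sum(res$labels == "low"), 50)
  expect_true(res$logrank$p_value < 0.05)   # strong effect, n = 200
  expect_setequal(unique(res$km$group), c("low", "high"))
  # rank-sum wrapper shares the Mann-Whitney implementation
  expect_equal(rank_sum_compare(d$expression[d$arm == "low"],
                                d$expression[d$arm == "high"])$p_value,
               compare_groups(d$expression[d$arm == "low"],
                              d$expression[d$arm == "high"])$p_value)
  # Cox pass-through returns a fitted survival::coxph object
  cf <- cox_fit(d)
  expect_s3_class(cf, "coxph")
  expect_length(stats::coef(cf), 1)
})
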