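test_that("Welch test basics: identical samples, equal-variance df limit", {
  x <- c(1, 2, 3, 4, 5)
  r0 <- welch_t(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # equal n and equal sample variances: Satterthwaite df = n1 + n2 - 2
  y <- x + 1
  r <- welch_t(x, y)
  expect_equal(r$df, length(x) + length(y) - 2)
  # Welch df never exceeds the pooled df
  set.seed(111)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), 0, runif(1, 0.2, 3))
    expect_lte(welch_t(a, b)$df, length(a) + length(b) - 2 + 1e-9)
  }
})

test_that("constant equal samples fall back to the p = 1 convention", {
  r <- welch_t(rep(2, 5), rep(2, 7))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("one-sample test has df = n - 1 and flags constant input", {
  set.seed(112)
  x <- rnorm(100, 0.6, 0.2)
  r <- one_sample_t(x, 0.5, "greater")
  expect_equal(r$df, 99)
  expect_equal(r$tail, "one")
  d <- one_sample_t(rep(0.5, 10), 0.5)
  expect_true(d$degenerate)
  # power sanity: a shifted sample at large n rejects easily
  big <- rnorm(5000, 0.55, 0.2) + 0.0  # shift of 0.05, se ~ 0.003
  set.seed(113)
  expect_lt(one_sample_t(rnorm(5000, 0.55, 0.2), 0.5, "greater")$p, 1e-6)
})

test_that("t-distribution tails match printed statistics and limits", {
  expect_equal(round(t_pvalue(2.451, 5, "two"), 3), 0.058)
  expect_equal(round(t_pvalue(-2.73, 145.5, "one"), 3), 0.004)
  expect_equal(t_pvalue(0, 12, "two"), 1)
  expect_equal(t_pvalue(1.2, 17, "one"), t_pvalue(1.2, 17, "two") / 2)
  # large-df limit equals the normal tail
  expect_equal(t_pvalue(1.7, 1e6, "one"), pnorm(-1.7), tolerance = 1e-4)
  expect_error(t_pvalue(1, 0), "df")
})

test_that("F tails match the printed ANOVA and the d1 = 2 closed form", {
  expect_equal(round(f_pvalue(8.060, 2, 10), 3), 0.008)
  expect_equal(f_pvalue(0, 3, 10), 1)
  for (f in c(0.5, 2, 8)) for (d2 in c(4, 10, 30))
    expect_equal(f_pvalue(f, 2, d2), (1 + 2 * f / d2)^(-d2 / 2),
                 tolerance = 1e-10)
})

test_that("repeated-measures ANOVA: null, df, and paired-t equivalence", {
  set.seed(114)
  base <- matrix(rnorm(18, 0.8, 0.1), 6, 3)
  # remove all level effects: F must be 0
  flat <- base - rep(colMeans(base), each = 6)
  r0 <- rm_anova_oneway(flat)
  expect_equal(r0$statistic, 0, tolerance = 1e-10)
  r <- rm_anova_oneway(base)
  expect_equal(r$df, c(2, 10))
  expect_true(r$effect >= 0 && r$effect <= 1)
  # two levels: F equals the squared paired-t statistic, same p
  two <- base[, 1:2]
  r2 <- rm_anova_oneway(two)
  tt <- t.test(two[, 1], two[, 2], paired = TRUE)
  expect_equal(r2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_error(rm_anova_oneway(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("ceiling/floor criteria pass on a well-separated scenario", {
  des <- endogenous_design()
  sc <- scenario_config(des, c(a0 = 0.258, a1 = 0.0112, a2 = -8e-5,
                               b = -3e-4, c1 = 0, c2 = 0),
                        baseline_weight = 0, seed = 115)
  tab <- generate_dataset(sc)
  rep <- check_ceiling_floor(tab)
  expect_true(rep$pass)
  expect_true(rep$c1$pass)
  expect_true(rep$c2$pass)
  expect_equal(rep$c1$test$tail, "one")
  expect_equal(rep$c2$test$tail, "one")
})

test_that("criteria fail in the degenerate scenarios they guard against", {
  # no masking at all: masked cells equal baseline -> C1 fails
  des <- endogenous_design(reps_per_condition = 100)
  flat <- scenario_config(des, c(a0 = 0.02, a1 = 0, a2 = 0, b = 0,
                                 c1 = 0, c2 = 0),
                          baseline_weight = 0.02, seed = 116)
  r1 <- check_ceiling_floor(generate_dataset(flat))
  expect_false(r1$c1$pass)
  # guessing everywhere: worst cell is at chance -> C2 fails
  guess <- scenario_config(des, c(a0 = 1, a1 = 0, a2 = 0, b = 0,
                                  c1 = 0, c2 = 0),
                           baseline_weight = 0, seed = 117)
  r2 <- check_ceiling_floor(generate_dataset(guess))
  expect_false(r2$c2$pass)
})

test_that("C1's one-tailed test holds its nominal size under the null", {
  set.seed(118)
  rej <- 0; n_rep <- 2000
  for (i in seq_len(n_rep)) {
    x <- rnorm(100, 0.8, 0.15); y <- rnorm(100, 0.8, 0.15)
    if (welch_t(x, y, "less")$p < 0.05) rej <- rej + 1
  }
  rate <- rej / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lte(abs(rate - 0.05), 2 * se + 1e-12)
})

test_that("missing baseline leaves C1 not evaluable", {
  des <- design_spec("endogenous", ctoas = c(0, 200), soas = c(40, 80),
                     include_baseline = FALSE, reps_per_condition = 50,
                     n_items = 6, cue_validity = 1)
  sc <- scenario_config(des, c(a0 = 0.3, a1 = 0, a2 = 0, b = -2e-4,
                               c1 = 0, c2 = 0), seed = 119)
  r <- check_ceiling_floor(generate_dataset(sc))
  expect_false(isTRUE(r$c1$evaluable))
  expect_true(is.na(r$c1$pass))
})
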