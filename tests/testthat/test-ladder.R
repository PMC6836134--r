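test_that("ladder term sets have the printed sizes and members", {
  lm_tab <- ladder_models()
  expect_equal(nrow(lm_tab), 21)
  expect_equal(lm_tab$p,
               c(1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 3, 3, 3, 4, 4, 4, 4, 4,
                 5, 5, 6))
  expect_identical(unname(design_matrix("M1", 40, 200)[1, ]), 1)
  expect_identical(unname(design_matrix("M16", 40, 200)[1, ]),
                   c(1, 40, 1600, 200))
  expect_equal(ncol(design_matrix("M21", 40, 200)), 6)
  expect_identical(unname(design_matrix("M21", 40, 200)[1, ]),
                   c(1, 40, 1600, 200, 8000, 320000))
  # M19 = M16 plus the linear interaction
  expect_identical(colnames(design_matrix("M19", 1, 1)),
                   c(colnames(design_matrix("M16", 1, 1)), "tau:n"))
})

test_that("baseline trials are rejected from ladder rows", {
  expect_error(design_matrix("M2", c(20, NA), c(0, 0)), "baseline")
  expect_error(design_matrix("M99", 1, 1), "unknown")
})

test_that("exact fits: constant and noiseless linear responses", {
  tau <- rep(c(20, 40, 60, 80, 120), each = 4)
  n <- rep(c(0, 200), 10)
  f1 <- fit_ols("M1", rep(3.5, 20), tau, n)
  expect_equal(f1$rss, 0)
  expect_equal(unname(f1$coefficients), 3.5)
  y <- 2 + 0.01 * tau
  f2 <- fit_ols("M2", y, tau, n)
  expect_equal(unname(f2$coefficients), c(2, 0.01), tolerance = 1e-9)
  expect_lt(f2$rss, 1e-18)
})

test_that("coefficients agree with the normal-equations oracle", {
  set.seed(81)
  tau <- runif(60, 10, 130); n <- sample(c(0, 200, 500), 60, TRUE)
  y <- 0.8 - 0.002 * tau + 1e-5 * tau^2 + 2e-4 * n + rnorm(60, 0, 0.05)
  for (m in c("M7", "M16", "M21")) {
    X <- design_matrix(m, tau, n)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    f <- fit_ols(m, y, tau, n)
    expect_equal(unname(f$coefficients), unname(drop(beta)),
                 tolerance = 1e-9)
    expect_equal(f$rss, sum((y - X %*% beta)^2), tolerance = 1e-9)
  }
})

test_that("the full model M21 has the smallest RSS on any data", {
  set.seed(82)
  tau <- runif(80, 10, 130); n <- sample(c(0, 200, 500), 80, TRUE)
  y <- rnorm(80)
  fits <- fit_ladder(y, tau, n)
  rss21 <- fits$M21$rss
  for (f in fits) expect_gte(f$rss + 1e-12, rss21)
})

test_that("centering tau leaves hierarchically closed models unchanged", {
  set.seed(83)
  tau <- runif(50, 10, 130); n <- sample(c(0, 200, 500), 50, TRUE)
  y <- rnorm(50, 0.7, 0.1)
  # these term sets are closed under tau -> tau - c, so the column span
  # and hence RSS/BIC cannot move
  for (m in c("M1", "M2", "M3", "M7", "M13", "M16", "M19", "M21")) {
    a <- fit_ols(m, y, tau, n)
    b <- fit_ols(m, y, tau - mean(tau), n)
    expect_equal(a$rss, b$rss, tolerance = 1e-8)
    expect_equal(a$bic, b$bic, tolerance = 1e-6)
  }
})

test_that("BIC and adjusted R^2 follow their definitions", {
  set.seed(84)
  tau <- runif(40, 10, 130); n <- rep(c(0, 500), 20)
  y <- 0.7 + 1e-4 * n + rnorm(40, 0, 0.05)
  f <- fit_ols("M7", y, tau, n)
  r2 <- 1 - f$rss / sum((y - mean(y))^2)
  expect_equal(f$bic, 40 * log(f$rss / 40) + 3 * log(40))
  expect_equal(f$adj_r2, 1 - (1 - r2) * 39 / (40 - 3 - 1))
})

test_that("selection follows min-BIC with the e^-x odds convention", {
  set.seed(85)
  tau <- rep(c(20, 40, 60, 80, 120), each = 30)
  n <- rep(c(0, 200, 500), 50)
  y <- 0.85 - 0.005 * tau + 3e-5 * tau^2 + 1.5e-4 * n + rnorm(150, 0, 0.05)
  fits <- fit_ladder(y, tau, n)
  sel <- select_model(fits)
  expect_equal(sel$winner, sel$table$model[which.min(sel$table$bic)])
  expect_lt(max(abs(sel$delta + t(sel$delta))), 1e-12)
  d <- sel$table$dbic_vs_winner
  expect_equal(sel$table$odds_vs_winner, exp(-d))
  expect_true(sel$table$nearly_equal[sel$table$model == sel$winner])
  half <- select_model(fits, convention = "half")
  expect_equal(half$table$odds_vs_winner, exp(-d / 2))
})

test_that("a single CTOA level makes CTOA terms rank deficient", {
  tau <- runif(30, 10, 130); n <- rep(200, 30)
  expect_warning(fit_ols("M7", rnorm(30), tau, n), "rank")
})

test_that("masking ladder runs at trial and cell level and prefers the
           additive quadratic model on additive data", {
  sc <- scenario_endogenous(seed = 86, reps_per_condition = 100)
  tab <- generate_dataset(sc)
  trial <- masking_ladder(tab)
  cellw <- masking_ladder(tab, level = "cell")
  expect_s3_class(trial$selection, "ladder_selection")
  expect_equal(nrow(trial$selection$table), 21)
  expect_equal(cellw$fits$M21$n_obs, 15)
  # the additive truth has quadratic SOA + linear CTOA: M16 or one of
  # its near-neighbours should be competitive at trial level
  expect_lte(trial$selection$table$dbic_vs_winner[
    trial$selection$table$model == "M16"], 6)
})
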