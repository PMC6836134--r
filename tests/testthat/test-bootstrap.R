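test_that("bootstrap mean of the guess weight brackets the truth", {
  cell <- gu_cell(seed = 91, w = 0.3, sigma = 10, n = 100)
  s <- bootstrap_cell(cell$errors, model = "GU", B = 500, seed = 92)
  wu <- s[s$parameter == "w_u", ]
  expect_lte(abs(wu$mean - 0.3), 2 * wu$se + 0.02)
  expect_true(attr(s, "valid"))
  expect_equal(unique(s$B), 500)
})

test_that("bootstrap SE of a near-linear statistic matches sd/sqrt(n)", {
  # the G model's mu estimate is essentially the sample mean, whose
  # bootstrap SE must track the closed form
  cell <- gu_cell(seed = 93, w = 0, sigma = 10, n = 100)
  s <- bootstrap_cell(cell$errors, model = "G", B = 500, seed = 94)
  closed <- sd(cell$errors) / sqrt(length(cell$errors))
  expect_equal(s$se[s$parameter == "mu"], closed, tolerance = 0.15 * closed)
})

test_that("degenerate cells give zero SE and fixed seeds reproduce exactly", {
  s1 <- suppressWarnings(bootstrap_cell(rep(5, 40), model = "GU", B = 40,
                                        seed = 95))
  expect_lt(s1$se[s1$parameter == "mu"], 1e-6)
  expect_equal(s1$mean[s1$parameter == "mu"], 5, tolerance = 0.5)
  cell <- gu_cell(seed = 96, n = 60)
  a <- bootstrap_cell(cell$errors, model = "GU", B = 25, seed = 97)
  b <- bootstrap_cell(cell$errors, model = "GU", B = 25, seed = 97)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("small cells and tiny B are rejected", {
  expect_error(bootstrap_cell(rnorm(10), model = "GU", B = 10, seed = 1),
               "20")
  expect_error(bootstrap_cell(rnorm(40, 0, 10), model = "GU", B = 1,
                              seed = 1), "B")
})

test_that("parameter surfaces select the expected ladder members", {
  grid <- expand.grid(soa_ms = c(20, 40, 60, 80, 120),
                      ctoa_ms = c(0, 200, 500))
  m16_wins <- m2021_wins <- 0
  for (r in 1:11) {
    set.seed(700 + r)
    noise <- rnorm(nrow(grid), 0, 0.01)
    add <- data.frame(grid, parameter = "w_u",
                      mean = weight_surface(c(a0 = 0.014, a1 = 0.0196,
                                              a2 = -1.4e-4, b = -4e-4,
                                              c1 = 0, c2 = 0),
                                            grid$soa_ms, grid$ctoa_ms) + noise)
    sel <- regress_parameter_surface(add)$selection
    if (sel$winner == "M16") m16_wins <- m16_wins + 1
    inter <- add
    inter$mean <- inter$mean - 4e-8 * grid$soa_ms^2 * grid$ctoa_ms * 10
    sel2 <- regress_parameter_surface(inter)$selection
    if (sel2$winner %in% c("M20", "M21")) m2021_wins <- m2021_wins + 1
  }
  expect_gte(m16_wins, 6)
  expect_gte(m2021_wins, 6)
})

test_that("a constant parameter surface selects the intercept model", {
  grid <- expand.grid(soa_ms = c(20, 40, 60, 80, 120),
                      ctoa_ms = c(0, 200, 500))
  flat <- data.frame(grid, parameter = "w_u", mean = 0.4)
  expect_equal(regress_parameter_surface(flat)$selection$winner, "M1")
  expect_error(regress_parameter_surface(flat[1:4, ]), "6 cells")
})

test_that("correlation endpoints: affine, identical and degenerate series", {
  cell <- gu_cell(seed = 98, n = 40)
  sc <- scenario_endogenous(seed = 99, reps_per_condition = 30)
  tab <- generate_dataset(sc)
  mf <- masking_function(tab, ctoa = 0)
  affine_down <- data.frame(soa_ms = mf$points$soa_ms,
                            mean = 2 - 3 * mf$points$mean_tp)
  expect_equal(correlate_parameter_with_masking(mf, affine_down)$r, -1)
  same <- data.frame(soa_ms = mf$points$soa_ms, mean = mf$points$mean_tp)
  expect_equal(correlate_parameter_with_masking(mf, same)$r, 1)
  const <- data.frame(soa_ms = mf$points$soa_ms, mean = 1)
  out <- correlate_parameter_with_masking(mf, const)
  expect_true(is.na(out$r))
  expect_match(out$reason, "zero-variance")
})

test_that("guess weight tracks masking more tightly than sigma does", {
  sc <- scenario_endogenous(seed = 101, reps_per_condition = 60)
  tab <- generate_dataset(sc)
  boot <- bootstrap_cells(tab, model = "GU", B = 30, seed = 102)
  r_wu <- r_sig <- c()
  for (ct in c(0, 200, 500)) {
    mf <- masking_function(tab, ctoa = ct)
    wu <- boot[boot$parameter == "w_u" & boot$ctoa_ms == ct, ]
    sg <- boot[boot$parameter == "sigma" & boot$ctoa_ms == ct, ]
    r_wu <- c(r_wu, correlate_parameter_with_masking(mf, wu)$r)
    r_sig <- c(r_sig, correlate_parameter_with_masking(mf, sg)$r)
  }
  expect_gt(mean(abs(r_wu)), mean(abs(r_sig)))
  expect_true(all(r_wu < -0.5))  # guessing mirrors the masking function
})
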