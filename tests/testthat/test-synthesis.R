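test_that("pure-guessing responses are uniform on the error axis", {
  cell <- gu_cell(seed = 21, w = 1, sigma = 8, n = 10000)
  ks <- suppressWarnings(stats::ks.test(cell$errors, "punif", -90, 90))
  expect_gt(ks$p.value, 0.01)
})

test_that("pure-encoding responses recover the generating SD", {
  cell <- gu_cell(seed = 22, w = 0, sigma = 8, n = 10000)
  expect_equal(sd(cell$errors), 8, tolerance = 0.05 * 8)
  expect_equal(mean(cell$errors), 0, tolerance = 0.3)
})

test_that("closest-angle misbinding recentres on the closest distractor", {
  des <- design_spec("endogenous", ctoas = 0, soas = 60,
                     include_baseline = FALSE, reps_per_condition = 2000,
                     n_items = 6, cue_validity = 1)
  sc <- scenario_config(des, c(a0 = 0, a1 = 0, a2 = 0, b = 0, c1 = 0, c2 = 0),
                        sigma_true = 6, misbind_rate = 1,
                        misbind_mode = "closest_angle", baseline_weight = 0,
                        seed = 23)
  tab <- generate_dataset(sc)
  ctx <- trial_contexts(tab)
  recentred <- wrap_half(tab$error_deg + ctx$c_ca)
  # reported = closest distractor + noise, so error + c_ca ~ N(0, sigma)
  expect_equal(mean(recentred), 0, tolerance = 0.5)
  expect_equal(sd(recentred), 6, tolerance = 0.5)
})

test_that("generative guess weight is recovered from histogram tails", {
  # beyond |e| > 60 the Gaussian (sigma = 8) carries ~no mass, so the
  # tail fraction is w * (60/180)
  cell <- gu_cell(seed = 24, w = 0.4, sigma = 8, n = 100000)
  w_hat <- 3 * mean(abs(cell$errors) > 60)
  expect_equal(w_hat, 0.4, tolerance = 0.02)
})

test_that("all generated orientations and errors are in range", {
  tab <- generate_dataset(scenario_endogenous(seed = 25,
                                              reps_per_condition = 20))
  expect_true(all(tab$target_deg >= 0 & tab$target_deg < 180))
  expect_true(all(tab$reported_deg >= 0 & tab$reported_deg < 180))
  expect_true(all(tab$error_deg >= -90 & tab$error_deg < 90))
  expect_equal(tab$error_deg,
               wrap_orientation_error(tab$target_deg, tab$reported_deg))
})

test_that("an additive weight surface produces pure vertical shifts", {
  sc <- scenario_endogenous(seed = 26, reps_per_condition = 2000)
  tab <- generate_dataset(sc)
  mfs <- masking_functions(tab)
  masked <- mfs[!is.na(mfs$soa_ms), ]
  ctoas <- sort(unique(masked$ctoa_ms))
  for (j in 2:length(ctoas)) {
    a <- masked[masked$ctoa_ms == ctoas[1], ]
    b <- masked[masked$ctoa_ms == ctoas[j], ]
    stopifnot(identical(a$soa_ms, b$soa_ms))
    d <- b$mean_tp - a$mean_tp
    sem_d <- sqrt(a$sem_tp^2 + b$sem_tp^2)
    z <- abs(d - mean(d)) / sem_d
    # per-SOA differences share a common shift: most within 2 SEM,
    # all within 3 (simultaneous bound over the 5 SOAs)
    expect_true(all(z <= 3))
    expect_gte(mean(z <= 2), 0.8)
  }
})

test_that("trial tables round-trip through CSV byte-identically", {
  sc <- scenario_endogenous(seed = 27, reps_per_condition = 3)
  tab <- generate_dataset(sc)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(generate_dataset(sc), p1)
  write_trials(generate_dataset(sc), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_trials(p1)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$error_deg, tab$error_deg, tolerance = 1e-6)
  expect_identical(is.na(back$soa_ms), is.na(tab$soa_ms))
})

test_that("reading a malformed trial CSV reports file and column context", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("observer,ctoa_ms\nS1,0", p)
  expect_error(read_trials(p), "missing columns")
  p2 <- withr::local_tempfile(fileext = ".csv")
  tab <- generate_dataset(scenario_endogenous(seed = 1,
                                              reps_per_condition = 2))
  tab$error_deg[3] <- 120
  write_trials(tab, p2)
  expect_error(read_trials(p2), "row")
})

test_that("misbinding modes demand enough distractors", {
  des <- design_spec("endogenous", ctoas = 0, soas = 60,
                     include_baseline = FALSE, reps_per_condition = 30,
                     n_items = 2, cue_validity = 1)
  expect_error(
    scenario_config(des, c(a0 = 0, a1 = 0, a2 = 0, b = 0, c1 = 0, c2 = 0),
                    misbind_rate = 0.5, misbind_mode = "nearest_neighbor",
                    seed = 1),
    "distractor")
})
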