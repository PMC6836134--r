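# Single-cell generators built from the package's own scenario
# machinery; used across the mixture, BMC and bootstrap tests.

# one masked cell with Gaussian + uniform truth (no misbinding)
gu_cell <- function(seed, w = 0.3, sigma = 10, n = 100, n_items = 6) {
  des <- design_spec("endogenous", ctoas = 0, soas = 60,
                     include_baseline = FALSE, reps_per_condition = n,
                     n_items = n_items, cue_validity = 1)
  sc <- scenario_config(des, c(a0 = w, a1 = 0, a2 = 0, b = 0,
                               c1 = 0, c2 = 0),
                        sigma_true = sigma, seed = seed,
                        baseline_weight = 0)
  tab <- generate_dataset(sc)
  list(errors = tab$error_deg, ctx = trial_contexts(tab), table = tab)
}

# random valid parameter set for a given model spec
random_params <- function(spec, box = prior_box()) {
  repeat {
    p <- list(mu = runif(1, box$mu[1], box$mu[2]),
              sigma = runif(1, box$sigma[1], box$sigma[2]),
              w_u = if (spec$uses_wu) runif(1) else 0,
              w_m = if (spec$uses_wm) runif(1) else 0)
    if (p$w_u + p$w_m <= 1) return(p)
  }
}

# numeric quadrature of a mixture density over [-90, 90)
density_integral <- function(params, model, ctx1 = NULL) {
  f <- function(x) {
    ctx <- if (!is.null(ctx1))
      ctx1[rep(1, length(x)), , drop = FALSE] else NULL
    error_density(x, params, model, ctx)
  }
  stats::integrate(f, -90, 89.9999999, rel.tol = 1e-9,
                   subdivisions = 500L)$value
}
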