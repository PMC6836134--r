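#' Uniform prior box for mixture-model parameters
#'
#' Closed parameter ranges over which the uniform prior of the Bayesian
#' model comparison is defined, together with the default number of
#' Riemann bins per dimension. Each model uses the sub-box of its own
#' free parameters. Defaults: mu in \[-45, 45\] deg, sigma in
#' \[0.5, 60\] deg, weights in \[0, 1\], 50 bins per dimension (the
#' study-default grid floor).
#'
#' @param mu,sigma,w_u,w_m length-2 numeric ranges `c(lower, upper)`.
#' @param bins default bins per dimension for grid integration.
#' @return object of class `prior_box`.
#' @export
prior_box <- function(mu = c(-45, 45), sigma = c(0.5, 60),
                      w_u = c(0, 1), w_m = c(0, 1), bins = 50) {
  rng <- list(mu = mu, sigma = sigma, w_u = w_u, w_m = w_m)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || r[1] >= r[2])
      stop(sprintf("range for %s must be finite with lower < upper", nm))
  }
  if (rng$sigma[1] <= 0) stop("sigma range must be positive")
  if (any(unlist(rng[c("w_u", "w_m")]) < 0) ||
      any(unlist(rng[c("w_u", "w_m")]) > 1))
    stop("weight ranges must lie within [0, 1]")
  if (bins < 1) stop("bins must be >= 1")
  structure(c(rng, list(bins = as.integer(bins))), class = "prior_box")
}

.box_bins <- function(spec, box, bins = NULL) {
  b <- if (is.null(bins)) box$bins else bins
  if (length(b) == 1) b <- stats::setNames(rep(b, spec$k), spec$par_names)
  if (!all(spec$par_names %in% names(b)))
    stop("bins must be scalar or named per free parameter")
  vapply(spec$par_names, function(p) as.integer(b[[p]]), integer(1))
}

# midpoint grid over one parameter range
.mids <- function(range, bins) {
  range[1] + (seq_len(bins) - 0.5) * diff(range) / bins
}

# Streaming evaluation of the log-likelihood over the midpoint Riemann
# grid. Chunked by (sigma, weights) with vectorisation over mu and
# trials, so 3- and 4-parameter grids never materialise. Tracks the
# grid maximum (and its location) and a stabilised log-sum-exp, and
# counts admissible cells (w_u + w_m <= 1).
.grid_scan <- function(spec, errors, ctx, box, bins) {
  n <- length(errors)
  g_mu <- .mids(box$mu, bins[["mu"]])
  g_sig <- .mids(box$sigma, bins[["sigma"]])
  g_wu <- if (spec$uses_wu) .mids(box$w_u, bins[["w_u"]]) else 0
  g_wm <- if (spec$uses_wm) .mids(box$w_m, bins[["w_m"]]) else 0
  run_m <- -Inf; run_s <- 0
  best_ll <- -Inf; best_par <- NULL
  n_adm <- 0L
  take <- function(ll, par_of_max) {
    M <- max(ll)
    if (M > best_ll) {
      best_ll <<- M
      best_par <<- par_of_max(which.max(ll))
    }
    M2 <- max(M, run_m)
    run_s <<- run_s * exp(run_m - M2) + sum(exp(ll - M2))
    run_m <<- M2
    n_adm <<- n_adm + length(ll)
  }
  floor_log <- function(d) log(pmax(d, 1e-300))
  for (sig in g_sig) {
    G <- stats::dnorm(outer(errors, g_mu, "-"), 0, sig)
    G <- sweep(G, 2, .tn_mass(g_mu, sig), "/")
    h <- if (!spec$uses_wm) NULL
    else if (spec$model_id == "GUCA") .dtnorm(errors, ctx$c_ca, sig)
    else 0.5 * (.dtnorm(errors, ctx$c_nn1, sig) +
                  .dtnorm(errors, ctx$c_nn2, sig))
    if (!spec$uses_wu) {
      take(colSums(floor_log(G)),
           function(i) c(mu = g_mu[i], sigma = sig))
    } else if (!spec$uses_wm) {
      for (wu in g_wu)
        take(colSums(floor_log((1 - wu) * G + wu / 180)),
             function(i) c(mu = g_mu[i], sigma = sig, w_u = wu))
    } else {
      for (wu in g_wu) for (wm in g_wm) {
        if (wu + wm > 1) next
        take(colSums(floor_log((1 - wu - wm) * G + wu / 180 + wm * h)),
             function(i) c(mu = g_mu[i], sigma = sig, w_u = wu, w_m = wm))
      }
    }
  }
  list(ll_max = best_ll, par_max = best_par,
       lse_rel = log(run_s) + (run_m - best_ll), n_adm = n_adm)
}

#' Maximum-likelihood fit of a mixture model
#'
#' Coarse midpoint-grid scan over the prior box followed by
#' derivative-free (Nelder-Mead) refinement from the best grid point.
#' The refined solution respects the box bounds and the weight simplex
#' (`w_u + w_m <= 1`); if refinement fails or ends below the grid
#' maximum, the grid maximum is returned with `fallback = TRUE` and a
#' warning.
#'
#' @param model a [mixture_spec()] or id string.
#' @param errors signed wrapped errors (>= 20 trials).
#' @param ctx per-trial contexts ([trial_contexts()]) for GUCA/GUNN.
#' @param box a [prior_box()].
#' @param coarse_bins bins per dimension for the initial scan.
#' @param min_n identifiability guard on the number of trials.
#' @return object of class `mixture_fit`: `model_id`, `params` (list
#'   `mu`, `sigma`, `w_u`, `w_m`), `ln_l_max`, `n`, `fallback`.
#' @export
fit_mle <- function(model, errors, ctx = NULL, box = prior_box(),
                    coarse_bins = 9, min_n = 20) {
  spec <- .as_spec(model)
  if (length(errors) < min_n)
    stop(sprintf("need >= %d trials for a stable fit", min_n))
  if (spec$uses_wm && is.null(ctx))
    stop(spec$model_id, " requires trial contexts")
  bins <- stats::setNames(rep(as.integer(coarse_bins), spec$k),
                          spec$par_names)
  scan <- .grid_scan(spec, errors, ctx, box, bins)
  lo <- vapply(spec$par_names, function(p) box[[p]][1], numeric(1))
  hi <- vapply(spec$par_names, function(p) box[[p]][2], numeric(1))
  neg_ll <- function(theta) {
    if (any(theta < lo) || any(theta > hi)) return(1e10)
    p <- as.list(theta); names(p) <- spec$par_names
    if ((if (is.null(p$w_u)) 0 else p$w_u) +
        (if (is.null(p$w_m)) 0 else p$w_m) > 1) return(1e10)
    -log_likelihood(spec, p, errors, ctx)
  }
  starts <- list(scan$par_max)
  if (spec$uses_wm) {
    # also refine from the nested GU optimum with no misbinding, so the
    # 4-parameter models can never end below the model they embed
    base <- fit_mle("GU", errors, NULL, box, coarse_bins, min_n)
    starts <- c(starts, list(c(
      mu = base$params$mu, sigma = base$params$sigma,
      w_u = min(base$params$w_u, box$w_u[2] - 1e-9), w_m = box$w_m[1])))
  }
  opt <- NULL
  for (s0 in starts) {
    o <- tryCatch(
      stats::optim(s0, neg_ll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(opt) || o$value < opt$value)) opt <- o
  }
  fallback <- is.null(opt) || -opt$value < scan$ll_max
  if (fallback) {
    warning("refinement did not improve on the grid maximum; ",
            "returning the grid point")
    theta <- scan$par_max; ll <- scan$ll_max
  } else {
    theta <- opt$par; ll <- -opt$value
  }
  params <- list(mu = unname(theta[["mu"]]), sigma = unname(theta[["sigma"]]),
                 w_u = if (spec$uses_wu) unname(theta[["w_u"]]) else 0,
                 w_m = if (spec$uses_wm) unname(theta[["w_m"]]) else 0)
  structure(list(model_id = spec$model_id, params = params, ln_l_max = ll,
                 n = length(errors), fallback = fallback),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit %s: lnLmax %.3f (n = %d)>\n", x$model_id,
              x$ln_l_max, x$n))
  cat(sprintf("  mu %.3f  sigma %.3f  w_u %.3f  w_m %.3f\n",
              x$params$mu, x$params$sigma, x$params$w_u, x$params$w_m))
  invisible(x)
}
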