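#' Mixture model specification
#'
#' The embedded family of error-distribution models over signed wrapped
#' report errors on \[-90, 90):
#' \describe{
#'   \item{G}{Gaussian encoding only (2 free parameters: mu, sigma).}
#'   \item{GU}{Gaussian + uniform guessing (3: mu, sigma, w_u).}
#'   \item{GUCA}{GU + a misbinding Gaussian centred on the distractor
#'     with the closest orientation to the target (4: + w_m).}
#'   \item{GUNN}{GU + two misbinding Gaussians centred on the two
#'     positionally nearest-neighbour distractors, sharing the
#'     misbinding weight equally (4: + w_m).}
#' }
#' All Gaussian components share the encoding SD `sigma` and are
#' truncated to \[-90, 90\] and renormalised.
#'
#' @param model_id one of `"G"`, `"GU"`, `"GUCA"`, `"GUNN"`.
#' @return object of class `mixture_spec` with elements `model_id`,
#'   `k` (free-parameter count), `par_names`, `uses_wu`, `uses_wm`.
#' @export
mixture_spec <- function(model_id = c("G", "GU", "GUCA", "GUNN")) {
  model_id <- match.arg(model_id)
  k <- c(G = 2L, GU = 3L, GUCA = 4L, GUNN = 4L)[[model_id]]
  par_names <- c("mu", "sigma", if (model_id != "G") "w_u",
                 if (k == 4L) "w_m")
  structure(list(model_id = model_id, k = k, par_names = par_names,
                 uses_wu = model_id != "G", uses_wm = k == 4L),
            class = "mixture_spec")
}

.as_spec <- function(model) {
  if (inherits(model, "mixture_spec")) model else mixture_spec(model)
}

#' Per-trial misbinding contexts
#'
#' Misbinding centres expressed on the error axis: `c_ca` is
#' `wrap(closest-angle distractor - target)`, and `c_nn1`/`c_nn2` are
#' the wrapped offsets of the two positionally adjacent distractors
#' (display positions live on a circle). Required by the GUCA and GUNN
#' models.
#'
#' @param table trial table with `target_deg`, `target_pos`,
#'   `distractor_degs` columns.
#' @return data frame with columns `c_ca`, `c_nn1`, `c_nn2` (the
#'   latter two `NA` for set size 2), one row per trial.
#' @export
trial_contexts <- function(table) {
  tab <- as.data.frame(table)
  need <- c("target_deg", "target_pos", "distractor_degs")
  if (!all(need %in% names(tab)))
    stop("table lacks display columns: ", paste(setdiff(need, names(tab)),
                                                collapse = ", "))
  .misbind_centers(tab$target_deg, tab$target_pos, tab$distractor_degs)
}

# truncated-normal normalising constant on [-90, 90]
.tn_mass <- function(mean, sd) {
  pmax(stats::pnorm(90, mean, sd) - stats::pnorm(-90, mean, sd), 1e-300)
}

# truncated-and-renormalised Gaussian density on [-90, 90], per degree
.dtnorm <- function(x, mean, sd) {
  stats::dnorm(x, mean, sd) / .tn_mass(mean, sd)
}

.check_params <- function(spec, params) {
  p <- as.list(params)
  if (is.null(p$mu) || is.null(p$sigma)) stop("params need mu and sigma")
  p$w_u <- if (is.null(p$w_u)) 0 else p$w_u
  p$w_m <- if (is.null(p$w_m)) 0 else p$w_m
  if (p$sigma <= 0) stop("sigma must be > 0")
  if (p$w_u < 0 || p$w_m < 0 || p$w_u + p$w_m > 1 + 1e-12)
    stop("weights must be >= 0 with w_u + w_m <= 1")
  if (!spec$uses_wu && p$w_u != 0) stop("model has no uniform component")
  if (!spec$uses_wm && p$w_m != 0) stop("model has no misbinding component")
  p
}

#' Mixture density of a signed report error
#'
#' Probability density (per degree) of an error under one of the
#' G/GU/GUCA/GUNN models:
#' `(1 - w_u - w_m) * Ntr(x; mu, sigma) + w_u / 180 + misbinding`,
#' where `Ntr` is a Gaussian truncated to \[-90, 90\] and renormalised.
#' GUCA's misbinding term is `w_m * Ntr(x; c_ca, sigma)`; GUNN's is
#' `(w_m/2) * (Ntr(x; c_nn1, sigma) + Ntr(x; c_nn2, sigma))`. The
#' misbinding Gaussians share `sigma` with the encoding component and
#' carry no extra bias, so GUCA/GUNN are one-parameter extensions of GU.
#'
#' @param x signed error(s) in \[-90, 90).
#' @param params list or named vector with `mu`, `sigma` and, as the
#'   model requires, `w_u`, `w_m`.
#' @param model a [mixture_spec()] or model id string.
#' @param ctx per-trial contexts ([trial_contexts()]), required for
#'   GUCA/GUNN; rows aligned with `x`.
#' @return density values, per degree; integrates to 1 over
#'   \[-90, 90\].
#' @export
error_density <- function(x, params, model, ctx = NULL) {
  spec <- .as_spec(model)
  p <- .check_params(spec, params)
  if (any(x < -90 | x >= 90)) stop("errors must lie in [-90, 90)")
  dens <- (1 - p$w_u - p$w_m) * .dtnorm(x, p$mu, p$sigma) + p$w_u / 180
  if (spec$uses_wm) {
    if (is.null(ctx)) stop(spec$model_id, " requires trial contexts")
    if (nrow(ctx) != length(x)) stop("ctx rows must match errors")
    if (spec$model_id == "GUCA") {
      dens <- dens + p$w_m * .dtnorm(x, ctx$c_ca, p$sigma)
    } else {
      if (anyNA(ctx$c_nn1) || anyNA(ctx$c_nn2))
        stop("GUNN requires both nearest-neighbour centres")
      dens <- dens + (p$w_m / 2) * (.dtnorm(x, ctx$c_nn1, p$sigma) +
                                      .dtnorm(x, ctx$c_nn2, p$sigma))
    }
  }
  dens
}

#' Total log-likelihood of a model
#'
#' Sum of per-trial log densities under [error_density()], with a
#' density floor of 1e-300 guarding against `-Inf`.
#'
#' @param model a [mixture_spec()] or id string.
#' @param params parameter list, see [error_density()].
#' @param errors signed wrapped errors.
#' @param ctx per-trial contexts for GUCA/GUNN.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(model, params, errors, ctx = NULL) {
  if (!length(errors)) stop("empty data")
  sum(log(pmax(error_density(errors, params, model, ctx), 1e-300)))
}
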