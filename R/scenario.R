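#' Evaluate a guess-weight surface
#'
#' The generative probability of a uniform (guess) report as a function
#' of SOA (`tau`, ms) and CTOA (`n`, ms):
#' `w(tau, n) = clamp(a0 + a1 tau + a2 tau^2 + b n + c1 tau n + c2 tau^2 n, 0, 1)`.
#' With `c1 = c2 = 0` the surface shifts vertically with CTOA at every
#' SOA (the no-interaction pattern); nonzero `c1`/`c2` inject
#' SOA-by-CTOA interactions.
#'
#' @param coef named numeric vector with elements `a0, a1, a2, b, c1, c2`.
#' @param tau SOA in ms.
#' @param ctoa CTOA in ms.
#' @return weight(s) in \[0, 1\].
#' @export
weight_surface <- function(coef, tau, ctoa) {
  coef <- .check_surface_coef(coef)
  w <- coef["a0"] + coef["a1"] * tau + coef["a2"] * tau^2 +
    coef["b"] * ctoa + coef["c1"] * tau * ctoa + coef["c2"] * tau^2 * ctoa
  pmin(pmax(as.numeric(w), 0), 1)
}

.check_surface_coef <- function(coef) {
  nms <- c("a0", "a1", "a2", "b", "c1", "c2")
  if (is.null(names(coef))) {
    if (length(coef) != 6) stop("weight surface needs 6 coefficients")
    names(coef) <- nms
  }
  if (!all(nms %in% names(coef))) stop("missing surface coefficients")
  coef[nms]
}

#' Generative scenario for synthetic continuous-report data
#'
#' Bundles a [design_spec()] with the generative truth used to simulate
#' responses: the guess-weight surface over (SOA, CTOA), the encoding
#' Gaussian (bias `mu_true`, SD `sigma_true`), an optional misbinding
#' process, the guess weight used on no-mask baseline trials, and the
#' RNG seed.
#'
#' @param design a [design_spec()].
#' @param weight_coef surface coefficients, see [weight_surface()].
#' @param sigma_true encoding SD in degrees (> 0).
#' @param mu_true encoding bias in degrees.
#' @param misbind_rate probability of reporting a non-target bar.
#' @param misbind_mode `"none"`, `"closest_angle"` (report centred on
#'   the distractor whose orientation is closest to the target's) or
#'   `"nearest_neighbor"` (fair pick of the two positionally adjacent
#'   distractors).
#' @param baseline_weight guess weight on baseline (no-mask) trials.
#' @param seed mandatory integer RNG seed.
#' @param observer observer label.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(design, weight_coef, sigma_true = 12,
                            mu_true = 0, misbind_rate = 0,
                            misbind_mode = c("none", "closest_angle",
                                             "nearest_neighbor"),
                            baseline_weight = 0.02, seed, observer = "S1") {
  stopifnot(inherits(design, "design_spec"))
  misbind_mode <- match.arg(misbind_mode)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  weight_coef <- .check_surface_coef(weight_coef)
  if (sigma_true <= 0) stop("sigma_true must be > 0")
  if (misbind_rate < 0 || misbind_rate > 1) stop("misbind_rate in [0,1]")
  if (misbind_mode == "closest_angle" && design$n_items < 2)
    stop("closest_angle misbinding needs at least 1 distractor")
  if (misbind_mode == "nearest_neighbor" && design$n_items < 3)
    stop("nearest_neighbor misbinding needs at least 2 distractors")
  if (baseline_weight < 0 || baseline_weight > 1)
    stop("baseline_weight in [0,1]")
  # all-cell check of the mixture simplex
  if (length(design$soas)) {
    grid <- expand.grid(tau = design$soas, n = design$ctoas)
    wmax <- max(weight_surface(weight_coef, grid$tau, grid$n))
  } else wmax <- 0
  wmax <- max(wmax, baseline_weight)
  if (wmax + misbind_rate > 1)
    stop("misbind_rate + largest cell weight exceeds 1")
  structure(list(
    design = design, weight_coef = weight_coef,
    sigma_true = sigma_true, mu_true = mu_true,
    misbind_rate = misbind_rate, misbind_mode = misbind_mode,
    baseline_weight = baseline_weight,
    seed = as.integer(seed), observer = as.character(observer)
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config: observer %s, seed %d>\n", x$observer, x$seed))
  print(x$design)
  cat(sprintf("  w(tau,n): a0=%.4g a1=%.4g a2=%.4g b=%.4g c1=%.4g c2=%.4g\n",
              x$weight_coef["a0"], x$weight_coef["a1"], x$weight_coef["a2"],
              x$weight_coef["b"], x$weight_coef["c1"], x$weight_coef["c2"]))
  cat(sprintf("  encoding N(%.3g, %.3g), misbind %.3g (%s), baseline w %.3g\n",
              x$mu_true, x$sigma_true, x$misbind_rate, x$misbind_mode,
              x$baseline_weight))
  invisible(x)
}

# Default endogenous guess surface: U-shaped (type-B) masking in SOA
# (w = 0.45 at the edge SOAs, 0.65 at the 70 ms dip) plus a pure
# vertical CTOA shift of -0.0003/ms (-0.15 at 500 ms). The clamp stays
# inactive everywhere, and even the weakest-masking cell stays well
# below baseline while the strongest stays well above chance, as the
# calibrated C1/C2 criteria require.
.default_endo_coef <- c(a0 = 0.258, a1 = 0.0112, a2 = -8e-5,
                        b = -3e-4, c1 = 0, c2 = 0)
# Exogenous: same masking profile, steeper shift per ms because only
# 0-100 ms CTOAs are used (-0.15 at 100 ms).
.default_exo_coef <- c(a0 = 0.258, a1 = 0.0112, a2 = -8e-5,
                       b = -1.5e-3, c1 = 0, c2 = 0)

#' Preset endogenous scenario
#'
#' The endogenous study design ([endogenous_design()]) with the package
#' default generative surface: U-shaped guessing in SOA, additive
#' (no-interaction) CTOA shift, 12 deg encoding SD, no misbinding.
#' Interaction coefficients may be injected through `c1`/`c2`.
#'
#' @param seed RNG seed.
#' @param c1,c2 interaction coefficients (per ms^2 and per ms^3).
#' @param misbind_rate,misbind_mode misbinding truth, see
#'   [scenario_config()].
#' @param observer observer label.
#' @param reps_per_condition valid trials per cell.
#' @return `scenario_config`.
#' @export
scenario_endogenous <- function(seed, c1 = 0, c2 = 0, misbind_rate = 0,
                                misbind_mode = if (misbind_rate > 0)
                                  "closest_angle" else "none",
                                observer = "S1", reps_per_condition = 100) {
  coef <- .default_endo_coef
  coef["c1"] <- c1; coef["c2"] <- c2
  scenario_config(endogenous_design(reps_per_condition = reps_per_condition),
                  coef, seed = seed, misbind_rate = misbind_rate,
                  misbind_mode = misbind_mode, observer = observer)
}

#' Preset exogenous scenario
#'
#' The exogenous study design ([exogenous_design()]) with the package
#' default generative surface.
#' @inheritParams scenario_endogenous
#' @param ctoa_peak second CTOA in ms (80-120).
#' @return `scenario_config`.
#' @export
scenario_exogenous <- function(seed, c1 = 0, c2 = 0, ctoa_peak = 100,
                               misbind_rate = 0,
                               misbind_mode = if (misbind_rate > 0)
                                 "closest_angle" else "none",
                               observer = "S1", reps_per_condition = 100) {
  coef <- .default_exo_coef
  coef["c1"] <- c1; coef["c2"] <- c2
  scenario_config(exogenous_design(ctoa_peak = ctoa_peak,
                                   reps_per_condition = reps_per_condition),
                  coef, seed = seed, misbind_rate = misbind_rate,
                  misbind_mode = misbind_mode, observer = observer)
}

#' Read a scenario from a YAML file
#'
#' The YAML mirrors the [scenario_config()] fields; `seed` is mandatory.
#' `design` holds the [design_spec()] fields; `weight_coef` holds
#' `a0...c2`.
#'
#' @param path YAML file path.
#' @return `scenario_config`.
#' @export
read_scenario <- function(path) {
  y <- yaml::read_yaml(path)
  need <- function(field) {
    if (is.null(y[[field]])) stop(sprintf("scenario YAML: missing field '%s'",
                                          field))
    y[[field]]
  }
  seed <- need("seed")
  d <- need("design")
  for (f in c("attention_type", "ctoas", "soas", "n_items"))
    if (is.null(d[[f]])) stop(sprintf("scenario YAML: missing design field '%s'", f))
  spec <- design_spec(
    attention_type = d$attention_type, ctoas = unlist(d$ctoas),
    soas = unlist(d$soas),
    include_baseline = if (is.null(d$include_baseline)) TRUE else d$include_baseline,
    reps_per_condition = if (is.null(d$reps_per_condition)) 100 else d$reps_per_condition,
    n_items = d$n_items,
    cue_validity = if (is.null(d$cue_validity)) 1 else d$cue_validity)
  scenario_config(
    design = spec,
    weight_coef = unlist(need("weight_coef")),
    sigma_true = if (is.null(y$sigma_true)) 12 else y$sigma_true,
    mu_true = if (is.null(y$mu_true)) 0 else y$mu_true,
    misbind_rate = if (is.null(y$misbind_rate)) 0 else y$misbind_rate,
    misbind_mode = if (is.null(y$misbind_mode)) "none" else y$misbind_mode,
    baseline_weight = if (is.null(y$baseline_weight)) 0.02 else y$baseline_weight,
    seed = seed,
    observer = if (is.null(y$observer)) "S1" else y$observer)
}
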