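#' Bootstrap mixture parameters within one cell
#'
#' Nonparametric bootstrap of the winning mixture model's parameters
#' for a single (CTOA, SOA) cell: `B` resamples of the cell's trials
#' drawn with replacement at the cell's own size, the model refitted to
#' each resample, and per-parameter means and standard errors taken
#' over the refits. Refit failures are counted; more than 10% failures
#' invalidates the cell.
#'
#' @param errors signed wrapped errors of the cell (>= 20 trials).
#' @param ctx per-trial contexts for GUCA/GUNN, or `NULL`.
#' @param model a [mixture_spec()] or id string.
#' @param B number of resamples (study default 500).
#' @param seed integer RNG seed; summaries are a pure function of
#'   (data, seed, B).
#' @param box a [prior_box()].
#' @param coarse_bins grid resolution passed to [fit_mle()].
#' @return object of class `bootstrap_summary`: data frame `parameter`,
#'   `mean`, `se`, `B`, `n_fail`, plus attributes `valid` and `n`.
#' @export
bootstrap_cell <- function(errors, ctx = NULL, model = "GU", B = 500,
                           seed = 1L, box = prior_box(), coarse_bins = 7) {
  spec <- .as_spec(model)
  n <- length(errors)
  if (n < 20) stop("cell has fewer than 20 trials")
  if (B < 2) stop("B must be >= 2")
  idx <- withr::with_seed(seed,
    matrix(sample.int(n, n * B, replace = TRUE), nrow = n))
  draws <- matrix(NA_real_, nrow = B, ncol = spec$k,
                  dimnames = list(NULL, spec$par_names))
  n_fail <- 0L
  for (b in seq_len(B)) {
    i <- idx[, b]
    fit <- tryCatch(
      suppressWarnings(fit_mle(spec, errors[i],
                               if (!is.null(ctx)) ctx[i, , drop = FALSE],
                               box, coarse_bins = coarse_bins)),
      error = function(e) NULL)
    if (is.null(fit)) { n_fail <- n_fail + 1L; next }
    draws[b, ] <- unlist(fit$params[spec$par_names])
  }
  ok <- stats::complete.cases(draws)
  valid <- n_fail <= 0.1 * B
  if (!valid)
    warning(sprintf("%d/%d bootstrap refits failed; cell invalidated",
                    n_fail, B))
  out <- data.frame(
    parameter = spec$par_names,
    mean = colMeans(draws[ok, , drop = FALSE]),
    se = apply(draws[ok, , drop = FALSE], 2, stats::sd),
    B = B, n_fail = n_fail, row.names = NULL)
  structure(out, class = c("bootstrap_summary", "data.frame"),
            valid = valid, n = n, model_id = spec$model_id)
}

#' Bootstrap every masked cell of an observer
#'
#' Applies [bootstrap_cell()] to each (CTOA, SOA) cell of the masked,
#' validly cued trials, with per-cell sub-seeds derived from `seed`.
#'
#' @param table trial table.
#' @param observer observer id (optional for single-observer tables).
#' @param model mixture model to refit.
#' @param B resamples per cell.
#' @param seed master seed.
#' @param box a [prior_box()].
#' @param coarse_bins grid resolution passed to [fit_mle()].
#' @return data frame `observer`, `ctoa_ms`, `soa_ms`, `parameter`,
#'   `mean`, `se`, `B`, `n_fail`.
#' @export
bootstrap_cells <- function(table, observer = NULL, model = "GU", B = 500,
                            seed = 1L, box = prior_box(), coarse_bins = 7) {
  spec <- .as_spec(model)
  tab <- .subset_observer(table, observer, valid_only = TRUE)
  tab <- tab[!is.na(tab$soa_ms), , drop = FALSE]
  cells <- unique(tab[, c("ctoa_ms", "soa_ms")])
  cells <- cells[order(cells$ctoa_ms, cells$soa_ms), , drop = FALSE]
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1, nrow(cells)))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    d <- tab[tab$ctoa_ms == cells$ctoa_ms[i] &
               tab$soa_ms == cells$soa_ms[i], , drop = FALSE]
    ctx <- if (spec$uses_wm) trial_contexts(d) else NULL
    s <- bootstrap_cell(d$error_deg, ctx, spec, B = B, seed = seeds[i],
                        box = box, coarse_bins = coarse_bins)
    out[[i]] <- cbind(observer = d$observer[1],
                      ctoa_ms = cells$ctoa_ms[i],
                      soa_ms = cells$soa_ms[i], as.data.frame(s))
  }
  do.call(rbind, out)
}

#' Ladder regression of a parameter surface
#'
#' Fits the regression ladder to per-cell means of one mixture
#' parameter over the (SOA, CTOA) design and selects by BIC, asking
#' whether the parameter carries an attention-masking interaction. The
#' regression is unweighted; bootstrap SEs are descriptive only.
#'
#' @param summaries data frame with columns `ctoa_ms`, `soa_ms`,
#'   `parameter`, `mean` (e.g. from [bootstrap_cells()]).
#' @param parameter which parameter surface to regress (e.g. `"w_u"`).
#' @param convention odds convention for [select_model()].
#' @return list with `fits` and `selection`, as [masking_ladder()].
#' @export
regress_parameter_surface <- function(summaries, parameter = "w_u",
                                      convention = "exp") {
  d <- summaries[summaries$parameter == parameter, , drop = FALSE]
  if (nrow(d) < 6) stop("need at least 6 cells to fit the ladder")
  fits <- fit_ladder(d$mean, d$soa_ms, d$ctoa_ms)
  list(fits = fits, selection = select_model(fits, convention))
}

#' Correlation between a masking function and a parameter curve
#'
#' Pearson correlation, at one CTOA, between mean transformed
#' performance over SOA and a mixture-parameter curve over the same
#' SOAs. A strong (negative) correlation for the guess weight indicates
#' that masking acts primarily through guessing.
#'
#' @param masking a [masking_function()].
#' @param parameter_curve data frame with `soa_ms` and `mean` for the
#'   parameter at the same CTOA.
#' @return list with `r` (Pearson coefficient, `NA` with a reason for
#'   degenerate input), `n_points`, `ctoa_ms`.
#' @export
correlate_parameter_with_masking <- function(masking, parameter_curve) {
  stopifnot(inherits(masking, "masking_function"))
  m <- merge(masking$points[, c("soa_ms", "mean_tp")],
             parameter_curve[, c("soa_ms", "mean")], by = "soa_ms")
  if (nrow(m) < 3) stop("need at least 3 matching SOA points")
  degenerate <- stats::sd(m$mean_tp) == 0 || stats::sd(m$mean) == 0
  list(r = if (degenerate) NA_real_ else stats::cor(m$mean_tp, m$mean),
       reason = if (degenerate) "zero-variance series" else NULL,
       n_points = nrow(m), ctoa_ms = masking$ctoa_ms)
}
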