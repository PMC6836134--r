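# Term sets of the embedded regression ladder. Column labels follow the
# fixed predictor order (1, tau, tau^2, n, tau*n, tau^2*n) with tau =
# SOA (ms) and n = CTOA (ms).
.ladder_terms <- list(
  M1  = c("1"),
  M2  = c("1", "tau"),
  M3  = c("1", "n"),
  M4  = c("1", "tau:n"),
  M5  = c("1", "tau2"),
  M6  = c("1", "tau2:n"),
  M7  = c("1", "tau", "n"),
  M8  = c("1", "tau", "tau:n"),
  M9  = c("1", "n", "tau:n"),
  M10 = c("1", "tau2", "n"),
  M11 = c("1", "tau2", "tau2:n"),
  M12 = c("1", "n", "tau2:n"),
  M13 = c("1", "tau", "tau2"),
  M14 = c("1", "tau", "n", "tau:n"),
  M15 = c("1", "tau2", "n", "tau2:n"),
  M16 = c("1", "tau", "tau2", "n"),
  M17 = c("1", "tau", "tau2", "tau:n"),
  M18 = c("1", "tau", "tau2", "tau2:n"),
  M19 = c("1", "tau", "tau2", "n", "tau:n"),
  M20 = c("1", "tau", "tau2", "n", "tau2:n"),
  M21 = c("1", "tau", "tau2", "n", "tau:n", "tau2:n"))

#' The regression-model ladder
#'
#' The 21 embedded linear/polynomial models over SOA (`tau`, ms) and
#' CTOA (`n`, ms) used to test for attention-masking interactions. M16
#' (`1, tau, tau^2, n`) is the largest purely additive model with a
#' quadratic masking profile; M19-M21 add `tau:n` and/or `tau^2:n`
#' interaction terms; M21 is the full model.
#'
#' @return data frame with `model` id, `p` (number of coefficients)
#'   and a `terms` string.
#' @export
ladder_models <- function() {
  data.frame(model = names(.ladder_terms),
             p = lengths(.ladder_terms),
             terms = vapply(.ladder_terms, paste, character(1),
                            collapse = " + "),
             row.names = NULL)
}

#' Design matrix of a ladder model
#'
#' Builds the predictor matrix from SOA and CTOA, keeping the fixed
#' column order `(1, tau, tau^2, n, tau*n, tau^2*n)` filtered to the
#' model's terms. Baseline trials (SOA `NA`) have no defined `tau` and
#' are rejected.
#'
#' @param model ladder id (`"M1"` ... `"M21"`).
#' @param tau SOA values in ms.
#' @param n CTOA values in ms.
#' @return numeric matrix, one row per observation.
#' @export
design_matrix <- function(model, tau, n) {
  terms <- .ladder_terms[[model]]
  if (is.null(terms)) stop("unknown ladder model: ", model)
  if (anyNA(tau)) stop("baseline trials (NA SOA) have no ladder row")
  if (length(tau) != length(n)) stop("tau and n lengths differ")
  full <- cbind("1" = rep(1, length(tau)), tau = tau, tau2 = tau^2,
                n = n, "tau:n" = tau * n, "tau2:n" = tau^2 * n)
  full[, terms, drop = FALSE]
}

#' Ordinary least squares fit of one ladder model
#'
#' Fits the model by least squares and reports RSS, BIC and adjusted
#' R^2. BIC uses the Gaussian profile form
#' `n log(max(rss, 1e-12)/n) + p log(n)`, so only differences between
#' ladder members are meaningful. Rank-deficient designs (e.g. a CTOA
#' term with a single CTOA level) are flagged.
#'
#' @param model ladder id.
#' @param y responses (e.g. trial-level transformed performance, or
#'   per-cell parameter means).
#' @param tau,n predictors in ms, aligned with `y`.
#' @return object of class `ladder_fit`: `model`, `coefficients`,
#'   `p`, `n_obs`, `rss`, `bic`, `adj_r2`, `rank_deficient`.
#' @export
fit_ols <- function(model, y, tau, n) {
  X <- design_matrix(model, tau, n)
  p <- ncol(X)
  n_obs <- length(y)
  if (n_obs <= p) stop("need more observations than coefficients")
  fit <- stats::lm.fit(X, y)
  rank_deficient <- fit$rank < p
  if (rank_deficient)
    warning(sprintf("%s: predictor matrix rank %d < %d (aliased terms)",
                    model, fit$rank, p))
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(
    model = model, coefficients = fit$coefficients, p = p, n_obs = n_obs,
    rss = rss,
    bic = n_obs * log(max(rss, 1e-12) / n_obs) + p * log(n_obs),
    adj_r2 = if (is.na(r2)) NA_real_
             else 1 - (1 - r2) * (n_obs - 1) / (n_obs - p - 1),
    rank_deficient = rank_deficient), class = "ladder_fit")
}

#' Fit the whole ladder
#'
#' @inheritParams fit_ols
#' @param models ladder ids to fit (default all 21).
#' @return list of `ladder_fit` objects, named by model id, with class
#'   `ladder_fits`.
#' @export
fit_ladder <- function(y, tau, n, models = names(.ladder_terms)) {
  out <- lapply(models, fit_ols, y = y, tau = tau, n = n)
  names(out) <- models
  structure(out, class = "ladder_fits")
}

#' @export
as.data.frame.ladder_fits <- function(x, ...) {
  data.frame(model = vapply(x, `[[`, character(1), "model"),
             p = vapply(x, `[[`, integer(1), "p"),
             rss = vapply(x, `[[`, numeric(1), "rss"),
             bic = vapply(x, `[[`, numeric(1), "bic"),
             adj_r2 = vapply(x, `[[`, numeric(1), "adj_r2"),
             row.names = NULL)
}

#' Select the best ladder model by BIC
#'
#' The winner has the smallest BIC. Pairwise differences
#' `dBIC = BIC_A - BIC_B` are reported with the odds convention
#' `e^-dBIC`-to-1 in favour of A (`convention = "exp"`); the common
#' BIC-to-Bayes-factor approximation `e^-dBIC/2` is available as
#' `convention = "half"`. Models whose BIC lies within 2 of the winner
#' are flagged as nearly equal.
#'
#' @param fits a `ladder_fits` list (see [fit_ladder()]); all fits must
#'   share the same responses.
#' @param convention odds convention, `"exp"` (default) or `"half"`.
#' @return object of class `ladder_selection`: `winner`, `table`
#'   (per-model BIC, dBIC vs winner, odds vs winner, tie flag),
#'   `delta` (pairwise antisymmetric dBIC matrix), `odds`.
#' @export
select_model <- function(fits, convention = c("exp", "half")) {
  convention <- match.arg(convention)
  stopifnot(inherits(fits, "ladder_fits"))
  ns <- vapply(fits, `[[`, integer(1), "n_obs")
  if (length(unique(ns)) != 1)
    stop("ladder fits disagree on the number of observations")
  bic <- vapply(fits, `[[`, numeric(1), "bic")
  winner <- names(bic)[which.min(bic)]
  delta <- outer(bic, bic, "-")
  expo <- if (convention == "exp") 1 else 0.5
  dvw <- bic - bic[winner]
  tab <- data.frame(model = names(bic), bic = unname(bic),
                    dbic_vs_winner = unname(dvw),
                    odds_vs_winner = unname(exp(-expo * dvw)),
                    nearly_equal = unname(abs(dvw) <= 2),
                    row.names = NULL)
  structure(list(winner = winner, table = tab, delta = delta,
                 odds = exp(-expo * delta), convention = convention),
            class = "ladder_selection")
}

#' @export
print.ladder_selection <- function(x, ...) {
  ties <- setdiff(x$table$model[x$table$nearly_equal], x$winner)
  cat(sprintf("<ladder_selection: winner %s (BIC %.2f)%s>\n", x$winner,
              x$table$bic[x$table$model == x$winner],
              if (length(ties)) paste0("; nearly equal: ",
                                       paste(ties, collapse = ", "))
              else ""))
  invisible(x)
}

#' Ladder analysis of masking performance
#'
#' Fits the full ladder to transformed performance of the masked,
#' validly cued trials of one observer, either at the trial level
#' (default, using every trial) or on cell means.
#'
#' @param table trial table.
#' @param observer observer id (optional for single-observer tables).
#' @param level `"trial"` or `"cell"` responses.
#' @param valid_only drop invalid-cue trials.
#' @param convention odds convention passed to [select_model()].
#' @return list with `fits` (`ladder_fits`) and `selection`
#'   (`ladder_selection`).
#' @export
masking_ladder <- function(table, observer = NULL,
                           level = c("trial", "cell"), valid_only = TRUE,
                           convention = "exp") {
  level <- match.arg(level)
  tab <- .subset_observer(table, observer, valid_only)
  tab <- tab[!is.na(tab$soa_ms), , drop = FALSE]
  if (!nrow(tab)) stop("no masked trials")
  if (level == "trial") {
    y <- transformed_performance(tab$error_deg)
    tau <- tab$soa_ms; n <- tab$ctoa_ms
  } else {
    cells <- stats::aggregate(
      transformed_performance(tab$error_deg),
      by = list(tau = tab$soa_ms, n = tab$ctoa_ms), FUN = mean)
    y <- cells$x; tau <- cells$tau; n <- cells$n
  }
  fits <- fit_ladder(y, tau, n)
  list(fits = fits, selection = select_model(fits, convention))
}
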