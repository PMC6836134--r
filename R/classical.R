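#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Satterthwaite degrees of
#' freedom, as used for the ceiling criterion (masked vs baseline
#' performance). Thin wrapper over [stats::t.test()] returning a flat
#' result. When both samples are constant and equal, `t = 0, p = 1` by
#' convention.
#'
#' @param x,y numeric samples (each >= 2 values).
#' @param alternative `"two.sided"`, `"less"` (mean(x) < mean(y)) or
#'   `"greater"`.
#' @return object of class `stat_test`: `statistic`, `df`, `p`,
#'   `tail` (`"one"`/`"two"`), `method`.
#' @export
welch_t <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  res <- tryCatch(stats::t.test(x, y, var.equal = FALSE,
                                alternative = alternative),
                  error = function(e) NULL)
  if (is.null(res)) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
      return(.stat_test(0, NA_real_, 1, alternative, "welch_t"))
    stop("t-test failed on degenerate input")
  }
  .stat_test(unname(res$statistic), unname(res$parameter), res$p.value,
             alternative, "welch_t")
}

#' One-sample t-test
#'
#' Test of a sample mean against a reference value, as used for the
#' floor criterion (worst masked performance vs the 0.5 chance level);
#' df = n - 1. A constant sample equal to `mu0` is reported as
#' degenerate.
#'
#' @param x numeric sample (>= 2 values).
#' @param mu0 reference mean.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return `stat_test`; `degenerate = TRUE` when t is undefined.
#' @export
one_sample_t <- function(x, mu0 = 0.5,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2) stop("need >= 2 values")
  if (stats::sd(x) == 0) {
    out <- .stat_test(NA_real_, length(x) - 1, NA_real_, alternative,
                      "one_sample_t")
    out$degenerate <- TRUE
    return(out)
  }
  res <- stats::t.test(x, mu = mu0, alternative = alternative)
  .stat_test(unname(res$statistic), unname(res$parameter), res$p.value,
             alternative, "one_sample_t")
}

.stat_test <- function(statistic, df, p, alternative, method,
                       effect = NULL) {
  structure(list(statistic = statistic, df = df, p = p,
                 tail = if (alternative == "two.sided") "two" else "one",
                 alternative = alternative, method = method,
                 effect = effect, degenerate = FALSE),
            class = "stat_test")
}

#' @export
print.stat_test <- function(x, ...) {
  df <- if (length(x$df) == 2)
    sprintf("%g, %g", x$df[1], x$df[2]) else sprintf("%.4g", x$df)
  cat(sprintf("<%s: stat %.4g, df %s, p %.4g (%s-tailed)%s>\n", x$method,
              x$statistic, df, x$p, x$tail,
              if (!is.null(x$effect))
                sprintf(", partial eta^2 %.3f", x$effect) else ""))
  invisible(x)
}

#' t-distribution tail probability
#'
#' P-value of an observed t statistic at (possibly fractional,
#' Satterthwaite) degrees of freedom. One-tailed takes the tail in the
#' direction of the observed statistic; two-tailed doubles it.
#'
#' @param t observed statistic.
#' @param df degrees of freedom (> 0; fractional allowed).
#' @param tail `"two"` or `"one"`.
#' @return p-value.
#' @export
t_pvalue <- function(t, df, tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (any(df <= 0)) stop("df must be > 0")
  p1 <- stats::pt(-abs(t), df)
  if (tail == "two") 2 * p1 else p1
}

#' F-distribution upper-tail probability
#'
#' @param f observed F statistic (>= 0).
#' @param d1,d2 numerator and denominator degrees of freedom.
#' @return p-value.
#' @export
f_pvalue <- function(f, d1, d2) {
  if (any(f < 0)) stop("F must be >= 0")
  stats::pf(f, d1, d2, lower.tail = FALSE)
}

#' One-way repeated-measures ANOVA
#'
#' Single within-subject factor, one observation per (subject, level)
#' cell, fitted with [stats::aov()] using a subject error stratum:
#' `F = MS_level / MS_(subject x level)` with df `(L-1, (S-1)(L-1))`,
#' and partial eta squared `SS_level / (SS_level + SS_error)`.
#'
#' @param mat numeric matrix, subjects in rows, factor levels in
#'   columns; complete (no `NA`).
#' @return `stat_test` with `df = c(d1, d2)` and `effect` = partial
#'   eta squared.
#' @export
rm_anova_oneway <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("matrix must be complete")
  if (nrow(mat) < 2 || ncol(mat) < 2) stop("need >= 2 subjects and levels")
  d <- data.frame(y = as.vector(mat),
                  subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                  level = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  fit <- stats::aov(y ~ level + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_eff <- tab["level", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  f <- tab["level", "F value"]
  d1 <- tab["level", "Df"]; d2 <- tab["Residuals", "Df"]
  out <- .stat_test(f, c(d1, d2), f_pvalue(f, d1, d2), "two.sided",
                    "rm_anova_oneway", effect = ss_eff / (ss_eff + ss_err))
  out$tail <- "upper"
  out
}

#' Ceiling/floor criterion checks
#'
#' The two design-validation criteria for masking experiments:
#' \describe{
#'   \item{C1 (no ceiling)}{the best masked cell (highest mean
#'     transformed performance) must be significantly *below* the
#'     baseline of the same CTOA - one-tailed Welch test.}
#'   \item{C2 (no floor)}{the worst masked cell must be significantly
#'     *above* the 0.5 chance level - one-tailed one-sample test.}
#' }
#' Both must reject at `alpha` for a PASS. One-tailed tests are used
#' because the criteria are directional.
#'
#' @param table trial table.
#' @param observer observer id (optional for single-observer tables).
#' @param alpha significance level.
#' @param valid_only drop invalid-cue trials.
#' @return object of class `criteria_report`: `c1`, `c2` (each with
#'   the cell used, `stat_test` and pass flag), `pass` overall,
#'   `alpha`. If no baseline trials exist, C1 is marked not evaluable.
#' @export
check_ceiling_floor <- function(table, observer = NULL, alpha = 0.05,
                                valid_only = TRUE) {
  tab <- .subset_observer(table, observer, valid_only)
  masked <- tab[!is.na(tab$soa_ms), , drop = FALSE]
  if (!nrow(masked)) stop("no masked trials")
  tp <- transformed_performance(masked$error_deg)
  key <- interaction(masked$ctoa_ms, masked$soa_ms, drop = TRUE)
  mtab <- data.frame(
    ctoa_ms = vapply(split(masked$ctoa_ms, key), `[`, numeric(1), 1),
    soa_ms = vapply(split(masked$soa_ms, key), `[`, numeric(1), 1),
    mean_tp = vapply(split(tp, key), mean, numeric(1)))
  best <- mtab[which.max(mtab$mean_tp), ]
  worst <- mtab[which.min(mtab$mean_tp), ]
  best_tp <- tp[masked$ctoa_ms == best$ctoa_ms &
                  masked$soa_ms == best$soa_ms]
  worst_tp <- tp[masked$ctoa_ms == worst$ctoa_ms &
                   masked$soa_ms == worst$soa_ms]
  base <- tab[is.na(tab$soa_ms) & tab$ctoa_ms == best$ctoa_ms, ,
              drop = FALSE]
  c1 <- if (nrow(base) >= 2) {
    test <- welch_t(best_tp, transformed_performance(base$error_deg),
                    alternative = "less")
    list(evaluable = TRUE, ctoa_ms = best$ctoa_ms, soa_ms = best$soa_ms,
         test = test, pass = test$p < alpha)
  } else {
    list(evaluable = FALSE, reason = "no baseline trials at the best cell's CTOA",
         pass = NA)
  }
  t2 <- one_sample_t(worst_tp, mu0 = 0.5, alternative = "greater")
  c2 <- list(evaluable = TRUE, ctoa_ms = worst$ctoa_ms,
             soa_ms = worst$soa_ms, test = t2,
             pass = !t2$degenerate && t2$p < alpha)
  structure(list(c1 = c1, c2 = c2,
                 pass = isTRUE(c1$pass) && isTRUE(c2$pass),
                 alpha = alpha, observer = unique(tab$observer)),
            class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  fmt <- function(cr, label) {
    if (!isTRUE(cr$evaluable))
      return(sprintf("  %s: not evaluable (%s)\n", label, cr$reason))
    sprintf("  %s: cell (ctoa %g, soa %g), t(%.1f) = %.2f, p = %.4g -> %s\n",
            label, cr$ctoa_ms, cr$soa_ms, cr$test$df, cr$test$statistic,
            cr$test$p, if (isTRUE(cr$pass)) "PASS" else "FAIL")
  }
  cat(sprintf("<criteria_report: observer %s, alpha %.2g, %s>\n",
              x$observer, x$alpha, if (x$pass) "PASS" else "FAIL"))
  cat(fmt(x$c1, "C1 (ceiling)"))
  cat(fmt(x$c2, "C2 (floor)"))
  invisible(x)
}
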