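#' Masking function for one observer and CTOA
#'
#' Per-SOA mean and standard error of transformed performance, i.e.
#' target visibility as a function of target-mask SOA, with the no-mask
#' baseline attached when present. In exogenous designs only validly
#' cued trials should enter the analysis (`valid_only = TRUE`, the
#' default).
#'
#' @param table trial table (see [generate_dataset()], [read_trials()]).
#' @param observer observer id; may be omitted when the table holds a
#'   single observer.
#' @param ctoa CTOA in ms.
#' @param valid_only drop invalid-cue trials first.
#' @return object of class `masking_function`: list with `observer`,
#'   `ctoa_ms`, `points` (data frame `soa_ms`, `mean_tp`, `sem_tp`,
#'   `n_trials`, ascending SOA) and `baseline` (one-row data frame or
#'   `NULL`).
#' @export
masking_function <- function(table, observer = NULL, ctoa,
                             valid_only = TRUE) {
  tab <- .subset_observer(table, observer, valid_only)
  observer <- unique(tab$observer)
  tab <- tab[tab$ctoa_ms == ctoa, , drop = FALSE]
  if (!nrow(tab)) stop(sprintf("no trials at CTOA %g", ctoa))
  masked <- tab[!is.na(tab$soa_ms), , drop = FALSE]
  small <- table(masked$soa_ms) < 2
  if (any(small))
    stop(sprintf("cells with < 2 trials at (ctoa=%g, soa=%s)", ctoa,
                 paste(names(small)[small], collapse = ", ")))
  pts <- .tp_summary(masked, masked$soa_ms)
  base <- tab[is.na(tab$soa_ms), , drop = FALSE]
  baseline <- if (nrow(base) >= 2) {
    b <- .tp_summary(base, rep(NA_real_, nrow(base)))
    b
  } else NULL
  structure(list(observer = observer, ctoa_ms = ctoa, points = pts,
                 baseline = baseline), class = "masking_function")
}

.subset_observer <- function(table, observer, valid_only) {
  tab <- as.data.frame(table)
  if (!is.null(observer)) tab <- tab[tab$observer %in% observer, , drop = FALSE]
  if (length(unique(tab$observer)) > 1)
    stop("table holds several observers; pass `observer`")
  if (valid_only) tab <- tab[tab$valid_cue == 1, , drop = FALSE]
  if (!nrow(tab)) stop("no trials left after subsetting")
  tab
}

.tp_summary <- function(tab, soa_key) {
  tp <- transformed_performance(tab$error_deg)
  key <-if (all(is.na(soa_key))) factor(rep("baseline", nrow(tab)))
         else factor(soa_key, levels = sort(unique(soa_key)))
  sp <- split(tp, key)
  out <- data.frame(
    soa_ms = if (all(is.na(soa_key))) NA_real_ else as.numeric(names(sp)),
    mean_tp = vapply(sp, mean, numeric(1)),
    sem_tp = vapply(sp, function(z) stats::sd(z) / sqrt(length(z)), numeric(1)),
    n_trials = vapply(sp, length, numeric(1)))
  rownames(out) <- NULL
  out[order(out$soa_ms, na.last = TRUE), , drop = FALSE]
}

#' @export
print.masking_function <- function(x, ...) {
  cat(sprintf("<masking_function: observer %s, CTOA %g ms>\n",
              x$observer, x$ctoa_ms))
  print(x$points, row.names = FALSE)
  if (!is.null(x$baseline))
    cat(sprintf("  baseline: mean_tp %.3f (sem %.3f, n %d)\n",
                x$baseline$mean_tp, x$baseline$sem_tp,
                as.integer(x$baseline$n_trials)))
  invisible(x)
}

#' Tidy masking functions for a whole table
#'
#' One row per (observer, CTOA, SOA-or-baseline) cell; baseline rows
#' carry `NA` in `soa_ms`. This is the exportable tidy form of
#' [masking_function()].
#'
#' @inheritParams masking_function
#' @return data frame `observer`, `ctoa_ms`, `soa_ms`, `mean_tp`,
#'   `sem_tp`, `n_trials`.
#' @export
masking_functions <- function(table, valid_only = TRUE) {
  tab <- as.data.frame(table)
  if (valid_only) tab <- tab[tab$valid_cue == 1, , drop = FALSE]
  out <- do.call(rbind, lapply(split(tab, tab[c("observer", "ctoa_ms")],
                                     drop = TRUE), function(d) {
    s <- rbind(.tp_summary(d[!is.na(d$soa_ms), , drop = FALSE],
                           d$soa_ms[!is.na(d$soa_ms)]),
               if (any(is.na(d$soa_ms)))
                 .tp_summary(d[is.na(d$soa_ms), , drop = FALSE],
                             rep(NA_real_, sum(is.na(d$soa_ms)))))
    cbind(observer = d$observer[1], ctoa_ms = d$ctoa_ms[1], s)
  }))
  rownames(out) <- NULL
  out[order(out$observer, out$ctoa_ms, out$soa_ms, na.last = TRUE), ,
      drop = FALSE]
}
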