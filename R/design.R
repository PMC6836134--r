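#' Factorial design of a cued masking experiment
#'
#' Describes one attention condition of a cued metacontrast experiment:
#' the cue-target onset asynchronies (CTOAs), the target-mask stimulus
#' onset asynchronies (SOAs), whether a no-mask baseline condition is
#' included, the number of valid trials per cell, the display set size
#' and the cue validity.
#'
#' @param attention_type `"endogenous"` or `"exogenous"`.
#' @param ctoas numeric vector of CTOAs in ms.
#' @param soas numeric vector of SOAs in ms (may be empty only if
#'   `include_baseline` is `TRUE` and you only want baselines).
#' @param include_baseline include a no-mask baseline condition per CTOA.
#' @param reps_per_condition valid trials per (CTOA x SOA-or-baseline)
#'   cell.
#' @param n_items display set size (number of oriented bars).
#' @param cue_validity probability that the pre-cued location is the
#'   probed target (1 for the central endogenous cue, 1/n_items for an
#'   uninformative peripheral cue).
#' @return object of class `design_spec`.
#' @seealso [endogenous_design()], [exogenous_design()], [build_design()]
#' @export
design_spec <- function(attention_type = c("endogenous", "exogenous"),
                        ctoas, soas, include_baseline = TRUE,
                        reps_per_condition = 100, n_items,
                        cue_validity = 1) {
  attention_type <- match.arg(attention_type)
  if (length(soas) == 0 && !include_baseline)
    stop("empty SOA set with no baseline: nothing to measure")
  if (reps_per_condition <= 0) stop("reps_per_condition must be > 0")
  if (cue_validity <= 0 || cue_validity > 1)
    stop("cue_validity must be in (0, 1]")
  if (n_items < 2) stop("n_items must be >= 2")
  if (length(soas) && any(duplicated(soas))) stop("duplicated SOA values")
  if (any(duplicated(ctoas))) stop("duplicated CTOA values")
  structure(list(
    attention_type = attention_type,
    ctoas = as.numeric(sort(ctoas)),
    soas = as.numeric(sort(soas)),
    include_baseline = isTRUE(include_baseline),
    reps_per_condition = as.integer(reps_per_condition),
    n_items = as.integer(n_items),
    cue_validity = as.numeric(cue_validity)
  ), class = "design_spec")
}

#' Default SOA grid
#'
#' SOAs spanning a typical U-shaped (type-B) metacontrast function, with
#' strongest masking expected at intermediate asynchronies.
#' @return numeric vector of SOAs in ms.
#' @export
default_soas <- function() c(20, 40, 60, 80, 120)

#' Endogenous (central cue) design
#'
#' Six oriented bars, a 100%-valid central pre-cue, CTOAs of 0, 200 and
#' 500 ms, five SOAs plus a no-mask baseline, 100 trials per cell:
#' 18 conditions and 1800 trials per observer.
#' @param soas SOA grid in ms.
#' @param reps_per_condition trials per cell.
#' @return `design_spec`.
#' @export
endogenous_design <- function(soas = default_soas(), reps_per_condition = 100) {
  design_spec("endogenous", ctoas = c(0, 200, 500), soas = soas,
              include_baseline = TRUE,
              reps_per_condition = reps_per_condition,
              n_items = 6, cue_validity = 1)
}

#' Exogenous (peripheral cue) design
#'
#' Four oriented bars, an uninformative peripheral pre-cue (25% valid),
#' two CTOAs (0 ms and one near the exogenous-attention peak, 80-120 ms
#' depending on observer), five SOAs plus baseline, 100 valid trials
#' per cell: 1200 valid trials out of roughly 4800.
#' @param soas SOA grid in ms.
#' @param ctoa_peak the second CTOA in ms, in \[80, 120\].
#' @param reps_per_condition valid trials per cell.
#' @return `design_spec`.
#' @export
exogenous_design <- function(soas = default_soas(), ctoa_peak = 100,
                             reps_per_condition = 100) {
  if (ctoa_peak < 80 || ctoa_peak > 120)
    stop("ctoa_peak must lie in [80, 120] ms")
  design_spec("exogenous", ctoas = c(0, ctoa_peak), soas = soas,
              include_baseline = TRUE,
              reps_per_condition = reps_per_condition,
              n_items = 4, cue_validity = 0.25)
}

#' @export
print.design_spec <- function(x, ...) {
  n_cells <- length(x$ctoas) * (length(x$soas) + x$include_baseline)
  cat(sprintf("<design_spec: %s attention>\n", x$attention_type))
  cat(sprintf("  CTOAs (ms): %s\n", paste(x$ctoas, collapse = ", ")))
  cat(sprintf("  SOAs (ms): %s%s\n", paste(x$soas, collapse = ", "),
              if (x$include_baseline) " + baseline" else ""))
  cat(sprintf("  %d items, cue validity %.2f, %d valid trials/cell (%d cells)\n",
              x$n_items, x$cue_validity, x$reps_per_condition, n_cells))
  invisible(x)
}

#' Expand a design into trial skeletons
#'
#' Builds the trial table skeleton (design factors only, no stimuli or
#' responses): exactly `reps_per_condition` valid trials per
#' (CTOA x SOA-or-baseline) cell. When `cue_validity < 1`, additional
#' invalid-cue trials are appended per cell, drawn so that the expected
#' fraction of valid trials equals the cue validity (as in an
#' uninformative peripheral cue, where invalid trials accrue until the
#' required number of valid ones is collected). Baseline trials carry
#' `NA` in `soa_ms`.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed controlling the number of invalid trials
#'   (only used when `cue_validity < 1`).
#' @return data frame with columns `attention_type`, `ctoa_ms`,
#'   `soa_ms` (`NA` for baseline), `valid_cue` (0/1), `trial_index`.
#' @export
build_design <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  soa_levels <- c(spec$soas, if (spec$include_baseline) NA_real_)
  cells <- expand.grid(ctoa_ms = spec$ctoas, soa_ms = soa_levels,
                       KEEP.OUT.ATTRS = FALSE)
  reps <- spec$reps_per_condition
  valid <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE]
  valid$valid_cue <- 1L
  out <- valid
  if (spec$cue_validity < 1) {
    # invalid count per cell: trials-to-success excess of a negative
    # binomial with success probability = cue_validity
    n_inv <- withr::with_seed(seed,
      stats::rnbinom(nrow(cells), size = reps, prob = spec$cue_validity))
    inv <- cells[rep(seq_len(nrow(cells)), times = n_inv), , drop = FALSE]
    if (nrow(inv)) {
      inv$valid_cue <- 0L
      out <- rbind(valid, inv)
    }
  }
  out$attention_type <- spec$attention_type
  out <- out[order(out$ctoa_ms, out$soa_ms, -out$valid_cue, na.last = TRUE), ]
  out$trial_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("trial_index", "attention_type", "ctoa_ms", "soa_ms", "valid_cue")]
}
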