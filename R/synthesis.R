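#' Sample stimulus displays for trial skeletons
#'
#' Draws, for each skeleton row, `n_items` independent orientations
#' uniform on \[0, 180) and a uniformly random target position. The
#' non-target orientations are recorded in ascending display-position
#' order.
#'
#' @param skeletons data frame of trial skeletons (see [build_design()]).
#' @param n_items display set size (>= 2).
#' @param seed integer RNG seed.
#' @return `skeletons` with added columns `target_pos`, `target_deg`
#'   and `distractor_degs` (semicolon-joined, display-position order).
#' @export
sample_display <- function(skeletons, n_items, seed = 1L) {
  if (n_items < 2) stop("n_items must be >= 2")
  n <- nrow(skeletons)
  withr::with_seed(seed, {
    ori <- matrix(stats::runif(n * n_items, 0, 180), nrow = n)
    pos <- sample.int(n_items, n, replace = TRUE)
  })
  tgt <- ori[cbind(seq_len(n), pos)]
  dis <- vapply(seq_len(n), function(i) {
    paste(formatC(ori[i, -pos[i]], digits = 6, format = "f"),
          collapse = ";")
  }, character(1))
  skeletons$target_pos <- pos
  skeletons$target_deg <- tgt
  skeletons$distractor_degs <- dis
  skeletons
}

# parse the semicolon-joined distractor column -> matrix n x (n_items-1)
.distractor_matrix <- function(distractor_degs) {
  parts <- strsplit(distractor_degs, ";", fixed = TRUE)
  k <- lengths(parts)
  if (length(unique(k)) != 1)
    stop("trials differ in number of distractors")
  matrix(as.numeric(unlist(parts)), ncol = k[1], byrow = TRUE)
}

# full display orientations by position: n x n_items
.display_matrix <- function(target_deg, target_pos, distractor_degs) {
  D <- .distractor_matrix(distractor_degs)
  n_items <- ncol(D) + 1
  out <- matrix(NA_real_, nrow = length(target_deg), ncol = n_items)
  for (i in seq_along(target_deg)) {
    out[i, target_pos[i]] <- target_deg[i]
    out[i, -target_pos[i]] <- D[i, ]
  }
  out
}

# per-trial misbinding centres: closest-angle distractor and the two
# positional nearest neighbours (positions live on a circle)
.misbind_centers <- function(target_deg, target_pos, distractor_degs) {
  D <- .distractor_matrix(distractor_degs)
  n <- length(target_deg)
  n_items <- ncol(D) + 1
  delta <- wrap_half(D - target_deg)    # recycles target down columns? no:
  # D is n x k; target_deg length n recycles by column correctly
  ca <- delta[cbind(seq_len(n), max.col(-abs(delta), ties.method = "first"))]
  if (n_items >= 3) {
    full <- .display_matrix(target_deg, target_pos, distractor_degs)
    up <- (target_pos %% n_items) + 1
    down <- ((target_pos - 2) %% n_items) + 1
    nn1 <- wrap_half(full[cbind(seq_len(n), down)] - target_deg)
    nn2 <- wrap_half(full[cbind(seq_len(n), up)] - target_deg)
  } else {
    nn1 <- nn2 <- rep(NA_real_, n)
  }
  data.frame(c_ca = ca, c_nn1 = nn1, c_nn2 = nn2)
}

#' Sample continuous reports for displayed trials
#'
#' Generative mirror of the Gaussian + uniform (+ misbinding) mixture:
#' with probability `w(tau, ctoa)` the report is uniform on \[0, 180)
#' (a guess); with probability `misbind_rate` it is a Gaussian draw
#' centred on a non-target bar (the closest-angle distractor, or a fair
#' pick of the two positional nearest neighbours); otherwise it is
#' `Normal(target + mu_true, sigma_true)` wrapped into \[0, 180).
#' Baseline (no-mask) trials use `baseline_weight` in place of the
#' surface value.
#'
#' @param trials data frame with design factors and display columns
#'   (see [sample_display()]).
#' @param scenario a [scenario_config()].
#' @param seed integer RNG seed.
#' @return `trials` with added `reported_deg` and `error_deg`.
#' @export
sample_response <- function(trials, scenario, seed = 1L) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (is.null(trials$target_deg))
    stop("trials lack displays; run sample_display() first")
  n <- nrow(trials)
  baseline <- is.na(trials$soa_ms)
  w <- ifelse(baseline, scenario$baseline_weight,
              weight_surface(scenario$weight_coef,
                             ifelse(baseline, 0, trials$soa_ms),
                             trials$ctoa_ms))
  mr <- scenario$misbind_rate
  if (mr > 0 && scenario$misbind_mode == "none")
    stop("misbind_rate > 0 requires a misbind_mode")
  withr::with_seed(seed, {
    u <- stats::runif(n)
    guess <- stats::runif(n, 0, 180)
    noise <- stats::rnorm(n, 0, scenario$sigma_true)
    pick <- stats::runif(n) < 0.5
  })
  comp <- ifelse(u < w, "U", ifelse(u < w + mr, "M", "G"))
  reported <- (trials$target_deg + scenario$mu_true + noise) %% 180
  if (any(comp == "M")) {
    ctr <- .misbind_centers(trials$target_deg, trials$target_pos,
                            trials$distractor_degs)
    center <- if (scenario$misbind_mode == "closest_angle") {
      trials$target_deg + ctr$c_ca
    } else {
      if (anyNA(ctr$c_nn1[comp == "M"]))
        stop("nearest_neighbor misbinding needs two neighbours")
      trials$target_deg + ifelse(pick, ctr$c_nn1, ctr$c_nn2)
    }
    mis <- (center + noise) %% 180
    reported[comp == "M"] <- mis[comp == "M"]
  }
  reported[comp == "U"] <- guess[comp == "U"]
  trials$reported_deg <- reported
  trials$error_deg <- wrap_orientation_error(trials$target_deg, reported)
  trials
}

#' Generate a full synthetic trial table
#'
#' Expands the scenario's design, samples displays and responses, and
#' returns a complete trial table with signed wrapped errors. The
#' design, display and response stages use sub-seeds derived from the
#' scenario seed, so the table is reproducible from the scenario alone.
#'
#' @param scenario a [scenario_config()].
#' @return a `trial_table` (data frame) with the columns of the trial
#'   CSV schema, see [write_trials()].
#' @export
generate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  seeds <- withr::with_seed(scenario$seed,
                            sample.int(.Machine$integer.max - 1, 3))
  tab <- build_design(scenario$design, seed = seeds[1])
  tab <- sample_display(tab, scenario$design$n_items, seed = seeds[2])
  tab <- sample_response(tab, scenario, seed = seeds[3])
  tab$observer <- scenario$observer
  tab <- tab[, c("observer", "attention_type", "ctoa_ms", "soa_ms",
                 "valid_cue", "target_pos", "target_deg",
                 "distractor_degs", "reported_deg", "error_deg")]
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Write a trial table to CSV
#'
#' Comma-delimited UTF-8 with header; `soa_ms` empty for baseline
#' trials; `distractor_degs` semicolon-joined in display-position
#' order; angles in decimal degrees. An optional `#` comment line can
#' carry provenance (config hash and seed); [read_trials()] skips it.
#'
#' @param x trial table.
#' @param path output file.
#' @param comment optional single comment line (without the leading
#'   `"# "`).
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path, comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  out <- as.data.frame(x)
  for (col in c("target_deg", "reported_deg", "error_deg"))
    out[[col]] <- formatC(out[[col]], digits = 6, format = "f")
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' @param path CSV file written by [write_trials()] (or following the
#'   same schema).
#' @return a `trial_table` data frame.
#' @export
read_trials <- function(path) {
  tab <- tryCatch(
    suppressWarnings(  # colClasses naming complains on malformed files
      utils::read.csv(path, comment.char = "#", na.strings = "",
                      colClasses = c(observer = "character",
                                     attention_type = "character",
                                     distractor_degs = "character"))),
    error = function(e) stop(sprintf("failed to read '%s': %s", path,
                                     conditionMessage(e))))
  need <- c("observer", "attention_type", "ctoa_ms", "soa_ms", "valid_cue",
            "target_pos", "target_deg", "distractor_degs", "reported_deg",
            "error_deg")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("'%s': missing columns: %s", path,
                 paste(miss, collapse = ", ")))
  bad <- which(!is.na(tab$error_deg) &
                 (tab$error_deg < -90 | tab$error_deg >= 90))
  if (length(bad))
    stop(sprintf("'%s': error_deg out of [-90, 90) at data row(s) %s",
                 path, paste(utils::head(bad, 5), collapse = ", ")))
  class(tab) <- c("trial_table", "data.frame")
  tab
}
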