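# FNV-1a over the deparsed config; provenance stamp for output files
.fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- (bitwXor(h, b) * 16777619) %% 4294967296
  sprintf("%08x", h)
}

#' Pipeline run configuration
#'
#' Bundles the input (a [scenario_config()] to simulate, or a trial CSV
#' to read), the mixture prior box and grid resolutions, the bootstrap
#' size, the stage toggles and the master seed.
#'
#' @param scenario a [scenario_config()] (exclusive with `input_csv`).
#' @param input_csv path to a trial CSV ([read_trials()] schema).
#' @param box a [prior_box()].
#' @param bins grid bins per dimension for the 2-3 parameter models
#'   (study default 50).
#' @param bins_misbind bins per dimension for the 4-parameter
#'   GUCA/GUNN grids (coarser by default to keep the 50^4-point grids
#'   tractable).
#' @param models mixture models to score per cell.
#' @param B bootstrap resamples per cell.
#' @param seed mandatory master seed; stage sub-seeds are derived from
#'   it so that toggling one stage leaves the others' draws unchanged.
#' @param stages analysis toggles, any of `"criteria"`, `"masking"`,
#'   `"mixtures"`, `"bootstrap"` (all on by default).
#' @param ladder_level `"trial"` or `"cell"` responses for the masking
#'   ladder.
#' @param out_dir optional output directory for the report bundle.
#' @return object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, input_csv = NULL,
                       box = prior_box(), bins = 50, bins_misbind = 16,
                       models = c("G", "GU", "GUCA", "GUNN"), B = 500,
                       seed, stages = c("criteria", "masking", "mixtures",
                                        "bootstrap"),
                       ladder_level = "trial", out_dir = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (is.null(scenario) == is.null(input_csv))
    stop("provide exactly one of scenario or input_csv")
  if (!is.null(scenario)) stopifnot(inherits(scenario, "scenario_config"))
  bad <- setdiff(stages, c("criteria", "masking", "mixtures", "bootstrap"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  structure(list(scenario = scenario, input_csv = input_csv, box = box,
                 bins = bins, bins_misbind = bins_misbind,
                 models = match.arg(models, c("G", "GU", "GUCA", "GUNN"),
                                    several.ok = TRUE),
                 B = B, seed = as.integer(seed), stages = stages,
                 ladder_level = ladder_level, out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, per observer, the four analyses of a cued masking study:
#' (1) ceiling/floor criteria, (2) masking functions and the regression
#' ladder on transformed performance, (3) per-cell mixture fits and
#' pairwise BMC matrices with an observer-level winner, and
#' (4) bootstrap parameter summaries, parameter-surface ladder
#' regressions and parameter-masking correlations. Stage failures are
#' recorded and dependent stages skipped; if `out_dir` is set, CSV/JSON
#' artifacts stamped with the config hash and seed are written.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_bundle`: per-observer results,
#'   `config_hash`, `seed`, `timings` (seconds per stage), `errors`,
#'   `skipped`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- .fnv1a(config[setdiff(names(config), "out_dir")])
  seeds <- withr::with_seed(config$seed,
    stats::setNames(sample.int(.Machine$integer.max - 1, 2),
                    c("data", "bootstrap")))
  t0 <- proc.time()[["elapsed"]]
  timings <- c(); errors <- list(); skipped <- character()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[stage] <<- t1 - t0
    t0 <<- t1
  }
  run_stage <- function(stage, expr) {
    on <- stage %in% config$stages
    out <- if (!on) NULL else tryCatch(expr, error = function(e) {
      errors[[stage]] <<- conditionMessage(e)
      NULL
    })
    tick(stage)
    out
  }

  table <- if (!is.null(config$scenario)) {
    sc <- config$scenario
    sc$seed <- seeds[["data"]]
    generate_dataset(sc)
  } else read_trials(config$input_csv)
  tick("data")

  observers <- unique(table$observer)
  results <- stats::setNames(vector("list", length(observers)), observers)
  for (obs in observers) {
    otab <- table[table$observer == obs, , drop = FALSE]
    res <- list()
    res$criteria <- run_stage("criteria", check_ceiling_floor(otab, obs))
    res$masking <- run_stage("masking", {
      fns <- masking_functions(otab)
      lad <- masking_ladder(otab, obs, level = config$ladder_level)
      list(functions = fns, ladder = lad)
    })
    res$mixtures <- run_stage("mixtures", {
      .mixture_stage(otab, config)
    })
    if ("bootstrap" %in% config$stages && is.null(res$mixtures)) {
      skipped <- union(skipped, "bootstrap")
      res$bootstrap <- list(skipped = "mixtures stage unavailable")
      tick("bootstrap")
    } else {
      res$bootstrap <- run_stage("bootstrap", {
        winner <- res$mixtures$winner
        boot <- bootstrap_cells(otab, obs, model = winner, B = config$B,
                                seed = seeds[["bootstrap"]],
                                box = config$box)
        spec <- mixture_spec(winner)
        surfaces <- stats::setNames(lapply(spec$par_names, function(p)
          regress_parameter_surface(boot, p)$selection), spec$par_names)
        cors <- lapply(sort(unique(otab$ctoa_ms)), function(ct) {
          mf <- masking_function(otab, obs, ct)
          wu <- boot[boot$parameter == "w_u" & boot$ctoa_ms == ct, ,
                     drop = FALSE]
          sg <- boot[boot$parameter == "sigma" & boot$ctoa_ms == ct, ,
                     drop = FALSE]
          list(ctoa_ms = ct,
               r_w_u = if (nrow(wu) >= 3)
                 correlate_parameter_with_masking(mf, wu)$r else NA_real_,
               r_sigma = if (nrow(sg) >= 3)
                 correlate_parameter_with_masking(mf, sg)$r else NA_real_)
        })
        list(summaries = boot, surfaces = surfaces, correlations = cors)
      })
    }
    results[[obs]] <- res
  }
  bundle <- structure(list(results = results, table = table,
                           config_hash = hash, seed = config$seed,
                           timings = timings, errors = errors,
                           skipped = skipped),
                      class = "pipeline_bundle")
  if (!is.null(config$out_dir)) .write_bundle(bundle, config)
  if (length(errors))
    warning("pipeline stages failed: ", paste(names(errors), collapse = ", "))
  bundle
}

# per-cell mixture fits + BMC matrices; observer winner by summed BMC
.mixture_stage <- function(otab, config) {
  masked <- otab[otab$valid_cue == 1 & !is.na(otab$soa_ms), , drop = FALSE]
  cells <- unique(masked[, c("ctoa_ms", "soa_ms")])
  cells <- cells[order(cells$ctoa_ms, cells$soa_ms), , drop = FALSE]
  per_cell <- vector("list", nrow(cells))
  totals <- stats::setNames(numeric(length(config$models)), config$models)
  for (i in seq_len(nrow(cells))) {
    d <- masked[masked$ctoa_ms == cells$ctoa_ms[i] &
                  masked$soa_ms == cells$soa_ms[i], , drop = FALSE]
    ctx <- trial_contexts(d)
    scores <- lapply(config$models, function(m) {
      spec <- mixture_spec(m)
      b <- if (spec$k == 4) config$bins_misbind else config$bins
      suppressWarnings(bmc_score(spec, d$error_deg, ctx, config$box,
                                 bins = b))
    })
    cmp <- compare_models(scores)
    totals <- totals + cmp$bmc[config$models]
    per_cell[[i]] <- list(ctoa_ms = cells$ctoa_ms[i],
                          soa_ms = cells$soa_ms[i],
                          scores = scores, comparison = cmp)
  }
  list(cells = per_cell, bmc_totals = totals,
       winner = names(totals)[which.max(totals)])
}

.write_bundle <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("maskmix config=%s seed=%d", bundle$config_hash,
                   bundle$seed)
  wcsv <- function(df, file) {
    path <- file.path(config$out_dir, file)
    con <- file(path, "wt"); on.exit(close(con))
    writeLines(paste("#", stamp), con)
    utils::write.csv(df, con, row.names = FALSE)
    path
  }
  files <- character()
  files <- c(files, wcsv(as.data.frame(bundle$table), "trials.csv"))
  for (obs in names(bundle$results)) {
    res <- bundle$results[[obs]]
    pre <- paste0(obs, "_")
    if (!is.null(res$masking)) {
      files <- c(files, wcsv(res$masking$functions,
                             paste0(pre, "masking.csv")))
      files <- c(files, wcsv(res$masking$ladder$selection$table,
                             paste0(pre, "ladder.csv")))
    }
    if (!is.null(res$mixtures)) {
      rows <- do.call(rbind, lapply(res$mixtures$cells, function(cl)
        do.call(rbind, lapply(cl$scores, function(s)
          data.frame(ctoa_ms = cl$ctoa_ms, soa_ms = cl$soa_ms,
                     model = s$model_id, bmc = s$bmc,
                     ln_l_max = s$ln_l_max, mu = s$mle$mu,
                     sigma = s$mle$sigma, w_u = s$mle$w_u,
                     w_m = s$mle$w_m)))))
      files <- c(files, wcsv(rows, paste0(pre, "bmc.csv")))
    }
    if (!is.null(res$bootstrap) && is.null(res$bootstrap$skipped))
      files <- c(files, wcsv(res$bootstrap$summaries,
                             paste0(pre, "bootstrap.csv")))
    if (!is.null(res$criteria)) {
      path <- file.path(config$out_dir, paste0(pre, "criteria.json"))
      cr <- res$criteria
      jsonlite::write_json(list(
        config = stamp, observer = obs, pass = cr$pass, alpha = cr$alpha,
        c1 = cr$c1[setdiff(names(cr$c1), "test")],
        c1_p = if (isTRUE(cr$c1$evaluable)) cr$c1$test$p else NULL,
        c2 = cr$c2[setdiff(names(cr$c2), "test")],
        c2_p = cr$c2$test$p), path, auto_unbox = TRUE, digits = NA)
      files <- c(files, path)
    }
  }
  jsonlite::write_json(list(config_hash = bundle$config_hash,
                            seed = bundle$seed,
                            timings = as.list(bundle$timings),
                            errors = bundle$errors,
                            skipped = bundle$skipped,
                            files = basename(files)),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(files)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf("<pipeline_bundle: %d observer(s), config %s, seed %d>\n",
              length(x$results), x$config_hash, x$seed))
  for (obs in names(x$results)) {
    res <- x$results[[obs]]
    cat(sprintf("  %s:", obs))
    if (!is.null(res$criteria))
      cat(sprintf(" criteria %s;", if (res$criteria$pass) "PASS" else "FAIL"))
    if (!is.null(res$masking))
      cat(sprintf(" ladder winner %s;", res$masking$ladder$selection$winner))
    if (!is.null(res$mixtures))
      cat(sprintf(" mixture winner %s;", res$mixtures$winner))
    cat("\n")
  }
  if (length(x$errors))
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a scenario to a trial CSV
#'
#' Wraps [generate_dataset()] + [write_trials()] and prints the per-cell
#' valid-trial counts.
#'
#' @param scenario a [scenario_config()] or path to a scenario YAML.
#' @param path output CSV path.
#' @return the trial table, invisibly.
#' @export
simulate_to_csv <- function(scenario, path) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_config"))
  tab <- generate_dataset(scenario)
  write_trials(tab, path, comment = sprintf("maskmix seed=%d", scenario$seed))
  valid <- tab[tab$valid_cue == 1, ]
  n_cells <- nrow(unique(valid[, c("ctoa_ms", "soa_ms")]))
  message(sprintf("%d valid trials (%d total) in %d cells -> %s",
                  nrow(valid), nrow(tab), n_cells, path))
  invisible(tab)
}
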