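#' Run the full analysis pipeline
#'
#' Orchestrates generate -> score -> model -> compare -> correlate into one
#' reproducible run. In `simulate` mode a synthetic cohort is generated from
#' a [cohort_spec()]; in `analyze` mode the five input tables are read from
#' disk. Either way the pipeline scores every participant, fits the degree
#' 1--3 age-trajectory models with IQ and SES covariates (and refits without
#' covariates), applies the majority-vote model selection, tests trajectory
#' equality for every pair of measures sharing a selected degree, and
#' computes the raw and age-adjusted correlation matrix.
#'
#' Artifacts written to `out_dir`: `scores.csv`, `table3.csv` (five-band
#' descriptives), `table4.csv` (fit indices per measure and degree with a
#' best-model flag), `table5.csv` (correlation matrix),
#' `trajectory_comparisons.csv`, `fits.json` (betas, R-squared, overall F,
#' information criteria, with and without covariates) and `run.log`.
#'
#' @param config list with elements `mode` (`"simulate"` or `"analyze"`),
#'   `seed`, `out_dir`, `log_transform` (default `TRUE`), `covariates`
#'   (default `TRUE`); for simulate mode optionally `spec` (a
#'   [cohort_spec()]) and `fresh_design`; for analyze mode `input_dir`
#'   containing `participants.csv`, `trials_stroop.csv`,
#'   `trials_switching.csv`, `trials_ospan.csv`, `trials_toh.csv`.
#' @return (invisibly) a list with `scores`, `selections`, `fits_nocov`,
#'   `comparisons`, `correlations` and the artifact paths.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("lifespanEF run, mode=%s, seed=%d, log_transform=%s, covariates=%s",
                         config$mode, config$seed, config$log_transform,
                         config$covariates))

  if (config$mode == "simulate") {
    cohort <- simulate_cohort(config$spec, config$seed,
                              fresh_design = config$fresh_design)
    write_cohort_csv(cohort, out_dir)
    inputs <- cohort
  } else {
    inputs <- read_input_tables(config$input_dir)
  }

  scores <- score_cohort(inputs$participants, inputs$stroop, inputs$switching,
                         inputs$ospan, inputs$toh,
                         log_transform = config$log_transform)
  utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)

  tab3 <- band_descriptives(scores)
  utils::write.csv(tab3, file.path(out_dir, "table3.csv"), row.names = FALSE)

  measures <- c("stroop_effect", "ospan_partial", "switch_cost",
                "mixing_cost", "toh_score")
  cov_m <- if (config$covariates) {
    cbind(fsiq = scores$fsiq, ses = scores$ses_index)
  } else NULL
  selections <- lapply(measures, function(ms) {
    select_best_model(scores[[ms]], scores$age_years, cov_m)
  })
  names(selections) <- measures
  fits_nocov <- lapply(measures, function(ms) {
    select_best_model(scores[[ms]], scores$age_years, NULL)
  })
  names(fits_nocov) <- measures
  degrees <- vapply(selections, `[[`, 0L, "chosen_degree")
  log_lines <- c(log_lines, sprintf("selected degree %d for %s (n = %d)",
                                    degrees, measures,
                                    vapply(selections, `[[`, 0L, "n")))

  tab4 <- table4_frame(selections)
  utils::write.csv(tab4, file.path(out_dir, "table4.csv"), row.names = FALSE)
  jsonlite::write_json(fits_json(selections, fits_nocov),
                       file.path(out_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  comparisons <- pairwise_trajectory_comparisons(scores, measures, degrees)
  utils::write.csv(comparisons,
                   file.path(out_dir, "trajectory_comparisons.csv"),
                   row.names = FALSE)

  cors <- ef_correlations(scores, degrees, measures)
  tab5 <- data.frame(measure = rownames(format_cormat(cors)),
                     format_cormat(cors), check.names = FALSE)
  utils::write.csv(tab5, file.path(out_dir, "table5.csv"), row.names = FALSE)

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(scores = scores, selections = selections,
                 fits_nocov = fits_nocov, comparisons = comparisons,
                 correlations = cors, out_dir = out_dir))
}

validate_config <- function(config) {
  defaults <- list(mode = "simulate", seed = 1L, out_dir = "ef_run",
                   log_transform = TRUE, covariates = TRUE,
                   fresh_design = TRUE, spec = NULL, input_dir = NULL)
  defaults[names(config)] <- config
  config <- defaults
  if (!config$mode %in% c("simulate", "analyze")) {
    stop("mode must be 'simulate' or 'analyze'", call. = FALSE)
  }
  config$seed <- as.integer(config$seed)
  if (config$mode == "simulate" && is.null(config$spec)) {
    config$spec <- cohort_spec()
  }
  if (config$mode == "analyze") {
    if (is.null(config$input_dir)) {
      stop("analyze mode requires `input_dir`", call. = FALSE)
    }
    needed <- file.path(config$input_dir,
                        c("participants.csv", "trials_stroop.csv",
                          "trials_switching.csv", "trials_ospan.csv",
                          "trials_toh.csv"))
    missing <- needed[!file.exists(needed)]
    if (length(missing)) {
      stop("missing input table(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  config
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Logical values
#' `true`/`false`, numbers, and strings are coerced.
#'
#' @param path file path.
#' @return named list usable as [run_pipeline()] config.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    out[[key]] <- if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else if (grepl("^-?[0-9.]+$", val)) {
      as.numeric(val)
    } else val
  }
  out
}

read_input_tables <- function(input_dir) {
  rd <- function(f) utils::read.csv(file.path(input_dir, f),
                                    stringsAsFactors = FALSE)
  list(participants = rd("participants.csv"),
       stroop = rd("trials_stroop.csv"),
       switching = rd("trials_switching.csv"),
       ospan = rd("trials_ospan.csv"),
       toh = rd("trials_toh.csv"))
}

#' Write a simulated cohort as the five CSV input tables
#'
#' Emits `participants.csv`, `trials_stroop.csv`, `trials_switching.csv`,
#' `trials_ospan.csv`, `trials_toh.csv` plus `cohort_truth.json` (the latent
#' person-level parameters, for recovery studies) into `out_dir` -- exactly
#' the schemas [run_pipeline()]'s analyze mode consumes.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants,
                   file.path(out_dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(cohort$stroop, file.path(out_dir, "trials_stroop.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$switching,
                   file.path(out_dir, "trials_switching.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$ospan, file.path(out_dir, "trials_ospan.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$toh, file.path(out_dir, "trials_toh.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$truth$seed,
         latents = lapply(cohort$truth$latents, unname),
         u = cohort$truth$u),
    file.path(out_dir, "cohort_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

band_descriptives <- function(scores) {
  band <- age_band(scores$age_years)
  measures <- intersect(c("stroop_effect", "ospan_absolute", "ospan_partial",
                          "switch_cost", "mixing_cost", "toh_score"),
                        names(scores))
  rows <- lapply(measures, function(ms) {
    x <- scores[[ms]]
    cell <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return("-")
      sprintf("%.2f (%.2f)", mean(v), stats::sd(v))
    }
    vals <- c(cell(x), vapply(levels(band),
                              function(b) cell(x[band == b]), ""))
    data.frame(measure = ms, n = sum(!is.na(x)),
               t(vals), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("measure", "n", "all", levels(band))
  out
}

table4_frame <- function(selections) {
  rows <- list()
  for (ms in names(selections)) {
    sel <- selections[[ms]]
    for (d in 1:3) {
      fit <- sel$fits[[d]]
      cmp_key <- grep(sprintf("v%d$", d), names(sel$comparisons), value = TRUE)
      cmp <- if (length(cmp_key)) sel$comparisons[[cmp_key[1]]] else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms, degree = d, n = fit$n, rss = fit$rss,
        f_change = if (is.null(cmp)) NA else cmp$f_change$statistic,
        f_change_p = if (is.null(cmp)) NA else cmp$f_change$p,
        loglik = fit$loglik,
        lr_chisq = if (is.null(cmp)) NA else cmp$lr_chisq$statistic,
        lr_p = if (is.null(cmp)) NA else cmp$lr_chisq$p,
        aic = fit$aic, bic = fit$bic,
        best = d == sel$chosen_degree)
    }
  }
  do.call(rbind, rows)
}

fits_json <- function(selections, fits_nocov) {
  one <- function(sel) {
    lapply(sel$fits, function(fit) list(
      degree = fit$degree, n = fit$n,
      beta_std = as.list(fit$beta_std),
      r_squared = fit$r_squared,
      f_overall = fit$f_overall,
      rss = fit$rss, loglik = fit$loglik, aic = fit$aic, bic = fit$bic,
      k_params = fit$k_params))
  }
  list(with_covariates = lapply(selections, function(s) {
         c(one(s), list(chosen_degree = s$chosen_degree))
       }),
       without_covariates = lapply(fits_nocov, function(s) {
         c(one(s), list(chosen_degree = s$chosen_degree))
       }))
}

pairwise_trajectory_comparisons <- function(scores, measures, degrees) {
  rows <- list()
  for (i in seq_along(measures)[-length(measures)]) {
    for (j in (i + 1):length(measures)) {
      ma <- measures[i]; mb <- measures[j]
      if (degrees[[ma]] != degrees[[mb]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          measure_a = ma, measure_b = mb, degree = NA, n = NA,
          rss_delta = NA, f = NA, df1 = NA, df2 = NA, p = NA,
          verdict = "not_compared_degree_mismatch")
        next
      }
      res <- compare_trajectories(
        data.frame(age_years = scores$age_years, score = scores[[ma]]),
        data.frame(age_years = scores$age_years, score = scores[[mb]]),
        degree_a = degrees[[ma]], labels = c(ma, mb))
      rows[[length(rows) + 1L]] <- data.frame(
        measure_a = ma, measure_b = mb, degree = res$degree, n = res$n,
        rss_delta = res$rss_delta, f = res$f_change$statistic,
        df1 = res$f_change$df1, df2 = res$f_change$df2, p = res$p,
        verdict = res$verdict)
    }
  }
  do.call(rbind, rows)
}
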