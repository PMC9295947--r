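#' Configuration for an end-to-end pipeline run
#'
#' Bundles everything one full analysis needs: a cohort generator config,
#' an optional phantom config, the candidate model families, the
#' gestational windows, an output directory and a seed. The run seed
#' overrides the seeds inside the cohort and phantom configs so a single
#' integer reproduces the whole run.
#'
#' @param cohort A [cohort_config()].
#' @param phantom Optional [phantom_config()].
#' @param candidate_models Model form names for BIC selection.
#' @param windows Gestational window labels used for stratified ROC.
#' @param output_dir Directory for run artifacts.
#' @param seed Integer seed propagated to all stochastic stages.
#' @param log_level `"info"` or `"quiet"`.
#' @return Object of class `pn_run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       phantom = NULL,
                       candidate_models = c("constant", "linear",
                                            "quadratic", "cubic", "sigmoid"),
                       windows = c("10-20", "20-30", "30+"),
                       output_dir = tempfile("placenorm_run_"),
                       seed = 1L,
                       log_level = c("info", "quiet")) {
  stopifnot(inherits(cohort, "pn_cohort_config"))
  if (!is.null(phantom)) stopifnot(inherits(phantom, "pn_phantom_config"))
  structure(list(cohort = cohort, phantom = phantom,
                 candidate_models = candidate_models, windows = windows,
                 output_dir = output_dir, seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "pn_run_config")
}

.pn_log <- function(config, fmt, ...) {
  msg <- sprintf(fmt, ...)
  if (config$log_level != "quiet") message("[placenorm] ", msg)
  log_file <- file.path(config$output_dir, "run.log")
  if (dir.exists(config$output_dir)) {
    cat(msg, "\n", file = log_file, append = TRUE, sep = "")
  }
  invisible(NULL)
}

.pn_stage <- function(config, name, expr) {
  .pn_log(config, "stage %s: start", name)
  out <- tryCatch(expr, error = function(e) {
    .pn_log(config, "stage %s: FAILED (%s)", name, conditionMessage(e))
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  .pn_log(config, "stage %s: done", name)
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> (optional phantom mapping) -> per-group model
#' selection -> UN-reference scoring -> stratified ROC -> report. Writes
#' `cohort.csv`, `fits/<group>.json`, `scores.csv`, `roc.json` and
#' `report.json` under the config's output directory and returns the
#' report as a list. The run is deterministic given the config seed; the
#' report carries no timestamps so repeated runs are byte-identical.
#'
#' When the cohort contains no PA scans (e.g. a UN-only cohort) the ROC
#' stage is skipped with a warning and the report is still written.
#'
#' @param config A [run_config()].
#' @return The report list, invisibly; side effect is the artifact files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pn_run_config"))
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  cat("", file = file.path(config$output_dir, "run.log"))  # truncate log

  cohort_cfg <- config$cohort
  cohort_cfg$seed <- config$seed
  cohort <- .pn_stage(config, "simulate", {
    coh <- simulate_cohort(cohort_cfg)
    write_cohort(coh, file.path(config$output_dir, "cohort.csv"))
    coh
  })

  phantom_summary <- NULL
  if (!is.null(config$phantom)) {
    phantom_summary <- .pn_stage(config, "map-t2star", {
      ph_cfg <- config$phantom
      ph_cfg$seed <- config$seed
      ph <- simulate_multiecho_phantom(ph_cfg)
      m <- map_t2star(ph, ph)
      m$summary$volume_cm3 <- placental_volume(ph, ph$voxel_dims_mm)
      m$summary$truth_median_ms <- stats::median(ph$truth[ph$mask])
      m$summary
    })
  }

  fits <- .pn_stage(config, "fit", {
    fit_dir <- file.path(config$output_dir, "fits")
    if (!dir.exists(fit_dir)) dir.create(fit_dir)
    out <- list()
    for (g in unique(cohort$group)) {
      d <- cohort[cohort$group == g, ]
      if (nrow(d) < 10L) next
      sel <- suppressWarnings(
        select_model_bic(d$ga_weeks, d$t2star_ms, config$candidate_models))
      write_fit(sel$best, file.path(fit_dir, paste0(g, ".json")))
      out[[g]] <- sel$best
    }
    if (is.null(out$UN)) stop("no usable UN scans to fit the reference")
    out
  })

  scores <- .pn_stage(config, "score", {
    sc <- score_cohort(cohort, fits$UN)
    utils::write.csv(sc, file.path(config$output_dir, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
    sc
  })

  separation <- NULL
  if (!is.null(fits$PA) && fits$PA$converged) {
    separation <- .pn_stage(config, "band-separation", {
      band_separation(fits$UN, fits$PA)
    })
  }

  roc <- NULL
  if (any(scores$group == "PA")) {
    roc <- .pn_stage(config, "roc", {
      keep <- scores$group %in% c("UN", "PA")  # primary contrast excludes SA
      r <- suppressWarnings(
        windowed_roc(scores[keep, ], scores$group[keep] == "PA",
                     windows = config$windows))
      obj <- lapply(r, function(x) {
        list(auc = x$auc, j_max = x$j_max, c_opt = x$c_opt,
             n_pos = x$n_pos, n_neg = x$n_neg,
             thresholds = x$thresholds, sens = x$sens, spec = x$spec)
      })
      jsonlite::write_json(obj, file.path(config$output_dir, "roc.json"),
                           auto_unbox = TRUE, digits = NA)
      r
    })
  } else {
    warning("cohort has no PA scans; ROC stage skipped")
    .pn_log(config, "stage roc: skipped (no PA scans)")
  }

  report <- list(
    software = list(package = "placenorm",
                    version = as.character(utils::packageVersion("placenorm"))),
    config = list(seed = config$seed,
                  n_subjects = cohort_cfg$n_subjects,
                  group_probs = as.list(cohort_cfg$group_probs),
                  candidate_models = config$candidate_models,
                  windows = config$windows),
    n_scans = nrow(cohort),
    group_fits = lapply(fits, function(f) {
      list(form = f$spec$form, params = f$params, rms = f$rms_residual,
           n = f$n_obs, bic = f$bic, converged = f$converged)
    }),
    band_separation = if (!is.null(separation)) {
      lapply(seq_len(nrow(separation)),
             function(i) list(start = separation$start[i],
                              end = separation$end[i]))
    } else list(),
    group_stats = lapply(split(scores, scores$group), function(d) {
      list(n = nrow(d), mean_z = mean(d$z), sd_z = stats::sd(d$z),
           median_z = stats::median(d$z))
    }),
    roc = if (!is.null(roc)) {
      lapply(roc, function(x) list(auc = x$auc, j_max = x$j_max,
                                   c_opt = x$c_opt, n_pos = x$n_pos,
                                   n_neg = x$n_neg))
    } else list(),
    phantom = if (!is.null(phantom_summary)) phantom_summary else list()
  )
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Render diagnostic plots for a completed run
#'
#' Reads the artifacts of a [run_pipeline()] output directory and writes
#' PNG diagnostics: a scatter-plus-band plot per fitted group, the
#' percentile histogram bar chart, and the overall ROC polyline (skipped
#' when the run had no ROC stage). Plot failures are logged, never fatal.
#'
#' @param run_dir Output directory of a completed run.
#' @param out_dir Directory for the plot files (default `run_dir`).
#' @return Character vector of written file paths, invisibly.
#' @export
render_diagnostics <- function(run_dir, out_dir = run_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cohort <- read_cohort(file.path(run_dir, "cohort.csv"))
  written <- character(0)
  safe_png <- function(path, expr) {
    ok <- tryCatch({
      grDevices::png(path, width = 900, height = 700, res = 120)
      on.exit(grDevices::dev.off(), add = TRUE)
      expr
      TRUE
    }, error = function(e) {
      message("plot failed (", path, "): ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }
  fit_files <- list.files(file.path(run_dir, "fits"), pattern = "\\.json$",
                          full.names = TRUE)
  for (ff in fit_files) {
    g <- sub("\\.json$", "", basename(ff))
    fit <- read_fit(ff)
    d <- cohort[cohort$group == g, ]
    safe_png(file.path(out_dir, paste0("fit_", g, ".png")), {
      grid <- seq(10, 40, by = 0.1)
      band <- confidence_band(fit, grid)
      plot(d$ga_weeks, d$t2star_ms, pch = 16, cex = 0.5,
           col = "grey40", xlab = "Gestational age (weeks)",
           ylab = "Median placental T2* (ms)",
           main = sprintf("%s: %s fit", g, fit$spec$form))
      graphics::lines(grid, band$mean, lwd = 2)
      graphics::lines(grid, band$ci_lo, lty = 2)
      graphics::lines(grid, band$ci_hi, lty = 2)
      graphics::lines(grid, band$pi_lo, lty = 4)
      graphics::lines(grid, band$pi_hi, lty = 4)
    })
  }
  scores_path <- file.path(run_dir, "scores.csv")
  if (file.exists(scores_path)) {
    scores <- utils::read.csv(scores_path, stringsAsFactors = FALSE)
    safe_png(file.path(out_dir, "percentile_histogram.png"), {
      h <- percentile_histogram(scores$percentile, scores$group)
      graphics::barplot(t(h$fractions), beside = TRUE,
                        names.arg = sprintf("%d", h$breaks[-21]),
                        legend.text = colnames(h$fractions),
                        xlab = "T2* percentile bin (lower edge)",
                        ylab = "Fraction of scans",
                        main = "T2* percentile distribution by group")
    })
  }
  roc_path <- file.path(run_dir, "roc.json")
  if (file.exists(roc_path)) {
    roc <- jsonlite::read_json(roc_path, simplifyVector = TRUE)
    safe_png(file.path(out_dir, "roc_overall.png"), {
      ov <- roc$overall
      plot(1 - ov$spec, ov$sens, type = "l", lwd = 2,
           xlab = "1 - specificity", ylab = "Sensitivity",
           main = sprintf("ROC, PA vs UN (AUC = %.2f)", ov$auc))
      graphics::abline(0, 1, lty = 3)
    })
  }
  invisible(written)
}
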