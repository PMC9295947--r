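#' Default group-specific generative models
#'
#' Returns the generative parameter sets used by [cohort_config()]: for
#' each outcome group (UN uncomplicated/normal, PA primary adverse, SA
#' secondary abnormal) a logistic-sigmoid trajectory for median placental
#' T2* with a Gaussian residual SD (ms), and linear gestational trends with
#' Gaussian residuals for maternal hemoglobin, maternal SpO2 (%), placental
#' volume (cm^3) and median placental T1 (ms). Values are the published
#' best-fit regression parameters for each group; the UN T1 row uses the
#' single-site fit, the only one available for uncomplicated pregnancies.
#' Hemoglobin units are carried opaquely (the source tables mix mg/dl and
#' mmol labels for identical numbers).
#'
#' @return Nested list: `$t2star[[group]] = list(params, sd)` (sigmoid) and
#'   `$hb`, `$spo2`, `$volume`, `$t1` analogous with linear `params =
#'   c(intercept, slope)`.
#' @export
default_group_models <- function() {
  list(
    t2star = list(
      UN = list(params = c(-59.2, -0.24, 29.3, 84.6), sd = 9.6),
      PA = list(params = c(-57.6, -0.19, 25.2, 82.9), sd = 13.8),
      SA = list(params = c(-53.7, -0.28, 26.8, 85.4), sd = 12.5)),
    hb = list(
      UN = list(params = c(13.27, -0.046), sd = 1.02),
      PA = list(params = c(13.46, -0.039), sd = 1.04),
      SA = list(params = c(12.65, -0.018), sd = 0.92)),
    spo2 = list(
      UN = list(params = c(97.05, 0.003), sd = 2.4),
      PA = list(params = c(95.99, 0.052), sd = 3.1),
      SA = list(params = c(98.54, -0.043), sd = 1.4)),
    volume = list(
      UN = list(params = c(-372.4, 32.2), sd = 122),
      PA = list(params = c(-360.5, 30.0), sd = 132),
      SA = list(params = c(-383.0, 33.1), sd = 158)),
    t1 = list(
      UN = list(params = c(2513, -26.9), sd = 208),
      PA = list(params = c(2591, -31.2), sd = 246),
      SA = list(params = c(2556, -26.5), sd = 158))
  )
}

#' Configuration for a synthetic longitudinal cohort
#'
#' Defines the generative model for a seeded synthetic pregnancy cohort
#' with the statistical structure the analysis pipeline assumes: each
#' subject is assigned an outcome group and site, completes 1-3 scans in
#' distinct gestational windows, and contributes per-scan median placental
#' T2* (group-specific sigmoid trajectory plus Gaussian residual) and
#' ancillary scalars (linear trends plus Gaussian residuals).
#'
#' Defaults mirror the study population the package emulates: 316
#' subjects; outcome proportions 62.6 / 22.2 / 15.2% (UN / PA / SA); scan
#' completion 14 / 20 / 66% for one / two / three scans; two sites at
#' 56.6 / 43.4%; gestational windows 10-20, 20-30 and 30-40 weeks with
#' equal weights; generative parameters from [default_group_models()].
#'
#' @param n_subjects Number of subjects.
#' @param group_probs Named probabilities for groups UN, PA, SA (sum 1).
#' @param scans_per_subject_probs Probabilities for completing 1, 2 or 3
#'   scans (sum 1).
#' @param ga_windows List of three `c(lo, hi)` gestational intervals in
#'   weeks, ordered and non-overlapping.
#' @param window_probs Weights for assigning scans to windows.
#' @param site_probs Named probabilities for sites A and B (sum 1).
#' @param seed Integer seed; expands to per-subject substreams so changing
#'   `n_subjects` does not reshuffle earlier subjects.
#' @param group_t2star_models,ancillary_models Generative parameter sets in
#'   the shape produced by [default_group_models()].
#' @return An object of class `pn_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 316L,
                          group_probs = c(UN = 0.626, PA = 0.222, SA = 0.152),
                          scans_per_subject_probs = c(0.14, 0.20, 0.66),
                          ga_windows = list(c(10, 20), c(20, 30), c(30, 40)),
                          window_probs = c(1, 1, 1) / 3,
                          site_probs = c(A = 0.566, B = 0.434),
                          seed = 1L,
                          group_t2star_models = default_group_models()$t2star,
                          ancillary_models = default_group_models()[
                            c("hb", "spo2", "volume", "t1")]) {
  chk_probs <- function(p, what, len) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("invalid %s: must be %d nonnegative values summing to 1",
                   what, len))
    }
  }
  chk_probs(group_probs, "group_probs", 3L)
  chk_probs(scans_per_subject_probs, "scans_per_subject_probs", 3L)
  chk_probs(site_probs, "site_probs", 2L)
  if (length(window_probs) != 3L || any(window_probs < 0)) {
    stop("window_probs must be 3 nonnegative weights")
  }
  if (length(ga_windows) != 3L) stop("ga_windows must list 3 intervals")
  lo <- vapply(ga_windows, `[`, 0, 1L)
  hi <- vapply(ga_windows, `[`, 0, 2L)
  if (any(hi <= lo) || any(lo[-1L] < hi[-3L])) {
    stop("ga_windows must be ordered, non-overlapping intervals")
  }
  all_sds <- c(vapply(group_t2star_models, `[[`, 0, "sd"),
               unlist(lapply(ancillary_models,
                             function(m) vapply(m, `[[`, 0, "sd"))))
  if (any(all_sds < 0)) stop("residual SDs must be nonnegative")
  structure(list(
    n_subjects = as.integer(n_subjects),
    group_probs = group_probs,
    scans_per_subject_probs = scans_per_subject_probs,
    ga_windows = ga_windows,
    window_probs = window_probs / sum(window_probs),
    site_probs = site_probs,
    seed = as.integer(seed),
    group_t2star_models = group_t2star_models,
    ancillary_models = ancillary_models
  ), class = "pn_cohort_config")
}

#' Simulate a longitudinal cohort of placental scans
#'
#' Draws, per subject: outcome group and site (categorical), number of
#' completed scans (1-3), distinct gestational windows for those scans, a
#' uniform gestational age inside each window, and the per-scan
#' measurements from the group-specific generative models of the config.
#' Scan gestational ages within a subject are strictly increasing. Each
#' subject uses its own RNG substream derived from the config seed, so two
#' calls with the same config are identical and extending the cohort does
#' not reshuffle existing subjects.
#'
#' @param config A [cohort_config()].
#' @return data.frame with one row per scan: `subject_id`, `group`,
#'   `site`, `ga_weeks`, `t2star_ms`, `hb`, `spo2_pct`, `volume_cm3`,
#'   `t1_ms`.
#' @examples
#' coh <- simulate_cohort(cohort_config(n_subjects = 20, seed = 7))
#' head(coh)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "pn_cohort_config"))
  groups <- c("UN", "PA", "SA")
  sites <- c("A", "B")
  n <- config$n_subjects
  col <- list(subject_id = vector("list", n), group = vector("list", n),
              site = vector("list", n), ga_weeks = vector("list", n),
              t2star_ms = vector("list", n), hb = vector("list", n),
              spo2_pct = vector("list", n), volume_cm3 = vector("list", n),
              t1_ms = vector("list", n))
  wlo <- vapply(config$ga_windows, `[`, 0, 1L)
  whi <- vapply(config$ga_windows, `[`, 0, 2L)
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  # one independent L'Ecuyer-CMRG substream per subject: growing the cohort
  # appends streams without reshuffling earlier subjects
  set.seed(config$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", globalenv())
  for (i in seq_len(n)) {
    assign(".Random.seed", stream, envir = globalenv())
    stream <- parallel::nextRNGStream(stream)
    grp <- sample(groups, 1L, prob = config$group_probs)
    site <- sample(sites, 1L, prob = config$site_probs)
    n_scans <- sample(1:3, 1L, prob = config$scans_per_subject_probs)
    win_idx <- sort(sample.int(3L, n_scans, prob = config$window_probs))
    ga <- stats::runif(n_scans, wlo[win_idx], whi[win_idx])
    tm <- config$group_t2star_models[[grp]]
    curve <- evaluate_model("sigmoid", tm$params, ga)
    t2 <- curve + stats::rnorm(n_scans, 0, tm$sd)
    # residuals are Gaussian truncated to positive T2*: redraw the rare
    # (~0.1%) late-gestation draws that would cross zero
    while (any(bad <- t2 <= 0)) {
      t2[bad] <- curve[bad] + stats::rnorm(sum(bad), 0, tm$sd)
    }
    anc <- lapply(config$ancillary_models, function(m) {
      mm <- m[[grp]]
      mm$params[1L] + mm$params[2L] * ga + stats::rnorm(n_scans, 0, mm$sd)
    })
    col$subject_id[[i]] <- rep.int(sprintf("S%05d", i), n_scans)
    col$group[[i]] <- rep.int(grp, n_scans)
    col$site[[i]] <- rep.int(site, n_scans)
    col$ga_weeks[[i]] <- ga
    col$t2star_ms[[i]] <- t2
    col$hb[[i]] <- anc$hb
    col$spo2_pct[[i]] <- anc$spo2
    col$volume_cm3[[i]] <- anc$volume
    col$t1_ms[[i]] <- anc$t1
  }
  out <- data.frame(lapply(col, function(x) unlist(x, use.names = FALSE)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.cohort_columns <- c("subject_id", "group", "site", "ga_weeks", "t2star_ms",
                     "hb", "spo2_pct", "volume_cm3", "t1_ms")
.cohort_numeric <- c("ga_weeks", "t2star_ms", "hb", "spo2_pct",
                     "volume_cm3", "t1_ms")

# Save/restore the caller's RNG state (including generator kind) so the
# seeded generators never perturb the surrounding session.
.save_rng <- function() {
  list(kind = RNGkind(),
       seed = if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
         get(".Random.seed", globalenv())
       } else NULL)
}

.restore_rng <- function(old) {
  do.call(RNGkind, as.list(old$kind))
  if (is.null(old$seed)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old$seed, envir = globalenv())
  }
  invisible(NULL)
}

#' Write / read a cohort table as CSV
#'
#' The CSV carries exactly the documented columns (`subject_id`, `group`,
#' `site`, `ga_weeks`, `t2star_ms`, `hb`, `spo2_pct`, `volume_cm3`,
#' `t1_ms`). `read_cohort()` validates the header and numeric fields and
#' names the offending column or line on failure; `read_cohort(write_cohort(x))`
#' reproduces `x` up to float formatting (differences below 1e-9).
#'
#' @param records Cohort data.frame.
#' @param path CSV file path.
#' @return `read_cohort` returns the cohort data.frame; `write_cohort` the
#'   path, invisibly.
#' @export
write_cohort <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.cohort_columns, names(records))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(records[, .cohort_columns, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("parse error in %s: missing required column(s) %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  for (col in .cohort_numeric) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & nzchar(v))
      if (length(bad)) {
        stop(sprintf("parse error in %s: non-numeric '%s' at line %d (column %s)",
                     path, v[bad[1L]], bad[1L] + 1L, col))
      }
      df[[col]] <- vn
    }
    if (anyNA(df[[col]])) {
      stop(sprintf("parse error in %s: missing value at line %d (column %s)",
                   path, which(is.na(df[[col]]))[1L] + 1L, col))
    }
  }
  df[, .cohort_columns, drop = FALSE]
}
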