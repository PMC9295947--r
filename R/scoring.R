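#' Z-score of a scan against the uncomplicated-pregnancy reference
#'
#' Standardizes an observed median placental T2* against the reference
#' regression fitted to uncomplicated (UN) pregnancies:
#' `z = (t2star - mu(ga)) / sigma_pred(ga)`, where `mu` is the fitted
#' reference curve and `sigma_pred` the prediction-interval SD — the
#' square root of the residual variance plus the delta-method curve
#' variance. The prediction SD (not the narrower curve-CI SD) is the
#' standardizer because only it makes reference-population z-scores unit
#' variance. Percentile is `100 * pnorm(z)`.
#'
#' Gestational ages outside the 10-40 week modeling range are refused
#' rather than extrapolated.
#'
#' @param t2star_ms Observed median placental T2* values, ms.
#' @param ga_weeks Gestational ages at scan, weeks, in `[10, 40]`.
#' @param reference A converged `pn_fit` for the UN reference.
#' @return data.frame with columns `z` and `percentile`.
#' @export
zscore <- function(t2star_ms, ga_weeks, reference) {
  stopifnot(inherits(reference, "pn_fit"))
  if (!reference$converged) stop("reference fit did not converge")
  if (length(t2star_ms) != length(ga_weeks)) stop("length mismatch")
  if (any(ga_weeks < 10 | ga_weeks > 40)) {
    stop("gestational age outside [10, 40] weeks: extrapolation refused")
  }
  mu <- evaluate_model(reference$spec, reference$params, ga_weeks)
  G <- model_gradient(reference$spec, reference$params, ga_weeks)
  var_curve <- pmax(rowSums((G %*% reference$param_cov) * G), 0)
  sigma_pred <- sqrt(reference$sigma2 + var_curve)
  z <- (t2star_ms - mu) / sigma_pred
  data.frame(z = z, percentile = 100 * stats::pnorm(z))
}

#' Score every scan of a cohort
#'
#' Applies [zscore()] to each scan and attaches the gestational window
#' label.
#'
#' @param cohort Cohort data.frame (see [simulate_cohort()]).
#' @param reference UN reference `pn_fit`.
#' @return data.frame with `scan_id`, `subject_id`, `group`, `site`,
#'   `ga_weeks`, `t2star_ms`, `z`, `percentile`, `window`.
#' @export
score_cohort <- function(cohort, reference) {
  zs <- zscore(cohort$t2star_ms, cohort$ga_weeks, reference)
  data.frame(scan_id = sprintf("%s_%02d", cohort$subject_id,
                               stats::ave(seq_len(nrow(cohort)),
                                          cohort$subject_id,
                                          FUN = seq_along)),
             subject_id = cohort$subject_id,
             group = cohort$group,
             site = cohort$site,
             ga_weeks = cohort$ga_weeks,
             t2star_ms = cohort$t2star_ms,
             z = zs$z,
             percentile = zs$percentile,
             window = ga_window(cohort$ga_weeks),
             stringsAsFactors = FALSE)
}

#' Gestational-age window labels
#'
#' Assigns each scan to one of the three analysis windows: 10-20 weeks
#' (`[10, 20)`), 20-30 weeks (`[20, 30)`), and 30+ weeks (`[30, 40]`).
#' Every gestational age in `[10, 40]` falls in exactly one window.
#'
#' @param ga_weeks Gestational ages, weeks.
#' @return Character vector with values `"10-20"`, `"20-30"`, `"30+"`.
#' @export
ga_window <- function(ga_weeks) {
  if (any(ga_weeks < 10 | ga_weeks > 40)) {
    stop("gestational age outside [10, 40] weeks")
  }
  ifelse(ga_weeks < 20, "10-20", ifelse(ga_weeks < 30, "20-30", "30+"))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Thin wrapper around [stats::ks.test()] (two-sided, asymptotic p-value),
#' the test used throughout the analysis for continuous variables.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @return List with `D` (max ECDF gap) and `p` (two-tailed asymptotic
#'   p-value).
#' @export
ks_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 in both samples")
  ht <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                        exact = FALSE))
  list(D = unname(ht$statistic), p = unname(ht$p.value))
}

#' Cohen's d effect size
#'
#' `|mean(a) - mean(b)|` divided by the pooled standard deviation
#' `sqrt(((nA-1) sA^2 + (nB-1) sB^2) / (nA + nB - 2))`.
#'
#' @param a,b Numeric samples, each with at least 2 values.
#' @return Nonnegative effect size.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("need n >= 2 in both samples")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("pooled SD is zero")
  abs(mean(a) - mean(b)) / sqrt(sp2)
}

#' Chi-square proportion test with relative risk
#'
#' Compares the frequency of a binary outcome between two groups with the
#' 2x2 chi-square test without continuity correction (via
#' [stats::prop.test()]), and reports the relative risk
#' `(countA/nA) / (countB/nB)` with its Wald 95% CI on the log scale.
#'
#' @param count_a,n_a Events and total in group A.
#' @param count_b,n_b Events and total in group B.
#' @return List with `statistic`, `p`, `rr`, `rr_ci` (length-2 vector).
#' @examples
#' chi2_proportion(25, 179, 9, 137)
#' @export
chi2_proportion <- function(count_a, n_a, count_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("group sizes must be positive")
  if (count_a > n_a || count_b > n_b || count_a < 0 || count_b < 0) {
    stop("counts must lie in [0, n]")
  }
  ht <- suppressWarnings(stats::prop.test(c(count_a, count_b), c(n_a, n_b),
                                          correct = FALSE))
  pa <- count_a / n_a; pb <- count_b / n_b
  rr <- pa / pb
  ci <- if (count_a > 0 && count_b > 0) {
    se <- sqrt(1 / count_a - 1 / n_a + 1 / count_b - 1 / n_b)
    exp(log(rr) + c(-1, 1) * stats::qnorm(0.975) * se)
  } else c(NA_real_, NA_real_)
  list(statistic = unname(ht$statistic), p = unname(ht$p.value),
       rr = rr, rr_ci = ci)
}

#' Per-group z-score summaries
#'
#' @param scores Scored cohort (see [score_cohort()]) or any data.frame
#'   with `group` and `z`.
#' @return data.frame with one row per group: `group`, `n`, `mean_z`,
#'   `sd_z`, `median_z`.
#' @export
group_zstats <- function(scores) {
  parts <- split(scores$z, scores$group)
  out <- data.frame(
    group = names(parts),
    n = vapply(parts, length, 0L),
    mean_z = vapply(parts, mean, 0),
    sd_z = vapply(parts, stats::sd, 0),
    median_z = vapply(parts, stats::median, 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percentile histogram in twenty 5%-wide bins
#'
#' Bins T2* percentiles into twenty equally spaced bins spanning 0 to 100.
#' Bins are left-closed, right-open (`[0,5), [5,10), ...`) except the last,
#' `[95, 100]`, which is closed. In a reference population the counts are
#' expected to be uniform, with roughly 5% of observations in each bin.
#'
#' @param percentiles Numeric vector in `[0, 100]`.
#' @param groups Optional grouping vector (same length); when given, one
#'   column of counts per group.
#' @return List with `breaks` (length 21), `counts` (20 x n_groups
#'   matrix) and `fractions` (columns sum to 1; `NaN` for empty groups).
#' @export
percentile_histogram <- function(percentiles, groups = NULL) {
  if (length(percentiles) &&
      (any(percentiles < 0) || any(percentiles > 100))) {
    stop("percentiles must lie in [0, 100]")
  }
  if (is.null(groups)) groups <- rep("all", length(percentiles))
  if (length(groups) != length(percentiles)) stop("groups length mismatch")
  glev <- unique(as.character(groups))
  if (!length(glev)) glev <- "all"
  bin <- pmin(floor(percentiles / 5) + 1L, 20L)
  counts <- vapply(glev, function(g) {
    tabulate(bin[groups == g], nbins = 20L)
  }, integer(20L))
  counts <- matrix(counts, nrow = 20L, dimnames = list(NULL, glev))
  fractions <- sweep(counts, 2L, colSums(counts), `/`)
  list(breaks = seq(0, 100, by = 5), counts = counts, fractions = fractions)
}
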