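#' ROC curve for low-percentile prediction of adverse outcome
#'
#' Builds the ROC curve of a score (T2* percentile relative to the UN
#' reference, or the z-score itself) for a binary adverse-outcome label,
#' with the orientation that a *low* score flags adversity: a scan is
#' called positive when its score is at or below the cutoff. Candidate
#' cutoffs are the midpoints between consecutive distinct scores plus
#' `-Inf`/`+Inf` sentinels. The AUC (C-statistic) is the trapezoidal
#' integral of the ROC polyline, which equals the normalized Mann-Whitney
#' U statistic with ties counted half. Youden's J is
#' `sensitivity + specificity - 1`; `c_opt` is the cutoff maximizing it.
#'
#' @param score Numeric scores, one per scan.
#' @param is_adverse Logical (or 0/1) labels; both classes must occur.
#' @return Object of class `pn_roc`: list with `thresholds`, `sens`,
#'   `spec`, `auc`, `j_max`, `c_opt`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(1, 2, 3, 10, 11, 12), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
roc_curve <- function(score, is_adverse) {
  is_adverse <- as.logical(is_adverse)
  if (length(score) != length(is_adverse)) stop("length mismatch")
  if (anyNA(score) || anyNA(is_adverse)) stop("missing values in input")
  n_pos <- sum(is_adverse); n_neg <- sum(!is_adverse)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to build a ROC curve")
  }
  u <- sort(unique(score))
  thr <- c(-Inf, if (length(u) > 1L) (u[-length(u)] + u[-1L]) / 2, Inf)
  pos <- score[is_adverse]; neg <- score[!is_adverse]
  sens <- vapply(thr, function(ct) mean(pos <= ct), 0)
  spc <- vapply(thr, function(ct) mean(neg > ct), 0)
  fpr <- 1 - spc
  auc <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  j <- sens + spc - 1
  i <- which.max(j)
  structure(list(thresholds = thr, sens = sens, spec = spc,
                 auc = auc, j_max = j[i], c_opt = thr[i],
                 n_pos = n_pos, n_neg = n_neg),
            class = "pn_roc")
}

#' @export
print.pn_roc <- function(x, ...) {
  cat(sprintf("<ROC: %d pos / %d neg, AUC = %.3f, Jmax = %.3f at cutoff %.3g>\n",
              x$n_pos, x$n_neg, x$auc, x$j_max, x$c_opt))
  invisible(x)
}

#' ROC curves stratified by gestational window
#'
#' Computes the overall ROC curve and one per gestational window. Windows
#' with a single outcome class are skipped with a warning. Optionally
#' aggregates to subject level first, scoring each subject in a window by
#' its most severe (minimum) percentile.
#'
#' @param scores Scored cohort (see [score_cohort()]) or any data.frame
#'   with columns `percentile`, `ga_weeks` and (for subject aggregation)
#'   `subject_id`.
#' @param is_adverse Logical labels aligned with `scores` rows.
#' @param windows Character vector of window labels to stratify on
#'   (default the three analysis windows); `NULL` or empty for overall
#'   only.
#' @param level `"scan"` (default; each completed study is one ROC point)
#'   or `"subject"` (minimum percentile per subject per stratum).
#' @return Named list of `pn_roc` objects: `overall` plus one entry per
#'   usable window.
#' @export
windowed_roc <- function(scores, is_adverse,
                         windows = c("10-20", "20-30", "30+"),
                         level = c("scan", "subject")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(scores), "percentile" %in% names(scores))
  is_adverse <- as.logical(is_adverse)
  if (length(is_adverse) != nrow(scores)) stop("label length mismatch")
  win <- ga_window(scores$ga_weeks)
  pick <- function(keep) {
    sc <- scores$percentile[keep]; lab <- is_adverse[keep]
    if (level == "subject") {
      sid <- scores$subject_id[keep]
      sc <- tapply(sc, sid, min)
      lab <- tapply(lab, sid, any)
      sc <- as.numeric(sc); lab <- as.logical(lab)
    }
    list(score = sc, lab = lab)
  }
  all_in <- pick(rep(TRUE, nrow(scores)))
  out <- list(overall = roc_curve(all_in$score, all_in$lab))
  for (w in windows) {
    keep <- win == w
    if (!any(keep)) next
    d <- pick(keep)
    if (length(unique(d$lab)) < 2L) {
      warning(sprintf("window %s has a single outcome class; skipped", w))
      next
    }
    out[[w]] <- roc_curve(d$score, d$lab)
  }
  out
}
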