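#' Fit a trajectory model by least squares
#'
#' Fits one of the candidate gestational models to observations `(t, y)`.
#' Polynomial families (constant through cubic) are linear in their
#' parameters and solved exactly by ordinary least squares; the sigmoid
#' families are fitted by Levenberg-Marquardt nonlinear least squares
#' ([minpack.lm::nls.lm()]) with analytic Jacobians and a deterministic
#' multistart (a data-driven initialization plus a grid of 20 alternative
#' `(p2, p3)` starts), keeping the solution with the smallest residual sum
#' of squares. Logistic fits are prone to local minima; the multistart
#' makes recovery robust without consuming the caller's RNG stream.
#'
#' Conventions:
#' * `param_cov = s2 * (J'J)^-1` with `s2 = RSS / (n - k)` (Gauss-Newton
#'   covariance). When `J'J` is numerically singular — e.g. a
#'   near-degenerate sigmoid on nearly linear data — the Moore-Penrose
#'   pseudoinverse is used so the fit is reported with very large
#'   uncertainties rather than failing.
#' * `rms_residual = sqrt(RSS / n)`, the root-mean-square residual.
#' * `bic = n * log(RSS / n) + k * log(n)` (the Gaussian-likelihood BIC up
#'   to an additive constant shared by all candidates).
#'
#' @param t Gestational ages, weeks.
#' @param y Observations (same length as `t`).
#' @param spec A [model_spec()] or form name.
#' @return An object of class `pn_fit`: list with `spec`, `params`,
#'   `param_cov`, `rms_residual`, `sigma2` (residual variance
#'   `RSS/(n-k)`), `rss`, `n_obs`, `bic`, `converged`, `t_range`.
#' @examples
#' t <- seq(11, 38, length.out = 60)
#' y <- evaluate_model("linear", c(-372.4, 32.2), t)
#' fit_model(t, y, "linear")$params
#' @export
fit_model <- function(t, y, spec) {
  spec <- as_model_spec(spec)
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (!all(is.finite(t)) || !all(is.finite(y))) stop("t and y must be finite")
  n <- length(y); k <- spec$n_params
  if (n <= k + 1L) stop(sprintf("need more than %d observations for form '%s'", k + 1L, spec$form))

  if (spec$form %in% c("constant", "linear", "quadratic", "cubic")) {
    X <- model_gradient(spec, numeric(k), t)  # design matrix (linear in params)
    qrX <- qr(X)
    params <- as.numeric(qr.coef(qrX, y))
    res <- y - as.numeric(X %*% params)
    converged <- qrX$rank == k
    J <- X
  } else {
    start0 <- .sigmoid_start(spec, t, y)
    starts <- c(list(start0), .sigmoid_start_grid(spec, start0))
    best <- NULL
    for (s in starts) {
      # individual starts may stall without converging; that is expected
      # for a multistart and judged afterwards via info and best SSE
      out <- tryCatch(
        suppressWarnings(minpack.lm::nls.lm(
          par = s,
          fn = function(p) y - evaluate_model(spec, p, t),
          jac = function(p) -model_gradient(spec, p, t),
          control = minpack.lm::nls.lm.control(maxiter = 200))),
        error = function(e) NULL)
      if (is.null(out)) next
      if (is.null(best) || out$deviance < best$deviance) best <- out
    }
    if (is.null(best)) stop(sprintf("all starts failed for form '%s'", spec$form))
    params <- as.numeric(best$par)
    res <- y - evaluate_model(spec, params, t)
    converged <- best$info %in% 1:4 && all(is.finite(params))
    J <- model_gradient(spec, params, t)
  }

  rss <- sum(res^2)
  sigma2 <- rss / (n - k)
  JtJ <- crossprod(J)
  inv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    inv <- MASS::ginv(JtJ)
    converged <- converged && FALSE
  }
  param_cov <- sigma2 * (inv + t(inv)) / 2

  structure(list(
    spec = spec,
    params = params,
    param_cov = param_cov,
    rms_residual = sqrt(rss / n),
    sigma2 = sigma2,
    rss = rss,
    n_obs = n,
    bic = n * log(rss / n) + k * log(n),
    converged = converged,
    t_range = range(t)
  ), class = "pn_fit")
}

# Data-driven initialization for the logistic families.
.sigmoid_start <- function(spec, t, y) {
  if (spec$form == "sigmoid") {
    early <- y[t < 20]; late <- y[t > 34]
    p4 <- if (length(early)) mean(early) else max(y)
    p1 <- (if (length(late)) mean(late) else min(y)) - p4
    if (!is.finite(p1) || p1 == 0) p1 <- min(y) - max(y)
    c(p1 = p1, p2 = -0.2, p3 = 30, p4 = p4)
  } else {
    # negative bump with peak -p1*p2/4 at t = p3
    i <- which.min(y)
    peak <- min(y[i], -1e-8)
    p2 <- -0.2
    c(p1 = -4 * peak / p2, p2 = p2, p3 = t[i])
  }
}

.sigmoid_start_grid <- function(spec, start0) {
  p2s <- c(-0.05, -0.1, -0.2, -0.35, -0.5)
  p3s <- c(15, 22, 29, 36)
  out <- vector("list", length(p2s) * length(p3s))
  i <- 0L
  for (p2 in p2s) for (p3 in p3s) {
    s <- start0
    s["p2"] <- p2
    s["p3"] <- p3
    out[[i <- i + 1L]] <- s
  }
  out
}

#' @export
print.pn_fit <- function(x, ...) {
  cat(sprintf("<%s fit, n = %d%s>\n", x$spec$form, x$n_obs,
              if (x$converged) "" else ", NOT converged"))
  se <- sqrt(pmax(diag(x$param_cov), 0))
  for (i in seq_along(x$params)) {
    cat(sprintf("  p%d = %.6g (+/- %.3g)\n", i, x$params[i], se[i]))
  }
  cat(sprintf("  rms residual = %.4g, BIC = %.4g\n", x$rms_residual, x$bic))
  invisible(x)
}

#' Select among candidate models by BIC
#'
#' Fits each candidate family to the same data and returns the fit with the
#' smallest Bayes Information Criterion. Ties are broken toward the model
#' with fewer parameters. Candidates whose fit does not converge are
#' excluded with a warning.
#'
#' @inheritParams fit_model
#' @param candidates Character vector of model form names (or list of
#'   [model_spec()]s); at least two.
#' @return List with `best` (a `pn_fit`) and `fits` (all converged fits,
#'   named by form).
#' @export
select_model_bic <- function(t, y, candidates = c("constant", "linear",
                                                  "quadratic", "cubic",
                                                  "sigmoid")) {
  if (length(candidates) < 2L) stop("need at least two candidate models")
  specs <- lapply(candidates, as_model_spec)
  fits <- lapply(specs, function(s) {
    tryCatch(fit_model(t, y, s), error = function(e) NULL)
  })
  names(fits) <- vapply(specs, `[[`, "", "form")
  bad <- vapply(fits, function(f) is.null(f) || !f$converged, TRUE)
  if (any(bad)) {
    warning(sprintf("excluding non-converged candidate(s): %s",
                    paste(names(fits)[bad], collapse = ", ")))
  }
  fits <- fits[!bad]
  if (!length(fits)) stop("no candidate model converged")
  # stable order by parameter count so BIC ties resolve to fewer parameters
  fits <- fits[order(vapply(fits, function(f) f$spec$n_params, 0L))]
  best <- fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
  list(best = best, fits = fits)
}

#' Confidence and prediction bands for a fitted model
#'
#' Pointwise 95% (by default) confidence and prediction bands on a
#' gestational-age grid, by the delta method: the curve variance at `t` is
#' `g(t)' C g(t)` where `g` is the parameter gradient of the model and `C`
#' the parameter covariance; the prediction variance adds the residual
#' variance `s2 = RSS/(n-k)`. Normal quantiles are used.
#'
#' @param fit A converged `pn_fit`.
#' @param grid_t Gestational-age grid (weeks).
#' @param level Coverage level, default 0.95.
#' @return A data.frame with columns `grid_t`, `mean`, `ci_lo`, `ci_hi`,
#'   `pi_lo`, `pi_hi`; pointwise `pi_lo <= ci_lo <= mean <= ci_hi <= pi_hi`.
#' @export
confidence_band <- function(fit, grid_t, level = 0.95) {
  stopifnot(inherits(fit, "pn_fit"))
  if (!fit$converged) stop("fit did not converge; no band available")
  ev <- eigen(fit$param_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("parameter covariance is not positive semidefinite")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  mu <- evaluate_model(fit$spec, fit$params, grid_t)
  G <- model_gradient(fit$spec, fit$params, grid_t)
  var_curve <- pmax(rowSums((G %*% fit$param_cov) * G), 0)
  se_ci <- sqrt(var_curve)
  se_pi <- sqrt(var_curve + fit$sigma2)
  data.frame(grid_t = grid_t, mean = mu,
             ci_lo = mu - z * se_ci, ci_hi = mu + z * se_ci,
             pi_lo = mu - z * se_pi, pi_hi = mu + z * se_pi)
}

#' Gestational intervals where two group curves separate
#'
#' Two regression curves are considered significantly different at
#' gestational age `t` when their pointwise 95% confidence intervals do not
#' overlap. Returns the contiguous intervals of the grid where that holds.
#'
#' @param fit_a,fit_b Converged `pn_fit` objects for the two groups.
#' @param grid_t Common gestational-age grid (weeks); default 10 to 40 in
#'   steps of 0.1.
#' @param level Confidence level for the bands.
#' @return data.frame with columns `start`, `end` (weeks); zero rows when
#'   the curves never separate.
#' @export
band_separation <- function(fit_a, fit_b, grid_t = seq(10, 40, by = 0.1),
                            level = 0.95) {
  ba <- confidence_band(fit_a, grid_t, level)
  bb <- confidence_band(fit_b, grid_t, level)
  sep <- ba$ci_hi < bb$ci_lo | bb$ci_hi < ba$ci_lo
  if (!any(sep)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  r <- rle(sep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = grid_t[starts[keep]], end = grid_t[ends[keep]])
}

#' Within-subject rates of T2* change
#'
#' For the ordered scans of one subject, forms the centered finite
#' differences between consecutive scans: the x value is the mean
#' gestational age of the pair and the y value the change in T2* divided by
#' the change in gestational age (ms/week).
#'
#' @param ga_weeks Gestational ages of one subject's scans, strictly
#'   increasing.
#' @param t2star_ms Median T2* at each scan.
#' @return data.frame with columns `mid_ga_weeks`, `rate`; one row per
#'   consecutive pair.
#' @examples
#' rate_pairs(c(20, 30), c(80, 50))  # mid 25, rate -3 ms/wk
#' @export
rate_pairs <- function(ga_weeks, t2star_ms) {
  if (length(ga_weeks) != length(t2star_ms)) stop("length mismatch")
  if (length(ga_weeks) < 2L) stop("need at least 2 scans")
  dt <- diff(ga_weeks)
  if (any(dt == 0)) stop("duplicate gestational ages (zero denominator)")
  if (any(dt < 0)) stop("gestational ages must be increasing")
  data.frame(mid_ga_weeks = (ga_weeks[-length(ga_weeks)] + ga_weeks[-1L]) / 2,
             rate = diff(t2star_ms) / dt)
}

#' Rate pairs for every subject in a cohort
#'
#' @param cohort A cohort data.frame (see [simulate_cohort()]); scans of a
#'   subject must be in increasing gestational-age order.
#' @return data.frame with `subject_id`, `mid_ga_weeks`, `rate`.
#' @export
cohort_rate_pairs <- function(cohort) {
  parts <- split(cohort, cohort$subject_id)
  out <- lapply(parts, function(d) {
    if (nrow(d) < 2L) return(NULL)
    d <- d[order(d$ga_weeks), , drop = FALSE]
    p <- rate_pairs(d$ga_weeks, d$t2star_ms)
    p$subject_id <- d$subject_id[1L]
    p
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(subject_id = character(0), mid_ga_weeks = numeric(0),
                      rate = numeric(0)))
  }
  rownames(out) <- NULL
  out[, c("subject_id", "mid_ga_weeks", "rate")]
}

#' Fit the analytic-derivative model to rate pairs
#'
#' Fits the 3-parameter time derivative of the logistic sigmoid to
#' within-subject rate-of-change pairs, with the same covariance and BIC
#' conventions as [fit_model()].
#'
#' @param pairs data.frame with columns `mid_ga_weeks` and `rate`
#'   (ms/week), e.g. from [cohort_rate_pairs()]; at least 10 pairs.
#' @return A `pn_fit` with spec `sigmoid_derivative`.
#' @export
fit_rate_model <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("mid_ga_weeks", "rate") %in% names(pairs)))
  if (nrow(pairs) < 10L) stop("need at least 10 rate pairs")
  fit_model(pairs$mid_ga_weeks, pairs$rate, "sigmoid_derivative")
}

#' Serialize / read a model fit as JSON
#'
#' @param fit A `pn_fit`.
#' @param path File path.
#' @return `read_fit` returns a `pn_fit`; `write_fit` its path, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "pn_fit"))
  obj <- list(form = fit$spec$form,
              params = fit$params,
              cov = as.numeric(t(fit$param_cov)),   # row-major
              rms = fit$rms_residual,
              sigma2 = fit$sigma2,
              rss = fit$rss,
              n = fit$n_obs,
              bic = fit$bic,
              converged = fit$converged,
              t_range = fit$t_range)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- model_spec(obj$form)
  k <- spec$n_params
  structure(list(
    spec = spec,
    params = as.numeric(obj$params),
    param_cov = matrix(as.numeric(obj$cov), k, k, byrow = TRUE),
    rms_residual = obj$rms,
    sigma2 = obj$sigma2,
    rss = obj$rss,
    n_obs = obj$n,
    bic = obj$bic,
    converged = isTRUE(obj$converged),
    t_range = as.numeric(obj$t_range)
  ), class = "pn_fit")
}
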