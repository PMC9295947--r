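#' Voxelwise T2* estimate from multi-echo signals
#'
#' Fits the mono-exponential decay `S(TE) = S0 * exp(-TE / T2*)` to the
#' signals of one voxel by nonlinear least squares (Levenberg-Marquardt),
#' initialized from the log-linear regression of `log(S)` on TE. The
#' relative uncertainty is the delta-method SD of the T2* estimate — the
#' square root of the T2* diagonal entry of the Gauss-Newton covariance
#' `RSS/(n-2) * (J'J)^-1` — divided by the fitted T2*.
#'
#' A voxel is marked invalid (`valid = FALSE`, estimates `NA`) when fewer
#' than three echoes have positive signal, when the decay is absent or
#' inverted (non-negative log-linear slope), or when the fit diverges or
#' returns a non-positive T2*. Such voxels are noise-dominated and carry
#' no usable relaxometry information.
#'
#' @param signals Numeric vector of signal magnitudes, one per echo.
#' @param echo_times_ms Echo times, ms, same length as `signals`.
#' @return List of class `pn_voxel_fit`: `t2star_ms`, `s0`,
#'   `rel_uncertainty`, `valid`.
#' @examples
#' te <- c(4.92, 9.84, 19.68, 29.52, 36.90, 49.20)
#' fit_t2star_voxel(100 * exp(-te / 50), te)
#' @export
fit_t2star_voxel <- function(signals, echo_times_ms) {
  if (length(signals) != length(echo_times_ms)) {
    stop("signals and echo_times_ms must have equal length")
  }
  invalid <- structure(list(t2star_ms = NA_real_, s0 = NA_real_,
                            rel_uncertainty = NA_real_, valid = FALSE),
                       class = "pn_voxel_fit")
  pos <- is.finite(signals) & signals > 0
  if (sum(pos) < 3L) return(invalid)
  te <- echo_times_ms[pos]
  s <- signals[pos]
  # log-linear initialization: log S = log S0 - TE / T2*
  co <- stats::coef(stats::lm.fit(cbind(1, te), log(s)))
  if (!all(is.finite(co)) || co[2L] >= 0) return(invalid)
  start <- c(s0 = exp(co[[1L]]), t2 = -1 / co[[2L]])
  out <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start,
      fn = function(p) s - p[1L] * exp(-te / p[2L]),
      jac = function(p) {
        decay <- exp(-te / p[2L])
        -cbind(decay, p[1L] * decay * te / p[2L]^2)
      },
      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out$par)) || out$par[2L] <= 0) {
    return(invalid)
  }
  s0 <- out$par[[1L]]; t2 <- out$par[[2L]]
  n <- length(s)
  decay <- exp(-te / t2)
  J <- cbind(decay, s0 * decay * te / t2^2)
  rss <- sum((s - s0 * decay)^2)
  cov <- tryCatch(rss / (n - 2) * solve(crossprod(J)),
                  error = function(e) NULL)
  rel <- if (is.null(cov)) Inf else sqrt(max(cov[2L, 2L], 0)) / t2
  structure(list(t2star_ms = t2, s0 = s0, rel_uncertainty = rel,
                 valid = TRUE),
            class = "pn_voxel_fit")
}

#' Map T2* over a placental ROI
#'
#' Runs [fit_t2star_voxel()] at every masked voxel and summarizes the
#' placenta with the median, the robust choice because intra-placental T2*
#' distributions are markedly non-Gaussian. Voxels whose fitted T2* is
#' 250 ms or more are excluded from the median and the uncertainty summary
#' (such long values indicate signal contamination by amniotic fluid), as
#' are invalid voxel fits. The exclusion threshold is applied to the
#' fitted values and is a strict `>= 250`.
#'
#' @param volume A `pn_phantom`-like list with `signal` (4D array) and
#'   `echo_times_ms`, or any list with those fields.
#' @param roi List with `mask` (3D logical aligned to the signal grid) and
#'   optional `missing_slices`; a bare logical array is also accepted.
#' @param exclude_ms Exclusion threshold (default 250 ms).
#' @return List with `map` (3D array of fitted T2*, `NA` outside the mask
#'   or where invalid) and `summary`: `median_t2star_ms`, `n_voxels_used`,
#'   `n_voxels_excluded_over_threshold`, `n_voxels_invalid`,
#'   `median_rel_uncertainty`.
#' @export
map_t2star <- function(volume, roi, exclude_ms = 250) {
  mask <- if (is.list(roi)) roi$mask else roi
  signal <- volume$signal
  te <- volume$echo_times_ms
  if (!identical(dim(signal)[1:3], dim(mask)[1:3])) {
    stop("mask shape does not match signal spatial dimensions")
  }
  if (dim(signal)[4L] != length(te)) {
    stop("echo axis length does not match number of echo times")
  }
  idx <- which(mask)
  if (!length(idx)) stop("empty ROI")
  nvox <- prod(dim(mask))
  sig_mat <- matrix(signal, nrow = nvox)[idx, , drop = FALSE]
  t2 <- rep(NA_real_, length(idx))
  rel <- rep(NA_real_, length(idx))
  for (j in seq_along(idx)) {
    vf <- fit_t2star_voxel(sig_mat[j, ], te)
    if (vf$valid) {
      t2[j] <- vf$t2star_ms
      rel[j] <- vf$rel_uncertainty
    }
  }
  map <- array(NA_real_, dim(mask))
  map[idx] <- t2
  valid <- !is.na(t2)
  over <- valid & t2 >= exclude_ms
  used <- valid & !over
  structure(list(
    map = map,
    summary = list(
      median_t2star_ms = if (any(used)) stats::median(t2[used]) else NA_real_,
      n_voxels_used = sum(used),
      n_voxels_excluded_over_threshold = sum(over),
      n_voxels_invalid = sum(!valid),
      median_rel_uncertainty = if (any(used)) stats::median(rel[used]) else NA_real_
    )), class = "pn_t2star_map")
}

#' Placental volume from a binary ROI mask
#'
#' Volume is the per-slice masked voxel count times the per-voxel volume,
#' summed over slices. Slices missing due to motion contribute the linear
#' interpolation (by slice index) of the counts of the nearest present
#' slice on each side; a missing slice with present neighbors on one side
#' only copies the nearest present slice's count.
#'
#' @param roi List with `mask` (3D logical) and optional integer
#'   `missing_slices` (z indices whose mask is all false), or a bare
#'   logical array.
#' @param voxel_dims_mm Voxel edge lengths, mm.
#' @return Volume in cm^3.
#' @examples
#' m <- array(TRUE, c(10, 10, 10))
#' placental_volume(m, c(1.75, 1.75, 3.5))  # 1000 voxels -> 10.71875 cm^3
#' @export
placental_volume <- function(roi, voxel_dims_mm) {
  mask <- if (is.list(roi)) roi$mask else roi
  missing_slices <- if (is.list(roi)) as.integer(roi$missing_slices %||% integer(0)) else integer(0)
  stopifnot(length(dim(mask)) == 3L, length(voxel_dims_mm) == 3L,
            all(voxel_dims_mm > 0))
  nz <- dim(mask)[3L]
  counts <- apply(mask, 3L, sum)
  if (length(missing_slices)) {
    if (any(missing_slices < 1L | missing_slices > nz)) {
      stop("missing_slices out of range")
    }
    if (any(counts[missing_slices] != 0)) {
      stop("missing slices must have an all-false mask")
    }
    present <- setdiff(seq_len(nz), missing_slices)
    if (!length(present)) stop("all slices missing")
    for (ms in missing_slices) {
      lo <- present[present < ms]
      hi <- present[present > ms]
      if (length(lo) && length(hi)) {
        l <- max(lo); h <- min(hi)
        w <- (ms - l) / (h - l)
        counts[ms] <- (1 - w) * counts[l] + w * counts[h]
      } else if (length(lo)) {
        counts[ms] <- counts[max(lo)]
      } else {
        counts[ms] <- counts[min(hi)]
      }
    }
  }
  if (sum(counts) == 0) stop("empty ROI")
  sum(counts) * prod(voxel_dims_mm) / 1000
}

`%||%` <- function(a, b) if (is.null(a)) b else a
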