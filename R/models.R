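#' Candidate gestational-age trajectory models
#'
#' The package models a scalar measurement (median placental T2*, maternal
#' hemoglobin, SpO2, placental volume, median T1, or within-subject rate of
#' T2* change) as a function of gestational age `t` in weeks, using one of
#' six closed-form model families:
#'
#' * `constant`: `y(t) = p1`
#' * `linear`: `y(t) = p1 + p2*t`
#' * `quadratic`: `y(t) = p1 + p2*t + p3*t^2`
#' * `cubic`: `y(t) = p1 + p2*t + p3*t^2 + p4*t^3`
#' * `sigmoid`: `y(t) = p1 / (1 + exp(p2*(t - p3))) + p4`
#' * `sigmoid_derivative`:
#'   `y(t) = -p1*p2*exp(p2*(t - p3)) / (1 + exp(p2*(t - p3)))^2`,
#'   the analytic time derivative of the sigmoid, used for rate-of-change
#'   data (3 free parameters; the sigmoid offset `p4` drops out).
#'
#' With `p2 < 0` the sigmoid decreases from an early plateau `p4` toward a
#' late plateau `p1 + p4`, with inflection at `t = p3` — the shape placental
#' T2* follows across gestation.
#'
#' @param form One of `"constant"`, `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"sigmoid"`, `"sigmoid_derivative"`.
#' @return An object of class `pn_model_spec`: a list with elements `form`
#'   and `n_params`.
#' @examples
#' model_spec("sigmoid")
#' @export
model_spec <- function(form) {
  form <- match.arg(form, names(.pn_model_forms))
  structure(list(form = form, n_params = .pn_model_forms[[form]]),
            class = "pn_model_spec")
}

.pn_model_forms <- c(constant = 1L, linear = 2L, quadratic = 3L,
                     cubic = 4L, sigmoid = 4L, sigmoid_derivative = 3L)

as_model_spec <- function(spec) {
  if (inherits(spec, "pn_model_spec")) return(spec)
  if (is.character(spec) && length(spec) == 1L) return(model_spec(spec))
  stop("`spec` must be a model form name or a pn_model_spec")
}

#' @export
print.pn_model_spec <- function(x, ...) {
  cat(sprintf("<model spec: %s, %d parameter%s>\n", x$form, x$n_params,
              if (x$n_params == 1L) "" else "s"))
  invisible(x)
}

#' Evaluate a trajectory model
#'
#' Evaluates the closed form of a candidate model at gestational ages `t`.
#' The logistic terms are computed through [stats::plogis()], so evaluation
#' is overflow-safe for arbitrarily large `|p2*(t - p3)|`.
#'
#' @param spec A [model_spec()] or a model form name.
#' @param params Numeric parameter vector of length `spec$n_params`.
#' @param t Gestational ages (weeks) at which to evaluate.
#' @return Numeric vector of model values, same length as `t`.
#' @examples
#' # uncomplicated-pregnancy T2* curve at its inflection point
#' evaluate_model("sigmoid", c(-59.2, -0.24, 29.3, 84.6), 29.3)
#' @export
evaluate_model <- function(spec, params, t) {
  spec <- as_model_spec(spec)
  params <- as.numeric(params)
  if (length(params) != spec$n_params) {
    stop(sprintf("form '%s' needs %d parameters, got %d",
                 spec$form, spec$n_params, length(params)))
  }
  stopifnot(is.numeric(t))
  switch(spec$form,
    constant  = rep_len(params[1L], length(t)),
    linear    = params[1L] + params[2L] * t,
    quadratic = params[1L] + params[2L] * t + params[3L] * t^2,
    cubic     = params[1L] + params[2L] * t + params[3L] * t^2 + params[4L] * t^3,
    sigmoid   = {
      # p1 / (1 + e^u) == p1 * plogis(-u),  u = p2 (t - p3)
      u <- params[2L] * (t - params[3L])
      params[1L] * stats::plogis(-u) + params[4L]
    },
    sigmoid_derivative = {
      # -p1 p2 e^u / (1 + e^u)^2 == -p1 p2 plogis(u) plogis(-u)
      u <- params[2L] * (t - params[3L])
      -params[1L] * params[2L] * stats::plogis(u) * stats::plogis(-u)
    })
}

# Analytic parameter gradient d y / d p, an length(t) x n_params matrix.
# Used for the Gauss-Newton covariance and delta-method bands.
model_gradient <- function(spec, params, t) {
  spec <- as_model_spec(spec)
  n <- length(t)
  switch(spec$form,
    constant  = matrix(1, n, 1L),
    linear    = cbind(1, t),
    quadratic = cbind(1, t, t^2),
    cubic     = cbind(1, t, t^2, t^3),
    sigmoid   = {
      u <- params[2L] * (t - params[3L])
      sig <- stats::plogis(-u)              # 1 / (1 + e^u)
      w <- sig * stats::plogis(u)           # e^u / (1 + e^u)^2
      cbind(sig,
            -params[1L] * w * (t - params[3L]),
            params[1L] * params[2L] * w,
            1)
    },
    sigmoid_derivative = {
      u <- params[2L] * (t - params[3L])
      su <- stats::plogis(u)
      w <- su * stats::plogis(-u)
      dw <- w * (1 - 2 * su)                # dw/du
      cbind(-params[2L] * w,
            -params[1L] * (w + params[2L] * dw * (t - params[3L])),
            params[1L] * params[2L]^2 * dw)
    })
}
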