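# Least-squares exponential-decay fits: perfusion-insensitive ADC on the
# high-b portion of a DWI curve, T2* on a multi-echo BOLD curve, and the
# segmented (two-stage) IVIM initialisation. All nonlinear fits use the
# Levenberg-Marquardt algorithm (minpack.lm), initialised from a two-point
# log-linear solution. Failures are returned as non-converged results, not
# exceptions, so voxelwise drivers can carry on.

decay_fit_result <- function(params, model, curve, subset, converged,
                             note = NA_character_) {
  fitted <- rep(NA_real_, length(curve$abscissa))
  resid <- rep(NA_real_, length(curve$abscissa))
  rn <- NA_real_
  if (!is.null(params)) {
    fwd <- switch(model,
                  adc = , mono = function(a) monoexp_signal(params, a),
                  t2star = function(a) t2star_signal(params, a))
    fitted <- fwd(curve$abscissa)
    resid <- curve$signal - fitted
    dof <- max(length(subset) - 2L, 1L)
    rn <- sum(resid[subset]^2) / dof
    if (!is.finite(rn)) converged <- FALSE
  }
  structure(list(params = params, model = model, curve = curve,
                 subset = subset, fitted = fitted, residuals = resid,
                 residual_norm = rn, converged = converged, note = note),
            class = "decay_fit")
}

# Two-point log-linear solution between the first and last positive points;
# returns c(s0, rate) for S = s0 * exp(-rate * x), or NULL.
loglin_two_point <- function(x, y) {
  pos <- which(y > 0)
  if (length(pos) < 2L) return(NULL)
  i <- pos[1]; j <- pos[length(pos)]
  rate <- log(y[i] / y[j]) / (x[j] - x[i])
  s0 <- y[i] * exp(rate * x[i])
  c(s0 = s0, rate = rate)
}

lm_exp_fit <- function(x, y, start_s0, start_rate) {
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ s0 * exp(-rate * x), data = df,
                      start = list(s0 = start_s0, rate = start_rate),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cf <- coef(fit)
  if (!all(is.finite(cf)) || cf[["s0"]] <= 0) return(NULL)
  cf
}

#' Fit the perfusion-insensitive ADC
#'
#' Monoexponential Levenberg-Marquardt fit restricted to b-values at or
#' above `b_min` (default 200 s/mm^2), where the fast pseudodiffusion
#' compartment has decayed away, yielding an apparent diffusion coefficient
#' insensitive to perfusion. With `b_min = 0` this is the all-b
#' monoexponential fit used for model comparison against IVIM.
#'
#' @param curve A [decay_curve()] of kind `"dwi"`.
#' @param b_min Threshold b-value (s/mm^2).
#' @param include_b_min Whether `b == b_min` is retained (default `TRUE`,
#'   matching the ADC definition "b = 200 s/mm^2 and above").
#' @return A `decay_fit` whose `params` are [monoexp_params()]; check
#'   `$converged`.
#' @examples
#' cur <- decay_curve(dwi_b_scheme(),
#'                    monoexp_signal(monoexp_params(500, 1.1e-3), dwi_b_scheme()))
#' coef(fit_adc(cur))
#' @export
fit_adc <- function(curve, b_min = 200, include_b_min = TRUE) {
  stopifnot(inherits(curve, "decay_curve"))
  if (curve$kind != "dwi") stop_invalid("fit_adc expects a dwi curve")
  keep <- if (include_b_min) curve$abscissa >= b_min else curve$abscissa > b_min
  subset <- which(keep)
  if (length(subset) < 2L)
    stop_invalid("need at least two points with b >= b_min")
  x <- curve$abscissa[subset]; y <- curve$signal[subset]
  if (all(y <= 0))
    return(decay_fit_result(NULL, "adc", curve, subset, FALSE,
                            "all retained signals non-positive"))
  init <- loglin_two_point(x, y)
  if (is.null(init) || !is.finite(init[["rate"]]))
    init <- c(s0 = max(y), rate = 1e-3)
  cf <- lm_exp_fit(x, y, max(init[["s0"]], 1e-9), max(init[["rate"]], 1e-9))
  if (is.null(cf) || cf[["rate"]] <= 0)
    return(decay_fit_result(NULL, "adc", curve, subset, FALSE,
                            "Levenberg-Marquardt fit failed"))
  decay_fit_result(monoexp_params(cf[["s0"]], cf[["rate"]]),
                   "adc", curve, subset, TRUE)
}

#' Fit T2* from a multi-echo curve
#'
#' Monoexponential Levenberg-Marquardt fit of signal against echo time;
#' no noise-floor term is included (acquisitions are screened for
#' SNR > 20 at all echoes).
#'
#' @param curve A [decay_curve()] of kind `"bold"`.
#' @param t2_max T2* values above this bound (ms) are flagged
#'   non-converged (non-decaying, effectively unidentifiable curves).
#' @return A `decay_fit` whose `params` are [t2star_params()].
#' @export
fit_t2star <- function(curve, t2_max = 50 * max(curve$abscissa)) {
  stopifnot(inherits(curve, "decay_curve"))
  if (curve$kind != "bold") stop_invalid("fit_t2star expects a bold curve")
  if (length(curve$abscissa) < 2L) stop_invalid("need at least two echoes")
  x <- curve$abscissa; y <- curve$signal
  subset <- seq_along(x)
  if (all(y <= 0))
    return(decay_fit_result(NULL, "t2star", curve, subset, FALSE,
                            "all signals non-positive"))
  init <- loglin_two_point(x, y)
  rate0 <- if (is.null(init) || !is.finite(init[["rate"]]) ||
               init[["rate"]] <= 0) 1 / t2_max else init[["rate"]]
  s00 <- if (is.null(init)) max(y) else init[["s0"]]
  cf <- lm_exp_fit(x, y, max(s00, 1e-9), rate0)
  if (is.null(cf) || cf[["rate"]] <= 0 || 1 / cf[["rate"]] > t2_max)
    return(decay_fit_result(NULL, "t2star", curve, subset, FALSE,
                            "non-decaying or failed fit"))
  decay_fit_result(t2star_params(cf[["s0"]], 1 / cf[["rate"]]),
                   "t2star", curve, subset, TRUE)
}

#' Segmented IVIM initialisation
#'
#' Two-stage estimate used to initialise the Bayesian IVIM fit: a
#' monoexponential fit at high b gives the tissue diffusivity D; projecting
#' that fit back to b = 0 gives an intercept A, and the perfusion fraction
#' is initialised as `f = 1 - A / S(0)`, clamped to \[0, 1\]. D* is
#' initialised at a fixed multiple of D (its scale is not identifiable from
#' the high-b segment).
#'
#' @param curve A [decay_curve()] of kind `"dwi"` containing b = 0 and
#'   points on both sides of `b_min`.
#' @param b_min High-b threshold (s/mm^2); inclusive by default, see
#'   [fit_adc()].
#' @param include_b_min Passed to the high-b fit.
#' @param d_star_ratio Initial D*/D ratio (default 25, placing D* at the
#'   pseudodiffusion scale for renal tissue).
#' @return An [ivim_params()] estimate with attributes `converged`,
#'   `clamped` (intercept above S(0)) and `highb_fit` (the stage-one
#'   `decay_fit`), or a non-converged `decay_fit` when S(0) <= 0.
#' @export
segmented_init <- function(curve, b_min = 200, include_b_min = TRUE,
                           d_star_ratio = 25) {
  stopifnot(inherits(curve, "decay_curve"))
  if (curve$abscissa[1] != 0)
    stop_invalid("segmented initialisation needs the b = 0 point")
  if (!any(curve$abscissa < b_min) || !any(curve$abscissa >= b_min))
    stop_invalid("curve must have points below and at/above b_min")
  s0_meas <- curve$signal[1]
  if (s0_meas <= 0) {
    est <- decay_fit_result(NULL, "adc", curve, seq_along(curve$abscissa),
                            FALSE, "S(0) non-positive")
    return(est)
  }
  highb <- fit_adc(curve, b_min = b_min, include_b_min = include_b_min)
  if (!highb$converged) {
    attr(highb, "stage") <- "high-b fit failed"
    return(highb)
  }
  a_intercept <- highb$params$s0
  f_raw <- 1 - a_intercept / s0_meas
  clamped <- f_raw < 0 || f_raw > 1
  f_init <- min(max(f_raw, 0), 1)
  d_init <- highb$params$adc
  init <- ivim_params(s0 = s0_meas, f = f_init, d = d_init,
                      d_star = d_star_ratio * d_init)
  attr(init, "converged") <- TRUE
  attr(init, "clamped") <- clamped
  attr(init, "highb_fit") <- highb
  init
}

#' @export
print.decay_fit <- function(x, ...) {
  lab <- switch(x$model, adc = "perfusion-insensitive ADC",
                mono = "monoexponential (all b)", t2star = "T2*")
  cat(sprintf("<decay_fit: %s, %s>\n", lab,
              if (x$converged) "converged" else "NOT converged"))
  if (!is.null(x$params)) {
    cf <- coef(x)
    cat("  ", paste(sprintf("%s = %.6g", names(cf), cf), collapse = ", "),
        "\n", sep = "")
    cat(sprintf("  residual norm (SSR/dof): %.4g over %d fitted points\n",
                x$residual_norm, length(x$subset)))
  }
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) {
  if (is.null(object$params)) return(c(s0 = NA_real_))
  unlist(object$params)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$params)) stop_invalid("fit did not converge")
  x <- if (is.null(newdata)) object$curve$abscissa else newdata
  if (is.list(x)) x <- x[[1]]
  switch(object$model,
         adc = , mono = monoexp_signal(object$params, x),
         t2star = t2star_signal(object$params, x))
}

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
plot.decay_fit <- function(x, ...) {
  xlab <- if (x$model == "t2star") "TE (ms)" else "b (s/mm^2)"
  plot(x$curve$abscissa, x$curve$signal, pch = 19, xlab = xlab,
       ylab = "signal (a.u.)", ...)
  if (!is.null(x$params)) {
    xs <- seq(min(x$curve$abscissa), max(x$curve$abscissa), length.out = 200)
    lines(xs, predict(x, xs), col = "grey40")
    points(x$curve$abscissa[x$subset], x$curve$signal[x$subset], pch = 1,
           cex = 1.8)
  }
  invisible(x)
}
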