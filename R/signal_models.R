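#' renomri: multiparametric renal MRI analysis
#'
#' Forward signal models, a synthetic kidney phantom, voxelwise parameter
#' estimation (perfusion-insensitive ADC, Bayesian IVIM, multi-echo T2*),
#' cortex/medulla ROI summaries, and the repeatability / drug-challenge
#' statistics used in renal functional MRI studies.
#'
#' @keywords internal
#' @importFrom stats aov coef cor median optimize pnorm quantile
#'   rnorm runif sd setNames t.test uniroot wilcox.test
#' @importFrom graphics lines points legend
#' @importFrom utils capture.output modifyList write.csv
"_PACKAGE"

# Internal unit convention: diffusivities in mm^2/s, times in ms, signal in
# arbitrary units. Scaling to the reporting scales (ADC and D in 1e-5 mm^2/s,
# D* in 1e-2 mm^2/s, fD* in 1e-4 mm^2/s, f in %) happens only at the
# reporting boundary; see `reporting_scale()`.

#' Default diffusion-weighting scheme
#'
#' Nine b-values (s/mm^2) spanning the perfusion-sensitive low-b regime and
#' the diffusion-dominated high-b regime, as used for trace-weighted renal
#' DWI on clinical platforms.
#'
#' @return Numeric vector of b-values (s/mm^2).
#' @export
dwi_b_scheme <- function() c(0, 20, 40, 60, 80, 100, 200, 400, 800)

#' Default multi-echo gradient-echo scheme
#'
#' Five echo times (ms) for BOLD T2* relaxometry.
#'
#' @return Numeric vector of echo times (ms).
#' @export
bold_te_scheme <- function() c(5, 10, 20, 30, 40)

stop_invalid <- function(...) {
  stop(structure(class = c("renomri_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid(name, " must be a single positive finite number")
  invisible(x)
}

#' IVIM parameter set
#'
#' Bundle of biexponential intravoxel-incoherent-motion parameters.
#' The perfusion fraction `f` is stored as a fraction in \[0, 1\] and only
#' rendered as a percentage at the reporting boundary.
#'
#' @param s0 Signal amplitude at b = 0 (arbitrary units, > 0).
#' @param f Perfusion (fast-compartment) fraction in \[0, 1\].
#' @param d Tissue diffusion coefficient (mm^2/s, > 0).
#' @param d_star Pseudodiffusion coefficient (mm^2/s, > 0).
#' @return An object of class `ivim_params`.
#' @examples
#' ivim_params(s0 = 1000, f = 0.269, d = 1.245e-3, d_star = 4e-2)
#' @export
ivim_params <- function(s0, f, d, d_star) {
  check_scalar_pos(s0, "s0")
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop_invalid("f must lie in [0, 1]")
  check_scalar_pos(d, "d")
  check_scalar_pos(d_star, "d_star")
  structure(list(s0 = s0, f = f, d = d, d_star = d_star),
            class = "ivim_params")
}

#' Monoexponential (ADC) parameter set
#'
#' @param s0 Signal amplitude at b = 0 (> 0).
#' @param adc Apparent diffusion coefficient (mm^2/s, > 0).
#' @return An object of class `monoexp_params`.
#' @export
monoexp_params <- function(s0, adc) {
  check_scalar_pos(s0, "s0")
  check_scalar_pos(adc, "adc")
  structure(list(s0 = s0, adc = adc), class = "monoexp_params")
}

#' T2* relaxometry parameter set
#'
#' @param s0 Signal amplitude at TE = 0 (> 0).
#' @param t2_star Effective transverse relaxation time (ms, > 0).
#' @return An object of class `t2star_params`.
#' @export
t2star_params <- function(s0, t2_star) {
  check_scalar_pos(s0, "s0")
  check_scalar_pos(t2_star, "t2_star")
  structure(list(s0 = s0, t2_star = t2_star), class = "t2star_params")
}

#' Signal decay curve
#'
#' One voxel's (or an ROI-averaged) signal as a function of b-value (`dwi`)
#' or echo time (`bold`).
#'
#' @param abscissa Strictly increasing b-values (s/mm^2) or echo times (ms).
#' @param signal Signal intensities, same length as `abscissa`.
#' @param kind `"dwi"` or `"bold"`.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(abscissa, signal, kind = c("dwi", "bold")) {
  kind <- match.arg(kind)
  if (!is.numeric(abscissa) || !is.numeric(signal))
    stop_invalid("abscissa and signal must be numeric")
  if (length(abscissa) != length(signal))
    stop_invalid("abscissa and signal must have equal length")
  if (anyNA(abscissa) || any(diff(abscissa) <= 0))
    stop_invalid("abscissa must be strictly increasing and finite")
  if (any(abscissa < 0)) stop_invalid("abscissa values must be >= 0")
  structure(list(abscissa = as.numeric(abscissa),
                 signal = as.numeric(signal), kind = kind),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  lab <- if (x$kind == "dwi") "b-value (s/mm^2)" else "TE (ms)"
  cat(sprintf("<decay_curve: %s, %d points, %s>\n", x$kind,
              length(x$abscissa), lab))
  print(data.frame(abscissa = x$abscissa, signal = x$signal))
  invisible(x)
}

check_b <- function(b) {
  if (!is.numeric(b) || anyNA(b) || any(b < 0))
    stop_invalid("b-values / echo times must be non-negative numbers")
  b
}

#' IVIM forward signal model
#'
#' Biexponential two-compartment decay
#' `S(b) = S0 * (f * exp(-b * D*) + (1 - f) * exp(-b * D))`.
#'
#' @param params An [ivim_params()] object.
#' @param b b-value(s) in s/mm^2 (>= 0); vectorised.
#' @return Signal intensity at each `b`.
#' @export
ivim_signal <- function(params, b) {
  if (!inherits(params, "ivim_params")) params <- do.call(ivim_params, params)
  check_b(b)
  params$s0 * (params$f * exp(-b * params$d_star) +
               (1 - params$f) * exp(-b * params$d))
}

#' Monoexponential forward signal model
#'
#' `S(b) = S0 * exp(-b * ADC)`.
#'
#' @param params A [monoexp_params()] object.
#' @param b b-value(s) in s/mm^2 (>= 0); vectorised.
#' @return Signal intensity at each `b`.
#' @export
monoexp_signal <- function(params, b) {
  if (!inherits(params, "monoexp_params"))
    params <- do.call(monoexp_params, params)
  check_b(b)
  params$s0 * exp(-b * params$adc)
}

#' T2* forward signal model
#'
#' `S(TE) = S0 * exp(-TE / T2*)`.
#'
#' @param params A [t2star_params()] object.
#' @param te Echo time(s) in ms (>= 0); vectorised.
#' @return Signal intensity at each `te`.
#' @export
t2star_signal <- function(params, te) {
  if (!inherits(params, "t2star_params"))
    params <- do.call(t2star_params, params)
  check_b(te)
  params$s0 * exp(-te / params$t2_star)
}

#' Flow product fD*
#'
#' The product of the perfusion fraction and the pseudodiffusion
#' coefficient, an index of incoherent flow. Zero exactly when `f` is zero.
#'
#' @param f Perfusion fraction in \[0, 1\]; vectorised.
#' @param d_star Pseudodiffusion coefficient (mm^2/s, > 0); vectorised.
#' @return fD* in mm^2/s.
#' @export
flow_product <- function(f, d_star) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop_invalid("f must lie in [0, 1]")
  if (any(!is.finite(d_star)) || any(d_star <= 0))
    stop_invalid("d_star must be positive")
  f * d_star
}

#' Reporting-unit scale factors
#'
#' Fitted parameters are kept in base units (mm^2/s, ms) internally and
#' divided by these factors only when reported, so that tables read in the
#' conventional scales: ADC and D in 1e-5 mm^2/s, D* in 1e-2 mm^2/s,
#' fD* in 1e-4 mm^2/s, f in percent, T2* and S0 unscaled.
#'
#' @param parameter Parameter name(s): one of `"f"`, `"d"`, `"adc"`,
#'   `"d_star"`, `"f_d_star"`, `"t2_star"`, `"s0"`.
#' @return Named numeric vector of divisors.
#' @export
reporting_scale <- function(parameter) {
  scales <- c(f = 0.01, d = 1e-5, adc = 1e-5, d_star = 1e-2,
              f_d_star = 1e-4, t2_star = 1, s0 = 1)
  bad <- setdiff(parameter, names(scales))
  if (length(bad)) stop_invalid("unknown parameter(s): ",
                                paste(bad, collapse = ", "))
  scales[parameter]
}

#' Convert a parameter value to reporting units
#'
#' @param value Value(s) in base units (mm^2/s, ms, fraction).
#' @param parameter Parameter name, as for [reporting_scale()].
#' @return Value(s) in reporting units.
#' @export
to_reporting_units <- function(value, parameter) {
  value / unname(reporting_scale(parameter))
}
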