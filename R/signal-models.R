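#' Monoexponential diffusion-weighted signal
#'
#' Forward model for the signal intensity of a diffusion-weighted acquisition
#' under a single apparent diffusion coefficient:
#' \deqn{SI(b) = SI_0 \, e^{-b \cdot ADC}}
#'
#' All diffusivities are in plain mm^2/s (typical tissue values are of order
#' 1e-3); conversion to the conventional reporting unit of 1e-3 mm^2/s happens
#' only when tables are rendered.
#'
#' @param b Diffusion weighting(s), s/mm^2, non-negative.
#' @param si0 Unweighted signal amplitude (arbitrary units), positive.
#' @param adc Apparent diffusion coefficient, mm^2/s.
#' @return Numeric vector of signal amplitudes, recycled over inputs.
#' @examples
#' mono_signal(b = c(0, 800), si0 = 1000, adc = 1.04e-3)
#' @seealso [biexp_signal()], [two_point_adc()]
#' @export
mono_signal <- function(b, si0, adc) {
  stopifnot(all(b >= 0), all(si0 > 0))
  si0 * exp(-b * adc)
}

#' Biexponential (IVIM) diffusion-weighted signal
#'
#' Forward model of the intravoxel incoherent motion (IVIM) two-compartment
#' signal decay:
#' \deqn{SI(b) = SI_0 \left[(1 - f_p)\, e^{-b D} + f_p\, e^{-b D^*}\right]}
#' where \eqn{D} is the tissue diffusion coefficient, \eqn{D^*} the
#' pseudo-diffusion coefficient of the vascular compartment and \eqn{f_p} its
#' volume (perfusion) fraction. With `fp = 0` or `d_star = d` this reduces
#' exactly to [mono_signal()] with `adc = d`.
#'
#' @param b Diffusion weighting(s), s/mm^2, non-negative.
#' @param si0 Unweighted signal amplitude, positive.
#' @param d Tissue diffusion coefficient, mm^2/s.
#' @param d_star Pseudo-diffusion coefficient, mm^2/s; `d_star >= d`.
#' @param fp Perfusion fraction in `[0, 1]`.
#' @return Numeric vector of signal amplitudes.
#' @examples
#' biexp_signal(b = c(0, 50, 100, 250, 800),
#'              si0 = 1, d = 0.84e-3, d_star = 11.9e-3, fp = 0.16)
#' @export
biexp_signal <- function(b, si0, d, d_star, fp) {
  stopifnot(all(b >= 0), all(si0 > 0), all(fp >= 0), all(fp <= 1),
            all(d >= 0), all(d_star >= d))
  si0 * ((1 - fp) * exp(-b * d) + fp * exp(-b * d_star))
}

#' Exact two-point ADC
#'
#' Closed-form apparent diffusion coefficient through two signal measurements:
#' the chord slope of the log-signal,
#' \eqn{ADC = \ln(SI_a / SI_b) / (b_b - b_a)}. This is the exact least-squares
#' solution of the monoexponential model through two points and serves as the
#' analytic oracle for every two-b-value scheme.
#'
#' @param si_a,si_b Signal amplitudes at `b_a` and `b_b`; must be positive
#'   (non-positive signals indicate a noise-dominated voxel and raise an
#'   error).
#' @param b_a,b_b Diffusion weightings, s/mm^2, with `b_b > b_a`.
#' @return ADC in mm^2/s (vectorised).
#' @examples
#' two_point_adc(1, 0, exp(-0.8), 800) # 1e-3
#' @export
two_point_adc <- function(si_a, b_a, si_b, b_b) {
  if (any(si_a <= 0) || any(si_b <= 0)) {
    rlang::abort("signals must be positive for log-linear ADC computation",
                 class = "ivimsim_domain_error")
  }
  if (any(b_b <= b_a)) {
    rlang::abort("`b_b` must be strictly greater than `b_a`",
                 class = "ivimsim_domain_error")
  }
  log(si_a / si_b) / (b_b - b_a)
}

#' IVIM parameter set
#'
#' Validated tibble of biexponential model parameters, vectorised so it can
#' hold one row per lesion or per voxel. Invariants: `si0 > 0`,
#' `0 <= d <= d_star`, `0 <= fp <= 1`.
#'
#' @param si0 Unweighted amplitude.
#' @param d Tissue diffusion coefficient, mm^2/s.
#' @param d_star Pseudo-diffusion coefficient, mm^2/s.
#' @param fp Perfusion fraction.
#' @return A tibble with columns `si0`, `d`, `d_star`, `fp`.
#' @export
ivim_params <- function(si0, d, d_star, fp) {
  out <- tibble::tibble(si0 = si0, d = d, d_star = d_star, fp = fp)
  if (any(out$si0 <= 0)) rlang::abort("`si0` must be positive")
  if (any(out$d < 0) || any(out$d > out$d_star)) {
    rlang::abort("require 0 <= d <= d_star")
  }
  if (any(out$fp < 0) || any(out$fp > 1)) {
    rlang::abort("`fp` must lie in [0, 1]")
  }
  out
}

#' Monoexponential parameter set
#'
#' @param si0 Unweighted amplitude, positive.
#' @param adc Apparent diffusion coefficient, mm^2/s; finite. Negative values
#'   are permitted (they arise in noise-dominated voxels) and are left for
#'   downstream quality control to flag.
#' @return A tibble with columns `si0`, `adc`.
#' @export
mono_params <- function(si0, adc) {
  out <- tibble::tibble(si0 = si0, adc = adc)
  if (any(out$si0 <= 0)) rlang::abort("`si0` must be positive")
  if (any(!is.finite(out$adc))) rlang::abort("`adc` must be finite")
  out
}
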