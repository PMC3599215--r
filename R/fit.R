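#' @importFrom rlang .data
NULL

# Levenberg-Marquardt control shared by both fitters; tolerances are tight
# because noiseless phantom fits must recover truth to ~1e-6 relative.
.lm_control <- function() {
  minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15, gtol = 0,
                             maxiter = 500)
}

# Log-linear starting values for the mono fit; exact on noiseless data.
.mono_start <- function(b, s) {
  if (all(s > 0)) {
    fit <- stats::lm.fit(cbind(1, b), log(s))
    c(si0 = exp(fit$coefficients[[1]]), adc = -fit$coefficients[[2]])
  } else {
    c(si0 = max(s, 1), adc = 1e-3)
  }
}

.fit_mono_core <- function(b, s) {
  start <- .mono_start(b, s)
  if (all(s <= 0)) {
    return(list(si0 = NA_real_, adc = NA_real_, converged = FALSE,
                fitted = rep(NA_real_, length(b))))
  }
  res <- try(minpack.lm::nls.lm(
    par = start,
    fn = function(p) s - p[[1]] * exp(-b * p[[2]]),
    control = .lm_control()), silent = TRUE)
  if (inherits(res, "try-error")) {
    return(list(si0 = start[[1]], adc = start[[2]], converged = FALSE,
                fitted = start[[1]] * exp(-b * start[[2]])))
  }
  p <- res$par
  # info 1-3: ftol/xtol convergence; 4: residual orthogonal to the Jacobian,
  # reached at exact zero-residual solutions -- also a success
  ok <- res$info %in% 1:4 && all(is.finite(unlist(p))) && p[[1]] > 0
  list(si0 = p[[1]], adc = p[[2]], converged = ok,
       fitted = p[[1]] * exp(-b * p[[2]]))
}

# Biexponential bounds, mm^2/s: wide enough to contain reported lesion
# ranges (D up to 1.6e-3, D* up to 72.1e-3) with generous headroom.
.biexp_bounds <- function() {
  list(lower = c(si0 = 1e-12, d = 0, delta = 0, fp = 0),
       upper = c(si0 = Inf, d = 5e-3, delta = 0.5, fp = 1))
}

.biexp_predict <- function(p, b) {
  p[[1]] * ((1 - p[[4]]) * exp(-b * p[[2]]) + p[[4]] * exp(-b * (p[[2]] + p[[3]])))
}

.clip_biexp_start <- function(start, bounds) {
  pmin(pmax(start, bounds$lower + c(1e-9, 0, 0, 0)),
       c(Inf, bounds$upper[-1] - c(0, 0, 1e-6)))
}

# The IVIM least-squares surface has local optima when D* is small and f_p
# large (the perfusion compartment then contaminates the high-b segment and
# the segmented start is poor). The primary start is therefore backed by a
# small deterministic grid over (f_p, D*); the best residual wins, stopping
# early once the fit is essentially exact.
.biexp_start_grid <- function(init, s) {
  grid <- tidyr::expand_grid(fp = c(0.1, 0.3, 0.5),
                             d_star = c(5e-3, 15e-3, 50e-3))
  purrr::pmap(grid, function(fp, d_star) {
    d <- min(init$d, 0.8 * d_star)
    c(si0 = max(s), d = d, delta = d_star - d, fp = fp)
  })
}

.fit_biexp_core <- function(b, s, init) {
  bounds <- .biexp_bounds()
  if (all(s <= 0)) {
    return(list(si0 = NA_real_, d = NA_real_, d_star = NA_real_,
                fp = NA_real_, converged = FALSE,
                fitted = rep(NA_real_, length(b))))
  }
  starts <- c(list(c(si0 = init$si0, d = init$d,
                     delta = max(init$d_star - init$d, 1e-4), fp = init$fp)),
              .biexp_start_grid(init, s))
  ss_tot <- sum(s^2)
  best <- NULL
  for (start in starts) {
    res <- try(minpack.lm::nls.lm(
      par = .clip_biexp_start(start, bounds),
      fn = function(p) s - .biexp_predict(p, b),
      lower = bounds$lower, upper = bounds$upper,
      control = .lm_control()), silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
    if (best$deviance <= 1e-20 * ss_tot) break
  }
  if (is.null(best)) {
    start <- starts[[1L]]
    return(list(si0 = start[[1]], d = start[[2]],
                d_star = start[[2]] + start[[3]], fp = start[[4]],
                converged = FALSE, fitted = .biexp_predict(start, b)))
  }
  p <- best$par
  ok <- best$info %in% 1:4 && all(is.finite(unlist(p))) && p[[1]] > 0 &&
    p[[4]] < 1 - 1e-9
  list(si0 = p[[1]], d = p[[2]], d_star = p[[2]] + p[[3]], fp = p[[4]],
       converged = ok, fitted = .biexp_predict(p, b))
}

.as_series <- function(data, b_values = NULL) {
  if (is.data.frame(data)) {
    stopifnot(all(c("b_value", "signal") %in% names(data)))
    list(b = data$b_value, s = data$signal)
  } else {
    stopifnot(is.numeric(data), !is.null(b_values),
              length(data) == length(b_values))
    list(b = as.numeric(b_values), s = as.numeric(data))
  }
}

.new_dwi_fit <- function(model, b, s, core, extra = list()) {
  gof <- goodness_of_fit(s, core$fitted,
                         normalise_by = s[which.min(b)])
  structure(
    c(list(model = model, b_value = b, signal = s, fitted = core$fitted,
           converged = core$converged, n_points = length(b),
           r_squared = gof$r_squared, chi_squared = gof$chi_squared),
      core[setdiff(names(core), c("fitted", "converged"))], extra),
    class = "dwi_fit")
}

#' Fit the monoexponential model to one voxel series
#'
#' Estimates `(si0, adc)` by Levenberg-Marquardt least squares on the signal
#' in linear space, \eqn{\min \sum_b (SI_b - SI_0 e^{-b\,ADC})^2}. Starting
#' values come from a log-linear regression. For exactly two b values the
#' result coincides with the closed-form [two_point_adc()]. Non-fittable
#' input (all signals non-positive) yields `converged = FALSE` rather than an
#' error, so map-level fitting never aborts mid-volume.
#'
#' @param data A data frame with columns `b_value` and `signal`, or a numeric
#'   signal vector (then supply `b_values`).
#' @param b_values b values matching `data` when `data` is a bare vector.
#' @return A `"dwi_fit"` object; see [tidy.dwi_fit()] and [glance.dwi_fit()].
#' @examples
#' sig <- mono_signal(c(0, 50, 100, 250, 800), si0 = 500, adc = 1.3e-3)
#' fit <- fit_mono(data.frame(b_value = c(0, 50, 100, 250, 800), signal = sig))
#' glance(fit)
#' @export
fit_mono <- function(data, b_values = NULL) {
  ser <- .as_series(data, b_values)
  if (length(ser$b) < 2L) {
    rlang::abort("monoexponential fitting needs at least 2 b values",
                 class = "ivimsim_config_error")
  }
  core <- .fit_mono_core(ser$b, ser$s)
  .new_dwi_fit("mono", ser$b, ser$s, core)
}

#' Fit the biexponential (IVIM) model to one voxel series
#'
#' Estimates `(si0, d, d_star, fp)` by bounded Levenberg-Marquardt least
#' squares on the full two-compartment model. The constraint
#' `0 <= d <= d_star` is enforced by optimising over `delta = d_star - d >= 0`;
#' `fp` is box-bounded to `[0, 1]`. At least four distinct b values are
#' required for the four-parameter model.
#'
#' @param data Data frame with `b_value` and `signal` columns, or a numeric
#'   signal vector with `b_values` supplied.
#' @param b_values b values when `data` is a bare vector.
#' @param init `"segmented"` (default; see [segmented_init()]) or an explicit
#'   one-row parameter set from [ivim_params()].
#' @param b_threshold Perfusion-free cut-off passed to [segmented_init()].
#' @return A `"dwi_fit"` object.
#' @examples
#' b <- c(0, 50, 100, 250, 800)
#' sig <- biexp_signal(b, si0 = 1, d = 0.84e-3, d_star = 11.9e-3, fp = 0.16)
#' tidy(fit_biexp(data.frame(b_value = b, signal = sig)))
#' @export
fit_biexp <- function(data, b_values = NULL, init = "segmented",
                      b_threshold = 250) {
  ser <- .as_series(data, b_values)
  if (length(unique(ser$b)) < 4L) {
    rlang::abort("biexponential fitting needs at least 4 distinct b values",
                 class = "ivimsim_config_error")
  }
  init_params <- if (identical(init, "segmented")) {
    segmented_init(tibble::tibble(b_value = ser$b, signal = ser$s),
                   b_threshold = b_threshold)
  } else {
    tibble::as_tibble(init)
  }
  core <- .fit_biexp_core(ser$b, ser$s, as.list(init_params[1L, ]))
  .new_dwi_fit("biexp", ser$b, ser$s, core,
               extra = list(init = init_params))
}

#' Segmented IVIM starting values
#'
#' Standard two-stage initialisation: the tissue diffusion coefficient `d` is
#' estimated by a log-linear fit over the perfusion-free high-b segment
#' (`b >= b_threshold`), the perfusion fraction from one minus the ratio of
#' the back-extrapolated high-b intercept to the measured lowest-b signal,
#' and `d_star` is seeded at a fixed multiple (10x) of `d`. All values are
#' clipped into the fitter's bounds. With fewer than two high-b points or no
#' low-b point, a documented default initialisation is returned and flagged.
#'
#' @param data Data frame with `b_value` and `signal` columns.
#' @param b_threshold Segment cut-off, s/mm^2 (default 250, the largest
#'   sub-maximal b value of the reference acquisition).
#' @return One-row tibble `si0, d, d_star, fp, fallback`.
#' @export
segmented_init <- function(data, b_threshold = 250) {
  b <- data$b_value; s <- data$signal
  hi <- b >= b_threshold & s > 0
  lo <- b < b_threshold
  s0 <- s[which.min(b)]
  if (sum(hi) < 2L || sum(lo) < 1L || s0 <= 0) {
    return(tibble::tibble(si0 = max(s, 1), d = 1e-3, d_star = 1e-2,
                          fp = 0.1, fallback = TRUE))
  }
  fit <- stats::lm.fit(cbind(1, b[hi]), log(s[hi]))
  d0 <- min(max(-fit$coefficients[[2]], 0), 5e-3)
  intercept <- exp(fit$coefficients[[1]])
  fp0 <- min(max(1 - intercept / s0, 0), 0.95)
  tibble::tibble(si0 = s0, d = d0,
                 d_star = min(max(10 * d0, 3e-3), 0.5),
                 fp = fp0, fallback = FALSE)
}

#' Goodness of fit between measured and model signals
#'
#' Returns the squared Pearson correlation between measured and fitted
#' signals (`r_squared`) and the summed squared residuals (`chi_squared`).
#' `chi_squared` is computed on signals normalised by a reference amplitude
#' (by default the measured signal at the lowest b value) so that quality
#' thresholds are scale-free. When either signal vector has zero variance the
#' correlation is undefined and `r_squared` is `NA`; downstream QC treats
#' that as a failure.
#'
#' @param observed Measured signals.
#' @param fitted Model-predicted signals.
#' @param normalise_by Reference amplitude for the residual normalisation;
#'   default the first observed value.
#' @return List with `r_squared` and `chi_squared`.
#' @export
goodness_of_fit <- function(observed, fitted, normalise_by = observed[1L]) {
  stopifnot(length(observed) == length(fitted))
  if (any(!is.finite(fitted))) {
    return(list(r_squared = NA_real_, chi_squared = NA_real_))
  }
  ref <- if (is.finite(normalise_by) && normalise_by > 0) normalise_by else 1
  chi2 <- sum(((observed - fitted) / ref)^2)
  r2 <- if (stats::sd(observed) == 0 || stats::sd(fitted) == 0) {
    NA_real_
  } else {
    stats::cor(observed, fitted)^2
  }
  list(r_squared = r2, chi_squared = chi2)
}

#' @export
print.dwi_fit <- function(x, ...) {
  cat(sprintf("<dwi_fit: %sexponential, %d points, %s>\n",
              ifelse(x$model == "mono", "mono", "bi"), x$n_points,
              ifelse(x$converged, "converged", "NOT converged")))
  print(tidy(x))
  cat(sprintf("r^2 = %.6g, chi^2 = %.6g (normalised)\n",
              x$r_squared, x$chi_squared))
  invisible(x)
}

#' Tidy a single-voxel fit
#'
#' @param x A `"dwi_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter (`term`,
#'   `estimate`), in mm^2/s for diffusivities.
#' @method tidy dwi_fit
#' @export
tidy.dwi_fit <- function(x, ...) {
  terms <- if (x$model == "mono") c("si0", "adc") else c("si0", "d", "d_star", "fp")
  tibble::tibble(term = terms,
                 estimate = vapply(terms, function(t) x[[t]], numeric(1)))
}

#' One-row fit summary
#'
#' @param x A `"dwi_fit"` object.
#' @param ... Unused.
#' @return One-row tibble: `model`, `r_squared`, `chi_squared`, `converged`,
#'   `n_points`.
#' @method glance dwi_fit
#' @export
glance.dwi_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r_squared = x$r_squared,
                 chi_squared = x$chi_squared, converged = x$converged,
                 n_points = x$n_points)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
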