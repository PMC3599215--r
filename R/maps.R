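#' Quality-control thresholds for voxel fits
#'
#' A voxel passes QC when its fit converged, its squared Pearson correlation
#' `r_squared` is at least `r2_min`, and its normalised summed squared
#' residual `chi_squared` is at most `chi2_max`. The residuals are normalised
#' by the lowest-b signal of the series, so the thresholds are independent of
#' the (arbitrary) amplitude units. The defaults are deliberately strict:
#' they retain essentially all well-specified monoexponential fits while
#' rejecting a fraction of noisy biexponential fits, mirroring the different
#' acceptance rates of the two models on clinical data.
#'
#' @param r2_min Minimum acceptable `r_squared`, in `[0, 1]`.
#' @param chi2_max Maximum acceptable normalised `chi_squared`, positive.
#' @return An object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(r2_min = 0.98, chi2_max = 0.05) {
  stopifnot(r2_min >= 0, r2_min <= 1, chi2_max > 0)
  structure(list(r2_min = r2_min, chi2_max = chi2_max),
            class = "qc_thresholds")
}

#' Apply QC thresholds to a table of voxel fits
#'
#' Adds a logical `qc_pass` column: `converged & r_squared >= r2_min &
#' chi_squared <= chi2_max`. Undefined `r_squared` (zero-variance signal)
#' fails. The attached `"qc_report"` attribute summarises the fraction of
#' voxels passing per lesion and per model (see [qc_report()]).
#'
#' @param fits Tibble of voxel fits as produced by [compute_maps()] (needs
#'   columns `converged`, `r_squared`, `chi_squared`; `lesion` and `model`
#'   are used for the report when present).
#' @param thresholds A [qc_thresholds()] object.
#' @return `fits` with a `qc_pass` column and a `"qc_report"` attribute.
#' @export
qc_filter <- function(fits, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  fits <- dplyr::mutate(
    fits,
    qc_pass = .data$converged &
      !is.na(.data$r_squared) & .data$r_squared >= thresholds$r2_min &
      !is.na(.data$chi_squared) & .data$chi_squared <= thresholds$chi2_max
  )
  if (all(c("lesion", "model") %in% names(fits))) {
    attr(fits, "qc_report") <- fits |>
      dplyr::filter(.data$lesion > 0L) |>
      dplyr::group_by(.data$lesion, .data$model) |>
      dplyr::summarise(n_voxels = dplyr::n_distinct(.data$voxel_id),
                       frac_pass = mean(.data$qc_pass), .groups = "drop")
  }
  fits
}

#' Per-lesion QC acceptance summary
#'
#' @param fits Output of [qc_filter()] (or [compute_maps()], which applies
#'   it).
#' @return Tibble with per-model mean/sd/range of the per-lesion fraction of
#'   voxels passing QC.
#' @export
qc_report <- function(fits) {
  rep <- attr(fits, "qc_report")
  if (is.null(rep)) rlang::abort("no QC report attached; run qc_filter() first")
  rep |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(n_lesions = dplyr::n_distinct(.data$lesion),
                     mean_pass = mean(.data$frac_pass),
                     sd_pass = stats::sd(.data$frac_pass),
                     min_pass = min(.data$frac_pass),
                     max_pass = max(.data$frac_pass), .groups = "drop")
}

#' Voxel-wise parameter maps for a set of b-value schemes
#'
#' Fits every requested scheme to every (by default lesion) voxel of a
#' dataset: the monoexponential model for `model = "mono"` schemes on the
#' scheme's b-value subset, and the biexponential model for `"biexp"`
#' schemes, then applies QC. This is the workhorse that turns a 4-D dataset
#' into an ADC map per combination plus one (D, D*, f_p) map set.
#'
#' @param phantom A `"dwi_phantom"` (from [generate_phantom()] or
#'   [read_dataset()]) or a long tibble with columns `voxel_id`, `lesion`,
#'   `b_value`, `signal`.
#' @param schemes Scheme tibble; default [builtin_schemes()]. A scheme that
#'   requests a b value absent from the acquisition raises a configuration
#'   error naming the scheme.
#' @param thresholds [qc_thresholds()] used for the `qc_pass` column.
#' @param init Initialisation for biexponential fits (`"segmented"` or an
#'   [ivim_params()] row).
#' @param roi_only If `TRUE` (default) only lesion voxels are fitted,
#'   mirroring ROI-based analysis; set `FALSE` to fit the full grid.
#' @return Long tibble, one row per voxel per scheme: coordinates, `lesion`,
#'   `scheme_id`, `model`, parameter estimates (`si0`, `adc` or
#'   `d`/`d_star`/`fp`), `r_squared`, `chi_squared`, `converged`, `n_points`,
#'   `qc_pass`; with the QC report attached (see [qc_report()]).
#' @examples
#' ph <- generate_phantom(phantom_spec(n_lesions = 2, noise_model = "none"))
#' maps <- compute_maps(ph, builtin_schemes()[c(1, 14), ])
#' dplyr::count(maps, scheme_id)
#' @export
compute_maps <- function(phantom, schemes = builtin_schemes(),
                         thresholds = qc_thresholds(), init = "segmented",
                         roi_only = TRUE) {
  data <- if (inherits(phantom, "dwi_phantom")) phantom$data else phantom
  stopifnot(all(c("voxel_id", "b_value", "signal") %in% names(data)))
  acquired <- sort(unique(data$b_value))
  for (i in seq_len(nrow(schemes))) {
    miss <- setdiff(schemes$b_values[[i]], acquired)
    if (length(miss)) {
      rlang::abort(sprintf(
        "scheme '%s' requests unacquired b value(s): %s",
        schemes$scheme_id[i], paste(miss, collapse = ", ")),
        class = "ivimsim_config_error")
    }
  }
  if (roi_only && "lesion" %in% names(data)) {
    data <- dplyr::filter(data, .data$lesion > 0L)
  }

  data <- dplyr::arrange(data, .data$voxel_id, .data$b_value)
  vox_info <- dplyr::distinct(
    data, dplyr::across(dplyr::any_of(c("voxel_id", "x", "y", "z", "lesion"))))
  sig <- matrix(data$signal, nrow = length(acquired),
                dimnames = list(NULL, NULL))
  b_order <- data$b_value[seq_along(acquired)]

  fits <- purrr::map(seq_len(nrow(schemes)), function(i) {
    bv <- schemes$b_values[[i]]
    rows <- match(bv, b_order)
    model <- schemes$model[i]
    per_voxel <- purrr::map(seq_len(ncol(sig)), function(j) {
      s <- sig[rows, j]
      if (model == "mono") {
        core <- .fit_mono_core(bv, s)
        est <- c(si0 = core$si0, adc = core$adc,
                 d = NA_real_, d_star = NA_real_, fp = NA_real_)
      } else {
        ip <- if (identical(init, "segmented")) {
          as.list(segmented_init(tibble::tibble(b_value = bv, signal = s))[1L, ])
        } else as.list(tibble::as_tibble(init)[1L, ])
        core <- .fit_biexp_core(bv, s, ip)
        est <- c(si0 = core$si0, adc = NA_real_,
                 d = core$d, d_star = core$d_star, fp = core$fp)
      }
      gof <- goodness_of_fit(s, core$fitted, normalise_by = s[which.min(bv)])
      c(est, r_squared = gof$r_squared, chi_squared = gof$chi_squared,
        converged = as.numeric(core$converged))
    })
    m <- do.call(rbind, per_voxel)
    dplyr::bind_cols(
      vox_info,
      tibble::tibble(scheme_id = schemes$scheme_id[i], model = model,
                     n_points = length(bv)),
      tibble::as_tibble(m)
    )
  })
  out <- dplyr::bind_rows(fits) |>
    dplyr::mutate(converged = .data$converged > 0)
  qc_filter(out, thresholds)
}
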