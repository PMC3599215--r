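#' Per-lesion ROI summaries of parameter maps
#'
#' Reduces voxel-wise maps to per-lesion descriptive statistics, using only
#' voxels that passed QC. Lesions whose QC-passing voxel count is zero for a
#' scheme/parameter are flagged `usable = FALSE` (with a warning) and are
#' excluded from cohort tests downstream. Cohort statistics operate on the
#' per-lesion medians, the standard summary for single-ROI lesion analysis.
#'
#' @param maps Output of [compute_maps()] (must contain `qc_pass`).
#' @param parameters Which parameters to summarise; default all estimated
#'   ones (`adc` for mono schemes, `d`, `d_star`, `fp` for biexp).
#' @return Tibble with one row per lesion x scheme x parameter: `lesion`,
#'   `scheme_id`, `model`, `parameter`, `median`, `mean`, `sd`, `min`, `max`,
#'   `n_voxels_used`, `usable`.
#' @export
summarize_roi <- function(maps, parameters = c("adc", "d", "d_star", "fp")) {
  stopifnot("qc_pass" %in% names(maps))
  long <- maps |>
    dplyr::filter(.data$lesion > 0L) |>
    tidyr::pivot_longer(dplyr::any_of(parameters), names_to = "parameter",
                        values_to = "value") |>
    dplyr::filter(!(.data$model == "mono" & .data$parameter != "adc"),
                  !(.data$model == "biexp" & .data$parameter == "adc"))
  out <- long |>
    dplyr::group_by(.data$lesion, .data$scheme_id, .data$model,
                    .data$parameter) |>
    dplyr::summarise(
      median = stats::median(.data$value[.data$qc_pass]),
      mean = mean(.data$value[.data$qc_pass]),
      sd = stats::sd(.data$value[.data$qc_pass]),
      min = suppressWarnings(min(.data$value[.data$qc_pass])),
      max = suppressWarnings(max(.data$value[.data$qc_pass])),
      n_voxels_used = sum(.data$qc_pass),
      .groups = "drop"
    ) |>
    dplyr::mutate(usable = .data$n_voxels_used >= 1L,
                  dplyr::across(c("median", "mean", "sd", "min", "max"),
                                ~ ifelse(.data$n_voxels_used >= 1L, .x, NA_real_)))
  if (any(!out$usable)) {
    rlang::warn(sprintf(
      "%d lesion/scheme summaries have no QC-passing voxels and are flagged unusable",
      sum(!out$usable)))
  }
  out
}

#' Percent deviation between two central values
#'
#' `100 * (a - b) / b`: the relative difference of `a` with respect to
#' reference `b`, in percent. Satisfies the reciprocal identity
#' `(1 + deviation(a, b)/100) * (1 + deviation(b, a)/100) = 1`.
#'
#' @param a Value being compared.
#' @param b Reference value; zero gives `NA` with a warning.
#' @return Percent deviation (vectorised).
#' @export
deviation <- function(a, b) {
  out <- 100 * (a - b) / b
  if (any(b == 0, na.rm = TRUE)) {
    rlang::warn("zero reference value: deviation undefined, returning NA")
    out[b == 0] <- NA_real_
  }
  out
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Signed-rank test with the conventions used throughout the package: zero
#' differences are dropped (Wilcoxon's convention); for n <= 25 the exact
#' null distribution of the statistic is used, computed by convolution of
#' the rank generating function so it stays exact under tied absolute
#' differences; above that the tie-corrected normal approximation with
#' continuity correction is used. If every paired difference is zero the
#' samples are indistinguishable and `p = 1` is returned by convention.
#'
#' @param x,y Equal-length paired samples (per-lesion medians), `n >= 5`.
#' @return Two-sided p-value.
#' @export
paired_compare <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) {
    rlang::abort("paired comparison needs at least 5 complete pairs",
                 class = "ivimsim_config_error")
  }
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  if (length(d) <= 25L) {
    .signed_rank_exact_p(d)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value
    )
  }
}

# Exact null distribution of the signed-rank statistic for the observed rank
# configuration, by convolution of the per-observation generating functions
# prod_i (1 + t^{r_i}) / 2^n. Unlike the tabulated distribution this remains
# exact under tied |differences| (ranks are doubled to stay integral).
# p is two-sided: twice the smaller tail, capped at 1.
.signed_rank_exact_p <- function(d) {
  r <- rank(abs(d))
  w <- as.integer(round(2 * r))
  tot <- sum(w)
  f <- numeric(tot + 1L)
  f[1L] <- 1
  for (wi in w) {
    g <- f
    idx <- (wi + 1L):(tot + 1L)
    g[idx] <- g[idx] + f[seq_len(tot + 1L - wi)]
    f <- g
  }
  f <- f / 2^length(w)
  v2 <- as.integer(round(2 * sum(r[d > 0])))
  p_le <- sum(f[seq_len(v2 + 1L)])
  p_ge <- sum(f[(v2 + 1L):(tot + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Spearman rank correlation with p-value
#'
#' Tie-corrected Spearman's rho with a two-sided p-value. Constant input
#' makes the correlation undefined; `rho` and `p` are then `NA`.
#'
#' @param x,y Equal-length samples (per-lesion medians), `n >= 5`.
#' @return Tibble with columns `rho` and `p_value`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5L) {
    rlang::abort("rank correlation needs at least 5 complete pairs",
                 class = "ivimsim_config_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Pairwise percent-deviation matrix with paired tests
#'
#' Builds the scheme-by-scheme comparison of a diffusion parameter: percent
#' deviations between central values together with paired signed-rank
#' p-values. Deviations can be computed from cohort medians of the
#' per-lesion medians (`method = "group_median"`, the default group-level
#' reading) or as the cohort median of per-lesion pairwise deviations
#' (`method = "per_lesion"`); the two differ at the percent level on real
#' cohorts, so both are exposed.
#'
#' @param summaries Output of [summarize_roi()].
#' @param scheme_ids Ordered scheme labels to compare. Each contributes its
#'   diffusivity parameter: `adc` for mono schemes, `d` for the biexp scheme.
#' @param method Aggregation for the deviation entries (see Description).
#' @return Object of class `"deviation_matrix"`: list with `scheme_ids`,
#'   `central` (named cohort medians), `deviations` and `p_values` (square
#'   matrices), `method`.
#' @export
deviation_matrix <- function(summaries,
                             scheme_ids = c(paste0("B", 0:5), "B0_biexp"),
                             method = c("group_median", "per_lesion")) {
  method <- match.arg(method)
  wide <- summaries |>
    dplyr::filter(.data$scheme_id %in% scheme_ids,
                  .data$parameter %in% c("adc", "d"),
                  .data$usable) |>
    dplyr::select("lesion", "scheme_id", "median") |>
    tidyr::pivot_wider(names_from = "scheme_id", values_from = "median")
  missing <- setdiff(scheme_ids, names(wide))
  if (length(missing)) {
    rlang::abort(paste0("no summaries for scheme(s): ",
                        paste(missing, collapse = ", ")),
                 class = "ivimsim_config_error")
  }
  k <- length(scheme_ids)
  central <- vapply(scheme_ids, function(id) stats::median(wide[[id]],
                                                           na.rm = TRUE),
                    numeric(1))
  dev <- matrix(0, k, k, dimnames = list(scheme_ids, scheme_ids))
  pv <- matrix(NA_real_, k, k, dimnames = list(scheme_ids, scheme_ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      dev[i, j] <- if (method == "group_median") {
        deviation(central[i], central[j])
      } else {
        stats::median(deviation(wide[[scheme_ids[i]]], wide[[scheme_ids[j]]]),
                      na.rm = TRUE)
      }
      pv[i, j] <- .safe_paired_p(wide[[scheme_ids[i]]], wide[[scheme_ids[j]]])
    }
  }
  structure(list(scheme_ids = scheme_ids, central = central,
                 deviations = dev, p_values = pv, method = method),
            class = "deviation_matrix")
}

# Cohorts can have too few usable lesions for a given scheme pair (QC can
# disqualify a lesion wholesale); report NA rather than aborting the matrix.
.safe_paired_p <- function(x, y) {
  if (sum(stats::complete.cases(x, y)) < 5L) return(NA_real_)
  paired_compare(x, y)
}

#' @export
print.deviation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("<deviation_matrix> %d schemes, method = %s\n",
              length(x$scheme_ids), x$method))
  stars <- ifelse(x$p_values < 0.001, "***",
                  ifelse(x$p_values < 0.01, "**",
                         ifelse(x$p_values < 0.05, "*", "")))
  stars[is.na(x$p_values)] <- ""
  disp <- matrix(paste0(format(round(x$deviations, 1), trim = TRUE), stars),
                 nrow = nrow(x$deviations), dimnames = dimnames(x$deviations))
  diag(disp) <- "0"
  print(disp, quote = FALSE)
  invisible(x)
}

#' @describeIn deviation_matrix Long-format tibble of the matrix entries
#'   (`scheme_a`, `scheme_b`, `deviation_pct`, `p_value`).
#' @param x A `"deviation_matrix"`.
#' @param ... Unused.
#' @method tidy deviation_matrix
#' @export
tidy.deviation_matrix <- function(x, ...) {
  tidyr::expand_grid(scheme_a = x$scheme_ids, scheme_b = x$scheme_ids) |>
    dplyr::mutate(
      deviation_pct = purrr::map2_dbl(.data$scheme_a, .data$scheme_b,
                                      ~ x$deviations[.x, .y]),
      p_value = purrr::map2_dbl(.data$scheme_a, .data$scheme_b,
                                ~ x$p_values[.x, .y])
    )
}

#' Cohort-level report tables
#'
#' Assembles the standard cohort outputs from per-lesion summaries:
#' \describe{
#'   \item{descriptives}{one row per scheme/parameter with cohort mean +/- SD,
#'     median and range of the per-lesion medians, rendered in the
#'     conventional reporting unit of 1e-3 mm^2/s for diffusivities
#'     (`unit` column).}
#'   \item{deviations}{a [deviation_matrix()] for the clinically used
#'     combinations plus the biexponential D.}
#'   \item{correlations}{Spearman correlation of the biexp D with each mono
#'     ADC in the matrix.}
#'   \item{qc}{per-model QC acceptance rates when `maps` is supplied.}
#' }
#'
#' @param summaries Output of [summarize_roi()].
#' @param scheme_ids Schemes entering the deviation matrix and correlation
#'   row.
#' @param maps Optional [compute_maps()] output used for the QC section.
#' @param method Deviation aggregation, see [deviation_matrix()].
#' @return Object of class `"cohort_report"` (list of the tables above).
#' @export
cohort_report <- function(summaries,
                          scheme_ids = c(paste0("B", 0:5), "B0_biexp"),
                          maps = NULL,
                          method = "group_median") {
  usable <- dplyr::filter(summaries, .data$usable)
  if (dplyr::n_distinct(usable$lesion) < 2L) {
    rlang::abort("cohort report needs at least 2 usable lesions",
                 class = "ivimsim_config_error")
  }
  scale3 <- function(p, v) ifelse(p %in% c("adc", "d", "d_star"), v * 1e3, v)
  descriptives <- usable |>
    dplyr::group_by(.data$scheme_id, .data$model, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$median), sd = stats::sd(.data$median),
                     min = min(.data$median), max = max(.data$median),
                     # assigned last: overwrites the column it aggregates
                     median = stats::median(.data$median),
                     n_lesions = dplyr::n(), .groups = "drop") |>
    dplyr::relocate("median", .after = "sd") |>
    dplyr::mutate(
      dplyr::across(c("mean", "sd", "median", "min", "max"),
                    ~ scale3(.data$parameter, .x)),
      unit = ifelse(.data$parameter %in% c("adc", "d", "d_star"),
                    "x10^-3 mm^2/s", "dimensionless")
    ) |>
    dplyr::arrange(match(.data$scheme_id,
                         c(paste0("B", 0:12), "B0_biexp")),
                   .data$parameter)

  devs <- NULL
  correlations <- NULL
  present <- intersect(scheme_ids, unique(usable$scheme_id))
  if (length(present) >= 2L) {
    devs <- deviation_matrix(summaries, present, method = method)
    ref <- grep("biexp", present, value = TRUE)
    if (length(ref) == 1L) {
      wide <- usable |>
        dplyr::filter(.data$scheme_id %in% present,
                      .data$parameter %in% c("adc", "d")) |>
        dplyr::select("lesion", "scheme_id", "median") |>
        tidyr::pivot_wider(names_from = "scheme_id", values_from = "median")
      correlations <- purrr::map_dfr(setdiff(present, ref), function(id) {
        rc <- if (sum(stats::complete.cases(wide[[ref]], wide[[id]])) < 5L) {
          tibble::tibble(rho = NA_real_, p_value = NA_real_)
        } else {
          rank_correlation(wide[[ref]], wide[[id]])
        }
        dplyr::bind_cols(tibble::tibble(scheme_id = id), rc)
      })
    }
  }
  qc <- if (!is.null(maps)) qc_report(maps) else NULL
  structure(list(descriptives = descriptives, deviations = devs,
                 correlations = correlations, qc = qc),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("== Cohort descriptives (per-lesion medians) ==\n")
  print(x$descriptives, n = Inf)
  if (!is.null(x$deviations)) {
    cat("\n== Deviation matrix [%] (row vs column) ==\n")
    print(x$deviations)
  }
  if (!is.null(x$correlations)) {
    cat("\n== Spearman correlation of biexp D with mono ADCs ==\n")
    print(x$correlations)
  }
  if (!is.null(x$qc)) {
    cat("\n== QC acceptance (fraction of ROI voxels) ==\n")
    print(x$qc)
  }
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits `descriptives.csv`, `deviations.csv`, `p_values.csv`,
#' `correlations.csv`, `qc.csv` (as applicable) plus a machine-readable
#' `report.json` bundling every table.
#'
#' @param report A [cohort_report()].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$descriptives, file.path(path, "descriptives.csv"),
                   row.names = FALSE)
  json <- list(descriptives = report$descriptives)
  if (!is.null(report$deviations)) {
    utils::write.csv(report$deviations$deviations,
                     file.path(path, "deviations.csv"))
    utils::write.csv(report$deviations$p_values,
                     file.path(path, "p_values.csv"))
    json$deviations <- tidy(report$deviations)
    json$central_medians <- as.list(report$deviations$central)
  }
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations, file.path(path, "correlations.csv"),
                     row.names = FALSE)
    json$correlations <- report$correlations
  }
  if (!is.null(report$qc)) {
    utils::write.csv(report$qc, file.path(path, "qc.csv"), row.names = FALSE)
    json$qc <- report$qc
  }
  jsonlite::write_json(json, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
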