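#' Construct a b-value scheme
#'
#' A scheme is one combination of diffusion weightings together with the decay
#' model it is fitted with. Monoexponential schemes need at least two b values,
#' biexponential schemes at least four distinct ones; b values must be
#' non-negative and strictly increasing.
#'
#' @param scheme_id Short label, e.g. `"B0"`, `"B7"`, `"B0_biexp"`.
#' @param b_values Strictly increasing numeric vector of b values, s/mm^2.
#' @param model `"mono"` or `"biexp"`.
#' @param clinical Logical; whether the combination is flagged as clinically
#'   used (schemes B0-B5 of the built-in registry).
#' @return One-row tibble with columns `scheme_id`, `model`, `clinical` and a
#'   list-column `b_values`.
#' @examples
#' bvalue_scheme("B6", c(250, 800))
#' @export
bvalue_scheme <- function(scheme_id, b_values, model = c("mono", "biexp"),
                          clinical = FALSE) {
  model <- match.arg(model)
  b_values <- as.numeric(b_values)
  if (any(b_values < 0)) rlang::abort("b values must be non-negative")
  if (is.unsorted(b_values, strictly = TRUE)) {
    rlang::abort("b values must be strictly increasing")
  }
  min_n <- if (model == "mono") 2L else 4L
  if (length(b_values) < min_n) {
    rlang::abort(sprintf("a %s scheme needs at least %d b values", model, min_n))
  }
  tibble::tibble(
    scheme_id = as.character(scheme_id),
    model = model,
    clinical = isTRUE(clinical),
    b_values = list(b_values)
  )
}

#' Built-in b-value scheme registry
#'
#' The thirteen monoexponential b-value combinations B0-B12 plus the
#' biexponential scheme B0_biexp that uses the full acquisition
#' (b = 0, 50, 100, 250, 800 s/mm^2). B0-B5 carry the clinical-relevance
#' annotation: they are the combinations in current clinical use.
#'
#' @return Tibble with one row per scheme (14 rows): `scheme_id`, `model`,
#'   `clinical`, list-column `b_values`.
#' @examples
#' builtin_schemes()
#' @export
builtin_schemes <- function() {
  defs <- list(
    B0  = c(0, 50, 100, 250, 800),
    B1  = c(0, 800),
    B2  = c(50, 800),
    B3  = c(50, 100, 250, 800),
    B4  = c(100, 250, 800),
    B5  = c(100, 800),
    B6  = c(250, 800),
    B7  = c(0, 50),
    B8  = c(0, 100),
    B9  = c(0, 250),
    B10 = c(50, 100),
    B11 = c(50, 250),
    B12 = c(100, 250)
  )
  mono <- purrr::imap(defs, function(b, id) {
    bvalue_scheme(id, b, "mono", clinical = id %in% paste0("B", 0:5))
  })
  dplyr::bind_rows(c(mono, list(
    bvalue_scheme("B0_biexp", c(0, 50, 100, 250, 800), "biexp")
  )))
}

#' Look up the b values of a scheme
#'
#' @param schemes Scheme tibble as returned by [builtin_schemes()].
#' @param scheme_id Single scheme label.
#' @return Numeric vector of b values.
#' @export
scheme_bvalues <- function(schemes, scheme_id) {
  row <- schemes[schemes$scheme_id == scheme_id, ]
  if (nrow(row) != 1L) {
    rlang::abort(sprintf("scheme '%s' not found in registry", scheme_id),
                 class = "ivimsim_config_error")
  }
  row$b_values[[1L]]
}
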