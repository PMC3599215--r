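#' Write a phantom dataset to disk
#'
#' Serialises a [generate_phantom()] result in a conventional diffusion-MRI
#' layout: a 4-D NIfTI signal volume (`signal.nii`), an FSL-style
#' whitespace-separated `signal.bval` sidecar, one 3-D NIfTI mask per lesion
#' (`mask_lesionNN.nii`), per-parameter ground-truth NIfTI maps
#' (`truth_<param>.nii`) and a `meta.json` provenance file (grid shape,
#' b values, noise settings, seed). Real datasets stored in the same layout
#' can be read back with [read_dataset()] and enter the pipeline at the
#' fitting stage.
#'
#' @param phantom A `"dwi_phantom"` object.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(phantom, path) {
  stopifnot(inherits(phantom, "dwi_phantom"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  gs <- phantom$grid_shape
  nb <- length(phantom$b_values)

  sig <- array(0, dim = c(gs, nb))
  dat <- dplyr::arrange(phantom$data, .data$b_value, .data$voxel_id)
  # voxel_id enumerates the grid in x-fastest order, matching NIfTI layout
  sig[] <- dat$signal
  RNifti::writeNifti(RNifti::asNifti(sig), file.path(path, "signal.nii"))

  writeLines(paste(format(phantom$b_values, trim = TRUE), collapse = " "),
             file.path(path, "signal.bval"))

  tr <- dplyr::arrange(phantom$truth, .data$voxel_id)
  for (i in seq_len(max(tr$lesion))) {
    m <- array(as.integer(tr$lesion == i), dim = gs)
    RNifti::writeNifti(RNifti::asNifti(m),
                       file.path(path, sprintf("mask_lesion%02d.nii", i)))
  }
  for (p in c("si0", "d", "d_star", "fp")) {
    RNifti::writeNifti(RNifti::asNifti(array(tr[[p]], dim = gs)),
                       file.path(path, sprintf("truth_%s.nii", p)))
  }
  meta <- list(grid_shape = gs, b_values = phantom$b_values,
               n_lesions = max(tr$lesion), seed = phantom$seed,
               noise_model = phantom$spec$noise_model,
               snr = phantom$spec$snr, si0 = phantom$spec$si0,
               software = paste0("ivimsim ",
                                 as.character(utils::packageVersion("ivimsim"))))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a phantom-layout dataset from disk
#'
#' Inverse of [write_dataset()]. The signal volume, b-value table, lesion
#' masks and (if present) ground-truth maps are reassembled into a
#' `"dwi_phantom"` object. A b-value table whose length does not match the
#' fourth signal dimension raises a parse error naming the offending
#' component.
#'
#' @param path Directory written by [write_dataset()] (or a real dataset in
#'   the same layout).
#' @return A `"dwi_phantom"` object; `truth` is `NULL` when no truth maps are
#'   stored.
#' @export
read_dataset <- function(path) {
  need <- file.path(path, c("signal.nii", "signal.bval"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    rlang::abort(paste0("dataset component missing: ",
                        paste(basename(missing), collapse = ", ")),
                 class = "ivimsim_parse_error")
  }
  sig <- as.array(RNifti::readNifti(file.path(path, "signal.nii")))
  bvals <- scan(file.path(path, "signal.bval"), what = numeric(),
                quiet = TRUE)
  if (length(dim(sig)) != 4L) {
    rlang::abort("signal.nii: expected a 4-D volume",
                 class = "ivimsim_parse_error")
  }
  if (dim(sig)[4] != length(bvals)) {
    rlang::abort(sprintf(
      "signal.bval: %d b values but signal.nii has %d volumes",
      length(bvals), dim(sig)[4]), class = "ivimsim_parse_error")
  }
  gs <- dim(sig)[1:3]
  n_vox <- prod(gs)

  mask_files <- sort(list.files(path, pattern = "^mask_lesion\\d+\\.nii$",
                                full.names = TRUE))
  lesion <- rep(0L, n_vox)
  for (i in seq_along(mask_files)) {
    m <- as.array(RNifti::readNifti(mask_files[i]))
    if (!identical(dim(m)[1:3], as.integer(gs))) {
      rlang::abort(sprintf("%s: mask grid does not match signal grid",
                           basename(mask_files[i])),
                   class = "ivimsim_parse_error")
    }
    lesion[as.vector(m) > 0] <- i
  }

  coords <- tidyr::crossing(z = seq_len(gs[3]), y = seq_len(gs[2]),
                            x = seq_len(gs[1])) |>
    dplyr::arrange(.data$z, .data$y, .data$x) |>
    dplyr::mutate(voxel_id = dplyr::row_number(), lesion = lesion) |>
    dplyr::select("voxel_id", "x", "y", "z", "lesion")

  data <- tidyr::crossing(coords, b_value = bvals) |>
    dplyr::arrange(.data$b_value, .data$voxel_id) |>
    dplyr::mutate(signal = as.vector(sig)) |>
    dplyr::arrange(.data$voxel_id, .data$b_value)

  truth <- NULL
  truth_files <- file.path(path, sprintf("truth_%s.nii",
                                         c("si0", "d", "d_star", "fp")))
  if (all(file.exists(truth_files))) {
    truth <- coords
    for (p in c("si0", "d", "d_star", "fp")) {
      truth[[p]] <- as.vector(as.array(
        RNifti::readNifti(file.path(path, sprintf("truth_%s.nii", p)))))
    }
  }

  meta <- list(seed = NA_integer_)
  meta_file <- file.path(path, "meta.json")
  if (file.exists(meta_file)) meta <- jsonlite::read_json(meta_file)

  structure(
    list(data = data, truth = truth, b_values = bvals,
         grid_shape = as.integer(gs),
         seed = if (!is.null(meta$seed)) as.integer(meta$seed) else NA_integer_,
         spec = meta),
    class = "dwi_phantom"
  )
}
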