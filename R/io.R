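#' Write / read an isotopologue spectra table
#'
#' Tab-separated, columns `metabolite`, `n_carbons`, `condition`,
#' `replicate`, `m0` ... `mN` (intensity columns beyond a metabolite's
#' carbon count are empty).
#'
#' @param spectra wide spectra tibble (see [gen_isotopologue_dataset()]).
#' @param path file path.
#' @return `path` (write) / the spectra tibble (read), invisibly for write.
#' @export
write_spectra_tsv <- function(spectra, path) {
  readr::write_tsv(spectra, path)
  invisible(path)
}

#' @rdname write_spectra_tsv
#' @export
read_spectra_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write / read an ICP-MS run table
#'
#' Comma-separated, columns `sample`, `role` (standard/sample), `type`,
#' `nominal_ppb`, `pt194`, `pt195`, `pt196`, `ir193`.
#'
#' @param run run tibble (see [gen_calibration_run()]).
#' @param path file path.
#' @return `path` / the run tibble.
#' @export
write_calibration_csv <- function(run, path) {
  readr::write_csv(run, path)
  invisible(path)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a two-channel field as a multi-page TIFF
#'
#' Page order is DAPI then the damage channel. Intensities are stored as
#' 16-bit grayscale with a fixed full scale of 65535 arbitrary units, so
#' values round-trip to within 1 a.u.
#'
#' @param field a `nuclei_field` (or list with `dapi` and `gh2ax` matrices).
#' @param path file path.
#' @return `path` / list with `dapi` and `gh2ax` matrices.
#' @export
write_field_tiff <- function(field, path) {
  pages <- lapply(list(field$dapi, field$gh2ax),
                  function(x) pmin(x / 65535, 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) abort("expected a 2-page TIFF (DAPI, damage).")
  list(dapi = pages[[1]] * 65535, gh2ax = pages[[2]] * 65535)
}

#' Write / read a ground-truth sidecar as JSON
#'
#' @param truth list or tibble of ground-truth values.
#' @param path file path.
#' @return `path` / the parsed object.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
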