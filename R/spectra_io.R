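#' Read a wide-format spectra CSV
#'
#' The interchange format is a wide CSV: first column `sample_id`, remaining
#' column headers the band wavelengths in nm, one row per sample. This is the
#' shape in which field spectrometer exports (e.g. ASD post-processing
#' software) typically circulate.
#'
#' @param path path to the CSV file.
#' @param expected_grid optional numeric vector; when given, the file's
#'   wavelength grid must match it exactly.
#' @return a [spectra_set()].
#' @export
read_spectra <- function(path, expected_grid = NULL) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("spectra CSV needs a sample_id column plus bands")
  wl <- suppressWarnings(as.numeric(names(dt)[-1]))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header(s): ",
         paste(names(dt)[-1][is.na(wl)], collapse = ", "))
  }
  check_uniform_grid(wl)
  if (!is.null(expected_grid) &&
      !isTRUE(all.equal(wl, as.numeric(expected_grid)))) {
    stop("wavelength grid does not match expected_grid")
  }
  ids <- dt[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicated sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(dt[, -1, with = FALSE], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric reflectance in column '%s'", names(dt)[bad + 1]))
  }
  if (anyNA(mat) || !all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite reflectance at row %d, column %g nm",
                 bad[1], wl[bad[2]]))
  }
  spectra_set(mat, wl, ids)
}

#' Write a spectra set to wide CSV
#'
#' Values are written with enough digits to round-trip exactly
#' ([read_spectra()] recovers a bit-identical matrix).
#'
#' @param spectra a [spectra_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  # 17 significant digits guarantee an exact double round-trip
  chr <- matrix(sprintf("%.17g", spectra$reflectance),
                nrow = nrow(spectra$reflectance),
                ncol = ncol(spectra$reflectance))
  dt <- data.table::as.data.table(chr)
  data.table::setnames(dt, as.character(spectra$wavelengths))
  dt <- cbind(data.table::data.table(sample_id = spectra$sample_ids), dt)
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Read a label table CSV
#'
#' Expected columns: `sample_id`, `lcc_area` (mg/dm^2), `lcc_weight` (mg/g);
#' optional `d663`, `d645` (absorbance), `fresh_weight` (g), `leaf_area`
#' (dm^2).
#'
#' @param path path to the CSV file.
#' @return a data.frame with one row per sample.
#' @export
read_labels <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if (!"sample_id" %in% names(df)) stop("label table needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample_id in label table")
  }
  for (col in c("lcc_area", "lcc_weight")) {
    if (col %in% names(df) && any(df[[col]] <= 0, na.rm = TRUE)) {
      stop(col, " must be positive")
    }
  }
  df
}

#' Write a label table CSV
#' @param labels data.frame with a `sample_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  data.table::fwrite(data.table::as.data.table(labels), path)
  invisible(path)
}

#' Align spectra with a label table
#'
#' Inner join on `sample_id`, preserving the spectra's sample order. Samples
#' present on only one side are dropped and reported.
#'
#' @param spectra a [spectra_set()].
#' @param labels data.frame with a `sample_id` column.
#' @return list with `spectra` (subset, original order), `labels` (rows
#'   reordered to match), and `dropped` (character vector of ids found on
#'   only one side).
#' @export
align_spectra_labels <- function(spectra, labels) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!"sample_id" %in% names(labels)) stop("labels need a sample_id column")
  ids <- as.character(labels$sample_id)
  keep <- spectra$sample_ids %in% ids
  if (!any(keep)) {
    stop("alignment error: no sample_id shared between spectra and labels")
  }
  dropped <- c(setdiff(spectra$sample_ids, ids), setdiff(ids, spectra$sample_ids))
  kept_ids <- spectra$sample_ids[keep]
  out_spec <- spectra_set(spectra$reflectance[keep, , drop = FALSE],
                          spectra$wavelengths, kept_ids)
  out_lab <- labels[match(kept_ids, ids), , drop = FALSE]
  rownames(out_lab) <- NULL
  list(spectra = out_spec, labels = out_lab, dropped = dropped)
}
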