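#' Localization tables ("coordinate matrices")
#'
#' A localization set is the tabular product of localization microscopy: one
#' row per detected fluorophore, with its position, photon count, signal
#' widths, localization precisions and acquisition metadata. It is the
#' interchange format between every stage of the pipeline (rendering,
#' clustering, shell profiling, dosimetry).
#'
#' Required columns: `frame` (integer >= 0), `channel` (character),
#' `x_nm`, `y_nm` (position in nm), `photons` (> 0), `sigma_x_nm`,
#' `sigma_y_nm` (>= 0), `precision_x_nm`, `precision_y_nm` (> 0),
#' `background` (counts/pixel, >= 0).
#'
#' @param frame integer vector of acquisition frame indices (>= 0).
#' @param channel character vector of channel labels.
#' @param x_nm,y_nm numeric positions in nm.
#' @param photons photon sums Q (> 0).
#' @param sigma_x_nm,sigma_y_nm signal standard deviations in nm (>= 0).
#' @param precision_x_nm,precision_y_nm localization precisions in nm (> 0).
#' @param background per-frame background level in counts/pixel.
#' @return A tibble with the localization-table schema.
#' @export
localization_set <- function(frame = integer(), channel = character(),
                             x_nm = numeric(), y_nm = numeric(),
                             photons = numeric(),
                             sigma_x_nm = numeric(), sigma_y_nm = numeric(),
                             precision_x_nm = numeric(),
                             precision_y_nm = numeric(),
                             background = numeric()) {
  out <- tibble::tibble(
    frame = as.integer(frame), channel = as.character(channel),
    x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
    photons = as.numeric(photons),
    sigma_x_nm = as.numeric(sigma_x_nm), sigma_y_nm = as.numeric(sigma_y_nm),
    precision_x_nm = as.numeric(precision_x_nm),
    precision_y_nm = as.numeric(precision_y_nm),
    background = as.numeric(background)
  )
  validate_localization_set(out)
}

loc_columns <- c("frame", "channel", "x_nm", "y_nm", "photons",
                 "sigma_x_nm", "sigma_y_nm", "precision_x_nm",
                 "precision_y_nm", "background")

#' Validate a localization table
#'
#' Checks the schema and row invariants of a localization table and returns
#' it unchanged. `source_line_offset` shifts reported row numbers so file
#' readers can point at physical file lines (header = line 1).
#'
#' @param points a data frame with the localization-table columns.
#' @param source_line_offset added to row indices in error messages.
#' @return `points`, invisibly unchanged, as a tibble.
#' @export
validate_localization_set <- function(points, source_line_offset = 0L) {
  missing <- setdiff(loc_columns, names(points))
  cl_assert(length(missing) == 0L,
            "localization table is missing mandatory column(s): ",
            paste(missing, collapse = ", "))
  bad <- which(!is.finite(points$x_nm) | !is.finite(points$y_nm) |
                 !(points$photons > 0) |
                 points$sigma_x_nm < 0 | points$sigma_y_nm < 0 |
                 !(points$precision_x_nm > 0) | !(points$precision_y_nm > 0) |
                 points$background < 0 | points$frame < 0)
  if (length(bad) > 0L) {
    cl_stop("invalid localization record(s) at line(s) ",
            paste(utils::head(bad + source_line_offset, 10L), collapse = ", "),
            " (need finite positions, photons > 0, sigma >= 0, precision > 0)")
  }
  tibble::as_tibble(points)
}

#' Read a localization table from TSV
#'
#' Reads the tab-separated interchange format written by
#' [write_localization_table()]. Positions are in nm. Malformed rows are
#' rejected with their file line numbers; a file holding only the header is
#' an empty, valid set.
#'
#' @param path path to a TSV file with the localization-table header.
#' @return A localization-table tibble.
#' @export
read_localization_table <- function(path) {
  cl_assert(file.exists(path), "no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  # header occupies file line 1, so data row i is physical line i + 1
  validate_localization_set(df, source_line_offset = 1L)
}

#' Write a localization table to TSV
#'
#' @param points a valid localization table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(points, path) {
  points <- validate_localization_set(points)
  utils::write.table(points[loc_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
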