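#' Standard file-format readers and writers
#'
#' FASTA via Biostrings, BED as 0-based half-open tab-separated tables, and
#' multi-frame grayscale TIFF stacks of raw camera counts.
#'
#' @name formats
NULL

#' Read a FASTA file
#'
#' Headers are truncated at the first whitespace. With
#' `mask_lowercase = TRUE`, soft-masked (lowercase) bases are converted to
#' N before uppercasing, so they can never match a probe; by default
#' lowercase matches like uppercase (masking is annotation, not absence).
#'
#' @param path FASTA path.
#' @param mask_lowercase convert soft-masked bases to N (default FALSE).
#' @return a `Biostrings::DNAStringSet`.
#' @export
read_fasta <- function(path, mask_lowercase = FALSE) {
  cl_assert(file.exists(path), "no such file: ", path)
  if (mask_lowercase) {
    raw <- Biostrings::readBStringSet(path)
    seqs <- chartr("acgtn", "NNNNN", as.character(raw))
    out <- Biostrings::DNAStringSet(seqs)
  } else {
    out <- Biostrings::readDNAStringSet(path)
  }
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a `DNAStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(as_dna_set(seqs), path)
  invisible(path)
}

bed_columns <- c("chrom", "start", "end", "name", "score", "strand")

#' Read a BED file (4-6 columns tolerated)
#'
#' Coordinates stay 0-based half-open. Intervals with `start >= end` are an
#' error. Track/browser header lines are skipped.
#'
#' @param path BED path.
#' @return tibble with `chrom`, `start`, `end` and any of `name`, `score`,
#'   `strand` present in the file, sorted by chromosome and start.
#' @export
read_bed <- function(path) {
  cl_assert(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character()))
  }
  df <- utils::read.table(text = lines, sep = "", header = FALSE,
                          stringsAsFactors = FALSE)
  cl_assert(ncol(df) >= 3L, "BED needs at least chrom, start, end")
  names(df) <- bed_columns[seq_len(min(ncol(df), 6L))]
  cl_assert(all(df$start < df$end), "BED interval with start >= end")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  tibble::as_tibble(df)
}

#' Write intervals as BED
#'
#' Writes the columns among chrom/start/end/name/score/strand that are
#' present; round-trips with [read_bed()] on valid sets.
#'
#' @param intervals data frame with at least `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cl_assert(all(c("chrom", "start", "end") %in% names(intervals)),
            "intervals need chrom, start, end")
  cl_assert(all(intervals$start < intervals$end),
            "BED interval with start >= end")
  cols <- intersect(bed_columns, names(intervals))
  utils::write.table(intervals[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a multi-frame grayscale TIFF stack
#'
#' Returns raw integer counts (no intensity rescaling). Colour TIFFs are
#' rejected.
#'
#' @param path TIFF path.
#' @return list of numeric matrices, one per frame.
#' @export
read_stack <- function(path) {
  cl_assert(file.exists(path), "no such file: ", path)
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  bad <- vapply(frames, function(f) length(dim(f)) != 2L, logical(1))
  cl_assert(!any(bad), "stack must be grayscale (one sample per pixel)")
  frames
}

#' Write a list of frames as a 16-bit grayscale TIFF stack
#'
#' Counts are clamped to the unsigned 16-bit range.
#'
#' @param frames list of numeric matrices of counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  cl_assert(is.list(frames) && length(frames) > 0, "frames must be a non-empty list")
  scaled <- lapply(frames, function(f) pmin(pmax(round(f), 0), 65535L) / 65535)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}
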