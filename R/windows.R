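#' Methylation window identifiers
#'
#' Windows are fixed-size, 0-based, half-open genomic bins `[start, start + size)`
#' labelled `"chrom_start"`, e.g. `"chrZ_30195000"`. `window_id()` builds ids
#' from coordinates and `parse_window_id()` inverts it.
#'
#' @param chrom Chromosome name(s).
#' @param start Window start(s) in bp (0-based).
#' @return `window_id()` a character vector; `parse_window_id()` a tibble with
#'   columns `window_id`, `chrom`, `start`.
#' @export
#' @examples
#' window_id("chrZ", 30195000)
#' parse_window_id("chrZ_30195000")
window_id <- function(chrom, start) {
  stopifnot(all(start >= 0))
  paste0(chrom, "_", format(start, scientific = FALSE, trim = TRUE))
}

#' @rdname window_id
#' @param id Window id(s) of the form `"chrom_start"`.
#' @export
parse_window_id <- function(id) {
  pos <- regexpr("_[0-9]+$", id)
  if (any(pos < 0)) {
    stop("malformed window id: ", paste(id[pos < 0], collapse = ", "))
  }
  tibble::tibble(
    window_id = id,
    chrom = substr(id, 1L, pos - 1L),
    start = as.numeric(substring(id, pos + 1L))
  )
}

#' Bin read positions into fixed-size windows
#'
#' Tallies, per individual, the reads whose mapped position falls in each
#' half-open window `[start, start + window_size)`. All windows of each
#' chromosome are retained, including windows in which no individual has a
#' read, so that matrices from different runs align.
#'
#' @param reads A data frame with columns `id` (individual), `chrom`, `pos`
#'   (bp, 0-based, non-negative).
#' @param window_size Window size in bp (default 1000).
#' @param chrom_sizes Optional named numeric vector of chromosome sizes in bp;
#'   when given, windows tile `[0, size)` per chromosome and reads beyond a
#'   chromosome end are an error. Otherwise windows run to the furthest read.
#' @return A wide tibble with columns `window_id`, `chrom`, `start`, then one
#'   count column per individual, sorted by `(chrom, start)`.
#' @export
bin_reads <- function(reads, window_size = 1000, chrom_sizes = NULL) {
  stopifnot(is.data.frame(reads), all(c("id", "chrom", "pos") %in% names(reads)))
  if (window_size <= 0) stop("window_size must be positive")
  if (any(reads$pos < 0)) stop("negative read coordinate")
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(reads$chrom), names(chrom_sizes))
    if (length(unknown)) stop("unknown chromosome: ", paste(unknown, collapse = ", "))
    if (any(reads$pos >= chrom_sizes[reads$chrom])) stop("read beyond chromosome end")
    sizes <- chrom_sizes
  } else {
    sizes <- tapply(reads$pos, reads$chrom, max) + 1
  }
  ids <- sort(unique(reads$id))
  grid <- dplyr::bind_rows(lapply(names(sizes), function(ch) {
    starts <- seq(0, max(0, sizes[[ch]] - 1), by = window_size)
    tibble::tibble(chrom = ch, start = starts)
  }))
  grid <- dplyr::arrange(grid, .data$chrom, .data$start)
  grid$window_id <- window_id(grid$chrom, grid$start)

  counts <- matrix(0L, nrow(grid), length(ids), dimnames = list(grid$window_id, ids))
  key <- window_id(reads$chrom, (reads$pos %/% window_size) * window_size)
  tab <- table(key, reads$id)
  counts[rownames(tab), colnames(tab)] <- counts[rownames(tab), colnames(tab)] + as.matrix(tab)

  dplyr::bind_cols(grid[, c("window_id", "chrom", "start")], tibble::as_tibble(counts))
}

#' Normalize window read counts by per-individual library size
#'
#' Each individual's window counts are divided by that individual's total read
#' count and multiplied by a common scale constant, yielding library-size-free
#' methylation levels. Raw totals are kept as an attribute so the raw counts
#' can be recovered exactly with [denormalize_methylation()].
#'
#' @param counts Wide count tibble as produced by [bin_reads()] (columns
#'   `window_id`, `chrom`, `start`, then one column per individual).
#' @param scale Scale constant applied after division (default `1e6`,
#'   counts-per-million-like). Thresholds quoted elsewhere in the package are
#'   on whatever scale was used here.
#' @return A tibble of the same shape with normalized values; attributes
#'   `totals` (named per-individual raw totals), `scale`, and
#'   `integer_counts` (whether the input counts were integral).
#' @export
normalize_methylation <- function(counts, scale = 1e6) {
  vals <- as_value_matrix(counts)
  totals <- colSums(vals)
  if (any(totals <= 0)) {
    stop("degenerate library: individual(s) with zero total reads: ",
         paste(names(totals)[totals <= 0], collapse = ", "))
  }
  norm <- sweep(vals, 2, totals, "/") * scale
  out <- dplyr::bind_cols(
    counts[, intersect(c("window_id", "chrom", "start"), names(counts))],
    tibble::as_tibble(norm)
  )
  attr(out, "totals") <- totals
  attr(out, "scale") <- scale
  attr(out, "integer_counts") <- all(vals == round(vals))
  out
}

#' @rdname normalize_methylation
#' @param values A normalized matrix produced by [normalize_methylation()].
#' @export
denormalize_methylation <- function(values) {
  totals <- attr(values, "totals")
  scale <- attr(values, "scale")
  if (is.null(totals) || is.null(scale)) {
    stop("input does not carry normalization attributes (totals, scale)")
  }
  vals <- as_value_matrix(values)
  raw <- sweep(vals, 2, totals, "*") / scale
  if (isTRUE(attr(values, "integer_counts"))) raw <- round(raw)
  out <- dplyr::bind_cols(
    values[, intersect(c("window_id", "chrom", "start"), names(values))],
    tibble::as_tibble(raw)
  )
  out
}

#' Read and write wide phenotype matrices and sample sheets
#'
#' Matrices are TSV files whose first column is the row id (`window_id` or
#' `probeset`) followed by one column per individual. The sample sheet is a
#' TSV with columns `id`, `sex` (`male`/`female`), `batch`.
#'
#' @param path File path.
#' @param x Tibble to write.
#' @param id_col Name of the row-id column (`"window_id"` or `"probeset"`).
#' @return Readers return tibbles; for `read_meth_matrix` the `chrom`/`start`
#'   columns are reconstructed from the window ids.
#' @name matrix_io
NULL

#' @rdname matrix_io
#' @export
read_meth_matrix <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[1] <- "window_id"
  coords <- parse_window_id(x$window_id)
  out <- dplyr::bind_cols(coords, x[, -1, drop = FALSE])
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' @rdname matrix_io
#' @export
write_matrix_tsv <- function(x, path, id_col = "window_id") {
  keep <- c(id_col, value_cols(x))
  readr::write_tsv(x[, keep], path)
  invisible(path)
}

#' @rdname matrix_io
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("id", "sex", "batch") %in% names(x)))
  if (!all(x$sex %in% c("male", "female"))) stop("sex must be 'male' or 'female'")
  x
}

#' @rdname matrix_io
#' @export
write_sample_sheet <- function(x, path) {
  readr::write_tsv(x[, c("id", "sex", "batch")], path)
  invisible(path)
}

#' Export windows as BED3
#'
#' @param x A tibble with `chrom` and `start` columns (window starts).
#' @param window_size Window size in bp.
#' @return A tibble with `chrom`, `start`, `end` (half-open), sorted and
#'   deduplicated.
#' @export
windows_as_bed <- function(x, window_size = 1000) {
  out <- dplyr::distinct(dplyr::arrange(
    tibble::tibble(chrom = x$chrom, start = x$start, end = x$start + window_size),
    .data$chrom, .data$start
  ))
  out
}
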