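# Image containers, TIFF input, ROI extraction and tidy metric output.
#
# Coordinate convention used throughout the package: (row, col), 0-based
# origins, half-open ranges. Pixel size comes from configuration, never from
# TIFF metadata.

#' Single-channel intensity image with physical pixel size
#'
#' The basic unit of ICS analysis: a rectangular grid of non-negative
#' intensities plus the physical pixel size. `origin_px` records where a
#' region of interest sits inside its source image, as a 0-based
#' `(row, col)` pair.
#'
#' @param values Numeric matrix of finite, non-negative intensities.
#' @param pixel_size_nm Positive scalar, physical size of one pixel in nm.
#' @param channel_label Character label for the detection channel.
#' @param origin_px Integer `(row, col)` of the grid's top-left corner within
#'   its source image (0-based). `c(0, 0)` for a full image.
#' @return An object of class `pixel_grid`.
#' @export
pixel_grid <- function(values, pixel_size_nm, channel_label = "ch0",
                       origin_px = c(0L, 0L)) {
  if (!is.matrix(values) || length(values) == 0L)
    stop("`values` must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  if (any(values < 0))
    stop("`values` must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive scalar", call. = FALSE)
  structure(
    list(values = values, pixel_size_nm = pixel_size_nm,
         channel_label = as.character(channel_label),
         origin_px = as.integer(origin_px)),
    class = "pixel_grid"
  )
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d px, %.3g nm/px, channel '%s'\n",
              nrow(x$values), ncol(x$values), x$pixel_size_nm,
              x$channel_label))
  cat(sprintf("  intensity range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
dim.pixel_grid <- function(x) dim(x$values)

#' Read a grayscale TIFF as a list of pixel grids
#'
#' Reads a single- or multi-page 8/16-bit grayscale TIFF. Each page becomes
#' one [pixel_grid()] with channel labels `"ch0"`, `"ch1"`, ... in page
#' order. Integer sample values are preserved losslessly. Multi-sample (RGB)
#' or floating-point pages are rejected unless `allow_float = TRUE`, because
#' quantitative fluctuation analysis assumes raw single-channel counts.
#'
#' @param path Path to the TIFF file.
#' @param pixel_size_nm Physical pixel size in nm (from acquisition
#'   configuration; TIFF metadata is not consulted).
#' @param allow_float Accept floating-point grayscale pages.
#' @return List of `pixel_grid`, one per page.
#' @export
read_image <- function(path, pixel_size_nm, allow_float = FALSE) {
  if (missing(pixel_size_nm))
    stop("`pixel_size_nm` must be supplied: pixel size is configuration, ",
         "not TIFF metadata", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e)
      stop(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
  )
  lapply(seq_along(pages), function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3L)
      stop(sprintf("page %d of '%s' has %d samples per pixel; only ",
                   i, path, dim(pg)[3]),
           "single-channel grayscale TIFFs are supported", call. = FALSE)
    if (!allow_float && (any(pg != round(pg)) || any(pg < 0)))
      stop(sprintf("page %d of '%s' is not 8/16-bit integer grayscale ",
                   i, path),
           "(floating-point or 32-bit data); pass allow_float = TRUE to ",
           "accept non-integer grayscale", call. = FALSE)
    storage.mode(pg) <- "double"
    pixel_grid(pg, pixel_size_nm, channel_label = sprintf("ch%d", i - 1L))
  })
}

#' Write a pixel grid to a 16-bit grayscale TIFF
#'
#' Values are rounded to integers and must fit the 16-bit range. Reading the
#' file back with [read_image()] recovers the rounded values exactly.
#'
#' @param grid A [pixel_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path) {
  stopifnot(inherits(grid, "pixel_grid"))
  v <- round(grid$values)
  if (any(v < 0) || any(v > 65535))
    stop("intensities outside the 16-bit range [0, 65535]", call. = FALSE)
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' ROI specification table
#'
#' Builds (or validates) the data frame describing regions of interest:
#' 0-based origin, size in pixels and channel label. The default size is the
#' 128 x 128 px analysis window.
#'
#' @param origin_row,origin_col 0-based origins, recycled to common length.
#' @param rows,cols ROI extent in pixels.
#' @param channel Channel label each ROI refers to.
#' @return `data.frame` with columns origin_row, origin_col, rows, cols,
#'   channel.
#' @export
roi_spec <- function(origin_row, origin_col, rows = 128L, cols = 128L,
                     channel = "ch0") {
  df <- data.frame(origin_row = as.integer(origin_row),
                   origin_col = as.integer(origin_col),
                   rows = as.integer(rows), cols = as.integer(cols),
                   channel = as.character(channel),
                   stringsAsFactors = FALSE)
  if (any(df$rows <= 0L) || any(df$cols <= 0L))
    stop("ROI sizes must be positive", call. = FALSE)
  if (any(df$origin_row < 0L) || any(df$origin_col < 0L))
    stop("ROI origins must be non-negative", call. = FALSE)
  df
}

#' Extract rectangular ROIs from an image
#'
#' Each ROI copies the pixel values (no aliasing of the source storage),
#' inherits the pixel size and records its origin within the source.
#'
#' @param image A [pixel_grid()].
#' @param specs ROI table as produced by [roi_spec()].
#' @return List of `pixel_grid`, one per row of `specs`.
#' @export
extract_rois <- function(image, specs) {
  stopifnot(inherits(image, "pixel_grid"))
  nr <- nrow(image$values); nc <- ncol(image$values)
  bad <- which(specs$origin_row + specs$rows > nr |
               specs$origin_col + specs$cols > nc |
               specs$origin_row < 0L | specs$origin_col < 0L)
  if (length(bad) > 0L)
    stop(sprintf("ROI(s) %s extend outside the %d x %d image",
                 paste(bad, collapse = ", "), nr, nc), call. = FALSE)
  lapply(seq_len(nrow(specs)), function(i) {
    r0 <- specs$origin_row[i]; c0 <- specs$origin_col[i]
    vals <- image$values[(r0 + 1L):(r0 + specs$rows[i]),
                         (c0 + 1L):(c0 + specs$cols[i]), drop = FALSE]
    pixel_grid(vals, image$pixel_size_nm,
               channel_label = image$channel_label,
               origin_px = c(r0, c0))
  })
}

#' Flag ROIs likely contaminated by large aggregates
#'
#' ICS assumes a speckle field of comparable assemblies; a single huge
#' aggregate dominates the variance and the analysis regions are therefore
#' picked away from such structures. This helper flags ROIs whose maximum
#' intensity exceeds a percentile of the whole-image intensity distribution,
#' as a screening aid for caller-supplied ROI lists.
#'
#' @param image Source [pixel_grid()].
#' @param specs ROI table ([roi_spec()]).
#' @param percentile Whole-image intensity quantile (default 0.999) above
#'   which an ROI maximum is flagged.
#' @return Logical vector, `TRUE` for flagged (aggregate-contaminated) ROIs.
#' @export
flag_aggregate_rois <- function(image, specs, percentile = 0.999) {
  cutoff <- stats::quantile(image$values, probs = percentile, names = FALSE)
  rois <- extract_rois(image, specs)
  vapply(rois, function(r) max(r$values) > cutoff, logical(1))
}

#' Write per-ROI/per-trace metric rows as CSV
#'
#' Deterministic column order (the key order of the first record), header
#' always written, decimal point independent of locale. `NaN` values are
#' serialized as empty cells and counted in a message.
#'
#' @param rows Data frame, or list of named lists sharing one key set.
#' @param path Output CSV path.
#' @param schema Character vector of column names; required to write a
#'   header-only file when `rows` is empty.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(rows, path, schema = NULL) {
  if (is.data.frame(rows)) {
    df <- rows
  } else if (length(rows) == 0L) {
    if (is.null(schema))
      stop("empty `rows` needs an explicit `schema` for the header",
           call. = FALSE)
    df <- as.data.frame(stats::setNames(
      replicate(length(schema), logical(0), simplify = FALSE), schema))
  } else {
    keys <- lapply(rows, function(r) sort(names(r)))
    if (!all(vapply(keys, identical, logical(1), y = keys[[1]])))
      stop("records do not share a single key set", call. = FALSE)
    df <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[names(rows[[1]])], stringsAsFactors = FALSE)))
  }
  n_nan <- sum(vapply(df, function(col)
    sum(is.numeric(col) & is.nan(col)), numeric(1)))
  if (n_nan > 0)
    message(sprintf("write_metrics: %d NaN value(s) written as empty cells",
                    n_nan))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
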