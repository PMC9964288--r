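#' Read a single-band raster from an Esri ASCII grid
#'
#' The only raster container in this package is the plain-text Esri ASCII
#' grid (`.asc`): a six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by `nrows`
#' whitespace-separated rows, first row = northernmost. No pre-installed R
#' package reads GeoTIFF in this environment, and the format carries
#' everything the pipeline needs (values, cell size, nodata).
#'
#' Nodata cells become `NA` and are excluded from the park mask. For
#' `kind = "categorical"` values must be integers.
#'
#' @param path file path to an `.asc` grid.
#' @param kind `"categorical"` (land cover) or `"continuous"` (elevation,
#'   surface, heat).
#' @param cell_size_m override for a missing/zero `cellsize` header.
#' @return a [land_cover_grid()] for categorical rasters, an
#'   [elevation_grid()] otherwise.
#' @export
read_raster <- function(path, kind = c("categorical", "continuous"),
                        cell_size_m = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows"))
    if (is.null(hdr[[key]])) stop("malformed Esri ASCII header: missing ", key)
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows)
    stop("raster body has ", length(vals), " values; expected ",
         ncols * nrows, " (multiband rasters are not supported)")
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  cs <- if (!is.null(cell_size_m)) cell_size_m else hdr$cellsize
  if (is.null(cs) || !is.finite(cs) || cs <= 0)
    stop("cell size absent from header; supply cell_size_m explicitly")
  if (kind == "categorical") {
    if (any(abs(m - round(m)) > 1e-9, na.rm = TRUE))
      stop("categorical raster contains non-integer values")
    land_cover_grid(round(m), cell_size_m = cs)
  } else {
    elevation_grid(m, cell_size_m = cs)
  }
}

#' Write a grid to an Esri ASCII file
#'
#' Round-trips exactly with [read_raster()] (values printed at full
#' precision; masked-out cells written as the nodata value).
#'
#' @param grid a `land_cover_grid`, `elevation_grid` or bare numeric matrix.
#' @param path output path.
#' @param cell_size_m cell size when `grid` is a bare matrix.
#' @param nodata nodata sentinel written for masked/NA cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, cell_size_m = NULL, nodata = -9999) {
  if (is.matrix(grid)) {
    stopifnot(!is.null(cell_size_m))
    values <- grid; mask <- !is.na(grid); cs <- cell_size_m
  } else if (inherits(grid, "land_cover_grid")) {
    values <- grid$codes; mask <- grid$mask; cs <- grid$cell_size_m
  } else if (inherits(grid, "elevation_grid")) {
    values <- grid$elevation_m; mask <- grid$mask; cs <- grid$cell_size_m
  } else if (inherits(grid, "surface_grid")) {
    # vegetation_mask marks vegetated cells, not validity: keep all values
    values <- grid$surface_m; mask <- !is.na(values); cs <- grid$cell_size_m
  } else stop("unsupported grid object")
  values[!mask | is.na(values)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", format(cs, digits = 17)),
    paste("NODATA_value", nodata)
  ), con)
  apply(values, 1L, function(row)
    writeLines(paste(format(row, digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con))
  invisible(path)
}
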