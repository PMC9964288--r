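#' Grid containers
#'
#' All rasters in waterscape are plain R matrices wrapped in lightweight S3
#' objects. The convention is fixed: row-major grids, origin at the top-left
#' corner, half-open cell extents; the park mask is a logical matrix of
#' identical shape and masked-out (`FALSE`) cells are excluded from every
#' statistic. Nodata is never imputed.
#'
#' @param codes integer matrix of cover-class codes.
#' @param cell_size_m positive cell edge length in metres.
#' @param mask logical matrix, `TRUE` on cells inside the park. Defaults to
#'   all non-`NA` cells.
#' @param class_labels optional named character vector mapping class codes
#'   (as names) to labels.
#' @return An object of class `land_cover_grid`.
#' @export
land_cover_grid <- function(codes, cell_size_m, mask = NULL,
                            class_labels = NULL) {
  stopifnot(is.matrix(codes), is.numeric(cell_size_m), cell_size_m > 0)
  if (any(abs(codes - round(codes)) > 0, na.rm = TRUE))
    stop("categorical raster values must be integers")
  storage.mode(codes) <- "integer"
  mask <- check_mask(mask, codes)
  if (any(is.na(codes[mask])))
    stop("every masked cell must have a known class code")
  structure(
    list(codes = codes, cell_size_m = as.numeric(cell_size_m),
         mask = mask, class_labels = class_labels),
    class = "land_cover_grid"
  )
}

#' @param elevation_m numeric matrix of ground elevations (m).
#' @rdname land_cover_grid
#' @export
elevation_grid <- function(elevation_m, cell_size_m, mask = NULL) {
  stopifnot(is.matrix(elevation_m), is.numeric(cell_size_m), cell_size_m > 0)
  mask <- check_mask(mask, elevation_m)
  if (any(!is.finite(elevation_m[mask])))
    stop("elevations must be finite on the park mask")
  structure(
    list(elevation_m = elevation_m, cell_size_m = as.numeric(cell_size_m),
         mask = mask),
    class = "elevation_grid"
  )
}

#' @param surface_m numeric matrix of canopy-top / digital-surface
#'   elevations (m).
#' @param vegetation_mask logical matrix marking vegetated cells.
#' @rdname land_cover_grid
#' @export
surface_grid <- function(surface_m, cell_size_m, vegetation_mask = NULL) {
  stopifnot(is.matrix(surface_m), is.numeric(cell_size_m), cell_size_m > 0)
  vegetation_mask <- check_mask(vegetation_mask, surface_m)
  structure(
    list(surface_m = surface_m, cell_size_m = as.numeric(cell_size_m),
         vegetation_mask = vegetation_mask),
    class = "surface_grid"
  )
}

check_mask <- function(mask, values) {
  if (is.null(mask)) mask <- !is.na(values)
  stopifnot(is.logical(mask))
  if (!identical(dim(mask), dim(values)))
    stop("mask shape must match the grid shape")
  mask & !is.na(mask)
}

#' Cell area of a grid in hectares
#' @param grid a grid object with a `cell_size_m` field.
#' @return cell area in ha.
#' @keywords internal
cell_area_ha <- function(grid) grid$cell_size_m^2 / 1e4
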