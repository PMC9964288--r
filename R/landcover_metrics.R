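#' Shannon-Wiener diversity of vegetation structure classes
#'
#' `H = -sum(p_i * log(p_i))` where `p_i` is the area share of vegetation
#' class `i` among the masked vegetation cells. The "species" set is the
#' vegetation-structure classes (nine in the reference classification:
#' four arbor forests, four shrub forests, grassland); non-vegetation
#' classes (water, hardscape, bare soil) are excluded.
#'
#' @param grid a [land_cover_grid()].
#' @param vegetation_classes integer vector of class codes treated as
#'   vegetation. Defaults to every class present in the mask.
#' @return nonnegative real; `0 <= H <= log(S)` for `S` classes present.
#' @export
shannon_diversity <- function(grid, vegetation_classes = NULL) {
  p <- class_proportions(grid, vegetation_classes)
  if (length(p) == 0) stop("no vegetation cells in the mask: H is undefined")
  -sum(p * log(p))
}

#' Pielou's evenness
#'
#' `J = H / log(S)`: Shannon diversity relative to its maximum for `S`
#' classes, in `[0, 1]`.
#'
#' @param H Shannon diversity.
#' @param S number of classes, at least 2.
#' @return real in `[0, 1]`.
#' @export
pielou_evenness <- function(H, S) {
  stopifnot(is.numeric(H), H >= 0)
  if (S < 2) stop("evenness is undefined for fewer than 2 classes")
  H / log(S)
}

#' Hemeroby (human-disturbance) index
#'
#' `HI = sum(i * S_i) / (h * S_A)` where `S_i` is the area at disturbance
#' degree `i`, `S_A` the total masked area and `h` the number of degrees.
#' Equals `1` when all area sits at the most artificial degree and `1/h`
#' when fully natural.
#'
#' @param grid a [land_cover_grid()].
#' @param table a [hemeroby_table()] mapping every masked class code to a
#'   degree.
#' @return real in `(0, 1]`.
#' @export
hemeroby_index <- function(grid, table) {
  codes <- grid$codes[grid$mask]
  present <- unique(codes)
  unmapped <- setdiff(present, as.integer(names(table$degree_of)))
  if (length(unmapped))
    stop("hemeroby degree missing for class code(s): ",
         paste(sort(unmapped), collapse = ", "))
  deg <- table$degree_of[as.character(codes)]
  sum(deg) / (table$h * length(codes))  # cell areas cancel
}

#' Hemeroby degree table
#'
#' @param degree_of named integer vector: class code (name) to degree in
#'   `[1, h]`.
#' @param h number of hemeroby degrees; defaults to `max(degree_of)`.
#' @return an object of class `hemeroby_table`.
#' @export
hemeroby_table <- function(degree_of, h = max(degree_of)) {
  degree_of <- round(degree_of)
  if (any(degree_of < 1) || any(degree_of > h))
    stop("degrees must lie in [1, h]")
  structure(list(degree_of = degree_of, h = as.integer(h)),
            class = "hemeroby_table")
}

#' Landscape fragmentation index
#'
#' Total patch count divided by park area in hectares. A patch is an
#' 8-connected component of same-class cells inside the park mask
#' (Fragstats' default connectivity). All classes are pooled for the park
#' value; per-class counts are available via `per_class = TRUE`.
#'
#' @param grid a [land_cover_grid()].
#' @param per_class return the per-class patch counts instead of the index.
#' @return patches per hectare, or a named integer vector of patch counts.
#' @export
fragmentation_index <- function(grid, per_class = FALSE) {
  if (!any(grid$mask)) stop("empty park mask")
  labels <- label_patches(grid$codes, grid$mask)
  ids <- labels[grid$mask]
  if (per_class) {
    cls <- grid$codes[grid$mask]
    return(tapply(ids, cls, function(v) length(unique(v))))
  }
  n_patches <- length(unique(ids))
  area_ha <- sum(grid$mask) * cell_area_ha(grid)
  n_patches / area_ha
}

#' 8-connected component labelling of same-class cells
#'
#' Iterative seed-fill; cells outside `mask` get label `NA`.
#'
#' @param codes integer matrix.
#' @param mask logical matrix.
#' @return integer matrix of patch ids (1-based), `NA` off-mask.
#' @keywords internal
label_patches <- function(codes, mask) {
  nr <- nrow(codes); nc <- ncol(codes)
  labels <- matrix(NA_integer_, nr, nc)
  nb_dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  nb_dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  next_id <- 0L
  for (start in which(mask & is.na(labels))) {
    if (!is.na(labels[start])) next
    next_id <- next_id + 1L
    cls <- codes[start]
    stack <- start
    labels[start] <- next_id
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      rr <- r + nb_dr; cc <- c + nb_dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      idx <- (cc[ok] - 1L) * nr + rr[ok]
      idx <- idx[mask[idx] & is.na(labels[idx]) & codes[idx] == cls]
      if (length(idx)) {
        labels[idx] <- next_id
        stack <- c(stack, idx)
      }
    }
  }
  labels
}

#' Canopy density
#'
#' Ratio of canopy-projected cells to plot cells, in `[0, 1]`.
#'
#' @param canopy_mask logical matrix of canopy-covered cells; must be a
#'   subset of `plot_mask`.
#' @param plot_mask logical matrix of the standard plot.
#' @return real in `[0, 1]`.
#' @export
canopy_density <- function(canopy_mask, plot_mask) {
  stopifnot(is.logical(canopy_mask), is.logical(plot_mask),
            identical(dim(canopy_mask), dim(plot_mask)))
  if (!any(plot_mask)) stop("empty plot mask")
  if (any(canopy_mask & !plot_mask))
    stop("canopy cells fall outside the plot mask")
  sum(canopy_mask) / sum(plot_mask)
}

class_proportions <- function(grid, classes = NULL) {
  codes <- grid$codes[grid$mask]
  if (!is.null(classes)) codes <- codes[codes %in% classes]
  if (length(codes) == 0) return(numeric(0))
  tab <- table(codes)
  as.numeric(tab) / length(codes)
}
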