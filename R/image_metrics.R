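#' Vertical layer-transition matrix
#'
#' Partitions the image into `n_bands` equal vertical bands (top to
#' bottom), takes the modal layer label of each band within each pixel
#' column, and tallies the ordered pairs (band `k`, band `k+1`) into a
#' square matrix over the six layer classes. Diagonal entries are
#' same-class persistences, off-diagonal entries are layer changes. This
#' construction is this package's own realization of "superposition of
#' multiple landscape types" — the field literature gives no matrix-building
#' recipe — and outputs are flagged accordingly.
#'
#' @param image a [panorama()] with `layer_labels`.
#' @param n_bands number of vertical bands (default 6).
#' @return an object of class `layer_matrix`: a 6x6 count matrix with
#'   dimnames from [layer_classes()].
#' @export
build_layer_matrix <- function(image, n_bands = 6) {
  if (is.null(image$layer_labels))
    stop("layer_labels missing: supply a segmentation or use synthetic ",
         "scenes with ground-truth labels")
  lab <- image$layer_labels
  h <- nrow(lab); w <- ncol(lab)
  k <- length(layer_classes())
  band_of <- ceiling(seq_len(h) / h * n_bands)
  band_label <- matrix(0L, n_bands, w)
  for (b in seq_len(n_bands)) {
    rows <- which(band_of == b)
    sub <- lab[rows, , drop = FALSE]
    band_label[b, ] <- apply(sub, 2L, modal_int)
  }
  tally <- matrix(0L, k, k, dimnames = list(layer_classes(), layer_classes()))
  for (b in seq_len(n_bands - 1L)) {
    pairs <- table(factor(band_label[b, ], levels = 1:k),
                   factor(band_label[b + 1L, ], levels = 1:k))
    tally <- tally + as.matrix(pairs)
  }
  structure(tally, class = c("layer_matrix", "matrix"))
}

modal_int <- function(v) {
  tab <- tabulate(v)
  which.max(tab)  # ties: lowest class code
}

#' Layer superposition index (vertical visual level)
#'
#' `PA = T / F`: the trace of the layer-transition matrix over the sum of
#' all its elements, in `[0, 1]`. Low values mean many between-layer
#' transitions, i.e. a deeper superposition of landscape types.
#'
#' @param matrix a [build_layer_matrix()] result (any square count matrix).
#' @return real in `[0, 1]`.
#' @export
layer_superposition <- function(matrix) {
  m <- unclass(matrix)
  total <- sum(m)
  if (total <= 0) stop("layer matrix is empty")
  sum(diag(m)) / total
}

#' Colorfulness (opponent-channel metric)
#'
#' `C = sigma_rgyb + 0.3 * mu_rgyb` with per-pixel opponent channels
#' `rg = R - G` and `yb = (R + G)/2 - B`;
#' `sigma_rgyb = sqrt(var(rg) + var(yb))`,
#' `mu_rgyb = sqrt(mean(rg)^2 + mean(yb)^2)`. Computed in double precision
#' on the full pixel population (population variance). Zero iff the image
#' is achromatic.
#'
#' @param image a [panorama()] or bare `h x w x 3` array.
#' @return nonnegative real.
#' @export
colorfulness <- function(image) {
  rgb <- if (inherits(image, "panorama")) image$rgb else image
  r <- as.numeric(rgb[, , 1]); g <- as.numeric(rgb[, , 2])
  b <- as.numeric(rgb[, , 3])
  rg <- r - g
  yb <- (r + g) / 2 - b
  pvar <- function(x) mean((x - mean(x))^2)
  sqrt(pvar(rg) + pvar(yb)) + 0.3 * sqrt(mean(rg)^2 + mean(yb)^2)
}

#' Sky fraction (diffuse non-interceptance)
#'
#' Proportion of the panorama occupied by visible sky. Uses the
#' ground-truth `sky_mask` when present; otherwise falls back to an
#' HSV-style threshold rule (high brightness, blue-dominant) with
#' configurable cut-offs.
#'
#' @param image a [panorama()].
#' @param threshold optional list(`min_value`, `min_blue_excess`) for the
#'   fallback rule: a pixel is sky when `B >= min_value` and
#'   `B - max(R, G) >= min_blue_excess`.
#' @return real in `[0, 1]`.
#' @export
sky_fraction <- function(image, threshold = NULL) {
  if (!is.null(image$sky_mask)) return(mean(image$sky_mask))
  if (is.null(threshold))
    stop("no sky_mask and no threshold rule supplied")
  rgb <- image$rgb
  b <- rgb[, , 3]
  excess <- b - pmax(rgb[, , 1], rgb[, , 2])
  mean(b >= threshold$min_value & excess >= threshold$min_blue_excess)
}

#' Park-level panorama indicators
#'
#' Arithmetic mean of C5 (layer superposition), C6 (colorfulness) and C9
#' (sky fraction) over a park's panoramas, mirroring grid-sampled field
#' photography where each photo carries equal weight.
#'
#' @param images list of [panorama()] objects.
#' @param threshold passed to [sky_fraction()].
#' @return data.frame with one row: `C5_raw`, `C6_raw`, `C9_raw`,
#'   `n_photos`.
#' @export
park_image_metrics <- function(images, threshold = NULL) {
  stopifnot(length(images) > 0)
  c5 <- vapply(images, function(im)
    layer_superposition(build_layer_matrix(im)), numeric(1))
  c6 <- vapply(images, colorfulness, numeric(1))
  c9 <- vapply(images, sky_fraction, numeric(1), threshold = threshold)
  data.frame(C5_raw = mean(c5), C6_raw = mean(c6), C9_raw = mean(c9),
             n_photos = length(images))
}
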