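#' Panorama image container
#'
#' Holds an RGB image as an `h x w x 3` array of channel values in
#' `[0, 255]`, with optional ground-truth sky mask and per-pixel layer
#' labels. Layer labels use the fixed six-class vocabulary returned by
#' [layer_classes()].
#'
#' @param rgb numeric `h x w x 3` array, values in `[0, 255]`.
#' @param sky_mask optional logical `h x w` matrix, `TRUE` on sky pixels.
#' @param layer_labels optional integer `h x w` matrix of layer class codes
#'   in `1:6` (see [layer_classes()]).
#' @return an object of class `panorama`.
#' @export
panorama <- function(rgb, sky_mask = NULL, layer_labels = NULL) {
  stopifnot(is.array(rgb), length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  if (min(rgb) < 0 || max(rgb) > 255)
    stop("channel values must lie in [0, 255]")
  shp <- dim(rgb)[1:2]
  if (!is.null(sky_mask)) {
    stopifnot(is.logical(sky_mask))
    if (!identical(dim(sky_mask), shp))
      stop("sky_mask shape must match the image")
  }
  if (!is.null(layer_labels)) {
    if (!identical(dim(layer_labels), shp))
      stop("layer_labels shape must match the image")
    storage.mode(layer_labels) <- "integer"
  }
  structure(list(rgb = rgb, sky_mask = sky_mask,
                 layer_labels = layer_labels),
            class = "panorama")
}

#' The fixed vertical-layer vocabulary
#' @return character vector of the six layer classes, in code order 1..6.
#' @export
layer_classes <- function() {
  c("sky", "canopy", "understory", "ground", "water", "hardscape")
}

#' Read / write panoramas as plain-text netpbm images
#'
#' Images travel as ASCII PPM (`P3`, RGB) and masks / label grids as ASCII
#' PGM (`P2`, single channel); both are human-readable text and round-trip
#' exactly. Binary PNG/JPEG support would need an image library that is not
#' available here.
#'
#' @param path image path (`.ppm`); sidecar files `<stem>_sky.pgm` and
#'   `<stem>_layers.pgm` are read/written when present/available.
#' @return [read_panorama()]: a [panorama()]; [write_panorama()]: `path`,
#'   invisibly.
#' @export
read_panorama <- function(path) {
  rgb <- read_pnm(path)
  stem <- sub("\\.ppm$", "", path)
  sky <- NULL; layers <- NULL
  if (file.exists(paste0(stem, "_sky.pgm")))
    sky <- read_pnm(paste0(stem, "_sky.pgm")) > 0
  if (file.exists(paste0(stem, "_layers.pgm")))
    layers <- read_pnm(paste0(stem, "_layers.pgm"))
  panorama(rgb, sky_mask = sky, layer_labels = layers)
}

#' @param image a [panorama()].
#' @rdname read_panorama
#' @export
write_panorama <- function(image, path) {
  write_pnm(image$rgb, path)
  stem <- sub("\\.ppm$", "", path)
  if (!is.null(image$sky_mask))
    write_pnm(image$sky_mask * 255L, paste0(stem, "_sky.pgm"))
  if (!is.null(image$layer_labels))
    write_pnm(image$layer_labels, paste0(stem, "_layers.pgm"))
  invisible(path)
}

read_pnm <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  txt <- txt[!grepl("^#", txt)]
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  magic <- toks[1]
  dims <- as.integer(toks[2:3])   # width height
  vals <- as.numeric(toks[-(1:4)])  # skip maxval
  w <- dims[1]; h <- dims[2]
  if (magic == "P2") {
    if (length(vals) != w * h) stop("corrupt PGM: ", path)
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else if (magic == "P3") {
    if (length(vals) != 3 * w * h) stop("corrupt PPM: ", path)
    px <- matrix(vals, ncol = 3, byrow = TRUE)
    arr <- array(0, dim = c(h, w, 3))
    for (ch in 1:3)
      arr[, , ch] <- matrix(px[, ch], nrow = h, ncol = w, byrow = TRUE)
    arr
  } else stop("unsupported netpbm magic '", magic, "' in ", path)
}

write_pnm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.matrix(x)) {
    writeLines(c("P2", paste(ncol(x), nrow(x)), "255"), con)
    apply(x, 1L, function(row)
      writeLines(paste(as.integer(round(row)), collapse = " "), con))
  } else {
    h <- dim(x)[1]; w <- dim(x)[2]
    writeLines(c("P3", paste(w, h), "255"), con)
    for (i in seq_len(h)) {
      row <- as.integer(round(t(x[i, , ])))  # interleave R G B per pixel
      writeLines(paste(row, collapse = " "), con)
    }
  }
  invisible(path)
}
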