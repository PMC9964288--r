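#' Terrain position ("shape") index
#'
#' Per cell, `P = H_g - mean(H_i)` over the available 8-neighbourhood:
#' positive on local peaks, negative in depressions, zero on planes
#' (interior cells of a linear ramp have neighbour mean equal to the
#' centre). The park-level value is the plain mean of `P` over masked
#' cells and may be negative.
#'
#' @param dem an [elevation_grid()], at least 3x3.
#' @return list with `grid` (per-cell P) and `mean` (park value).
#' @export
terrain_position <- function(dem) {
  z <- dem$elevation_m
  if (nrow(z) < 3 || ncol(z) < 3) stop("grid must be at least 3x3")
  if (!any(dem$mask)) stop("empty park mask")
  nr <- nrow(z); nc <- ncol(z)
  zp <- matrix(NA_real_, nr + 2, nc + 2)
  zp[2:(nr + 1), 2:(nc + 1)] <- z
  nb_sum <- matrix(0, nr, nc); nb_n <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- zp[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    ok <- !is.na(shifted)
    nb_sum[ok] <- nb_sum[ok] + shifted[ok]
    nb_n <- nb_n + ok
  }
  p <- z - nb_sum / nb_n
  list(grid = p, mean = mean(p[dem$mask]))
}

#' Profile curvature
#'
#' Curvature of the surface along the gradient direction:
#' `Kp = -(r p^2 + 2 s p q + t q^2) / ((p^2+q^2) (p^2+q^2+1)^(3/2))`
#' with first (`p`, `q`) and second (`r`, `s`, `t`) derivatives estimated
#' by central finite differences on a replicate-padded grid. The
#' denominator vanishes on flat cells; where the squared gradient falls
#' below `eps` the curvature is defined as 0.
#'
#' @param dem an [elevation_grid()], at least 3x3.
#' @param eps gradient-singularity guard on `p^2 + q^2`.
#' @return list with `grid` (per-cell Kp) and `mean` (park value).
#' @export
profile_curvature <- function(dem, eps = 1e-6) {
  z <- dem$elevation_m
  if (nrow(z) < 3 || ncol(z) < 3) stop("grid must be at least 3x3")
  d <- dem$cell_size_m
  nr <- nrow(z); nc <- ncol(z)
  # replicate padding
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  ctr_r <- 2:(nr + 1); ctr_c <- 2:(nc + 1)
  sh <- function(dr, dc) zp[ctr_r + dr, ctr_c + dc]
  # x = columns (east), y = rows
  p <- (sh(0, 1) - sh(0, -1)) / (2 * d)
  q <- (sh(1, 0) - sh(-1, 0)) / (2 * d)
  r <- (sh(0, 1) - 2 * z + sh(0, -1)) / d^2
  t <- (sh(1, 0) - 2 * z + sh(-1, 0)) / d^2
  s <- (sh(1, 1) - sh(1, -1) - sh(-1, 1) + sh(-1, -1)) / (4 * d^2)
  g2 <- p^2 + q^2
  kp <- matrix(0, nr, nc)
  ok <- g2 >= eps
  kp[ok] <- -(r[ok] * p[ok]^2 + 2 * s[ok] * p[ok] * q[ok] +
                t[ok] * q[ok]^2) / (g2[ok] * (g2[ok] + 1)^1.5)
  list(grid = kp, mean = mean(kp[dem$mask]))
}

#' Tridimensional green biomass (green volume)
#'
#' `V = sum over vegetated cells of dd^2 * |h_ij - H_ij|`: the volume
#' between the canopy-top surface and the ground over vegetated cells,
#' in cubic metres. `dd` is the surface-grid resolution (0.1 m for the
#' reference imagery).
#'
#' @param dsm a [surface_grid()] with its `vegetation_mask`.
#' @param dem an [elevation_grid()] co-registered with `dsm`.
#' @return nonnegative volume in m^3.
#' @export
green_volume <- function(dsm, dem) {
  if (!identical(dim(dsm$surface_m), dim(dem$elevation_m)))
    stop("DSM and DEM shapes differ; grids must be co-registered")
  v <- dsm$vegetation_mask
  dd <- dsm$cell_size_m
  sum(dd^2 * abs(dsm$surface_m[v] - dem$elevation_m[v]))
}

#' Relief amplitude
#'
#' `RA = E_max - E_min` within the park mask, in metres.
#'
#' @param dem an [elevation_grid()].
#' @return nonnegative relief in m.
#' @export
relief_amplitude <- function(dem) {
  if (!any(dem$mask)) stop("empty park mask")
  z <- dem$elevation_m[dem$mask]
  max(z) - min(z)
}
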