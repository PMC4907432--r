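## Point samplers on regular grids. Coordinates are 0-based voxel indices
## (voxel centre i sits at coordinate i); queries outside the grid return
## `fill`.

#' Bilinear sampling of a matrix at arbitrary points
#'
#' @param m numeric matrix indexed `(x, y)`, 0-based query coordinates.
#' @param x,y numeric vectors of equal length.
#' @param fill value for out-of-bounds queries (default `min(m)`).
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(m, x, y, fill = min(m)) {
  nx <- nrow(m); ny <- ncol(m)
  out <- rep(fill, length(x))
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  fx <- x - x0; fy <- y - y0
  i0 <- x0 + 1; j0 <- y0 + 1   # 1-based corners
  v00 <- m[cbind(i0,     j0)]
  v10 <- m[cbind(i0 + 1, j0)]
  v01 <- m[cbind(i0,     j0 + 1)]
  v11 <- m[cbind(i0 + 1, j0 + 1)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
             v01 * (1 - fx) * fy       + v11 * fx * fy
  out
}

#' Trilinear sampling of a 3D array at arbitrary points
#'
#' @param a numeric 3D array, 0-based query coordinates.
#' @param x,y,z numeric vectors of equal length.
#' @param fill value for out-of-bounds queries (default `min(a)`).
#' @return numeric vector of sampled values.
#' @keywords internal
trilinear_sample <- function(a, x, y, z, fill = min(a)) {
  d <- dim(a); nx <- d[1L]; ny <- d[2L]; nz <- d[3L]
  out <- rep(fill, length(x))
  ok <- x >= 0 & x <= nx - 1 & y >= 0 & y <= ny - 1 & z >= 0 & z <= nz - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), nx - 2); y0 <- pmin(floor(y), ny - 2)
  z0 <- pmin(floor(z), nz - 2)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  ## linear indices of the 8 corners (1-based array)
  base <- (x0 + 1) + x0 * 0 + nx * y0 + nx * ny * z0
  sx <- 1; sy <- nx; sz <- nx * ny
  v000 <- a[base];            v100 <- a[base + sx]
  v010 <- a[base + sy];       v110 <- a[base + sx + sy]
  v001 <- a[base + sz];       v101 <- a[base + sx + sz]
  v011 <- a[base + sy + sz];  v111 <- a[base + sx + sy + sz]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) +
    v100 * fx       * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy       * (1 - fz) +
    v110 * fx       * fy       * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz +
    v101 * fx       * (1 - fy) * fz +
    v011 * (1 - fx) * fy       * fz +
    v111 * fx       * fy       * fz
  out
}
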