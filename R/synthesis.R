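#' Develop the panoramic surface into plane coordinates
#'
#' Joins the surface columns at a reference transverse row into a 3D
#' piecewise-linear polyline and straightens it by the arc-length rule: the
#' abscissa of column `i` is the cumulative sum of the 3D segment lengths
#' `w_i = sum_{j<=i} L_j` with `w_0 = 0`, while the ordinate keeps the axial
#' slice index, `h_j = z_j`. The development is therefore isometric along
#' the reference row.
#'
#' @param surf a `panoramic_surface`.
#' @param reference_row `"mid"` (default: middle axial row), `"per_row_mean"`
#'   (segment lengths averaged over all rows), or an integer row index
#'   (1-based), e.g. the occlusal-plane slice.
#' @return list with `w` (per-column abscissa, px), `h` (per-row ordinate,
#'   the 0-based slice indices), `reference_row`.
#' @export
develop_surface <- function(surf, reference_row = "mid") {
  stopifnot(inherits(surf, "panoramic_surface"))
  m <- ncol(surf$X)
  seglen <- function(j) {
    dx <- diff(surf$X[, j]); dy <- diff(surf$Y[, j]); dz <- diff(surf$Z[, j])
    sqrt(dx^2 + dy^2 + dz^2)
  }
  if (identical(reference_row, "per_row_mean")) {
    L <- rowMeans(vapply(seq_len(m), seglen, numeric(nrow(surf$X) - 1)))
  } else {
    j <- if (identical(reference_row, "mid")) as.integer((m + 1) / 2)
         else as.integer(reference_row)
    stopifnot(j >= 1, j <= m)
    L <- seglen(j)
  }
  list(w = c(0, cumsum(L)), h = surf$Z[1, ], reference_row = reference_row)
}

## shared slab sampler: offsets along per-vertex normals (0 offsets = sheet)
render_developed <- function(vol, surf, dev, n_slices = 1, aggregate = "mean") {
  stopifnot(n_slices >= 1, n_slices %% 2 == 1)
  w <- dev$w
  W <- as.integer(round(w[length(w)])) + 1L
  nz <- ncol(surf$X)
  cols <- seq_len(nrow(surf$X))
  ## fractional source column for each output abscissa
  ci <- stats::approx(w, cols, xout = 0:(W - 1), rule = 2)$y
  i0 <- pmin(floor(ci), length(cols) - 1L)
  tt <- ci - i0
  Xw <- (1 - tt) * surf$X[i0, ] + tt * surf$X[i0 + 1L, ]
  Yw <- (1 - tt) * surf$Y[i0, ] + tt * surf$Y[i0 + 1L, ]
  Zw <- (1 - tt) * surf$Z[i0, ] + tt * surf$Z[i0 + 1L, ]
  if (n_slices > 1) {
    if (is.null(surf$NX))
      stop("thickened rendering needs surface normals; run estimate_normals()")
    NXw <- (1 - tt) * surf$NX[i0, ] + tt * surf$NX[i0 + 1L, ]
    NYw <- (1 - tt) * surf$NY[i0, ] + tt * surf$NY[i0 + 1L, ]
    NZw <- (1 - tt) * surf$NZ[i0, ] + tt * surf$NZ[i0 + 1L, ]
    nn <- sqrt(NXw^2 + NYw^2 + NZw^2)
    nn[nn < 1e-12] <- 1
    NXw <- NXw / nn; NYw <- NYw / nn; NZw <- NZw / nn
    offsets <- seq(-(n_slices - 1) / 2, (n_slices - 1) / 2)
    acc <- NULL
    for (t_off in offsets) {
      s <- trilinear_sample(vol$data, as.vector(Xw + t_off * NXw),
                            as.vector(Yw + t_off * NYw),
                            as.vector(Zw + t_off * NZw))
      acc <- if (is.null(acc)) {
        if (aggregate == "max") s else s / n_slices
      } else {
        if (aggregate == "max") pmax(acc, s) else acc + s / n_slices
      }
    }
    img <- matrix(acc, W, nz)
  } else {
    img <- matrix(trilinear_sample(vol$data, as.vector(Xw), as.vector(Yw),
                                   as.vector(Zw)), W, nz)
  }
  structure(list(data = img, w_coords = w, h_coords = dev$h,
                 thickness_slices = n_slices, provenance = "surface",
                 spacing = vol$spacing[c(1, 3)]),
            class = c("developed_image"))
}

#' Synthesize the single-slice panoramic radiograph
#'
#' Inverts the development mapping (linear interpolation in `w` between
#' adjacent surface columns) at every integer output pixel and samples the
#' volume there by trilinear interpolation. The image height equals the
#' number of axial slices; the width equals the rounded total length of the
#' developed polyline plus one.
#'
#' @param vol a [cbct_volume].
#' @param surf a `panoramic_surface`.
#' @param dev development coordinates from [develop_surface].
#' @return a `developed_image` (fields `data` indexed (w, h), `w_coords`,
#'   `h_coords`, `thickness_slices = 1`, `provenance = "surface"`).
#' @export
render_single_slice <- function(vol, surf, dev) {
  render_developed(vol, surf, dev, n_slices = 1)
}

#' Synthesize a thickened panoramic radiograph
#'
#' Averages volume samples at integer voxel offsets along the per-vertex
#' surface normals (a slab of `n_slices` sheets centred on the surface).
#' Structures near but not on the surface, such as the mandibular canal,
#' become visible as the slab thickens. `n_slices = 1` reduces exactly to
#' [render_single_slice].
#'
#' @param vol a [cbct_volume].
#' @param surf a `panoramic_surface` with normals ([estimate_normals]).
#' @param dev development coordinates from [develop_surface].
#' @param n_slices odd slab thickness in voxels (default 21).
#' @param aggregate `"mean"` (default) or `"max"`.
#' @return a `developed_image`.
#' @export
render_thickened <- function(vol, surf, dev, n_slices = 21,
                             aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  render_developed(vol, surf, dev, n_slices = n_slices, aggregate = aggregate)
}

#' Cylinder-method baseline panoramic radiograph
#'
#' The classical baseline: the 2D dental arch curve is extruded vertically
#' into a cylinder sheet and the volume is sampled on it; thickening offsets
#' run along the curve's horizontal outward normal. Tilted tooth long axes
#' leave this sheet, which is why the baseline misses incisor crowns and
#' roots that the curved-surface method captures.
#'
#' @param vol a [cbct_volume].
#' @param curve an `arch_curve` (in axial pixel coordinates).
#' @param n_slices odd slab thickness in voxels (default 1).
#' @param aggregate `"mean"` or `"max"`.
#' @return a `developed_image` with `provenance = "cylinder"`.
#' @export
render_cylinder_baseline <- function(vol, curve, n_slices = 1,
                                     aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(curve, "arch_curve"), n_slices %% 2 == 1)
  lines <- sample_perpendicular_lines(curve, step_px = 1, half_length_px = 1)
  L <- curve$total_length
  W <- as.integer(round(L)) + 1L
  u <- stats::approx(curve$arclength_table$s, curve$arclength_table$u,
                     xout = pmin(0:(W - 1), L))$y
  feet <- eval_arch_curve(curve, u)
  d <- eval_arch_curve(curve, u, derivative = TRUE)
  tn <- d / sqrt(rowSums(d^2))
  nrm <- cbind(tn[, 2], -tn[, 1])
  ctr <- colMeans(curve$control_points)
  flip <- rowSums(nrm * sweep(feet, 2, ctr, `-`)) < -1e-9
  nrm[flip, ] <- -nrm[flip, ]
  nz <- dim(vol$data)[3L]
  zs <- rep(0:(nz - 1), each = W)
  offsets <- seq(-(n_slices - 1) / 2, (n_slices - 1) / 2)
  acc <- NULL
  for (t_off in offsets) {
    s <- trilinear_sample(vol$data,
                          rep(feet[, 1] + t_off * nrm[, 1], times = nz),
                          rep(feet[, 2] + t_off * nrm[, 2], times = nz),
                          zs)
    acc <- if (is.null(acc)) {
      if (aggregate == "max") s else s / n_slices
    } else {
      if (aggregate == "max") pmax(acc, s) else acc + s / n_slices
    }
  }
  structure(list(data = matrix(acc, W, nz),
                 w_coords = pmin(0:(W - 1), L), h_coords = 0:(nz - 1),
                 thickness_slices = n_slices, provenance = "cylinder",
                 spacing = vol$spacing[c(1, 3)]),
            class = "developed_image")
}

#' @export
print.developed_image <- function(x, ...) {
  cat(sprintf("<developed_image:%s> %d x %d px, thickness %d, range [%.4g, %.4g]\n",
              x$provenance, nrow(x$data), ncol(x$data), x$thickness_slices,
              min(x$data), max(x$data)))
  invisible(x)
}

#' Convert a developed image to a plain 2D image
#'
#' @param img a `developed_image`.
#' @return a [cbct_image] with provenance `"panoramic"`, suitable for
#'   [save_image].
#' @export
as_cbct_image <- function(img) {
  stopifnot(inherits(img, "developed_image"))
  cbct_image(img$data, spacing = img$spacing, provenance = "panoramic")
}
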