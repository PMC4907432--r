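#' Extract an oblique sagittal section along one normal line
#'
#' Samples the volume on the vertical sheet through the line
#' `foot + u * direction` for integer `u` in `[-half_length, half_length]`
#' and every axial slice `z`, with bilinear in-plane interpolation.
#' Positions outside the volume take the volume's minimum intensity.
#'
#' @param vol a [cbct_volume].
#' @param line_index which line of `lines` to use.
#' @param lines a `normal_lines` object from [sample_perpendicular_lines].
#' @return object of class `section_image`: `data` (width x n_slices matrix
#'   indexed (u, z)), `u` (offsets along the line), `foot`, `direction`,
#'   `arc_position`, `half_length`.
#' @export
extract_section <- function(vol, lines, line_index) {
  stopifnot(inherits(vol, "cbct_volume"), inherits(lines, "normal_lines"))
  hl <- lines$half_length
  u <- seq(-hl, hl)
  foot <- lines$foot[line_index, ]
  dir <- lines$direction[line_index, ]
  nz <- dim(vol$data)[3L]
  xs <- foot[1] + u * dir[1]
  ys <- foot[2] + u * dir[2]
  nu <- length(u)
  q <- trilinear_sample(vol$data,
                        rep(xs, times = nz),
                        rep(ys, times = nz),
                        rep(0:(nz - 1), each = nu))
  structure(list(data = matrix(q, nu, nz), u = u, foot = foot,
                 direction = dir,
                 arc_position = lines$arc_position[line_index],
                 half_length = hl),
            class = "section_image")
}

#' Segment teeth in a sagittal section
#'
#' Same clustering rule as [segment_bone] applied to the section intensities:
#' k-means++ with `k` classes, mask = brightest `top_m` cluster(s), then
#' removal of connected components smaller than `min_area` pixels (least
#' squares on salt noise is catastrophic, so speckles must go before the
#' long-axis fit).
#'
#' @param sec a `section_image`.
#' @param k clusters (default 4; use 2 for closed-bite scans where teeth
#'   and jaw merge).
#' @param seed RNG seed (default 0).
#' @param min_area speckle-removal threshold in px (default 10).
#' @param top_m brightest clusters kept (default 1).
#' @return logical matrix of the section's dimensions, with attribute
#'   `empty = TRUE` when no teeth were found.
#' @export
segment_teeth_section <- function(sec, k = 4, seed = 0, min_area = 10,
                                  top_m = 1) {
  stopifnot(inherits(sec, "section_image"), k >= 2)
  v <- as.vector(sec$data)
  if (length(unique(v)) < 2) {
    m <- matrix(FALSE, nrow(sec$data), ncol(sec$data))
    attr(m, "empty") <- TRUE
    return(m)
  }
  km <- kmeanspp_1d(v, k, seed)
  top_m <- min(top_m, km$k - 1)
  thr <- km$boundaries[km$k - top_m]
  mask <- sec$data >= thr
  if (any(mask) && min_area > 1) {
    lab <- EBImage::bwlabel(mask * 1)
    keep <- which(tabulate(lab[lab > 0]) >= min_area)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  attr(mask, "empty") <- !any(mask)
  mask
}

#' Fit the long axial curve of the teeth in one section
#'
#' Least-squares polynomial `u(z)` of the requested degree through the mask
#' pixel coordinates (a single curve spans upper and lower teeth; any bite
#' gap simply contributes no pixels and the polynomial bridges it). The fit
#' is computed on a centred/scaled z to keep high degrees numerically sane.
#'
#' @param mask logical matrix indexed (u, z) as produced by
#'   [segment_teeth_section].
#' @param degree polynomial degree, 1..7 (default 5, the quintic).
#' @param half_length half-length of the generating line; sampled `u` values
#'   are clipped to `[-half_length, half_length]`.
#' @return object of class `long_axial_curve`: `source` one of `"fitted"`,
#'   `"fallback"`; for fitted curves `u_of_z(z)` evaluates the curve,
#'   `z_range` is the fitted support, `coef` the scaled-basis coefficients,
#'   `z_scale` the (centre, half-width) used for scaling.
#' @export
fit_long_axial_curve <- function(mask, degree = 5, half_length = NULL) {
  stopifnot(degree >= 1, degree <= 7)
  if (is.null(half_length)) half_length <- (nrow(mask) - 1) / 2
  px <- which(mask, arr.ind = TRUE)
  zr_rows <- unique(px[, 2])
  if (length(zr_rows) < degree + 1) {
    return(structure(list(source = "fallback", degree = degree),
                     class = "long_axial_curve"))
  }
  uu <- px[, 1] - 1 - half_length     # 0-based, centred on the foot
  zz <- px[, 2] - 1
  zc <- mean(range(zz)); zh <- max(1, diff(range(zz)) / 2)
  t <- (zz - zc) / zh
  X <- stats::poly(t, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), uu)
  cf <- fit$coefficients
  cf[!is.finite(cf)] <- 0
  u_of_z <- function(z) {
    tt <- (z - zc) / zh
    out <- rep(cf[1], length(z))
    for (d in seq_len(degree)) out <- out + cf[d + 1] * tt^d
    pmin(half_length, pmax(-half_length, out))
  }
  structure(list(source = "fitted", degree = degree, coef = unname(cf),
                 z_scale = c(zc, zh), z_range = range(zz),
                 u_of_z = u_of_z, half_length = half_length),
            class = "long_axial_curve")
}

#' Assemble the 3D panoramic curved surface
#'
#' Vertex `(i, j)` is long-axis curve `i` evaluated at slice `j`, mapped back
#' through its generating line: `(x, y) = foot_i + u_i(z_j) * direction_i`.
#' Outside a curve's fitted z-range, `u` is clamped to its boundary value.
#' Sections where no teeth were found are filled by linear interpolation (in
#' arc length) of the `u(z)` profiles of the nearest fitted neighbours;
#' vertices are marked invalid only where both immediate neighbours of an
#' interpolated column were themselves fallbacks.
#'
#' @param curves list of `long_axial_curve`, one per line.
#' @param lines the `normal_lines` the sections were extracted along.
#' @param n_slices number of axial slices of the source volume.
#' @param smooth_px half-width (arc px) of a triangular kernel applied to
#'   the per-column `u(z)` profiles along the arch after interpolation
#'   (default 5, about half a tooth width). Independent per-section fits
#'   jitter at the voxel-quantisation level; unsmoothed, that jitter
#'   inflates the developed width because every 1-px chord of the
#'   development polyline picks up a spurious transverse component. The
#'   kernel is much narrower than the arch-level variation it must
#'   preserve. Set to 0 to disable.
#' @return object of class `panoramic_surface`: matrices `X`, `Y`, `Z`
#'   (n_sections x n_slices, voxel coords), `U` (the per-column profiles),
#'   `validity`, `source` per column, `arc_positions`, `lines`; normals are
#'   added by [estimate_normals].
#' @export
build_surface <- function(curves, lines, n_slices, smooth_px = 5) {
  n <- length(curves)
  stopifnot(n >= 2, n == nrow(lines$foot))
  zs <- 0:(n_slices - 1)
  src <- vapply(curves, `[[`, character(1), "source")
  if (!any(src == "fitted")) stop("no teeth found in any section")
  U <- matrix(NA_real_, n, n_slices)
  for (i in which(src == "fitted")) {
    cr <- curves[[i]]
    zcl <- pmin(cr$z_range[2], pmax(cr$z_range[1], zs))
    U[i, ] <- cr$u_of_z(zcl)
  }
  fitted_idx <- which(src == "fitted")
  s <- lines$arc_position
  for (i in which(src != "fitted")) {
    lo <- fitted_idx[fitted_idx < i]
    hi <- fitted_idx[fitted_idx > i]
    if (length(lo) && length(hi)) {
      i0 <- max(lo); i1 <- min(hi)
      t <- (s[i] - s[i0]) / (s[i1] - s[i0])
      U[i, ] <- (1 - t) * U[i0, ] + t * U[i1, ]
      src[i] <- "interpolated"
    } else if (length(lo)) {
      U[i, ] <- U[max(lo), ]; src[i] <- "interpolated"
    } else {
      U[i, ] <- U[min(hi), ]; src[i] <- "interpolated"
    }
  }
  ## invalid only where a toothless section's immediate neighbours were
  ## toothless too (stride-skipped sections are deliberate, not evidence-free)
  was_fb <- vapply(curves, `[[`, character(1), "source") == "fallback"
  validity <- matrix(TRUE, n, n_slices)
  for (i in which(was_fb)) {
    nb <- c(if (i > 1) was_fb[i - 1], if (i < n) was_fb[i + 1])
    if (length(nb) && all(nb)) validity[i, ] <- FALSE
  }
  if (smooth_px > 0 && n > 2) {
    s_arc <- lines$arc_position
    Us <- U
    for (i in seq_len(n)) {
      wgt <- pmax(0, 1 - abs(s_arc - s_arc[i]) / smooth_px)
      nb <- which(wgt > 0)
      if (length(nb) > 1)
        Us[i, ] <- colSums(U[nb, , drop = FALSE] * wgt[nb]) / sum(wgt[nb])
    }
    U <- Us
  }
  X <- lines$foot[, 1] + U * lines$direction[, 1]
  Y <- lines$foot[, 2] + U * lines$direction[, 2]
  Z <- matrix(zs, n, n_slices, byrow = TRUE)
  structure(list(X = X, Y = Y, Z = Z, U = U, validity = validity,
                 source = src, arc_positions = s, lines = lines),
            class = "panoramic_surface")
}

#' Estimate per-vertex surface normals by local PCA
#'
#' Each vertex's normal is the smallest-eigenvalue eigenvector of the
#' covariance of its grid neighbourhood (the plane-fit normal familiar from
#' point-cloud libraries), oriented to agree with the outward in-plane
#' normal of the generating line. Degenerate (collinear) neighbourhoods fall
#' back to that outward line normal.
#'
#' @param surf a `panoramic_surface`.
#' @param k_neighbors target neighbourhood size (default 9, a 3x3 grid
#'   window).
#' @return the surface with added arrays `NX`, `NY`, `NZ` (unit normals).
#' @export
estimate_normals <- function(surf, k_neighbors = 9) {
  stopifnot(inherits(surf, "panoramic_surface"), k_neighbors >= 3)
  r <- max(1L, as.integer(ceiling((sqrt(k_neighbors) - 1) / 2)))
  n <- nrow(surf$X); m <- ncol(surf$X)
  NX <- NY <- NZ <- matrix(0, n, m)
  dirs <- surf$lines$direction
  for (i in seq_len(n)) {
    i0 <- max(1L, i - r); i1 <- min(n, i + r)
    for (j in seq_len(m)) {
      j0 <- max(1L, j - r); j1 <- min(m, j + r)
      px <- as.vector(surf$X[i0:i1, j0:j1])
      py <- as.vector(surf$Y[i0:i1, j0:j1])
      pz <- as.vector(surf$Z[i0:i1, j0:j1])
      P <- cbind(px - mean(px), py - mean(py), pz - mean(pz))
      C <- crossprod(P) / nrow(P)
      ev <- eigen(C, symmetric = TRUE)
      nv <- ev$vectors[, 3]
      if (ev$values[2] < 1e-12 * max(ev$values[1], 1e-300)) {
        nv <- c(dirs[i, 1], dirs[i, 2], 0)   # collinear neighbourhood
      }
      if (sum(nv * c(dirs[i, 1], dirs[i, 2], 0)) < 0) nv <- -nv
      NX[i, j] <- nv[1]; NY[i, j] <- nv[2]; NZ[i, j] <- nv[3]
    }
  }
  surf$NX <- NX; surf$NY <- NY; surf$NZ <- NZ
  surf$k_neighbors <- k_neighbors
  surf
}

#' Export a panoramic surface as an ASCII PLY mesh
#'
#' Vertices carry normals when present; the triangle strip between adjacent
#' columns is expanded to triangles, skipping invalid vertices.
#'
#' @param surf a `panoramic_surface`.
#' @param path output `.ply` path.
#' @return `path`, invisibly.
#' @export
write_surface_ply <- function(surf, path) {
  n <- nrow(surf$X); m <- ncol(surf$X)
  has_n <- !is.null(surf$NX)
  vid <- matrix(seq_len(n * m) - 1L, n, m)  # 0-based vertex ids
  vb <- cbind(as.vector(surf$X), as.vector(surf$Y), as.vector(surf$Z))
  if (has_n) vb <- cbind(vb, as.vector(surf$NX), as.vector(surf$NY),
                         as.vector(surf$NZ))
  faces <- list()
  ok <- surf$validity
  for (i in seq_len(n - 1)) {
    for (j in seq_len(m - 1)) {
      if (ok[i, j] && ok[i + 1, j] && ok[i, j + 1] && ok[i + 1, j + 1]) {
        faces[[length(faces) + 1L]] <-
          c(vid[i, j], vid[i + 1, j], vid[i + 1, j + 1])
        faces[[length(faces) + 1L]] <-
          c(vid[i, j], vid[i + 1, j + 1], vid[i, j + 1])
      }
    }
  }
  con <- file(path, "w"); on.exit(close(con))
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(vb)),
           "property float x", "property float y", "property float z")
  if (has_n) hdr <- c(hdr, "property float nx", "property float ny",
                      "property float nz")
  hdr <- c(hdr, sprintf("element face %d", length(faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  utils::write.table(format(vb, trim = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (length(faces))
    writeLines(vapply(faces, function(f)
      paste(c(3L, f), collapse = " "), ""), con)
  invisible(path)
}

#' Extract the panoramic curved surface from a volume (pipeline step 2)
#'
#' Chains [extract_section], [segment_teeth_section], [fit_long_axial_curve]
#' and [build_surface] over all normal lines, then [estimate_normals].
#'
#' @param vol a [cbct_volume].
#' @param lines a `normal_lines` object.
#' @param k_section,seed,min_area passed to [segment_teeth_section].
#' @param degree long-axis polynomial degree (default 5).
#' @param k_neighbors for [estimate_normals]; set to NULL to skip normals.
#' @param min_tooth_intensity gray threshold separating sections that truly
#'   contain teeth from sections that only cut jaw bone between or beyond
#'   the dentition (the latter are bridged by interpolation instead of being
#'   fitted). `"auto"` (default) derives it from the spread of the
#'   per-section top-cluster centres: tooth enamel dominates the brightest
#'   sections, so sections whose top cluster sits in the lower half of that
#'   spread carry no tooth; when all sections contain teeth the spread is
#'   narrow and nothing is dropped. A number fixes the threshold; NULL
#'   disables the gate.
#' @param section_step_px arc-length spacing (px) between the sections that
#'   are actually segmented and fitted (default 1: every line; 10 mimics
#'   processing one section in every ten and interpolating intermediate
#'   columns, which suits dentitions with continuous proximal contacts but
#'   can step over an individually spaced tooth).
#' @param smooth_px passed to [build_surface] (default 5).
#' @return a `panoramic_surface` (with normals unless `k_neighbors = NULL`),
#'   plus attribute `n_fallback` (sections without teeth).
#' @export
extract_panoramic_surface <- function(vol, lines, k_section = 4, seed = 0,
                                      degree = 5, min_area = 10,
                                      k_neighbors = 9,
                                      min_tooth_intensity = "auto",
                                      section_step_px = 1,
                                      smooth_px = 5) {
  n <- nrow(lines$foot)
  line_step <- if (n > 1) stats::median(diff(lines$arc_position)) else 1
  stride <- max(1L, as.integer(round(section_step_px / line_step)))
  fit_at <- unique(c(seq(1L, n, by = stride), n))
  masks <- vector("list", n)
  top_val <- rep(NA_real_, n)
  for (i in fit_at) {
    sec <- extract_section(vol, lines, i)
    mask <- segment_teeth_section(sec, k = k_section, seed = seed,
                                  min_area = min_area)
    if (any(mask)) top_val[i] <- max(sec$data[mask])
    masks[[i]] <- mask
  }
  thr <- if (identical(min_tooth_intensity, "auto")) {
    rngv <- range(top_val, na.rm = TRUE)
    if (diff(rngv) > 0.15 * rngv[2]) mean(rngv) else -Inf
  } else if (is.null(min_tooth_intensity)) -Inf else min_tooth_intensity
  curves <- vector("list", n)
  for (i in seq_len(n)) {
    if (!(i %in% fit_at)) {
      curves[[i]] <- structure(list(source = "skipped", degree = degree),
                               class = "long_axial_curve")
      next
    }
    mask <- masks[[i]]
    if (!is.na(top_val[i]) && top_val[i] < thr) mask[] <- FALSE
    curves[[i]] <- fit_long_axial_curve(mask, degree = degree,
                                        half_length = lines$half_length)
  }
  surf <- build_surface(curves, lines, n_slices = dim(vol$data)[3L],
                        smooth_px = smooth_px)
  attr(surf, "n_fallback") <-
    sum(vapply(curves, `[[`, character(1), "source") == "fallback")
  attr(surf, "n_fitted") <-
    sum(vapply(curves, `[[`, character(1), "source") == "fitted")
  if (!is.null(k_neighbors)) surf <- estimate_normals(surf, k_neighbors)
  surf
}
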