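#' Mean distance from an arch curve to the true tooth centres
#'
#' @param curve an `arch_curve` in axial pixel coordinates.
#' @param truth a `phantom_truth`.
#' @param n_samples curve sampling density (default 1001).
#' @return mean over teeth of the minimum distance (voxels) from each tooth
#'   centre, projected to the axial plane, to the sampled curve.
#' @export
arch_truth_distance <- function(curve, truth, n_samples = 1001L) {
  u <- seq(0, nrow(curve$control_points) - 1, length.out = n_samples)
  p <- eval_arch_curve(curve, u)
  ctrs <- t(vapply(truth$teeth, function(t) t$center[1:2], numeric(2)))
  mean(vapply(seq_len(nrow(ctrs)), function(i)
    sqrt(min((p[, 1] - ctrs[i, 1])^2 + (p[, 2] - ctrs[i, 2])^2)), 0))
}

#' Distances from ground-truth axis points to the panoramic surface
#'
#' Uses the minimum distance to the surface's valid vertices; at ~1-voxel
#' vertex spacing this upper-bounds the true point-to-mesh distance.
#'
#' @param surf a `panoramic_surface`.
#' @param pts n x 3 matrix, e.g. from [truth_surface_points].
#' @return numeric vector of distances (voxels), one per point.
#' @export
surface_truth_distances <- function(surf, pts) {
  ok <- as.vector(surf$validity)
  vx <- as.vector(surf$X)[ok]; vy <- as.vector(surf$Y)[ok]
  vz <- as.vector(surf$Z)[ok]
  vapply(seq_len(nrow(pts)), function(i)
    sqrt(min((vx - pts[i, 1])^2 + (vy - pts[i, 2])^2 + (vz - pts[i, 3])^2)),
    0)
}

## single sheet at a fixed signed offset along the surface normals
render_offset_sheet <- function(vol, surf, dev, t_off) {
  w <- dev$w
  W <- as.integer(round(w[length(w)])) + 1L
  cols <- seq_len(nrow(surf$X))
  ci <- stats::approx(w, cols, xout = 0:(W - 1), rule = 2, ties = "ordered")$y
  i0 <- pmin(floor(ci), length(cols) - 1L)
  tt <- ci - i0
  Xw <- (1 - tt) * surf$X[i0, ] + tt * surf$X[i0 + 1L, ]
  Yw <- (1 - tt) * surf$Y[i0, ] + tt * surf$Y[i0 + 1L, ]
  Zw <- (1 - tt) * surf$Z[i0, ] + tt * surf$Z[i0 + 1L, ]
  if (t_off != 0) {
    NXw <- (1 - tt) * surf$NX[i0, ] + tt * surf$NX[i0 + 1L, ]
    NYw <- (1 - tt) * surf$NY[i0, ] + tt * surf$NY[i0 + 1L, ]
    NZw <- (1 - tt) * surf$NZ[i0, ] + tt * surf$NZ[i0 + 1L, ]
    nn <- sqrt(NXw^2 + NYw^2 + NZw^2); nn[nn < 1e-12] <- 1
    Xw <- Xw + t_off * NXw / nn
    Yw <- Yw + t_off * NYw / nn
    Zw <- Zw + t_off * NZw / nn
  }
  matrix(trilinear_sample(vol$data, as.vector(Xw), as.vector(Yw),
                          as.vector(Zw)), W, ncol(surf$X))
}

## single cylinder sheet at a fixed horizontal offset from the arch curve
render_cylinder_sheet <- function(vol, curve, t_off) {
  L <- curve$total_length
  W <- as.integer(round(L)) + 1L
  u <- stats::approx(curve$arclength_table$s, curve$arclength_table$u,
                     xout = pmin(0:(W - 1), L), ties = "ordered")$y
  feet <- eval_arch_curve(curve, u)
  d <- eval_arch_curve(curve, u, derivative = TRUE)
  tn <- d / sqrt(rowSums(d^2))
  nrm <- cbind(tn[, 2], -tn[, 1])
  ctr <- colMeans(curve$control_points)
  flip <- rowSums(nrm * sweep(feet, 2, ctr, `-`)) < -1e-9
  nrm[flip, ] <- -nrm[flip, ]
  nz <- dim(vol$data)[3L]
  matrix(trilinear_sample(vol$data,
                          rep(feet[, 1] + t_off * nrm[, 1], times = nz),
                          rep(feet[, 2] + t_off * nrm[, 2], times = nz),
                          rep(0:(nz - 1), each = W)), W, nz)
}

## developed abscissa of each tooth centre: project onto the fitted curve,
## then map arc length to w (identity for the cylinder method)
tooth_abscissas <- function(truth, curve, surf = NULL, dev = NULL) {
  ctrs <- t(vapply(truth$teeth, function(t) t$center[1:2], numeric(2)))
  s <- project_arc_position(curve, ctrs)
  if (is.null(surf)) return(s)
  stats::approx(surf$arc_positions, dev$w, xout = s, rule = 2,
                ties = "ordered")$y
}

## per-tooth truth-mapped windows in the developed plane; the pulp window is
## narrow (the pulp core's own image support) so that partial-volume pixels
## at distant tissue boundaries cannot mimic pulp-band intensities
tooth_windows <- function(truth, tooth_w, img_width, nz,
                          interior_trim = 0.15) {
  lapply(seq_along(truth$teeth), function(k) {
    t <- truth$teeth[[k]]
    e <- capsule_ends(t)
    r <- t$radius
    half_win <- round(r) + 2L
    win <- (round(tooth_w[k]) - half_win):(round(tooth_w[k]) + half_win) + 1L
    win <- win[win >= 1 & win <= img_width]
    pw <- max(2L, round(truth$pulp_radius_vox + 0.5))
    pulp_win <- (round(tooth_w[k]) - pw):(round(tooth_w[k]) + pw) + 1L
    pulp_win <- pulp_win[pulp_win >= 1 & pulp_win <= img_width]
    zmin <- min(e[, 3]); zmax <- max(e[, 3]); zext <- zmax - zmin
    interior <- round(zmin + interior_trim * zext):
                round(zmax - interior_trim * zext)
    interior <- interior[interior >= 0 & interior <= nz - 1]
    tip_z <- e["crown", 3]
    cap <- sort(round(c(tip_z, tip_z - sign(t$axis[3]) * r)))
    crown_rows <- cap[1]:cap[2]
    crown_rows <- crown_rows[crown_rows >= 0 & crown_rows <= nz - 1]
    list(id = t$id, win = win, pulp_win = pulp_win, interior = interior,
         crown = crown_rows)
  })
}

#' Per-tooth dentition coverage of a developed image
#'
#' A tooth counts as fully shown when (a) its crown window contains
#' enamel-band intensity (above the enamel/dentine midpoint) and (b) at
#' least `pulp_frac` of its axis-interior rows contain pulp-band intensity
#' (between the soft-tissue/pulp and pulp/dentine midpoints). Windows are
#' mapped from ground truth by projecting tooth centres onto the fitted
#' arch curve and through the development abscissa.
#'
#' @param img a `developed_image` (or a plain matrix indexed (w, h)).
#' @param truth a `phantom_truth`.
#' @param curve the fitted `arch_curve`.
#' @param surf,dev the panoramic surface and its development; leave NULL for
#'   the cylinder baseline (whose abscissa is the arc length itself).
#' @param pulp_frac required fraction of interior rows showing pulp
#'   (default 0.9).
#' @return data.frame: `id`, `enamel`, `pulp_row_fraction`, `covered`.
#' @export
dentition_coverage <- function(img, truth, curve, surf = NULL, dev = NULL,
                               pulp_frac = 0.9) {
  img_data <- if (inherits(img, "developed_image")) img$data else img
  ii <- truth$intensities
  thr_enamel <- (ii$enamel + ii$dentine) / 2
  pulp_lo <- (ii$soft_tissue + ii$pulp) / 2
  pulp_hi <- (ii$pulp + ii$dentine) / 2
  tw <- tooth_abscissas(truth, curve, surf, dev)
  wins <- tooth_windows(truth, tw, nrow(img_data), ncol(img_data))
  res <- lapply(wins, function(wn) {
    sub_c <- img_data[wn$win, wn$crown + 1L, drop = FALSE]
    enamel <- max(sub_c) >= thr_enamel
    okrow <- vapply(wn$interior, function(z) {
      v <- img_data[wn$pulp_win, z + 1L]
      any(v >= pulp_lo & v <= pulp_hi)
    }, TRUE)
    data.frame(id = wn$id, enamel = enamel,
               pulp_row_fraction = mean(okrow),
               covered = enamel && mean(okrow) >= pulp_frac)
  })
  do.call(rbind, res)
}

#' Minimum slab thickness that shows the whole dentition
#'
#' Renders single sheets at increasing normal offsets and finds the smallest
#' odd slab thickness whose union of sheets fully covers every tooth (crown
#' enamel plus `pulp_frac` of interior pulp rows) under
#' [dentition_coverage]'s intensity banding. This measures the geometric
#' information content of the slab, independent of the averaging used for
#' display.
#'
#' @param vol a [cbct_volume].
#' @param truth a `phantom_truth`.
#' @param curve the fitted `arch_curve`.
#' @param surf,dev surface method inputs; leave NULL for the cylinder
#'   baseline.
#' @param n_max largest slab tried (default 41).
#' @param pulp_frac see [dentition_coverage].
#' @return smallest odd `n` achieving full coverage, or `Inf`.
#' @export
minimum_covering_slab <- function(vol, truth, curve, surf = NULL, dev = NULL,
                                  n_max = 41, pulp_frac = 0.9) {
  half_max <- (n_max - 1) / 2
  ii <- truth$intensities
  pulp_lo <- (ii$soft_tissue + ii$pulp) / 2
  pulp_hi <- (ii$pulp + ii$dentine) / 2
  thr_enamel <- (ii$enamel + ii$dentine) / 2
  if (!is.null(surf)) {
    sheet <- function(t_off) render_offset_sheet(vol, surf, dev, t_off)
    W <- as.integer(round(dev$w[length(dev$w)])) + 1L
  } else {
    sheet <- function(t_off) render_cylinder_sheet(vol, curve, t_off)
    W <- as.integer(round(curve$total_length)) + 1L
  }
  nz <- dim(vol$data)[3L]
  tw <- tooth_abscissas(truth, curve, surf, dev)
  wins <- tooth_windows(truth, tw, W, nz)
  per_off <- lapply(0:half_max, function(o) {
    sheets <- if (o == 0) list(sheet(0)) else list(sheet(-o), sheet(o))
    lapply(wins, function(wn) {
      enamel <- any(vapply(sheets, function(S)
        max(S[wn$win, wn$crown + 1L]) >= thr_enamel, TRUE))
      rows <- vapply(wn$interior, function(z)
        any(vapply(sheets, function(S) {
          v <- S[wn$pulp_win, z + 1L]
          any(v >= pulp_lo & v <= pulp_hi)
        }, TRUE)), TRUE)
      list(enamel = enamel, rows = rows)
    })
  })
  for (half in 0:half_max) {
    covered <- vapply(seq_along(wins), function(ti) {
      en <- any(vapply(0:half + 1L, function(oi) per_off[[oi]][[ti]]$enamel,
                       TRUE))
      rows <- Reduce(`|`, lapply(0:half + 1L,
                                 function(oi) per_off[[oi]][[ti]]$rows))
      en && mean(rows) >= pulp_frac
    }, TRUE)
    if (all(covered)) return(2 * half + 1)
  }
  Inf
}

#' Mandibular-canal visibility in a developed image
#'
#' Maps the canal's ground-truth centreline into the developed plane and
#' tests, per column, (a) whether the canal row shows canal-band intensity
#' (band presence, the single-slice visibility notion) and (b) whether the
#' canal row is a local intensity minimum relative to rows `delta` above and
#' below (the thickened-slab visibility notion).
#'
#' @param img a `developed_image`.
#' @param truth a `phantom_truth` with a canal.
#' @param curve the fitted `arch_curve`.
#' @param surf,dev surface development mapping; NULL for the cylinder image.
#' @param delta row offset for the local-minimum contrast (default 6: must
#'   clear the canal radius plus interpolation smear).
#' @return list: `band_fraction`, `local_min_fraction`, `n_columns`.
#' @export
canal_visibility <- function(img, truth, curve, surf = NULL, dev = NULL,
                             delta = 6) {
  stopifnot(!is.null(truth$canal))
  ii <- truth$intensities
  z_row <- round(truth$canal[1, 3])
  arcs <- vapply(truth$teeth, `[[`, 0, "arc_pos")
  ## canal columns: projection of the canal centreline onto the curve
  step <- max(1L, nrow(truth$canal) %/% 60L)
  cpts <- truth$canal[seq(1, nrow(truth$canal), by = step), 1:2, drop = FALSE]
  s <- project_arc_position(curve, cpts)
  ## drop columns projected onto the curve ends (outside the canal span)
  s <- s[s > min(s) + 2 & s < max(s) - 2]
  wc <- if (is.null(surf)) s else
    stats::approx(surf$arc_positions, dev$w, xout = s, rule = 2,
                  ties = "ordered")$y
  wcols <- unique(round(wc)) + 1L
  wcols <- wcols[wcols >= 1 & wcols <= nrow(img$data)]
  v0 <- img$data[wcols, z_row + 1L]
  vup <- img$data[wcols, min(ncol(img$data), z_row + 1L + delta)]
  vdn <- img$data[wcols, max(1L, z_row + 1L - delta)]
  band_hi <- (ii$soft_tissue + ii$jaw_bone) / 2
  list(band_fraction = mean(v0 <= band_hi),
       local_min_fraction = mean(v0 < vup & v0 < vdn),
       n_columns = length(wcols))
}
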