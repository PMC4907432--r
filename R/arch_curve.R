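#' Segment the bone area of an axial MIP by k-means++ clustering
#'
#' Pixels are clustered into `k` intensity classes and the brightest
#' `top_m` clusters form the bone mask (enamel is the densest tissue in the
#' head, so teeth always land in the top cluster; with `top_m = 1` and a
#' well-separated enamel class the mask is teeth-only, while smaller `k` or
#' larger `top_m` merges jaw bone into the mask, as happens on scans where
#' tooth and jaw intensities are similar).
#'
#' @param mip a [cbct_image], typically from [mip_axial].
#' @param k number of clusters (default 5).
#' @param seed RNG seed for the k-means++ initialisation (default 0).
#' @param top_m number of top clusters counted as bone (default 1).
#' @return list with `mask` (logical matrix), `threshold` (intensity value
#'   separating bone from the rest), `centers` (sorted cluster centres),
#'   `k` (possibly reduced).
#' @export
segment_bone <- function(mip, k = 5, seed = 0, top_m = 1) {
  stopifnot(inherits(mip, "cbct_image"), k >= 2, top_m >= 1, top_m < k)
  km <- kmeanspp_1d(as.vector(mip$data), k, seed)
  top_m <- min(top_m, km$k - 1)
  thr <- km$boundaries[km$k - top_m]
  mask <- mip$data >= thr
  if (!any(mask)) stop("empty bone mask")
  list(mask = mask, threshold = thr, centers = km$centers, k = km$k)
}

#' Spatial quadrangle covering a proportion of a mask
#'
#' Returns the smallest axis-aligned rectangle, centred at the mask centroid
#' and grown with its aspect ratio fixed to the mask's per-axis standard
#' deviations, that contains at least a proportion `p` of mask pixels. The
#' dental arch is narrower than the jaws, so such a centroid-anchored
#' rectangle retains the teeth while discarding posterior jaw bone.
#'
#' @param mask logical matrix.
#' @param p required covered proportion, in (0, 1); default 0.75.
#' @return list with `center` (0-based pixel coords), `half_extents`,
#'   `covered_fraction`.
#' @export
spatial_quadrangle <- function(mask, p = 0.75) {
  stopifnot(is.matrix(mask), any(mask), p > 0, p < 1)
  idx <- which(mask, arr.ind = TRUE) - 1L
  ctr <- colMeans(idx)
  sdv <- pmax(apply(idx, 2, stats::sd), 1e-9)
  tneed <- pmax(abs(idx[, 1] - ctr[1]) / sdv[1],
                abs(idx[, 2] - ctr[2]) / sdv[2])
  tstar <- sort(tneed)[ceiling(p * length(tneed))]
  list(center = unname(ctr), half_extents = unname(tstar * sdv),
       covered_fraction = mean(tneed <= tstar))
}

#' Isolate the dental arch: mask AND quadrangle interior
#'
#' @param mask logical matrix (bone mask).
#' @param quad a quadrangle from [spatial_quadrangle].
#' @return logical matrix.
#' @export
isolate_arch <- function(mask, quad) {
  nx <- nrow(mask); ny <- ncol(mask)
  X <- matrix(0:(nx - 1), nx, ny)
  Y <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)
  inq <- abs(X - quad$center[1]) <= quad$half_extents[1] &
         abs(Y - quad$center[2]) <= quad$half_extents[2]
  out <- mask & inq
  if (!any(out)) stop("no dental arch found: quadrangle disjoint from mask")
  out
}

#' Least-squares parabola fit to mask pixels
#'
#' Fits `y = a x^2 + b x + c` over all mask pixel coordinates in a frame
#' rotated so the mask's principal axis is horizontal (making the fit
#' orientation-invariant); the rotation angle and centre are recorded so the
#' curve can be evaluated in original pixel coordinates.
#'
#' @param mask logical matrix.
#' @return object of class `arch_parabola`: `coef` (a, b, c in the rotated
#'   frame), `angle` (radians), `center` (rotation centre, 0-based),
#'   `x_range` (rotated-frame extent of the mask).
#' @export
fit_parabola <- function(mask) {
  idx <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(idx) < 3) stop("need at least 3 mask pixels")
  ctr <- colMeans(idx)
  cc <- sweep(idx, 2, ctr)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)
  if (ev$values[2] < 1e-9 * max(ev$values[1], 1))
    stop("degenerate mask: pixels are collinear")
  v1 <- ev$vectors[, 1]                       # principal axis
  ang <- atan2(v1[2], v1[1])
  R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
  rot <- cc %*% t(R)
  fit <- stats::lm.fit(cbind(1, rot[, 1], rot[, 1]^2), rot[, 2])
  ab <- fit$coefficients
  if (!is.finite(ab[3]) || abs(ab[3]) < 1e-12)
    stop("degenerate mask: no curvature along the principal axis")
  ## refine by geometric (orthogonal-distance) least squares: the vertical
  ## fit is biased through thick pixel clusters, whose vertical residuals
  ## are centred on the cluster, not on the sloping curve
  ab <- fit_parabola_odr(rot[, 1], rot[, 2],
                         c(ab[1], ab[2], ab[3]))
  pb <- structure(list(coef = c(a = unname(ab[3]), b = unname(ab[2]),
                                c = unname(ab[1])),
                       angle = ang, center = unname(ctr),
                       x_range = range(rot[, 1])),
                  class = "arch_parabola")
  apex <- parabola_points(pb, -pb$coef[2] / (2 * pb$coef[1]))
  if (apex[1] < 0 || apex[1] > nrow(mask) - 1 ||
      apex[2] < 0 || apex[2] > ncol(mask) - 1)
    warning("fitted parabola apex lies outside the image bounds")
  pb
}

## orthogonal-distance parabola fit y = c + b t + a t^2; par = (c, b, a).
## Inner loop projects each point onto the parabola by Newton iteration on
## the foot parameter; outer loop is a derivative-free simplex on (c, b, a).
fit_parabola_odr <- function(x, y, par0) {
  d2sum <- function(par) {
    cc <- par[1]; bb <- par[2]; aa <- par[3]
    t <- x
    for (it in 1:8) {
      ft <- aa * t^2 + bb * t + cc
      fp <- 2 * aa * t + bb
      g <- fp * (ft - y) + (t - x)            # d/dt of squared distance / 2
      gp <- 2 * aa * (ft - y) + fp^2 + 1
      t <- t - g / pmax(gp, 0.5)
    }
    ft <- aa * t^2 + bb * t + cc
    sum((x - t)^2 + (y - ft)^2)
  }
  res <- stats::optim(par0, d2sum, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  res <- stats::optim(res$par, d2sum, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))
  res$par
}

#' Evaluate an `arch_parabola` in original pixel coordinates
#'
#' @param pb an `arch_parabola`.
#' @param xr positions along the rotated-frame abscissa.
#' @return n x 2 matrix of (x, y) pixel coordinates.
#' @export
parabola_points <- function(pb, xr) {
  yr <- pb$coef[1] * xr^2 + pb$coef[2] * xr + pb$coef[3]
  R <- matrix(c(cos(pb$angle), sin(pb$angle),
                -sin(pb$angle), cos(pb$angle)), 2, 2)
  sweep(cbind(xr, yr) %*% t(R), 2, pb$center, `+`)
}

#' Select spline control points on a fitted parabola
#'
#' The middle point sits at the parabola apex; the remaining `n - 1` points
#' are placed at equal arc-length steps symmetrically about the apex, spanning
#' the mask's extent along the curve.
#'
#' @param pb an `arch_parabola` from [fit_parabola].
#' @param mask the mask the parabola was fitted to (its extent along the
#'   curve sets the span).
#' @param n odd number of control points >= 3 (default 7); reduced with a
#'   warning if the arc span is shorter than `n` pixels.
#' @return n x 2 matrix of (x, y) pixel coordinates, ordered along the curve.
#' @export
select_control_points <- function(pb, mask, n = 7) {
  stopifnot(inherits(pb, "arch_parabola"), n >= 3, n %% 2 == 1)
  a <- pb$coef[1]; b <- pb$coef[2]
  apex_x <- -b / (2 * a)
  ## extent of this mask along the rotated-frame abscissa
  idx <- which(mask, arr.ind = TRUE) - 1L
  cc <- sweep(idx, 2, pb$center)
  xr <- cc[, 1] * cos(-pb$angle) - cc[, 2] * sin(-pb$angle)
  pb$x_range <- range(xr)
  ## arc length along the rotated-frame parabola, measured from the apex
  arc_from_apex <- function(x)
    vapply(x, function(xi) {
      xs <- seq(apex_x, xi, length.out = 257L)
      dy <- 2 * a * xs + b
      sum((sqrt(1 + dy^2)[-1] + sqrt(1 + dy^2)[-257]) / 2) * (xi - apex_x) / 256
    }, 0)
  s_lo <- arc_from_apex(pb$x_range[1])
  s_hi <- arc_from_apex(pb$x_range[2])
  s_end <- max(abs(s_lo), abs(s_hi))
  if (2 * s_end < n) {
    n_new <- max(3L, as.integer(2 * floor(s_end) + 1))
    if (n_new %% 2 == 0) n_new <- n_new - 1L
    warning(sprintf("arc span %.1f px too small for %d control points; using %d",
                    2 * s_end, n, n_new))
    n <- n_new
  }
  ## invert s(x) over a dense table
  xs <- seq(apex_x - 1.2 * s_end, apex_x + 1.2 * s_end, length.out = 1025L)
  ss <- arc_from_apex(xs)
  s_targets <- seq(-s_end, s_end, length.out = n)
  x_targets <- stats::approx(ss, xs, xout = s_targets)$y
  parabola_points(pb, x_targets)
}

#' Build a Hermite cubic spline arch curve through control points
#'
#' Piecewise cubic Hermite interpolation with Catmull-Rom tangents (central
#' differences at interior points, one-sided at the ends), C1 at interior
#' control points, with a dense cumulative arc-length table for arc-length
#' parameterisation.
#'
#' @param ctrl n x 2 matrix of control points (n >= 3, no duplicates).
#' @param samples_per_segment arc-length table density (default 128).
#' @return object of class `arch_curve` with fields `control_points`,
#'   `tangents`, `arclength_table` (`u` global parameter, `s` cumulative arc
#'   length), `total_length`.
#' @export
build_hermite_spline <- function(ctrl, samples_per_segment = 128L) {
  ctrl <- as.matrix(ctrl)
  n <- nrow(ctrl)
  stopifnot(n >= 3, ncol(ctrl) == 2)
  if (any(rowSums(abs(diff(ctrl))) < 1e-12))
    stop("duplicate consecutive control points")
  tang <- rbind(ctrl[2, ] - ctrl[1, ],
                (ctrl[-(1:2), , drop = FALSE] -
                 ctrl[seq_len(n - 2), , drop = FALSE]) / 2,
                ctrl[n, ] - ctrl[n - 1, ])
  crv <- structure(list(control_points = ctrl, tangents = tang),
                   class = "arch_curve")
  u <- seq(0, n - 1, length.out = (n - 1) * samples_per_segment + 1)
  p <- eval_arch_curve(crv, u)
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  crv$arclength_table <- list(u = u, s = s)
  crv$total_length <- s[length(s)]
  crv
}

#' Evaluate an arch curve (and optionally its derivative)
#'
#' @param curve an `arch_curve`.
#' @param u global parameter values in `[0, n_segments]` (segment index plus
#'   local position).
#' @param derivative if TRUE return d(point)/du instead of the point.
#' @return length(u) x 2 matrix.
#' @export
eval_arch_curve <- function(curve, u, derivative = FALSE) {
  P <- curve$control_points; M <- curve$tangents
  nseg <- nrow(P) - 1L
  i <- pmin(pmax(floor(u), 0), nseg - 1L)
  t <- u - i
  i <- as.integer(i) + 1L   # 1-based segment start
  t2 <- t * t; t3 <- t2 * t
  if (!derivative) {
    h00 <- 2 * t3 - 3 * t2 + 1; h10 <- t3 - 2 * t2 + t
    h01 <- -2 * t3 + 3 * t2;    h11 <- t3 - t2
  } else {
    h00 <- 6 * t2 - 6 * t; h10 <- 3 * t2 - 4 * t + 1
    h01 <- -6 * t2 + 6 * t; h11 <- 3 * t2 - 2 * t
  }
  h00 * P[i, , drop = FALSE] + h10 * M[i, , drop = FALSE] +
    h01 * P[i + 1L, , drop = FALSE] + h11 * M[i + 1L, , drop = FALSE]
}

#' Sample lines perpendicular to the arch curve
#'
#' Feet are placed at uniform arc-length intervals (by inverting the
#' arc-length table); directions are unit normals of the curve tangent,
#' consistently oriented outward, away from the arch's concave side.
#'
#' @param curve an `arch_curve`.
#' @param step_px arc-length spacing of the feet in pixels (default 1).
#' @param half_length_px half-length of each line (default 20).
#' @return object of class `normal_lines`: matrices `foot` (n x 2) and
#'   `direction` (n x 2), vector `arc_position`, scalar `half_length`.
#' @export
sample_perpendicular_lines <- function(curve, step_px = 1, half_length_px = 20) {
  stopifnot(inherits(curve, "arch_curve"), step_px > 0, half_length_px > 0)
  L <- curve$total_length
  if (step_px > L) {
    warning("step exceeds curve length; returning a single mid-curve line")
    s_pos <- L / 2
  } else {
    s_pos <- seq(0, L, by = step_px)
    if (L - s_pos[length(s_pos)] > step_px / 2) s_pos <- c(s_pos, L)
  }
  u <- stats::approx(curve$arclength_table$s, curve$arclength_table$u,
                     xout = s_pos)$y
  feet <- eval_arch_curve(curve, u)
  d <- eval_arch_curve(curve, u, derivative = TRUE)
  tn <- d / sqrt(rowSums(d^2))
  nrm <- cbind(tn[, 2], -tn[, 1])
  ## orient away from the concave side (the control-point centroid)
  ctr <- colMeans(curve$control_points)
  dots <- rowSums(nrm * sweep(feet, 2, ctr, `-`))
  flip <- dots < -1e-9   # outward: positive dot with (foot - centroid)
  nrm[flip, ] <- -nrm[flip, ]
  structure(list(foot = feet, direction = nrm, arc_position = s_pos,
                 half_length = half_length_px),
            class = "normal_lines")
}

#' Project points onto an arch curve
#'
#' @param curve an `arch_curve`.
#' @param pts n x 2 matrix of axial points.
#' @param n_samples curve sampling density (default 2001).
#' @return numeric vector: arc-length position of the closest curve point
#'   for each input point.
#' @export
project_arc_position <- function(curve, pts, n_samples = 2001L) {
  u <- seq(0, nrow(curve$control_points) - 1, length.out = n_samples)
  p <- eval_arch_curve(curve, u)
  s <- stats::approx(curve$arclength_table$u, curve$arclength_table$s,
                     xout = u, ties = "ordered")$y
  pts <- matrix(pts, ncol = 2)
  vapply(seq_len(nrow(pts)), function(i)
    s[which.min((p[, 1] - pts[i, 1])^2 + (p[, 2] - pts[i, 2])^2)], 0)
}

#' Create the dental arch curve from an axial MIP (pipeline step 1)
#'
#' Chains [segment_bone], [spatial_quadrangle] + [isolate_arch] (optional),
#' [fit_parabola], [select_control_points] and [build_hermite_spline].
#'
#' @param mip a [cbct_image].
#' @param k,seed,top_m passed to [segment_bone].
#' @param p quadrangle coverage proportion (default 0.75).
#' @param n_control_points odd, default 7.
#' @param use_quadrangle disable to study the effect of the spatial
#'   threshold (default TRUE).
#' @return list: `curve` (an `arch_curve`), `parabola`, `mask` (isolated
#'   arch mask), `bone` (segment_bone output), `quad`.
#' @export
create_arch_curve <- function(mip, k = 5, p = 0.75, n_control_points = 7,
                              seed = 0, top_m = 1, use_quadrangle = TRUE) {
  bone <- segment_bone(mip, k = k, seed = seed, top_m = top_m)
  quad <- NULL
  mask <- bone$mask
  if (use_quadrangle) {
    quad <- spatial_quadrangle(mask, p = p)
    mask <- isolate_arch(mask, quad)
  }
  pb <- fit_parabola(mask)
  ## fit on the isolated arch, but span the full bone extent so the curve
  ## reaches the terminal molars the quadrangle may have clipped
  ctrl <- select_control_points(pb, bone$mask, n = n_control_points)
  curve <- build_hermite_spline(ctrl)
  list(curve = curve, parabola = pb, mask = mask, bone = bone, quad = quad)
}
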