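#' Configuration for the synthetic CBCT jaw phantom
#'
#' The phantom is a parabola-shaped dental arch of capsule-shaped teeth
#' (cylinder plus hemispherical caps) with a concentric enamel shell, dentine
#' body and pulp core, embedded in a wider jaw-bone band with posterior
#' ramus wings, all inside a soft-tissue ellipse. Tooth long axes are tilted
#' labially, most strongly at the incisors, which is the geometry that
#' defeats cylinder-projection panoramic synthesis. Every quantity needed by
#' a downstream test (arch coefficients, tooth centres, long-axis vectors,
#' canal path) is closed-form and returned as ground truth.
#'
#' Geometry defaults scale with `dims`; tooth sizes are given in mm and
#' converted through `spacing_mm`. Upper incisors tilt 15 degrees and lower
#' incisors 8 degrees from vertical by default (decreasing linearly to the
#' molar tilt of 0 along the arch), and upper teeth are slightly longer than
#' lower ones, mirroring typical human proclination asymmetry.
#'
#' @param dims integer length-3 volume dimensions (default 160^3).
#' @param spacing_mm isotropic voxel size in mm (default 0.3).
#' @param arch optional parabola coefficients `c(a, b, c)` for
#'   `y = a x^2 + b x + c` in axial voxel coordinates; default is an apex at
#'   `(0.5 nx, 0.72 ny)` dropping `0.2 ny` over a half-span of `0.28 nx`.
#' @param n_teeth_per_jaw teeth per jaw (default 10).
#' @param crown_radius_mm capsule radius (default 1.3).
#' @param tooth_length_lower_mm,tooth_length_upper_mm axis lengths
#'   (defaults 6.3 and 6.9).
#' @param enamel_thickness_mm outer shell thickness (default 0.7,
#'   a typical crown enamel cap; thick enough to survive partial-volume
#'   sampling at 0.3 mm voxels).
#' @param pulp_radius_mm core radius (default 0.42).
#' @param tilt_incisor_upper,tilt_incisor_lower,tilt_molar long-axis tilt
#'   from vertical in degrees, positive = labial (defaults 15, 8, 0).
#' @param intensities named list: `soft_tissue`, `jaw_bone`, `pulp`,
#'   `dentine`, `enamel`; must satisfy
#'   `soft_tissue < jaw_bone <= dentine < enamel` and `pulp < dentine`.
#' @param bite `"open"` (crowns separated by `bite_gap_vox`) or `"closed"`
#'   (upper teeth staggered half a pitch along the arch, crowns overlapping
#'   2 voxels in z).
#' @param bite_gap_vox occlusal gap in voxels for open bite (default 8).
#' @param canal logical, carve a low-intensity mandibular-canal tube
#'   (default FALSE); `canal_offset_vox` voxels lingual of the arch,
#'   radius `canal_radius_mm`.
#' @param canal_offset_vox,canal_radius_mm canal geometry (defaults 10, 0.75).
#' @param jaw_halfwidth_vox half-width of the jaw-bone band (default 14;
#'   wide enough that the canal tube runs inside bone, as it does
#'   anatomically).
#' @param implant logical, replace the last upper tooth by a very-high
#'   intensity capsule (default FALSE).
#' @param noise_sigma sd of additive Gaussian noise in gray units
#'   (default 40 on the 0..2000 default scale).
#' @param seed RNG seed for the noise (default 1).
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(dims = c(160, 160, 160),
                           spacing_mm = 0.3,
                           arch = NULL,
                           n_teeth_per_jaw = 10,
                           crown_radius_mm = 1.3,
                           tooth_length_lower_mm = 6.3,
                           tooth_length_upper_mm = 6.9,
                           enamel_thickness_mm = 0.7,
                           pulp_radius_mm = 0.42,
                           tilt_incisor_upper = 15,
                           tilt_incisor_lower = 8,
                           tilt_molar = 0,
                           intensities = list(soft_tissue = 200,
                                              jaw_bone = 1200,
                                              pulp = 800,
                                              dentine = 1400,
                                              enamel = 2000),
                           bite = c("open", "closed"),
                           bite_gap_vox = 8,
                           canal = FALSE,
                           canal_offset_vox = 10,
                           canal_radius_mm = 0.75,
                           jaw_halfwidth_vox = 14,
                           implant = FALSE,
                           noise_sigma = 40,
                           seed = 1) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 32L), spacing_mm > 0,
            n_teeth_per_jaw >= 2L, noise_sigma >= 0)
  bite <- match.arg(bite)
  ii <- intensities
  if (!(ii$soft_tissue < ii$jaw_bone && ii$jaw_bone <= ii$dentine &&
        ii$dentine < ii$enamel && ii$pulp < ii$dentine))
    stop("intensity ordering violated: need soft_tissue < jaw_bone <= ",
         "dentine < enamel and pulp < dentine")
  if (is.null(arch)) {
    x0 <- (dims[1] - 1) / 2
    half_span <- 0.28 * dims[1]
    drop <- 0.20 * dims[2]
    y0 <- 0.72 * dims[2]
    a <- -drop / half_span^2
    arch <- c(a, -2 * a * x0, y0 + a * x0^2)
    half_span_vox <- half_span
  } else {
    stopifnot(length(arch) == 3L, arch[1] != 0)
    half_span_vox <- 0.28 * dims[1]
  }
  structure(list(
    dims = dims, spacing_mm = spacing_mm, arch = as.numeric(arch),
    half_span_vox = half_span_vox,
    n_teeth_per_jaw = as.integer(n_teeth_per_jaw),
    crown_radius_mm = crown_radius_mm,
    tooth_length_lower_mm = tooth_length_lower_mm,
    tooth_length_upper_mm = tooth_length_upper_mm,
    enamel_thickness_mm = enamel_thickness_mm,
    pulp_radius_mm = pulp_radius_mm,
    tilt_incisor_upper = tilt_incisor_upper,
    tilt_incisor_lower = tilt_incisor_lower,
    tilt_molar = tilt_molar,
    intensities = ii, bite = bite, bite_gap_vox = bite_gap_vox,
    canal = canal, canal_offset_vox = canal_offset_vox,
    canal_radius_mm = canal_radius_mm,
    jaw_halfwidth_vox = jaw_halfwidth_vox,
    implant = implant,
    noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "phantom_config")
}

## parabola helpers (0-based voxel coords)
parab_y <- function(abc, x) abc[1] * x^2 + abc[2] * x + abc[3]
parab_dy <- function(abc, x) 2 * abc[1] * x + abc[2]
parab_apex_x <- function(abc) -abc[2] / (2 * abc[1])

## arc length along the parabola from the apex, and its inverse
parab_arc_table <- function(abc, x_lo, x_hi, n = 2049L) {
  xs <- seq(x_lo, x_hi, length.out = n)
  ds <- sqrt(1 + parab_dy(abc, xs)^2)
  s <- c(0, cumsum((ds[-1] + ds[-n]) / 2 * diff(xs)))
  s0 <- stats::approx(xs, s, xout = parab_apex_x(abc))$y
  list(x = xs, s = s - s0)   # s = 0 at apex
}

## outward (labial) unit normal of the arch at x: away from the arch interior
parab_outward_normal <- function(abc, x) {
  dy <- parab_dy(abc, x)
  nrm <- cbind(-dy, 1) / sqrt(1 + dy^2)  # candidate normal
  ## interior reference point: below the apex for a downward-opening arch
  apex <- c(parab_apex_x(abc), parab_y(abc, parab_apex_x(abc)))
  inside <- apex + c(0, sign(abc[1])) * 0.25 * abs(apex[2])
  p <- cbind(x, parab_y(abc, x))
  flip <- rowSums(nrm * (matrix(inside, nrow(p), 2, byrow = TRUE) - p)) > 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

## per-tooth description table from a config
phantom_teeth <- function(cfg) {
  abc <- cfg$arch
  nx <- cfg$dims[1]; nz <- cfg$dims[3]
  sp <- cfg$spacing_mm
  r <- cfg$crown_radius_mm / sp
  x_apex <- parab_apex_x(abc)
  tab <- parab_arc_table(abc, x_apex - cfg$half_span_vox,
                         x_apex + cfg$half_span_vox)
  s_max <- min(abs(tab$s[1]), abs(tab$s[length(tab$s)]))
  n <- cfg$n_teeth_per_jaw
  pitch <- 2 * s_max / n
  s_lower <- seq(-s_max + pitch / 2, s_max - pitch / 2, length.out = n)
  s_upper <- if (cfg$bite == "closed") {
    ## stagger half a pitch, shifting the trailing tooth to the leading end
    ## so the upper row stays within the arch span
    sort(c(s_lower[1] - pitch / 2, s_lower[-n] + pitch / 2))
  } else s_lower
  mid_z <- (nz - 1) / 2
  gap <- if (cfg$bite == "open") cfg$bite_gap_vox else -2
  teeth <- list()
  id <- 0L
  for (jaw in c("lower", "upper")) {
    ss <- if (jaw == "lower") s_lower else s_upper
    L <- (if (jaw == "lower") cfg$tooth_length_lower_mm
          else cfg$tooth_length_upper_mm) / sp
    tilt_inc <- if (jaw == "lower") cfg$tilt_incisor_lower
                else cfg$tilt_incisor_upper
    for (s in ss) {
      id <- id + 1L
      x <- stats::approx(tab$s, tab$x, xout = s)$y
      y <- parab_y(abc, x)
      n_out <- parab_outward_normal(abc, x)[1, ]
      tilt <- cfg$tilt_molar +
        (tilt_inc - cfg$tilt_molar) * (1 - abs(s) / s_max)
      th <- tilt * pi / 180
      zsgn <- if (jaw == "lower") 1 else -1   # crown points toward bite plane
      v <- c(sin(th) * n_out, zsgn * cos(th)) # unit, root -> crown
      tip_z <- if (jaw == "lower") mid_z - gap / 2 else mid_z + gap / 2
      cz <- tip_z - zsgn * (L / 2) * cos(th)
      ctr <- c(x, y, cz)
      teeth[[id]] <- list(id = id, jaw = jaw, center = ctr, axis = v,
                          length = L, radius = r, arc_pos = s, tilt = tilt)
    }
  }
  teeth
}

#' Generate a synthetic CBCT jaw phantom
#'
#' Renders the phantom described by a [phantom_config] and returns both the
#' volume and the exact ground truth needed for parameter-recovery tests.
#' Deterministic for a fixed seed; the seed affects only the additive noise,
#' so zero-noise phantoms are identical across seeds.
#'
#' @param cfg a [phantom_config].
#' @return list with elements `volume` (a [cbct_volume]) and `truth`
#'   (a `phantom_truth` list: arch coefficients, per-tooth centre / long-axis
#'   unit vector / id / arc position, canal centreline polyline, bite gap,
#'   intensities).
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  nx <- cfg$dims[1]; ny <- cfg$dims[2]; nz <- cfg$dims[3]
  sp <- cfg$spacing_mm
  ii <- cfg$intensities
  vol <- array(0, dim = cfg$dims)
  X <- matrix(0:(nx - 1), nx, ny)
  Y <- matrix(0:(ny - 1), nx, ny, byrow = TRUE)

  ## soft-tissue ellipse (full z range)
  ex <- (nx - 1) / 2; ey <- 0.5 * (ny - 1)
  sa <- 0.4875 * nx; sb <- 0.47 * ny
  soft2d <- ((X - ex) / sa)^2 + ((Y - ey) / sb)^2 <= 1
  idx_soft <- which(soft2d)
  plane <- as.double(nx) * ny
  vol[as.vector(outer(idx_soft, (0:(nz - 1)) * plane, "+"))] <- ii$soft_tissue

  ## jaw-bone band following the arch + posterior ramus wings
  abc <- cfg$arch
  yc <- parab_y(abc, X[, 1])
  band2d <- abs(sweep(Y, 1, yc)) <= cfg$jaw_halfwidth_vox &
    abs(X - ex) <= 0.362 * nx
  rami2d <- abs(X - ex) >= 0.3125 * nx & abs(X - ex) <= 0.40 * nx &
    Y >= 0.24 * ny & Y <= 0.41 * ny
  jaw2d <- (band2d | rami2d) & soft2d
  idx_jaw <- which(jaw2d)
  mid_z <- (nz - 1) / 2
  z_mand <- seq(max(0, round(mid_z - 0.275 * nz)), round(mid_z - 0.05 * nz))
  z_max  <- seq(round(mid_z + 0.05 * nz), min(nz - 1, round(mid_z + 0.275 * nz)))
  vol[as.vector(outer(idx_jaw, z_mand * plane, "+"))] <- ii$jaw_bone
  vol[as.vector(outer(idx_jaw, z_max * plane, "+"))] <- ii$jaw_bone

  ## mandibular canal: tube along the arch offset lingually, below the roots
  canal_pts <- NULL
  if (isTRUE(cfg$canal)) {
    x_apex <- parab_apex_x(abc)
    xs <- seq(x_apex - cfg$half_span_vox, x_apex + cfg$half_span_vox,
              length.out = 257L)
    nrm <- parab_outward_normal(abc, xs)
    cx <- xs - cfg$canal_offset_vox * nrm[, 1]
    cy <- parab_y(abc, xs) - cfg$canal_offset_vox * nrm[, 2]
    cz <- mid_z - 0.2 * nz
    canal_pts <- cbind(cx, cy, rep(cz, length(cx)))
    cr <- cfg$canal_radius_mm / sp
    bx <- range(cx); by <- range(cy)
    gx <- max(0, floor(bx[1] - cr - 1)):min(nx - 1, ceiling(bx[2] + cr + 1))
    gy <- max(0, floor(by[1] - cr - 1)):min(ny - 1, ceiling(by[2] + cr + 1))
    G <- expand.grid(x = gx, y = gy)
    d2min <- rep(Inf, nrow(G))
    for (i in seq_len(nrow(canal_pts))) {
      d2 <- (G$x - canal_pts[i, 1])^2 + (G$y - canal_pts[i, 2])^2
      d2min <- pmin(d2min, d2)
    }
    gz <- max(0, floor(cz - cr)):min(nz - 1, ceiling(cz + cr))
    for (z in gz) {
      keep <- d2min + (z - cz)^2 <= cr^2
      if (any(keep))
        vol[(G$x[keep] + 1) + nx * G$y[keep] + plane * z] <- ii$soft_tissue
    }
  }

  ## teeth: concentric capsules (pulp core, dentine body, enamel shell)
  teeth <- phantom_teeth(cfg)
  r <- cfg$crown_radius_mm / sp
  r_den <- r - cfg$enamel_thickness_mm / sp
  r_pulp <- cfg$pulp_radius_mm / sp
  ## closed bite: verify staggering keeps enamel shells disjoint
  if (cfg$bite == "closed") {
    ctrs <- t(vapply(teeth, `[[`, numeric(3), "center"))
    jaws <- vapply(teeth, `[[`, character(1), "jaw")
    for (i in which(jaws == "lower")) for (j in which(jaws == "upper")) {
      d <- seg_seg_dist(capsule_ends(teeth[[i]]), capsule_ends(teeth[[j]]))
      if (d < 2 * r)
        stop("closed-bite enamel shells would intersect (teeth ",
             teeth[[i]]$id, ", ", teeth[[j]]$id,
             "); reduce crown_radius_mm or n_teeth_per_jaw")
    }
  }
  bad <- integer(0)
  for (t in teeth) {
    e <- capsule_ends(t)
    if (any(pmin(e[1, ], e[2, ]) - r < 0) ||
        any(pmax(e[1, ], e[2, ]) + r > cfg$dims - 1))
      bad <- c(bad, t$id)
  }
  if (length(bad))
    stop("teeth overlap the volume boundary: ids ",
         paste(bad, collapse = ", "))
  n_low <- cfg$n_teeth_per_jaw
  for (t in teeth) {
    e <- capsule_ends(t)
    is_implant <- isTRUE(cfg$implant) && t$id == 2L * n_low
    gx <- floor(min(e[, 1]) - r):ceiling(max(e[, 1]) + r)
    gy <- floor(min(e[, 2]) - r):ceiling(max(e[, 2]) + r)
    gz <- floor(min(e[, 3]) - r):ceiling(max(e[, 3]) + r)
    G <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    d <- point_seg_dist(G, e[1, ], e[2, ])
    lin <- (G[, 1] + 1) + nx * G[, 2] + plane * G[, 3]
    if (is_implant) {
      vol[lin[d <= r]] <- 2 * ii$enamel
    } else {
      vol[lin[d <= r]] <- ii$enamel
      vol[lin[d <= r_den]] <- ii$dentine
      vol[lin[d <= r_pulp]] <- ii$pulp
    }
  }

  if (cfg$noise_sigma > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(cfg$seed)
    vol <- vol + array(stats::rnorm(length(vol), 0, cfg$noise_sigma),
                       dim = dim(vol))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  truth <- structure(list(
    arch = abc, teeth = teeth, canal = canal_pts,
    bite = cfg$bite,
    bite_gap_vox = if (cfg$bite == "open") cfg$bite_gap_vox else -2,
    intensities = ii, dims = cfg$dims, spacing_mm = sp,
    crown_radius_vox = r, pulp_radius_vox = r_pulp),
    class = "phantom_truth")
  list(volume = cbct_volume(vol, spacing = rep(sp, 3)), truth = truth)
}

## root-apex / crown-tip endpoints of a tooth capsule axis
capsule_ends <- function(t) {
  rbind(root = t$center - (t$length / 2) * t$axis,
        crown = t$center + (t$length / 2) * t$axis)
}

## distance from points (n x 3) to segment AB
point_seg_dist <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  ap <- sweep(p, 2, a)
  tt <- pmin(1, pmax(0, (ap %*% ab) / len2))
  dd <- ap - tt %*% t(ab)
  sqrt(rowSums(dd^2))
}

## min distance between two segments (each 2 x 3), by dense sampling
seg_seg_dist <- function(e1, e2, n = 33L) {
  tt <- seq(0, 1, length.out = n)
  p1 <- cbind(e1[1,1] + tt * (e1[2,1] - e1[1,1]),
              e1[1,2] + tt * (e1[2,2] - e1[1,2]),
              e1[1,3] + tt * (e1[2,3] - e1[1,3]))
  min(point_seg_dist(p1, e2[1, ], e2[2, ]))
}

#' Sample points along every tooth's true long axis
#'
#' @param truth a `phantom_truth`.
#' @param samples_per_tooth integer >= 2; points are spaced uniformly from
#'   root apex to crown tip.
#' @return numeric matrix (`n_teeth * samples_per_tooth`) x 3, with a
#'   `tooth_id` attribute.
#' @export
truth_surface_points <- function(truth, samples_per_tooth = 9) {
  stopifnot(inherits(truth, "phantom_truth"), samples_per_tooth >= 2)
  tt <- seq(0, 1, length.out = samples_per_tooth)
  pts <- lapply(truth$teeth, function(t) {
    e <- capsule_ends(t)
    cbind(e[1, 1] + tt * (e[2, 1] - e[1, 1]),
          e[1, 2] + tt * (e[2, 2] - e[1, 2]),
          e[1, 3] + tt * (e[2, 3] - e[1, 3]))
  })
  out <- do.call(rbind, pts)
  attr(out, "tooth_id") <- rep(vapply(truth$teeth, `[[`, integer(1), "id"),
                               each = samples_per_tooth)
  out
}

#' Write / read phantom ground truth as JSON
#'
#' @param truth a `phantom_truth`.
#' @param path JSON path.
#' @return `path` invisibly; `read_phantom_truth` returns a `phantom_truth`.
#' @export
write_phantom_truth <- function(truth, path) {
  stopifnot(inherits(truth, "phantom_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_phantom_truth
#' @export
read_phantom_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$teeth <- lapply(seq_len(nrow(x$teeth)), function(i) {
    t <- as.list(x$teeth[i, ])
    t$center <- unlist(t$center); t$axis <- unlist(t$axis)
    t
  })
  if (!is.null(x$canal)) x$canal <- as.matrix(x$canal)
  x$dims <- as.integer(unlist(x$dims))
  x$arch <- as.numeric(unlist(x$arch))
  structure(x, class = "phantom_truth")
}
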