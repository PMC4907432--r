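## tiny helper: a normal_lines object for hand-built geometry
make_lines <- function(foot, direction, half_length = 5) {
  arc <- if (nrow(foot) > 1)
    c(0, cumsum(sqrt(rowSums(diff(foot)^2)))) else 0
  structure(list(foot = foot, direction = direction, arc_position = arc,
                 half_length = half_length), class = "normal_lines")
}

test_that("sections reproduce the volume exactly along grid axes", {
  vol <- cbct_volume(array(7, dim = c(12, 12, 6)))
  lines <- make_lines(matrix(c(6, 6), 1), matrix(c(0, 1), 1), half_length = 4)
  sec <- extract_section(vol, lines, 1)
  expect_true(all(sec$data == 7))
  expect_equal(dim(sec$data), c(9, 6))
  ## axis-aligned line through integer coordinates copies the voxel plane
  arr <- array(seq_len(12 * 12 * 6), dim = c(12, 12, 6))
  vol2 <- cbct_volume(arr)
  sec2 <- extract_section(vol2, lines, 1)
  expect_equal(sec2$data, arr[7, 3:11, ], ignore_attr = TRUE)
})

test_that("a 45-degree section interpolates with hand-computed bilinear weights", {
  ## checkerboard in (x, y): value = (x + y) mod 2
  arr <- array(0, dim = c(9, 9, 2))
  for (x in 0:8) for (y in 0:8) arr[x + 1, y + 1, ] <- (x + y) %% 2
  vol <- cbct_volume(arr)
  d <- c(1, 1) / sqrt(2)
  lines <- make_lines(matrix(c(4, 4), 1), matrix(d, 1), half_length = 2)
  sec <- extract_section(vol, lines, 1)
  ## sample at u = 1: position (4.707, 4.707) straddles corners with checker
  ## values 0, 1, 1, 0, so the bilinear mix is 2 fx (1 - fx)
  fx <- 1 / sqrt(2)
  expected <- 2 * fx * (1 - fx)
  expect_equal(sec$data[4, 1], expected, tolerance = 1e-12)
  expect_equal(sec$data[2, 1], expected, tolerance = 1e-12)  # u = -1
})

test_that("section segmentation finds enamel, drops speckles, and flags empties", {
  ph <- small_phantom()
  st <- fixture("small_steps", function() run_steps(small_phantom()))
  t1 <- ph$truth$teeth[[1]]
  s1 <- project_arc_position(st$arch$curve, matrix(t1$center[1:2], 1))
  i1 <- which.min(abs(st$lines$arc_position - s1))
  sec <- extract_section(ph$volume, st$lines, i1)
  m1 <- segment_teeth_section(sec, k = 4, seed = 0)
  expect_false(attr(m1, "empty"))
  ## mask is a superset of the pure-enamel pixels of the section
  expect_true(all(m1[sec$data == ph$truth$intensities$enamel]))
  m2 <- segment_teeth_section(sec, k = 4, seed = 0)
  expect_identical(m1, m2)
  const <- structure(list(data = matrix(1, 11, 10), u = -5:5,
                          foot = c(0, 0), direction = c(0, 1),
                          arc_position = 0, half_length = 5),
                     class = "section_image")
  me <- segment_teeth_section(const, k = 4, seed = 0)
  expect_true(attr(me, "empty"))
})

test_that("polynomial long-axis fits recover exact data and degenerate bars", {
  ## pixels exactly on u(z) = 0.001 z^3 - 0.2 z + 3 within a 41-wide section
  hl <- 20
  zz <- 0:60
  uu <- round(0.001 * (zz - 30)^2 - 0.1 * (zz - 30) + 3)
  mask <- matrix(FALSE, 2 * hl + 1, 61)
  mask[cbind(uu + hl + 1, zz + 1)] <- TRUE
  fit <- fit_long_axial_curve(mask, degree = 5, half_length = hl)
  expect_equal(fit$source, "fitted")
  expect_lt(max(abs(fit$u_of_z(zz) - (uu))), 0.6)   # integer-rounded input
  ## exact recovery: symmetric straddle around a line is fitted exactly
  ## (the quintic basis contains it and residuals cancel pairwise)
  z2 <- 0:30
  u_line <- z2 - 15
  mask2 <- matrix(FALSE, 2 * hl + 1, 31)
  mask2[cbind(u_line + 1 + hl + 1, z2 + 1)] <- TRUE
  mask2[cbind(u_line - 1 + hl + 1, z2 + 1)] <- TRUE
  fit2 <- fit_long_axial_curve(mask2, degree = 5, half_length = hl)
  expect_equal(fit2$u_of_z(5:25), u_line[6:26], tolerance = 1e-8,
               ignore_attr = TRUE)
  ## vertical bar mask -> constant at the bar centre
  bar <- matrix(FALSE, 2 * hl + 1, 40)
  bar[hl + 4, ] <- TRUE
  fbar <- fit_long_axial_curve(bar, degree = 5, half_length = hl)
  expect_equal(unique(round(fbar$u_of_z(0:39), 9)), 3)
  ## too few rows -> fallback
  thin <- matrix(FALSE, 2 * hl + 1, 40); thin[hl, 5:7] <- TRUE
  expect_equal(fit_long_axial_curve(thin, degree = 5, half_length = hl)$source,
               "fallback")
})

test_that("surface assembly: planar strip, midpoint interpolation, verticality", {
  hl <- 5
  bar_mask <- function(u) {
    m <- matrix(FALSE, 2 * hl + 1, 30)
    m[u + hl + 1, ] <- TRUE
    m
  }
  c_plus <- fit_long_axial_curve(bar_mask(2), 1, hl)
  c_minus <- fit_long_axial_curve(bar_mask(-2), 1, hl)
  c_fb <- structure(list(source = "fallback", degree = 1),
                    class = "long_axial_curve")
  lines <- make_lines(foot = cbind(c(0, 1, 2), c(0, 0, 0)),
                      direction = cbind(c(0, 0, 0), c(1, 1, 1)), hl)
  surf <- build_surface(list(c_plus, c_fb, c_minus), lines, n_slices = 30,
                        smooth_px = 0)
  expect_equal(surf$source, c("fitted", "interpolated", "fitted"))
  expect_equal(unique(as.vector(surf$U[2, ])), 0)  # midpoint of +2 and -2
  expect_true(all(surf$validity))
  ## two identical vertical columns give a planar quad strip
  surf2 <- build_surface(list(c_plus, c_plus), make_lines(
    cbind(c(0, 1), c(0, 0)), cbind(c(0, 0), c(1, 1)), hl), 30, smooth_px = 0)
  expect_equal(ncol(unique(cbind(as.vector(surf2$Y)))), 1)
  ## verticality: every column's (x, y) lies along its own line
  st <- tilt_steps()
  s <- st$surf
  for (i in seq(1, nrow(s$X), by = 20)) {
    dx <- s$X[i, ] - s$lines$foot[i, 1]
    dy <- s$Y[i, ] - s$lines$foot[i, 2]
    cross <- dx * s$lines$direction[i, 2] - dy * s$lines$direction[i, 1]
    expect_lt(max(abs(cross)), 1e-9)
  }
  expect_error(build_surface(list(c_fb, c_fb), make_lines(
    cbind(c(0, 1), c(0, 0)), cbind(c(0, 0), c(1, 1)), hl), 30), "no teeth")
})

test_that("PCA normals: planar patches, analytic cylinder, outward orientation", {
  ## planar surface tilted in y-z
  n <- 15; m <- 20
  X <- matrix(rep(seq_len(n), m), n, m)
  Y <- matrix(rep(seq_len(m), each = n) * 0.5, n, m)
  Z <- matrix(rep(seq_len(m), each = n), n, m)
  surf <- synthetic_surface(X, Y, Z,
                            directions = cbind(rep(0, n), rep(1, n)))
  surf <- estimate_normals(surf, 9)
  pn <- c(0, 1, -0.5) / sqrt(1.25)
  expect_lt(max(abs(surf$NX)), 1e-6)
  expect_lt(max(abs(surf$NY - pn[2])), 1e-6)
  expect_lt(max(abs(surf$NZ - pn[3])), 1e-6)
  ## right cylinder: normals horizontal and radial
  th <- seq(0.3 * pi, 0.7 * pi, length.out = 41)
  r <- 40
  Xc <- matrix(rep(60 + r * cos(th), 12), 41, 12)
  Yc <- matrix(rep(20 + r * sin(th), 12), 41, 12)
  Zc <- matrix(rep(seq_len(12), each = 41), 41, 12)
  dirs <- cbind(cos(th), sin(th))
  sc <- estimate_normals(synthetic_surface(Xc, Yc, Zc, dirs), 9)
  expect_lt(max(abs(sc$NZ)), 1e-6)
  radial <- abs(sc$NX * cos(th) + sc$NY * sin(th))
  expect_lt(max(abs(radial - 1)), 1e-3)
  dots <- sc$NX * cos(th) + sc$NY * sin(th)
  expect_true(all(dots > 0))
  ## unit length everywhere
  expect_equal(max(abs(sc$NX^2 + sc$NY^2 + sc$NZ^2 - 1)), 0, tolerance = 1e-9)
})

test_that("PLY export writes a consistent ASCII mesh", {
  st <- fixture("small_steps", function() run_steps(small_phantom()))
  path <- withr::local_tempfile(fileext = ".ply")
  write_surface_ply(st$surf, path)
  hdr <- readLines(path, n = 12)
  expect_equal(hdr[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", hdr, value = TRUE)))
  expect_equal(nv, nrow(st$surf$X) * ncol(st$surf$X))
  nf <- as.integer(sub("element face ", "", grep("element face", hdr, value = TRUE)))
  expect_gt(nf, 0)
})

test_that("coarse-to-fine line spacing does not hurt surface accuracy", {
  ph <- tilt_phantom()
  pts <- truth_surface_points(ph$truth, 9)
  st10 <- run_steps(ph, step_px = 10)
  st1 <- tilt_steps()
  d10 <- mean(surface_truth_distances(st10$surf, pts))
  d1 <- mean(surface_truth_distances(st1$surf, pts))
  expect_lte(d1, d10 + 1e-9)
})
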