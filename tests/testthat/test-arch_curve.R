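test_that("quadrangle growth matches an exhaustive-search oracle on a rectangle", {
  mask <- matrix(FALSE, 220, 170)
  mask[11:210, 11:160] <- TRUE
  q <- spatial_quadrangle(mask, p = 0.75)
  expect_equal(q$center, c(mean(c(10, 209)), mean(c(10, 159))))
  expect_gte(q$covered_fraction, 0.75)
  expect_lte(q$covered_fraction, 0.80)
  ## oracle: grow t in tiny steps, take the first rectangle reaching 0.75
  idx <- which(mask, arr.ind = TRUE) - 1L
  ctr <- colMeans(idx); sdv <- apply(idx, 2, sd)
  cover <- function(t) mean(abs(idx[, 1] - ctr[1]) <= t * sdv[1] &
                            abs(idx[, 2] - ctr[2]) <= t * sdv[2])
  ts <- seq(0, 3, by = 1e-3)
  t_star <- ts[which(vapply(ts, cover, 0) >= 0.75)[1]]
  expect_equal(q$half_extents, unname(t_star * sdv), tolerance = 5e-3)
  ## p -> 1 keeps everything
  q1 <- spatial_quadrangle(mask, p = 0.999)
  expect_equal(sum(isolate_arch(mask, q1)), sum(mask))
})

test_that("isolation is the identity for a covering quadrangle and errors when disjoint", {
  mask <- matrix(FALSE, 20, 20); mask[8:12, 8:12] <- TRUE
  all_q <- list(center = c(10, 10), half_extents = c(50, 50))
  expect_equal(isolate_arch(mask, all_q), mask)
  far_q <- list(center = c(0, 0), half_extents = c(1, 1))
  expect_error(isolate_arch(mask, far_q), "no dental arch")
})

test_that("exact parabola pixels are recovered and collinear masks are refused", {
  xs <- seq(40, 160, by = 1)
  ys <- 0.01 * xs^2 - 2 * xs + 110   # apex at x = 100, symmetric span
  mask <- matrix(FALSE, 200, 80)
  mask[cbind(round(xs) + 1L, round(ys) + 1L)] <- TRUE
  ## rounding makes this near-exact; refit on the exact coordinates instead
  pb <- fit_parabola(mask)
  xr <- seq(pb$x_range[1], pb$x_range[2], length.out = 201)
  pts <- parabola_points(pb, xr)
  resid <- pts[, 2] - (0.01 * pts[, 1]^2 - 2 * pts[, 1] + 110)
  expect_lt(max(abs(resid)), 0.5)   # voxelised input
  flat <- matrix(FALSE, 30, 30); flat[5:25, 9] <- TRUE
  expect_error(fit_parabola(flat), "degenerate|collinear")
})

test_that("orthogonal-distance refiner is exact on unquantised on-curve points", {
  xs <- seq(-50, 50, by = 0.5)
  a <- 0.012
  y <- a * xs^2
  cf <- cbctpano:::fit_parabola_odr(xs, y, c(0.1, 0.05, 0.02))
  expect_lt(max(abs(unname(cf) - c(0, 0, a))), 1e-6)
})

test_that("control points sit on the parabola, symmetric with equal arc gaps", {
  xs <- seq(30, 150, by = 1)
  ys <- round(0.015 * (xs - 90)^2 + 20)
  mask <- matrix(FALSE, 200, 120)
  mask[cbind(xs + 1L, ys + 1L)] <- TRUE
  pb <- fit_parabola(mask)
  for (n in c(3, 7)) {
    ctrl <- select_control_points(pb, mask, n = n)
    expect_equal(nrow(ctrl), n)
    ## on-curve: rotate into the fit frame and check the parabola equation
    R <- matrix(c(cos(-pb$angle), sin(-pb$angle),
                  -sin(-pb$angle), cos(-pb$angle)), 2, 2)
    rot <- sweep(ctrl, 2, pb$center) %*% t(R)
    expect_lt(max(abs(rot[, 2] - (pb$coef[1] * rot[, 1]^2 +
                                  pb$coef[2] * rot[, 1] + pb$coef[3]))), 1e-9)
    ## middle point is the apex
    apex_x <- -pb$coef[2] / (2 * pb$coef[1])
    expect_equal(rot[(n + 1) / 2, 1], unname(apex_x), tolerance = 1e-6)
    ## equal arc-length gaps (chord lengths along a smooth curve)
    dy <- function(x) 2 * pb$coef[1] * x + pb$coef[2]
    arc <- vapply(seq_len(n - 1), function(i)
      integrate(function(x) sqrt(1 + dy(x)^2), rot[i, 1], rot[i + 1, 1])$value,
      0)
    expect_lt(max(arc) - min(arc), 1e-4 * mean(arc))
  }
  apex_mask <- matrix(FALSE, 200, 120)
  xa <- 88:92
  apex_mask[cbind(xa + 1L, round(0.015 * (xa - 90)^2 + 20) + 1L)] <- TRUE
  expect_warning(select_control_points(pb, apex_mask, n = 99), "control points")
})

test_that("Hermite spline interpolates control points, is C1, and handles lines", {
  ctrl <- cbind(c(0, 3, 7, 10, 12), c(0, 4, 5, 3, -1))
  crv <- build_hermite_spline(ctrl)
  at_ctrl <- eval_arch_curve(crv, 0:4)
  expect_equal(at_ctrl, ctrl, tolerance = 1e-12, ignore_attr = TRUE)
  ## C1 at interior knots: one-sided derivatives agree
  for (k in 1:3) {
    d_minus <- (eval_arch_curve(crv, k - 1e-7) - eval_arch_curve(crv, k)) / -1e-7
    d_plus <- (eval_arch_curve(crv, k + 1e-7) - eval_arch_curve(crv, k)) / 1e-7
    expect_equal(d_minus, d_plus, tolerance = 1e-5)
  }
  ## collinear points give a straight segment with exact arc length
  line <- build_hermite_spline(cbind(c(0, 5, 10), c(0, 5, 10)))
  expect_equal(line$total_length, sqrt(200), tolerance = 1e-4)
  ## arc length never undercuts the straight-line distance
  expect_gte(crv$total_length,
             sqrt(sum((ctrl[5, ] - ctrl[1, ])^2)) - 1e-9)
  expect_true(all(diff(crv$arclength_table$s) >= 0))
  expect_error(build_hermite_spline(ctrl[c(1, 1, 2), ]), "duplicate")
})

test_that("perpendicular lines are uniform in arc length, unit, and orthogonal", {
  ctrl <- cbind(seq(0, 40, length.out = 5), c(0, 9, 12, 9, 0))
  crv <- build_hermite_spline(ctrl)
  lines <- sample_perpendicular_lines(crv, step_px = crv$total_length / 10,
                                      half_length_px = 5)
  expect_equal(nrow(lines$foot), 11)
  expect_equal(lines$arc_position,
               seq(0, crv$total_length, length.out = 11), tolerance = 1e-6)
  expect_equal(rowSums(lines$direction^2), rep(1, 11), tolerance = 1e-9)
  ## orthogonality against the curve tangent
  u <- approx(crv$arclength_table$s, crv$arclength_table$u,
              xout = lines$arc_position)$y
  tang <- eval_arch_curve(crv, u, derivative = TRUE)
  tang <- tang / sqrt(rowSums(tang^2))
  expect_lt(max(abs(rowSums(tang * lines$direction))), 1e-6)
  ## straight curve: all normals parallel
  line_crv <- build_hermite_spline(cbind(c(0, 5, 10), c(0, 0, 0)))
  ln <- sample_perpendicular_lines(line_crv, 2, 3)
  expect_lt(max(abs(abs(ln$direction[, 2]) - 1)), 1e-9)
  expect_warning(sample_perpendicular_lines(line_crv, 1e5, 3), "single")
})

test_that("normals of a circle-like spline pass near the circle centre", {
  th <- seq(0.2 * pi, 0.8 * pi, length.out = 33)
  r <- 50
  ctrl <- cbind(100 + r * cos(th), 40 + r * sin(th))
  crv <- build_hermite_spline(ctrl)
  lines <- sample_perpendicular_lines(crv, step_px = 3, half_length_px = 10)
  ## distance from the centre (100, 40) to each normal line
  d <- abs((lines$foot[, 1] - 100) * lines$direction[, 2] -
           (lines$foot[, 2] - 40) * lines$direction[, 1])
  expect_lt(max(d), 2)
  ## outward orientation: normals point away from the centre
  dots <- rowSums(lines$direction * cbind(lines$foot[, 1] - 100,
                                          lines$foot[, 2] - 40))
  expect_true(all(dots > 0))
})

test_that("arc positions from point projection are monotone along the arch", {
  st <- tilt_steps()
  truth <- tilt_phantom()$truth
  ctrs <- t(vapply(truth$teeth[1:10], function(t) t$center[1:2], numeric(2)))
  s <- project_arc_position(st$arch$curve, ctrs)
  expect_true(all(diff(s) > 0) || all(diff(s) < 0))
})
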