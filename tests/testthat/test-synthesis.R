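test_that("development applies the cumulative arc-length rule", {
  ## three columns with segment lengths 3 and 4 -> w = (0, 3, 7)
  X <- matrix(c(0, 3, 3), 3, 5)
  Y <- matrix(c(0, 0, 4), 3, 5)
  Z <- matrix(rep(0:4, each = 3), 3, 5)
  dev <- develop_surface(synthetic_surface(X, Y, Z))
  expect_equal(dev$w, c(0, 3, 7))
  expect_equal(dev$h, 0:4)
})

test_that("development is isometric, additive, and non-decreasing", {
  set.seed(31)
  n <- 25
  X <- matrix(cumsum(runif(n, 0.5, 2)), n, 7)
  Y <- matrix(rnorm(n, 0, 3), n, 7)
  Z <- matrix(rep(0:6, each = n), n, 7)
  surf <- synthetic_surface(X, Y, Z)
  dev <- develop_surface(surf)
  j <- 4  # mid row of 7
  seg <- sqrt(diff(X[, j])^2 + diff(Y[, j])^2 + diff(Z[, j])^2)
  expect_equal(diff(dev$w), seg, tolerance = 1e-12)
  expect_true(all(diff(dev$w) >= 0))
  ## additivity: develop [1..m] and [m..n], concatenate
  m <- 11
  d1 <- develop_surface(synthetic_surface(X[1:m, ], Y[1:m, ], Z[1:m, ]))
  d2 <- develop_surface(synthetic_surface(X[m:n, ], Y[m:n, ], Z[m:n, ]))
  expect_equal(c(d1$w, d1$w[m] + d2$w[-1]), dev$w, tolerance = 1e-9)
  ## per-row-mean variant exists and matches for row-independent geometry
  devm <- develop_surface(surf, reference_row = "per_row_mean")
  expect_equal(devm$w, dev$w, tolerance = 1e-9)
})

test_that("flat and cylindrical surfaces develop isometrically", {
  ## planar surface: width equals the straight arch length
  n <- 101
  X <- matrix(seq(2, 62, length.out = n), n, 9)
  Y <- matrix(5, n, 9)
  Z <- matrix(rep(0:8, each = n), n, 9)
  dev <- develop_surface(synthetic_surface(X, Y, Z))
  expect_equal(dev$w[n], 60, tolerance = 1e-9)
  ## semicircular cylinder of radius r develops to width ~ pi r
  r <- 40
  th <- seq(0, pi, length.out = 257)
  Xc <- matrix(rep(60 + r * cos(th), 9), 257, 9)
  Yc <- matrix(rep(10 + r * sin(th), 9), 257, 9)
  Zc <- matrix(rep(0:8, each = 257), 257, 9)
  devc <- develop_surface(synthetic_surface(Xc, Yc, Zc))
  expect_lt(abs(devc$w[257] - pi * r) / (pi * r), 0.005)
})

test_that("constant volumes render constant panoramas in all renderers", {
  vol <- cbct_volume(array(3, dim = c(40, 40, 12)))
  st <- fixture("small_steps", function() run_steps(small_phantom()))
  ## reuse the real surface but sample a constant volume of matching size
  volc <- cbct_volume(array(3, dim = dim(small_phantom()$volume$data)))
  img <- render_single_slice(volc, st$surf, st$dev)
  expect_equal(range(img$data), c(3, 3), tolerance = 1e-12)
  imgt <- render_thickened(volc, st$surf, st$dev, n_slices = 5)
  expect_equal(range(imgt$data), c(3, 3), tolerance = 1e-12)
  imgc <- render_cylinder_baseline(volc, st$arch$curve)
  expect_equal(range(imgc$data), c(3, 3), tolerance = 1e-12)
})

test_that("developed image dimensions follow the surface and volume", {
  st <- fixture("small_steps", function() run_steps(small_phantom()))
  img <- render_single_slice(small_phantom()$volume, st$surf, st$dev)
  expect_equal(ncol(img$data), dim(small_phantom()$volume$data)[3])
  expect_equal(nrow(img$data),
               as.integer(round(st$dev$w[length(st$dev$w)])) + 1L)
  expect_true(all(diff(img$w_coords) >= 0))
})

test_that("a 1-slice slab renders bitwise equal to the single slice", {
  st <- fixture("small_steps", function() run_steps(small_phantom()))
  vol <- small_phantom()$volume
  a <- render_single_slice(vol, st$surf, st$dev)
  b <- render_thickened(vol, st$surf, st$dev, n_slices = 1)
  expect_identical(a$data, b$data)
})

test_that("slab averaging monotonically reduces variance on pure noise", {
  set.seed(5)
  vol <- cbct_volume(array(rnorm(40 * 40 * 20), dim = c(40, 40, 20)))
  n <- 21
  X <- matrix(seq(8, 32, length.out = n), n, 20)
  Y <- matrix(20, n, 20)
  Z <- matrix(rep(0:19, each = n), n, 20)
  surf <- estimate_normals(
    synthetic_surface(X, Y, Z, directions = cbind(rep(0, n), rep(1, n))), 9)
  dev <- develop_surface(surf)
  v <- vapply(c(1, 3, 5, 7), function(k)
    stats::var(as.vector(render_thickened(vol, surf, dev, n_slices = k)$data)),
    0)
  expect_true(all(diff(v) < 0))
})

test_that("max-intensity slabs dominate mean slabs pixelwise", {
  st <- fixture("small_steps", function() run_steps(small_phantom()))
  vol <- small_phantom()$volume
  me <- render_thickened(vol, st$surf, st$dev, n_slices = 7, aggregate = "mean")
  mx <- render_thickened(vol, st$surf, st$dev, n_slices = 7, aggregate = "max")
  expect_true(all(mx$data >= me$data - 1e-9))
})

test_that("out-of-volume samples take the volume minimum", {
  arr <- array(10, dim = c(10, 10, 5)); arr[1, 1, 1] <- 4
  vol <- cbct_volume(arr)
  n <- 5
  X <- matrix(seq(-10, -2, length.out = n), n, 5)  # entirely outside
  Y <- matrix(5, n, 5)
  Z <- matrix(rep(0:4, each = n), n, 5)
  img <- render_single_slice(vol, synthetic_surface(X, Y, Z),
                             develop_surface(synthetic_surface(X, Y, Z)))
  expect_equal(unique(as.vector(img$data)), 4)
})
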