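## Shared fixtures, generated once per test run and cached. All phantoms are
## built in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

## small, fast zero-noise phantom for unit tests
small_phantom <- function() fixture("small0", function()
  generate_phantom(phantom_config(dims = c(120, 120, 120),
                                  n_teeth_per_jaw = 7, noise_sigma = 0)))

## full-size zero-noise phantom with the default 15-degree incisor tilt
tilt_phantom <- function() fixture("tilt0n", function()
  generate_phantom(phantom_config(noise_sigma = 0)))

## step-1..2 results on a phantom; p = 0.99 keeps the teeth-only mask intact
run_steps <- function(ph, half_length = 20, k_section = 4, degree = 5,
                      step_px = 1, p = 0.99, k = 5) {
  mip <- mip_axial(ph$volume)
  arch <- suppressWarnings(create_arch_curve(mip, k = k, p = p))
  lines <- sample_perpendicular_lines(arch$curve, step_px = step_px,
                                      half_length_px = half_length)
  surf <- extract_panoramic_surface(ph$volume, lines, k_section = k_section,
                                    degree = degree)
  dev <- develop_surface(surf)
  list(mip = mip, arch = arch, lines = lines, surf = surf, dev = dev)
}

tilt_steps <- function() fixture("tilt0n_steps", function()
  run_steps(tilt_phantom()))

## bare-bones surface builder for synthetic-geometry tests (development,
## normals): columns given directly as 3D point grids
synthetic_surface <- function(X, Y, Z, directions = NULL) {
  n <- nrow(X)
  if (is.null(directions)) {
    directions <- cbind(diff(Y[c(1, n)]) * 0 + 0, rep(1, n))
  }
  arc <- c(0, cumsum(sqrt(diff(X[, 1])^2 + diff(Y[, 1])^2 + diff(Z[, 1])^2)))
  structure(list(X = X, Y = Y, Z = Z, U = X * 0,
                 validity = matrix(TRUE, n, ncol(X)),
                 source = rep("fitted", n), arc_positions = arc,
                 lines = list(foot = cbind(X[, 1], Y[, 1]),
                              direction = directions,
                              arc_position = arc,
                              half_length = 1)),
            class = "panoramic_surface")
}
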