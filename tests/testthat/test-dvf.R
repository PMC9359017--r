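test_that("sampled deformation specs respect the sampling bounds", {
  b <- sampling_bounds(center = c(-12, 120, 704))
  s1 <- sample_deformation_spec(b, 42)
  s2 <- sample_deformation_spec(b, 42)
  expect_identical(s1, s2)                       # seed determinism
  expect_false(identical(s1, sample_deformation_spec(b, 43)))

  centers <- t(vapply(1:100, function(k) sample_deformation_spec(b, k)$center, numeric(3)))
  mags <- t(vapply(1:100, function(k) sample_deformation_spec(b, k)$magnitude, numeric(3)))
  sigmas <- vapply(1:100, function(k) sample_deformation_spec(b, k)$sigma, 0)
  for (a in 1:3) {
    expect_true(all(abs(centers[, a] - b$center[a]) <= b$extents[a] / 2))
    expect_true(all(abs(mags[, a]) >= 10 & abs(mags[, a]) <= 20))
    # one shared magnitude, independent signs
    expect_equal(abs(mags[, a]), abs(mags[, 1]))
    # centers cover > 80% of the box extent (uniform order statistics)
    expect_gt(diff(range(centers[, a])), 0.8 * b$extents[a])
  }
  expect_true(all(sigmas >= 15 & sigmas <= 25))

  # collapsed ranges pin the draw exactly
  bd <- sampling_bounds(center = c(0, 0, 0), magnitude_range = c(12, 12),
                        sigma_range = c(20, 20))
  sd <- sample_deformation_spec(bd, 1)
  expect_equal(abs(sd$magnitude), c(12, 12, 12))
  expect_equal(sd$sigma, 20)
})

test_that("rendered displacement fields follow the Gaussian closed form", {
  # at-center displacement equals the printed magnitude when the center
  # sits on a voxel center
  for (i in c(1L, 3L)) {
    spec <- reference_deformation_spec(i)
    g <- geometry(origin = spec$center - 10, spacing = c(1, 1, 1),
                  size = c(21, 21, 21))
    dvf <- render_displacement_field(spec, g)
    expect_equal(dvf$vectors[11, 11, 11, ], spec$magnitude, tolerance = 1e-12)
  }

  # a point at distance sigma sees m * exp(-1/2) per axis
  spec <- deformation_spec(c(15, -15, 15), c(0, 0, 0), sigma = 18)
  g <- geometry(origin = c(0, 0, 0), spacing = c(18, 1, 1), size = c(3, 1, 1))
  dvf <- render_displacement_field(spec, g)
  expect_equal(dvf$vectors[2, 1, 1, ], spec$magnitude * exp(-1 / 2),
               tolerance = 1e-12)
  # Gaussian tail: beyond 10 sigma the displacement vanishes numerically
  g10 <- geometry(origin = c(10 * 18, 0, 0), spacing = c(1, 1, 1), size = c(2, 1, 1))
  expect_lt(max(abs(render_displacement_field(spec, g10)$vectors)), 1e-8)

  # radial monotonicity along a ray from the center
  gr <- geometry(origin = c(0, 0, 0), spacing = c(2, 1, 1), size = c(30, 1, 1))
  mag <- abs(render_displacement_field(spec, gr)$vectors[, 1, 1, 1])
  expect_true(all(diff(mag) <= 0))
})

test_that("image warping follows pull-back semantics", {
  g <- geometry(size = c(12, 12, 12))
  zero <- displacement_field(g, array(0, c(g$size, 3)))
  img <- image_volume(g, array(withr::with_seed(3, rnorm(12^3)), g$size))
  expect_identical(warp_image(img, zero)$values, img$values)

  # constant shift on a linear ramp: exact by linearity of interpolation
  ramp <- image_volume(g, adaptqa:::coord_arrays(g)$x)
  shift <- displacement_field(g, array(rep(c(5, 0, 0), each = prod(g$size)),
                                       c(g$size, 3)))
  w <- warp_image(ramp, shift)
  expect_equal(w$values[1:6, , ], ramp$values[1:6, , ] + 5, tolerance = 1e-12)

  # shift then unshift restores the interior
  unshift <- displacement_field(g, array(rep(c(-5, 0, 0), each = prod(g$size)),
                                         c(g$size, 3)))
  back <- warp_image(w, unshift)
  expect_equal(back$values[6:12, , ], ramp$values[6:12, , ], tolerance = 1e-9)

  # linear interpolation cannot exceed the input range (plus fill)
  wr <- warp_image(img, shift)
  expect_true(all(wr$values >= min(img$values) & wr$values <= max(img$values)))

  expect_error(warp_image(img, displacement_field(geometry(size = c(6, 6, 6)),
                                                  array(0, c(6, 6, 6, 3)))),
               "geometry")
})

test_that("mask warping is a nearest-neighbor pull-back with integer-shift oracle", {
  g <- geometry(spacing = c(2, 2, 2), size = c(16, 16, 16))
  m <- sphere_mask(g, c(15, 15, 15), 8)
  zero <- displacement_field(g, array(0, c(g$size, 3)))
  expect_identical(warp_mask(m, zero)$inside, m$inside)

  # constant field of exactly -2 spacings in X translates the mask +2 voxels
  d <- displacement_field(g, array(rep(c(-4, 0, 0), each = prod(g$size)),
                                   c(g$size, 3)))
  w <- warp_mask(m, d)
  expected <- array(FALSE, g$size)
  expected[3:16, , ] <- m$inside[1:14, , ]
  expect_identical(w$inside, expected)

  # a sphere stays a single 6-connected component under study-scale fields
  for (i in 1:5) {
    spec <- reference_deformation_spec(i)
    gs <- geometry(origin = spec$center - 30, spacing = c(2, 2, 2),
                   size = c(31, 31, 31))
    sph <- sphere_mask(gs, spec$center, 14)
    wm <- warp_mask(sph, render_displacement_field(spec, gs))
    expect_equal(n_components_6(wm$inside), 1L)
  }
})

test_that("deformation Jacobians track the closed-form bound; folding is confined to the sharpest instance", {
  # For d(r) = m w(r), the Jacobian of phi = x + d is a rank-one update of
  # the identity with det = 1 + m . grad(w), minimized over space at
  # 1 - |m| exp(-1/2) / sigma.  Four of the five study instances are
  # fold-free; instance 3 (|m| = 32.6 mm, sigma = 15.6 mm) dips negative.
  bound <- function(spec) 1 - sqrt(sum(spec$magnitude^2)) * exp(-0.5) / spec$sigma
  for (i in 1:5) {
    spec <- reference_deformation_spec(i)
    g <- geometry(origin = spec$center - 60, spacing = c(4, 4, 4),
                  size = c(31, 31, 31))
    v <- render_displacement_field(spec, g)$vectors
    jmin <- Inf
    n <- g$size
    idx <- 2:(n[1] - 1)
    grad <- function(comp, ax) {
      d <- v[, , , comp]
      h <- 2 * g$spacing[ax]
      if (ax == 1) (d[3:n[1], 2:(n[2] - 1), 2:(n[3] - 1)] -
                    d[1:(n[1] - 2), 2:(n[2] - 1), 2:(n[3] - 1)]) / h
      else if (ax == 2) (d[2:(n[1] - 1), 3:n[2], 2:(n[3] - 1)] -
                         d[2:(n[1] - 1), 1:(n[2] - 2), 2:(n[3] - 1)]) / h
      else (d[2:(n[1] - 1), 2:(n[2] - 1), 3:n[3]] -
            d[2:(n[1] - 1), 2:(n[2] - 1), 1:(n[3] - 2)]) / h
    }
    j11 <- 1 + grad(1, 1); j12 <- grad(1, 2); j13 <- grad(1, 3)
    j21 <- grad(2, 1); j22 <- 1 + grad(2, 2); j23 <- grad(2, 3)
    j31 <- grad(3, 1); j32 <- grad(3, 2); j33 <- 1 + grad(3, 3)
    det <- j11 * (j22 * j33 - j23 * j32) - j12 * (j21 * j33 - j23 * j31) +
           j13 * (j21 * j32 - j22 * j31)
    expect_lt(abs(min(det) - bound(spec)), 0.08)   # coarse-grid sampling slack
    if (i == 3) expect_lt(min(det), 0) else expect_gt(min(det), 0)
  }
})

test_that("spec and field files roundtrip", {
  spec <- reference_deformation_spec(4)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_deformation_spec(spec, yml)
  expect_equal(read_deformation_spec(yml), spec)

  g <- geometry(spec$center - 6, c(2, 2, 2), c(7, 7, 7))
  dvf <- render_displacement_field(spec, g)
  mha <- withr::local_tempfile(fileext = ".mha")
  write_displacement_field(dvf, mha)
  dvf2 <- load_displacement_field(mha)
  expect_true(geometry_equal(dvf$geometry, dvf2$geometry))
  expect_identical(as.vector(dvf$vectors), as.vector(dvf2$vectors))
})
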