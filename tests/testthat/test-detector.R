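tiny_geom <- function(shape = c(64, 64), distance = 1000,
                      beam = c(32.5, 32.5))
  detector_geometry(shape = shape, pixel_size = 0.172, distance = distance,
                    wavelength = 1.0, beam_center = beam)

test_that("pixel_to_s is zero at the beam centre and inverts exactly", {
  g <- tiny_geom()
  expect_equal(pixel_to_s(g, 32.5, 32.5), 0)
  ## r = D tan(2 theta) reproduces a chosen theta to machine precision
  theta <- 0.013
  r_mm <- g$distance * tan(2 * theta)
  j <- 32.5 + r_mm / g$pixel_size
  s <- pixel_to_s(g, 32.5, j)
  expect_equal(asin(s * g$wavelength / (4 * pi)), theta, tolerance = 1e-12)
})

test_that("small-angle limit s ~ 2 pi r / (lambda D) holds to 0.1%", {
  g <- tiny_geom(distance = 5000)
  r_mm <- c(10, 50, 99)  # r/D < 0.02
  j <- 32.5 + r_mm / g$pixel_size
  s <- pixel_to_s(g, rep(32.5, 3), j)
  approx_s <- 2 * pi * r_mm / (g$wavelength * g$distance)
  expect_true(all(abs(s / approx_s - 1) < 1e-3))
})

test_that("flat curves give uniform expectations up to the cos^3 factor", {
  g <- tiny_geom()
  crv <- saxs_curve(c(1e-5, 1), c(3, 3), scale = "absolute")
  e <- exposure_model(flux = 1e10, exposure = 2, concentration = 1)
  em <- expected_image(crv, g, e)
  ## normalize out the solid angle: residual must be constant
  norm <- em$mu / (3 * 1e10 * 2 * saxskit:::detector_solid_angle(g))
  expect_equal(max(norm) - min(norm), 0, tolerance = 1e-10)
  ## doubling exposure time doubles mu everywhere
  e2 <- exposure_model(flux = 1e10, exposure = 4, concentration = 1)
  em2 <- expected_image(crv, g, e2)
  expect_equal(em2$mu, 2 * em$mu)
})

test_that("total expected counts match a quadrature over the solid angle", {
  ## smooth curve; compare sum(mu) with the integral of I(s(psi)) dOmega
  g <- tiny_geom(distance = 3000)
  s <- seq(1e-5, 0.2, length.out = 2000)
  crv <- saxs_curve(s, 5 * exp(-(s * 40)^2 / 3), scale = "absolute")
  e <- exposure_model(flux = 1e10, exposure = 1, concentration = 1)
  em <- expected_image(crv, g, e)
  ## quadrature oracle: per-pixel I * dOmega evaluated on a 4x supersampled
  ## pixel grid (midpoint rule)
  sub <- 4
  step <- 1 / sub
  off <- seq(step / 2 - 0.5, 0.5 - step / 2, by = step)
  tot <- 0
  for (di in off) for (dj in off) {
    ii <- matrix(seq_len(64) + di, 64, 64)
    jj <- matrix(seq_len(64) + dj, 64, 64, byrow = TRUE)
    smap <- matrix(pixel_to_s(g, as.numeric(ii), as.numeric(jj)), 64, 64)
    r <- saxskit:::pixel_radius_mm(g, as.numeric(ii), as.numeric(jj))
    cospsi <- g$distance / sqrt(g$distance^2 + r^2)
    dom <- matrix((g$pixel_size / g$distance)^2 * cospsi^3 / sub^2, 64, 64)
    tot <- tot + sum(approx(crv$s, crv$I, xout = smap, rule = 2)$y * dom)
  }
  expect_equal(sum(em$mu), 1e10 * tot, tolerance = 0.01)
})

test_that("Poisson sampling is seed-deterministic with correct moments", {
  g <- tiny_geom(shape = c(24, 24), beam = c(12.5, 12.5))
  crv <- saxs_curve(c(1e-5, 1), c(3, 3), scale = "absolute")
  e <- exposure_model(flux = 1, exposure = 1, concentration = 1)
  em <- expected_image(crv, g, e)
  em$mu[] <- 5                                     # force mu = 5 everywhere
  img1 <- sample_image(em, seed = 99)
  img2 <- sample_image(em, seed = 99)
  expect_identical(img1$counts, img2$counts)
  expect_false(identical(sample_image(em, seed = 100)$counts, img1$counts))
  draws <- vapply(1:200, function(k) {
    im <- sample_image(em, seed = k)
    c(mean(im$counts), stats::var(as.numeric(im$counts)))
  }, numeric(2))
  m <- mean(draws[1, ])
  expect_lt(abs(m - 5), 3 * sqrt(5 / (200 * 24^2)))  # Poisson mean
  expect_lt(abs(mean(draws[2, ]) / m - 1), 0.05)     # Fano factor = 1
  ## mu = 0 gives an all-zero image
  em$mu[] <- 0
  expect_true(all(sample_image(em, seed = 1)$counts == 0))
})

test_that("image arithmetic and mask logic behave as set operations", {
  g <- tiny_geom(shape = c(8, 8), beam = c(4, 4))
  a <- detector_image(matrix(5L, 8, 8), g)
  b <- detector_image(matrix(2L, 8, 8), g)
  expect_equal(image_op(a, b, "add")$counts, matrix(7, 8, 8))
  expect_equal(image_op(a, b, "sub")$counts, matrix(3, 8, 8))
  expect_warning(d <- image_op(b, a, "sub"), "clamped")
  expect_true(all(d$counts == 0))
  bin <- detector_image(matrix(rep(c(0L, 1L), 32), 8, 8), g)
  expect_true(all(image_op(bin, bin, "xor")$counts == 0))
  ones <- matrix(1L, 8, 8)
  expect_equal(image_op(bin, ones, "and")$counts, bin$counts)
  expect_equal(image_op(bin, matrix(0L, 8, 8), "or")$counts, bin$counts)
  expect_error(image_op(a, b, "xor"), "binary")
  masked <- image_op(a, {m <- ones; m[1, ] <- 0L; m}, "apply_mask")
  expect_true(all(masked$counts[1, ] == 0))
  expect_true(all(masked$mask[1, ] == 0))
  small <- detector_image(matrix(0L, 4, 4),
                          tiny_geom(shape = c(4, 4), beam = c(2, 2)))
  expect_error(image_op(a, small, "add"), "shape")
})

test_that("TIFF round trip preserves counts exactly", {
  g <- tiny_geom(shape = c(16, 16), beam = c(8, 8))
  set.seed(3)
  img <- detector_image(matrix(rpois(256, 1e5), 16, 16), g)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image(img, path)
  back <- read_image(path, g)
  expect_equal(back$counts, img$counts, ignore_attr = TRUE)
})
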