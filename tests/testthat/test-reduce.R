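test_that("the Anscombe transform and robust z follow their closed forms", {
  expect_equal(2 * sqrt(0 + 3 / 8), 1.2247449, tolerance = 1e-6)
  ## constant ring: MAD = 0, everything kept
  expect_true(all(anscombe_robust_z(rep(7L, 50))))
  ## a gross outlier among Poisson(100) draws is the only rejection
  set.seed(42)
  x <- c(rpois(199, 100), 10000L)
  keep <- anscombe_robust_z(x)
  expect_identical(which(!keep), 200L)
  ## one-sided mode only rejects on the high side
  y <- c(rpois(199, 100), 0L)
  expect_true(all(anscombe_robust_z(y, two_sided = FALSE)[200]))
})

test_that("a uniform image reduces to flat rings with Poisson errors", {
  g <- detector_geometry(shape = c(64, 64), pixel_size = 0.172,
                         distance = 1000, wavelength = 1,
                         beam_center = c(32.5, 32.5))
  v <- 49L
  img <- detector_image(matrix(v, 64, 64), g)
  red <- radial_average(img, nbins = 10, reject = FALSE)
  expect_true(all(abs(red$I - v) < 1e-9))
  ## sigma = sqrt(v / N_ring) per ring
  smap <- saxskit:::detector_s_map(g)
  edges <- seq(min(smap), max(smap), length.out = 11)
  bin <- findInterval(smap, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nring <- as.numeric(table(bin))
  expect_equal(red$sigma, sqrt(v / nring), tolerance = 1e-9)
})

test_that("a hot pixel is rejected without moving the ring mean", {
  g <- detector_geometry(shape = c(64, 64), pixel_size = 0.172,
                         distance = 1000, wavelength = 1,
                         beam_center = c(32.5, 32.5))
  set.seed(5)
  counts <- matrix(rpois(64 * 64, 10), 64, 64)
  hot <- counts; hot[40, 40] <- 1e6
  red_clean <- radial_average(detector_image(counts, g), 8, reject = FALSE)
  red_hot <- radial_average(detector_image(hot, g), 8, reject = TRUE)
  expect_true(all(abs(red_hot$I - red_clean$I) <= 3 * red_clean$sigma))
  red_norej <- radial_average(detector_image(hot, g), 8, reject = FALSE)
  expect_gt(max(abs(red_norej$I - red_clean$I)), 10)
})

test_that("reduce-then-average commutes with sum-then-reduce", {
  tb <- sim_testbed(shape = 128L, nbins = 80L)
  imgs <- lapply(1:4, function(k) sample_image(tb$expected, seed = 100 + k))
  curves <- lapply(imgs, radial_average, nbins = 80, reject = FALSE)
  avg_1d <- average_curves(curves)
  summed <- Reduce(function(a, b) image_op(a, b, "add"), imgs)
  red_sum <- radial_average(summed, nbins = 80, reject = FALSE)
  ## counts sum: the summed image carries the single-frame normalization,
  ## so its intensities are 4x the per-frame average, exactly
  expect_equal(red_sum$I / 4, avg_1d$I, tolerance = 1e-12)
  expect_equal(red_sum$s, avg_1d$s, tolerance = 1e-12)
  ## sigma: sqrt(sum c)/(4) vs sqrt(sum sigma_k^2)/4 on identical rings
  expect_equal(red_sum$sigma / 4, avg_1d$sigma, tolerance = 1e-12)
})

test_that("averaging identical curves keeps I and shrinks sigma as 1/sqrt(N)", {
  crv <- saxs_curve(seq(0.01, 0.1, 0.01), 10:1, sigma = rep(2, 10))
  avg2 <- average_curves(list(crv, crv))
  expect_equal(avg2$I, crv$I)
  expect_equal(avg2$sigma, crv$sigma / sqrt(2))
  noiseless <- saxs_curve(crv$s, crv$I)
  expect_equal(average_curves(list(noiseless, noiseless, noiseless))$I, crv$I)
})

test_that("averaged replicate variance shrinks as 1/N", {
  base <- saxs_curve(seq(0.01, 0.3, length.out = 60),
                     exp(-seq(0.01, 0.3, length.out = 60) * 5) * 100)
  for (N in c(2, 8)) {
    reps <- lapply(seq_len(200), function(k) {
      average_curves(lapply(seq_len(N), function(j)
        noisy_curve(base, sigma = 0.05, seed = 1000 * k + j)))
    })
    v <- var(vapply(reps, function(r) r$I[1], numeric(1)))
    v1 <- (0.05 * base$I[1])^2
    expect_lt(abs(v / (v1 / N) - 1), 0.45)   # 200-sample chi2 spread
  }
})

test_that("subtraction propagates errors and add undoes it", {
  a <- saxs_curve(1:5 / 100, c(10, 9, 8, 7, 6), sigma = rep(1, 5))
  d <- subtract_curves(a, a)
  expect_true(all(d$I == 0))
  expect_equal(d$sigma, rep(sqrt(2), 5))
  b <- saxs_curve(1:5 / 100, rep(2, 5), sigma = rep(0.5, 5))
  back <- add_curves(subtract_curves(a, b), b)
  expect_equal(back$I, a$I)
  mismatched <- saxs_curve(2:6 / 100, rep(1, 5))
  expect_error(subtract_curves(a, mismatched), "common s grid")
})

test_that("background-subtracted errors are consistent with frame scatter", {
  base <- saxs_curve(seq(0.01, 0.25, length.out = 120),
                     exp(-seq(0.01, 0.25, length.out = 120) * 8) * 50 + 5)
  bg <- saxs_curve(base$s, rep(5, 120))
  chi2 <- vapply(1:150, function(k) {
    s1 <- noisy_curve(base, sigma = 0.04, seed = 2 * k)
    b1 <- noisy_curve(bg, sigma = 0.04, seed = 2 * k + 1)
    diff <- subtract_curves(s1, b1)
    truth <- saxs_curve(base$s, base$I - bg$I, sigma = rep(1e-12, 120))
    mean(((diff$I - truth$I) / diff$sigma)^2)
  }, numeric(1))
  expect_lt(abs(mean(chi2) - 1), 3 * sqrt(2 / (150 * 120)))
})
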