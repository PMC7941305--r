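## Independent oracles used across test files.  These deliberately avoid
## the package's own code paths.

## Brute-force longest-run probability: enumerate all 2^n binary sequences.
brute_force_longest_run_p <- function(n, C) {
  hits <- 0L
  for (x in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(x))[seq_len(n)]
    if (max(rle(bits)$lengths) >= C) hits <- hits + 1L
  }
  hits / 2^n
}

## Asymptotic Anderson-Darling survival function by numerical inversion of
## the characteristic function of sum_j Z_j^2 / (j (j+1)) (Imhof's method).
ad_sf_imhof <- function(z, jmax = 50000) {
  j <- seq_len(jmax)
  lam <- 1 / (j * (j + 1))
  f <- function(u) {
    th <- 0.5 * sum(atan(u * lam)) - 0.5 * u * z
    sin(th) / (u * exp(0.25 * sum(log1p(lam^2 * u^2))))
  }
  0.5 + integrate(Vectorize(f), 0, Inf, rel.tol = 1e-10,
                  subdivisions = 2000)$value / pi
}

## Analytic solid-sphere intensity, written independently of the fixtures
## module (same closed form, separate code path).
oracle_sphere_I <- function(R, s, I0 = 1) {
  x <- s * R
  amp <- ifelse(x < 1e-6, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  I0 * amp^2
}

## Relative RMS deviation between two vectors.
rel_rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))

## Standard detector setup used by the simulation round-trip tests:
## sphere of radius 25 A at 30 kDa with a 1% flat background, corner beam.
sim_testbed <- function(shape = 512L, nbins = 1200L,
                        flux = 1e13, conc = 5) {
  s <- seq(0.0005, 0.28, length.out = 3000)
  src <- sphere_curve(25, s, I0 = 2.5e8)
  src$I <- src$I + 0.01 * 2.5e8
  crv <- to_absolute_scale(src, mw = 30000)
  geom <- detector_geometry(shape = c(shape, shape), pixel_size = 0.172,
                            distance = 6000 * shape / 1024,
                            wavelength = 1, beam_center = c(1, 1))
  expo <- exposure_model(flux = flux, exposure = 1, concentration = conc)
  em <- suppressWarnings(expected_image(crv, geom, expo))
  list(curve = crv, geometry = geom, exposure = expo, expected = em,
       nbins = nbins)
}

## Source-model intensities at the recovered ring positions.
testbed_reference <- function(tb, red) {
  saxs_curve(red$s, approx(tb$curve$s, tb$curve$I, xout = red$s)$y,
             scale = "absolute")
}
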