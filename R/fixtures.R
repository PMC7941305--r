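## Synthetic-data generators.
##
## Closed-form analytic models (solid sphere, point sets, Gaussian noise)
## serve as independent oracles for the calculators, transforms and
## statistics, and double as demo inputs: no external data are needed
## anywhere in the package.

#' Analytic scattering curve of a solid sphere
#'
#' `I(s) = I0 [3 (sin x - x cos x) / x^3]^2` with `x = s R`: the exact
#' form factor of a homogeneous sphere of radius `R`.  The first zero lies
#' at `x ~ 4.493` (root of `tan x = x`) and the Guinier radius is
#' `sqrt(3/5) R`.
#'
#' @param R sphere radius in Angstrom.
#' @param s_grid increasing momentum transfer grid (may include 0).
#' @param I0 forward scattering, default 1.
#' @return A [saxs_curve()] without error estimates.
#' @export
sphere_curve <- function(R, s_grid, I0 = 1) {
  stopifnot(R > 0, I0 > 0)
  x <- as.numeric(s_grid) * R
  amp <- ifelse(x < 1e-4,
                1 - x^2 / 10,             # series limit near x = 0
                3 * (sin(x) - x * cos(x)) / x^3)
  saxs_curve(s_grid, I0 * amp^2, scale = "relative")
}

#' Analytic pair distance distribution of a solid sphere
#'
#' The closed-form distance distribution of a homogeneous sphere,
#' `p(r) = N r^2 (1 - 3u/2 + u^3/2)` with `u = r / 2R` on `[0, 2R]`,
#' normalized so that `4 pi int p dr = I0` (matching [sphere_curve()]).
#' Its moments satisfy `Rg^2 = (3/5) R^2`.
#'
#' @param R sphere radius in Angstrom.
#' @param npoints number of grid points on `[0, 2R]`.
#' @param I0 forward scattering the normalization should reproduce.
#' @return A [pofr()] with `dmax = 2R`.
#' @export
sphere_pofr <- function(R, npoints = 201L, I0 = 1) {
  stopifnot(R > 0, I0 > 0)
  r <- seq(0, 2 * R, length.out = npoints)
  u <- r / (2 * R)
  p <- r^2 * (1 - 1.5 * u + 0.5 * u^3)
  p <- p * I0 / (4 * pi * pracma::trapz(r, p))
  pofr(r, p, dmax = 2 * R)
}

#' Uniform random points in a ball
#'
#' `n` points drawn uniformly in the ball of radius `R` (radial
#' inverse-CDF sampling, isotropic directions), labelled as carbon atoms
#' with unit occupancy.  The mean squared radius of the uniform ball is
#' `(3/5) R^2`.
#'
#' @param R ball radius in Angstrom.
#' @param n number of points.
#' @param seed integer RNG seed (deterministic output).
#' @return An [atom_set()] of `n` carbon-labelled points.
#' @export
sphere_points <- function(R, n, seed) {
  stopifnot(R > 0, n >= 1)
  set.seed(as.integer(seed))
  rad <- R * runif(n)^(1 / 3)
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  atom_set(rep("C", n), rad * v[, 1], rad * v[, 2], rad * v[, 3],
           label = sprintf("uniform ball R=%g n=%d", R, n))
}

#' Add recorded Gaussian noise to a curve
#'
#' Adds independent `Normal(0, sigma_i)` noise to the intensities and
#' records `sigma_i` as the curve's error estimate, emulating a reduced
#' 1D profile with well-estimated errors.  The default noise model is a
#' constant fraction of `|I|` with a small floor tied to the maximum
#' intensity (so points near intensity zeros keep a positive sigma).
#'
#' @param curve a [saxs_curve()].
#' @param sigma per-point standard deviations; either a numeric vector or
#'   a single fraction interpreted as
#'   `pmax(sigma * abs(I), sigma * max(abs(I)) * 1e-3)`.
#' @param seed integer RNG seed (deterministic output).
#' @return A [saxs_curve()] with noisy `I` and recorded `sigma`.
#' @export
noisy_curve <- function(curve, sigma = 0.02, seed) {
  stopifnot(inherits(curve, "saxs_curve"))
  n <- nrow(curve)
  if (length(sigma) == 1L)
    sigma <- pmax(sigma * abs(curve$I), sigma * max(abs(curve$I)) * 1e-3)
  if (length(sigma) != n || any(sigma < 0))
    stop("'sigma' must be a positive fraction or a length-matched vector")
  set.seed(as.integer(seed))
  saxs_curve(curve$s, curve$I + rnorm(n, 0, sigma), sigma = sigma,
             scale = curve_scale(curve))
}
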