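#' Scattering intensity from atomic coordinates by the Debye sum
#'
#' Computes the isotropic 1D scattering intensity of a particle in vacuum
#' by the Debye double sum over atoms,
#' `I(s) = sum_jk Re[f_j f_k*] w_j w_k sin(s r_jk)/(s r_jk)`,
#' with complex effective form factors `f = f0(s) + f'(E) + i f''(E)` and
#' occupancy weights `w`.  The sum is exact for point models (no multipole
#' truncation) and costs `O(n_atoms^2 * n_s)`; it is intended for
#' desk-scale models of up to a few thousand atoms.  No hydration shell or
#' excluded-volume solvent term is applied.
#'
#' When `energy` is given, the anomalous corrections are applied to all
#' atoms of `anom_element` only; all other elements scatter with their
#' regular `f0`.
#'
#' @param atoms an [atom_set()].
#' @param s_grid increasing momentum transfer grid, reciprocal Angstrom,
#'   `>= 0`.
#' @param energy optional X-ray energy in eV for anomalous corrections.
#' @param anom_element element receiving the anomalous correction (required
#'   when `energy` is given).
#' @param anom_table optional [anomalous_table()] or path to one; default
#'   is the built-in table for `anom_element`.
#' @return A relative-scale [saxs_curve()] in electrons-squared units,
#'   without error estimates.
#' @examples
#' atoms <- atom_set("C", 0, 0, 0)
#' crv <- debye_intensity(atoms, s_grid = seq(0, 0.5, length.out = 11))
#' crv$I[1]  # f0_C(0)^2 ~ 36 electrons^2
#' @export
debye_intensity <- function(atoms, s_grid, energy = NULL,
                            anom_element = NULL, anom_table = NULL) {
  stopifnot(inherits(atoms, "atom_set"))
  if (nrow(atoms) < 1L) stop("empty atom set")
  s_grid <- as.numeric(s_grid)
  if (any(s_grid < 0) || any(diff(s_grid) <= 0))
    stop("'s_grid' must be >= 0 and strictly increasing")
  if (!is.null(energy) && is.null(anom_element))
    stop("'anom_element' must name the absorbing element when 'energy' is given")
  elems <- sort(unique(atoms$element))
  fre <- matrix(0, length(s_grid), length(elems))
  fim <- matrix(0, length(s_grid), length(elems))
  for (i in seq_along(elems)) {
    f <- if (!is.null(energy) && elems[i] == normalize_element(anom_element))
      effective_f(elems[i], s_grid, energy = energy, table = anom_table)
    else effective_f(elems[i], s_grid)
    fre[, i] <- Re(f)
    fim[, i] <- Im(f)
  }
  idx <- match(atoms$element, elems) - 1L
  I <- .debye_sum(as.matrix(atoms[, c("x", "y", "z")]), atoms$occupancy,
                  idx, fre, fim, s_grid)
  saxs_curve(s_grid, I, scale = "relative")
}

#' Put a calculated curve on absolute scale per unit concentration
#'
#' Converts intensities from electrons-squared per particle to
#' `cm^-1 / (mg ml^-1)` by multiplying with `r_e^2 N_A / MW * 1e-3`:
#' the squared Thomson scattering length times the number of particles per
#' unit volume at 1 mg/ml.
#'
#' @param curve a relative-scale [saxs_curve()] in electrons-squared units.
#' @param mw molecular weight in Da.
#' @return An absolute-scale [saxs_curve()].
#' @export
to_absolute_scale <- function(curve, mw) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (!is.numeric(mw) || length(mw) != 1L || mw <= 0)
    stop("'mw' must be a positive molecular weight in Da")
  k <- absolute_scale_factor(mw)
  saxs_curve(curve$s, curve$I * k,
             sigma = if (has_sigma(curve)) curve$sigma * k,
             scale = "absolute")
}

## cm^-1 ml mg^-1 per electron^2: r_e^2 [cm^2] * N_A [1/mol] / MW [g/mol]
## * 1e-3 [g/mg] (concentration bookkeeping: 1 mg/ml = 1e-3 g/cm^3).
absolute_scale_factor <- function(mw) .re2_cm2 * .avogadro * 1e-3 / mw
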