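#' Guinier fit of the low-angle region
#'
#' Weighted linear regression of `ln I` on `s^2` over the largest low-angle
#' window satisfying `s * Rg <= srg_limit`, iterated to self-consistency:
#' starting from a fit over the first points, the window is re-derived from
#' the fitted `Rg` until it stabilizes.  The Guinier approximation
#' `I(s) = I0 exp(-s^2 Rg^2 / 3)` gives `Rg = sqrt(-3 * slope)` and
#' `I0 = exp(intercept)`; standard errors are propagated from the
#' regression.
#'
#' @param curve a [saxs_curve()]; intensities must be positive over the
#'   fitted window.  When error estimates are present the fit is weighted
#'   by `(I / sigma)^2` (the variance of `ln I`).
#' @param srg_limit upper validity limit on `s * Rg` (default 1.3; the
#'   Guinier region is conventionally `s < 1.3 / Rg` for globular
#'   particles).
#' @param min_points minimum number of points in the fitted window.
#' @return List with `Rg`, `I0`, `Rg_se`, `I0_se`, `range` (fitted s
#'   range), `n` (points used).
#' @export
guinier_fit <- function(curve, srg_limit = 1.3, min_points = 5L) {
  stopifnot(inherits(curve, "saxs_curve"))
  s <- curve$s; I <- curve$I
  fit_window <- function(idx) {
    x <- s[idx]^2; y <- log(I[idx])
    ## Var(ln I) = Var(I)/I^2, so WLS weights are (I/sigma)^2; without
    ## recorded errors, homoscedastic absolute noise gives w = I^2.
    w <- if (has_sigma(curve) && all(curve$sigma[idx] > 0))
      (I[idx] / curve$sigma[idx])^2
    else I[idx]^2
    lm(y ~ x, weights = w)
  }
  pos <- which(I > 0)
  if (length(pos) < min_points) stop("no valid Guinier window")
  ## initialize from the widest low-angle window with a decreasing trend;
  ## very narrow starts are noise-dominated on reduced detector data
  idx <- NULL
  for (m in unique(pmax(ceiling(length(pos) / c(2, 4, 8, 16)), min_points))) {
    cand <- pos[seq_len(min(m, length(pos)))]
    if (coef(fit_window(cand))[[2]] < 0) { idx <- cand; break }
  }
  if (is.null(idx))
    stop("no valid Guinier window: non-decreasing low-angle intensity")
  prev <- integer(0)
  for (iter in 1:50) {
    fit <- fit_window(idx)
    slope <- coef(fit)[[2]]
    if (slope >= 0)
      stop("no valid Guinier window: non-decreasing low-angle intensity")
    rg <- sqrt(-3 * slope)
    new_idx <- pos[s[pos] * rg <= srg_limit]
    if (length(new_idx) < min_points)
      new_idx <- pos[seq_len(min_points)]
    if (identical(new_idx, idx) || identical(new_idx, prev)) {
      idx <- new_idx
      break
    }
    prev <- idx
    idx <- new_idx
  }
  fit <- fit_window(idx)
  slope <- coef(fit)[[2]]
  if (slope >= 0) stop("no valid Guinier window")
  rg <- sqrt(-3 * slope)
  se <- sqrt(diag(vcov(fit)))
  list(Rg = rg,
       I0 = exp(coef(fit)[[1]]),
       Rg_se = 3 * se[[2]] / (2 * rg),
       I0_se = exp(coef(fit)[[1]]) * se[[1]],
       range = range(s[idx]),
       n = length(idx))
}

## Porod-tail amplitude A with I(s) ~ A s^-4 over the last fraction of the
## s range; NULL with a warning when the window is not Porod-like.  The
## check compares the window-averaged s^4 I(s) of the last window with the
## adjacent earlier window of equal width: averaging suppresses the
## form-factor oscillations of compact particles (Porod-like), while a
## systematic trend (s^4 I ~ s^2 for flexible chains, ~ s^4 for a flat
## background) shifts the window means apart.
porod_tail_amplitude <- function(curve, fraction = 0.25, ratio_max = 0.4) {
  smax <- max(curve$s)
  last <- curve$s >= smax * (1 - fraction)
  earlier <- curve$s >= smax * (1 - 2 * fraction) & !last
  if (sum(last) < 3L || sum(earlier) < 3L) return(NULL)
  A <- mean(curve$s[last]^4 * curve$I[last])
  A0 <- mean(curve$s[earlier]^4 * curve$I[earlier])
  if (A <= 0 || A0 <= 0 || abs(A / A0 - 1) > ratio_max) {
    warning("high-angle tail is not Porod-like; tail continuation skipped")
    return(NULL)
  }
  A
}

#' Porod invariant and Porod volume
#'
#' `Q_p = int s^2 I(s) ds` by the trapezoid rule over the data, plus an
#' `A s^-4` analytic tail continuation beyond the last measured point
#' (`int_smax^inf A s^-2 ds = A / smax`), and the volume
#' `V_p = 2 pi^2 I0 / Q_p`.  Both are invariant to intensity scaling
#' because `I0` and `Q_p` scale together.
#'
#' @param curve a [saxs_curve()] extending to angles where `s^4 I(s)` is
#'   roughly constant.
#' @param i0 forward scattering on the same intensity scale as the curve.
#' @param continuation extend the integral beyond `s_max` with the fitted
#'   Porod tail?  Skipped with a warning when the tail is not Porod-like.
#' @param tail_fraction fraction of the `s` range used for the tail fit.
#' @return List with `Qp` and `Vp` (Angstrom^3).
#' @export
porod <- function(curve, i0, continuation = TRUE, tail_fraction = 0.25) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (!is.numeric(i0) || i0 <= 0) stop("'i0' must be positive")
  Qp <- pracma::trapz(curve$s, curve$s^2 * curve$I)
  if (continuation) {
    A <- porod_tail_amplitude(curve, tail_fraction)
    if (!is.null(A)) Qp <- Qp + A / max(curve$s)
  }
  list(Qp = Qp, Vp = 2 * pi^2 * i0 / Qp)
}

#' Volume of correlation
#'
#' `V_c = I0 / int s I(s) ds` (dimension: Angstrom^2), with the integral
#' extended beyond `s_max` by the fitted Porod tail
#' (`int_smax^inf A s^-3 ds = A / (2 smax^2)`).  Scale-invariant in the
#' intensities; correlates with molecular weight for compact particles.
#'
#' @inheritParams porod
#' @return `V_c` in Angstrom^2.
#' @export
volume_of_correlation <- function(curve, i0, continuation = TRUE,
                                  tail_fraction = 0.25) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (!is.numeric(i0) || i0 <= 0) stop("'i0' must be positive")
  denom <- pracma::trapz(curve$s, curve$s * curve$I)
  if (continuation) {
    A <- porod_tail_amplitude(curve, tail_fraction)
    if (!is.null(A)) denom <- denom + A / (2 * max(curve$s)^2)
  }
  i0 / denom
}

## Volume-of-correlation -> MW power law (Rambo & Tainer correlation for
## proteins and RNA): MW = (Vc^2 / Rg / c)^k with the published constants.
.vc_mw_constants <- list(protein = list(c = 0.1231, k = 1),
                         rna = list(c = 0.00934, k = 0.808))

#' Concentration-independent molecular weight estimates
#'
#' `MW_vp` converts the Porod volume to Daltons by pure unit bookkeeping:
#' `MW = Vp[A^3] * 1e-24 [cm^3/A^3] * N_A / vbar`, with `vbar` the partial
#' specific volume in cm^3/g (0.74 for an average protein).  `MW_vc` uses
#' the published volume-of-correlation power law
#' `MW = (Vc^2 / Rg / c)^k` (Rambo-Tainer correlation; constants for
#' protein or RNA selectable via `molecule`).  Both estimates are strictly
#' invariant to intensity scaling.
#'
#' @param vp Porod volume in Angstrom^3 (or `NULL`).
#' @param vc volume of correlation in Angstrom^2 (or `NULL`).
#' @param rg radius of gyration in Angstrom (needed for `MW_vc`).
#' @param psv partial specific volume in cm^3/g, default 0.74.
#' @param molecule `"protein"` or `"rna"`: selects the `V_c` power-law
#'   constants.
#' @return List with `MW_vp` and `MW_vc` in Da (`NULL` where the inputs
#'   are absent).
#' @export
mw_estimates <- function(vp = NULL, vc = NULL, rg = NULL, psv = 0.74,
                         molecule = c("protein", "rna")) {
  molecule <- match.arg(molecule)
  stopifnot(psv > 0)
  mw_vp <- if (!is.null(vp)) vp * 1e-24 * .avogadro / psv
  mw_vc <- if (!is.null(vc) && !is.null(rg)) {
    k <- .vc_mw_constants[[molecule]]
    (vc^2 / rg / k$c)^k$k
  }
  list(MW_vp = mw_vp, MW_vc = mw_vc)
}

#' Model-free invariants report for a scattering curve
#'
#' Runs the Guinier fit (unless `rg`/`i0` are supplied), the Porod
#' invariant and volume, the volume of correlation and the
#' concentration-independent molecular weight estimates.
#'
#' @param curve a [saxs_curve()].
#' @param rg,i0 optional externally determined Guinier parameters; when
#'   `NULL` they are fitted with [guinier_fit()].
#' @param srg_limit passed to [guinier_fit()].
#' @param psv,molecule passed to [mw_estimates()].
#' @return An object of class `saxs_invariants` (a list with the Guinier,
#'   Porod, `V_c` and MW results).
#' @export
saxs_invariants <- function(curve, rg = NULL, i0 = NULL, srg_limit = 1.3,
                            psv = 0.74, molecule = c("protein", "rna")) {
  molecule <- match.arg(molecule)
  gf <- NULL
  if (is.null(rg) || is.null(i0)) {
    gf <- guinier_fit(curve, srg_limit = srg_limit)
    if (is.null(rg)) rg <- gf$Rg
    if (is.null(i0)) i0 <- gf$I0
  }
  pr <- porod(curve, i0)
  vc <- volume_of_correlation(curve, i0)
  mw <- mw_estimates(vp = pr$Vp, vc = vc, rg = rg, psv = psv,
                     molecule = molecule)
  structure(list(Rg = rg, I0 = i0,
                 Rg_se = gf$Rg_se, I0_se = gf$I0_se,
                 guinier_range = gf$range,
                 Qp = pr$Qp, Vp = pr$Vp, Vc = vc,
                 MW_vp = mw$MW_vp, MW_vc = mw$MW_vc),
            class = "saxs_invariants")
}

#' @export
print.saxs_invariants <- function(x, ...) {
  cat("Model-free invariants\n")
  cat(sprintf("  Rg    = %.4g A%s\n", x$Rg,
              if (!is.null(x$Rg_se)) sprintf(" +/- %.2g", x$Rg_se) else ""))
  cat(sprintf("  I(0)  = %.5g%s\n", x$I0,
              if (!is.null(x$I0_se)) sprintf(" +/- %.2g", x$I0_se) else ""))
  if (!is.null(x$guinier_range))
    cat(sprintf("  Guinier range: s in [%.4g, %.4g] A^-1\n",
                x$guinier_range[1], x$guinier_range[2]))
  cat(sprintf("  Qp    = %.5g\n", x$Qp))
  cat(sprintf("  Vp    = %.5g A^3\n", x$Vp))
  cat(sprintf("  Vc    = %.5g A^2\n", x$Vc))
  cat(sprintf("  MW(Vp) = %.4g Da, MW(Vc) = %.4g Da\n", x$MW_vp, x$MW_vc))
  invisible(x)
}
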