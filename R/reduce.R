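#' Anscombe-transform robust outlier flags for Poisson counts
#'
#' Variance-stabilizes counts with the Anscombe transform
#' `y = 2 sqrt(x + 3/8)` (approximately normal for Poisson input) and
#' computes a median-based robust z score
#' `z = 0.6745 (y - median(y)) / MAD(y)`.  Values with `|z| > cutoff`
#' (or `z > cutoff` for `two_sided = FALSE`) are flagged as outliers.
#' When the MAD is 0 (degenerate ring) all values are kept.
#'
#' @param counts non-negative integer counts.
#' @param cutoff robust z cutoff, default 4.
#' @param two_sided reject on `|z|` (default) or only on high `z`?
#' @return Logical keep-flags, same length as `counts`.
#' @export
anscombe_robust_z <- function(counts, cutoff = 4, two_sided = TRUE) {
  if (length(counts) < 1L) stop("need at least one value")
  if (any(counts < 0)) stop("counts must be >= 0")
  y <- 2 * sqrt(counts + 3 / 8)
  m <- median(y)
  s <- median(abs(y - m))  # raw MAD, no consistency constant
  if (s == 0) return(rep(TRUE, length(counts)))
  z <- 0.6745 * (y - m) / s
  if (two_sided) abs(z) <= cutoff else z <= cutoff
}

#' Radial (azimuthal) average of a detector image
#'
#' Collapses a 2D image into a 1D scattering curve by averaging pixels in
#' rings of constant momentum transfer.  Ring bins are equal-width in `s`
#' between the smallest and largest `s` of unmasked pixels; each pixel
#' contributes to exactly one ring (no pixel splitting).  Per ring,
#' outliers are optionally rejected by [anscombe_robust_z()], then the
#' intensity is the mean of kept (normalized) counts and the error
#' estimate follows Poisson counting statistics.  When the image carries
#' an [exposure_model()], counts are converted to absolute-scale
#' intensities by the per-pixel factor `c flux t T eta dOmega`; otherwise
#' intensities are plain mean counts with `sigma = sqrt(sum counts)/N`.
#' The `s` of each ring is the unweighted mean `s` of its kept pixels;
#' empty rings are omitted.
#'
#' @param image a [detector_image()].
#' @param nbins number of rings (`>= 2`).
#' @param reject apply Anscombe robust-z outlier rejection per ring?
#' @param cutoff robust z cutoff passed to [anscombe_robust_z()].
#' @return A [saxs_curve()] with error estimates; absolute scale when the
#'   image carries exposure metadata.
#' @export
radial_average <- function(image, nbins, reject = TRUE, cutoff = 4) {
  stopifnot(inherits(image, "detector_image"))
  nbins <- as.integer(nbins)
  if (nbins < 2L) stop("'nbins' must be >= 2")
  valid <- image$mask == 1L
  if (!any(valid)) stop("all pixels are masked")
  smap <- detector_s_map(image$geometry)
  s <- smap[valid]
  counts <- image$counts[valid]
  g <- if (!is.null(image$exposure)) {
    e <- image$exposure
    k <- e$concentration * e$flux * e$exposure * e$transmission * e$efficiency
    (k * detector_solid_angle(image$geometry))[valid]
  } else rep(1, length(counts))
  edges <- seq(min(s), max(s), length.out = nbins + 1L)
  bin <- findInterval(s, edges, rightmost.closed = TRUE, all.inside = TRUE)
  idx <- split(seq_along(counts), bin)
  res <- vapply(idx, function(ii) {
    ci <- counts[ii]; gi <- g[ii]; si <- s[ii]
    if (reject && length(ci) > 1L) {
      keep <- anscombe_robust_z(ci, cutoff = cutoff)
      ci <- ci[keep]; gi <- gi[keep]; si <- si[keep]
    }
    n <- length(ci)
    c(s = mean(si),
      I = mean(ci / gi),
      sigma = sqrt(sum(ci / gi^2)) / n)
  }, numeric(3))
  ord <- order(res["s", ])
  saxs_curve(res["s", ord], res["I", ord], sigma = res["sigma", ord],
             scale = if (is.null(image$exposure)) "relative" else "absolute")
}

#' Average replicate scattering curves
#'
#' Pointwise mean of curves on a common `s` grid, with independent-error
#' propagation `sigma_out = sqrt(sum sigma_i^2) / N`.
#'
#' @param curves list of [saxs_curve()] on identical grids (relative
#'   tolerance 1e-6 per point).
#' @return A [saxs_curve()].
#' @export
average_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "saxs_curve")))
  ref <- curves[[1]]
  for (crv in curves[-1]) check_common_grid(ref, crv)
  n <- length(curves)
  Im <- rowMeans(vapply(curves, function(c) c$I, numeric(nrow(ref))))
  sig <- if (all(vapply(curves, has_sigma, logical(1)))) {
    s2 <- rowSums(vapply(curves, function(c) c$sigma^2, numeric(nrow(ref))))
    sqrt(s2) / n
  } else NULL
  saxs_curve(ref$s, Im, sigma = sig, scale = curve_scale(ref))
}

#' Subtract a background curve from a sample curve
#'
#' `I = I_sample - I_background` with `sigma = sqrt(sigma_s^2 + sigma_b^2)`.
#'
#' @param sample,background [saxs_curve()] objects on identical grids.
#' @return A [saxs_curve()].
#' @export
subtract_curves <- function(sample, background) {
  stopifnot(inherits(sample, "saxs_curve"), inherits(background, "saxs_curve"))
  check_common_grid(sample, background)
  sig <- if (has_sigma(sample) && has_sigma(background))
    sqrt(sample$sigma^2 + background$sigma^2)
  else if (has_sigma(sample)) sample$sigma
  else if (has_sigma(background)) background$sigma
  saxs_curve(sample$s, sample$I - background$I, sigma = sig,
             scale = curve_scale(sample))
}

#' Add two scattering curves
#'
#' Pointwise sum with error propagation; inverse of [subtract_curves()].
#'
#' @param a,b [saxs_curve()] objects on identical grids.
#' @return A [saxs_curve()].
#' @export
add_curves <- function(a, b) {
  stopifnot(inherits(a, "saxs_curve"), inherits(b, "saxs_curve"))
  check_common_grid(a, b)
  sig <- if (has_sigma(a) && has_sigma(b)) sqrt(a$sigma^2 + b$sigma^2)
  saxs_curve(a$s, a$I + b$I, sigma = sig, scale = curve_scale(a))
}
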