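#' Detector geometry
#'
#' Physical mapping between detector pixels and scattering vectors for a
#' flat detector normal to the incident beam.
#'
#' @param shape integer `(rows, cols)` in pixels.
#' @param pixel_size pixel edge length in mm (square pixels).
#' @param distance sample-detector distance in mm.
#' @param wavelength X-ray wavelength in Angstrom.
#' @param beam_center `(row, col)` of the direct beam in fractional pixel
#'   coordinates (pixel centres at integer indices, 1-based); it may lie
#'   outside the image.
#' @return An object of class `detector_geometry`.
#' @export
detector_geometry <- function(shape, pixel_size, distance, wavelength,
                              beam_center) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 1L),
            pixel_size > 0, distance > 0, wavelength > 0,
            length(beam_center) == 2L, all(is.finite(beam_center)))
  structure(list(shape = shape, pixel_size = pixel_size,
                 distance = distance, wavelength = wavelength,
                 beam_center = as.numeric(beam_center)),
            class = "detector_geometry")
}

#' @export
print.detector_geometry <- function(x, ...) {
  cat(sprintf(
    "Detector: %dx%d px, %.4g mm pixels, D = %.5g mm, lambda = %.4g A, beam at (%.2f, %.2f)\n",
    x$shape[1], x$shape[2], x$pixel_size, x$distance, x$wavelength,
    x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Exposure model for image simulation
#'
#' @param flux incident photon flux, photons/s.
#' @param exposure exposure time, s.
#' @param concentration sample concentration, mg/ml.
#' @param transmission sample transmission in `[0, 1]`.
#' @param efficiency detector quantum efficiency in `[0, 1]`.
#' @return An object of class `exposure_model`.
#' @export
exposure_model <- function(flux, exposure, concentration,
                           transmission = 1, efficiency = 1) {
  stopifnot(flux >= 0, exposure >= 0, concentration >= 0,
            transmission >= 0, transmission <= 1,
            efficiency >= 0, efficiency <= 1)
  structure(list(flux = flux, exposure = exposure,
                 concentration = concentration,
                 transmission = transmission, efficiency = efficiency),
            class = "exposure_model")
}

## Radial distance of pixel centres from the beam centre, in mm.
pixel_radius_mm <- function(geometry, i, j) {
  sqrt((i - geometry$beam_center[1])^2 +
       (j - geometry$beam_center[2])^2) * geometry$pixel_size
}

#' Momentum transfer of a detector pixel
#'
#' `s = (4 pi / lambda) sin(theta)` with `2 theta = arctan(r / D)`, where
#' `r` is the in-plane distance of the pixel centre from the beam centre
#' and `D` the sample-detector distance.  In the small-angle limit this
#' reduces to `s ~ 2 pi r / (lambda D)`.
#'
#' @param geometry a [detector_geometry()].
#' @param i,j row and column pixel indices (vectorized, may be fractional).
#' @return Momentum transfer in reciprocal Angstrom.
#' @export
pixel_to_s <- function(geometry, i, j) {
  r <- pixel_radius_mm(geometry, i, j)
  theta <- atan2(r, geometry$distance) / 2
  4 * pi * sin(theta) / geometry$wavelength
}

## s for every pixel of the detector, as a matrix.
detector_s_map <- function(geometry) {
  nr <- geometry$shape[1]; nc <- geometry$shape[2]
  i <- matrix(seq_len(nr), nr, nc)
  j <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  matrix(pixel_to_s(geometry, as.numeric(i), as.numeric(j)), nr, nc)
}

## Solid angle subtended by each pixel: (p^2 / D^2) cos^3(psi) for a flat
## detector normal to the beam, psi the angle off the detector normal.
detector_solid_angle <- function(geometry) {
  nr <- geometry$shape[1]; nc <- geometry$shape[2]
  i <- matrix(seq_len(nr), nr, nc)
  j <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  r <- pixel_radius_mm(geometry, as.numeric(i), as.numeric(j))
  cospsi <- geometry$distance / sqrt(geometry$distance^2 + r^2)
  matrix((geometry$pixel_size / geometry$distance)^2 * cospsi^3, nr, nc)
}

#' Expected photon counts on a detector from an absolute-scale curve
#'
#' Per-pixel expectation
#' `mu_ij = I_abs(s_ij) * c * flux * t * T * eta * dOmega_ij`, with
#' `I_abs` the absolute-scale 1D intensity (cm^-1 per mg/ml) linearly
#' interpolated in `s`, and `dOmega_ij` the pixel solid angle of a flat
#' detector (`pixel_area cos^3 psi / D^2`).  Pixels whose `s` falls
#' outside the curve's range are masked with a warning.
#'
#' @param curve an absolute-scale [saxs_curve()].
#' @param geometry a [detector_geometry()].
#' @param exposure an [exposure_model()].
#' @param mask optional starting binary mask (1 = valid), same shape as the
#'   detector.
#' @return An object of class `detector_expectation`: list with the
#'   real-valued matrix `mu`, `geometry`, `exposure` and binary `mask`.
#' @export
expected_image <- function(curve, geometry, exposure, mask = NULL) {
  stopifnot(inherits(curve, "saxs_curve"),
            inherits(geometry, "detector_geometry"),
            inherits(exposure, "exposure_model"))
  if (curve_scale(curve) != "absolute")
    stop("'curve' must be on absolute scale (see to_absolute_scale)")
  smap <- detector_s_map(geometry)
  if (is.null(mask)) mask <- matrix(1L, geometry$shape[1], geometry$shape[2])
  check_mask(mask, geometry$shape)
  inrange <- smap >= min(curve$s) & smap <= max(curve$s)
  if (any(!inrange & mask == 1L)) {
    warning(sum(!inrange & mask == 1L),
            " pixel(s) outside the curve's s range were masked")
    mask[!inrange] <- 0L
  }
  Iabs <- matrix(0, nrow(smap), ncol(smap))
  Iabs[inrange] <- approx(curve$s, curve$I, xout = smap[inrange])$y
  k <- exposure$concentration * exposure$flux * exposure$exposure *
    exposure$transmission * exposure$efficiency
  mu <- Iabs * k * detector_solid_angle(geometry)
  mu[mask == 0L] <- 0
  structure(list(mu = mu, geometry = geometry, exposure = exposure,
                 mask = mask),
            class = "detector_expectation")
}

check_mask <- function(mask, shape) {
  if (!is.matrix(mask) || !identical(dim(mask), as.integer(shape)))
    stop("mask shape must equal the detector shape")
  if (!all(mask %in% c(0L, 1L)))
    stop("mask must be binary (0/1)")
  invisible(TRUE)
}

#' Simulated photon-counting detector image
#'
#' Draws independent Poisson counts `counts_ij ~ Poisson(mu_ij)` from an
#' expected-count model.  Masked pixels are set to 0.  The seed fully
#' determines the output.
#'
#' @param expected a `detector_expectation` from [expected_image()].
#' @param seed integer RNG seed.
#' @return A [detector_image()] carrying the geometry, mask and exposure
#'   normalization of the expectation.
#' @export
sample_image <- function(expected, seed) {
  stopifnot(inherits(expected, "detector_expectation"))
  if (any(expected$mu < 0)) stop("negative expected counts")
  set.seed(as.integer(seed))
  counts <- matrix(rpois(length(expected$mu), expected$mu),
                   nrow(expected$mu), ncol(expected$mu))
  counts[expected$mask == 0L] <- 0L
  detector_image(counts, expected$geometry, mask = expected$mask,
                 exposure = expected$exposure)
}

#' Detector image container
#'
#' Integer photon counts plus the physical pixel-to-s mapping.  When an
#' [exposure_model()] is attached, radial averaging can convert counts back
#' to absolute-scale intensities.
#'
#' @param counts non-negative integer matrix of photon counts.
#' @param geometry a [detector_geometry()] whose shape matches `counts`.
#' @param mask binary matrix (1 = valid pixel); default all valid.
#' @param exposure optional [exposure_model()] used to produce the image.
#' @return An object of class `detector_image`.
#' @export
detector_image <- function(counts, geometry, mask = NULL, exposure = NULL) {
  stopifnot(inherits(geometry, "detector_geometry"))
  counts <- as.matrix(counts)
  if (!identical(dim(counts), geometry$shape))
    stop("counts shape must equal the detector shape")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (is.null(mask)) mask <- matrix(1L, nrow(counts), ncol(counts))
  check_mask(mask, geometry$shape)
  structure(list(counts = counts, geometry = geometry, mask = mask,
                 exposure = exposure),
            class = "detector_image")
}

#' @export
print.detector_image <- function(x, ...) {
  cat(sprintf("Detector image: %dx%d px, %d masked, %.4g photons total\n",
              nrow(x$counts), ncol(x$counts), sum(x$mask == 0L),
              sum(x$counts)))
  invisible(x)
}

#' Elementwise image and mask arithmetic
#'
#' Addition and subtraction act on photon counts of equal-shaped images;
#' subtraction clamps at 0 (counts are non-negative) and records whether
#' clamping occurred in the `"clamped"` attribute, with a warning.  AND,
#' OR and XOR are for binary operands (masks, or images of 0/1 counts).
#' `apply_mask` permanently zeroes pixels of `a` where `b` is 0 and
#' intersects the masks.
#'
#' @param a a [detector_image()].
#' @param b a [detector_image()] or a binary matrix, same shape as `a`.
#' @param op one of `"add"`, `"sub"`, `"and"`, `"or"`, `"xor"`,
#'   `"apply_mask"`.
#' @return A [detector_image()].
#' @export
image_op <- function(a, b, op = c("add", "sub", "and", "or", "xor",
                                  "apply_mask")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "detector_image"))
  bc <- if (inherits(b, "detector_image")) b$counts else as.matrix(b)
  if (!identical(dim(bc), dim(a$counts)))
    stop("operands must have equal shapes")
  bmask <- if (inherits(b, "detector_image")) b$mask
           else matrix(1L, nrow(bc), ncol(bc))
  mask <- a$mask * bmask
  counts <- switch(op,
    add = a$counts + bc,
    sub = {
      d <- a$counts - bc
      clamped <- any(d < 0)
      if (clamped) warning("negative differences clamped at 0")
      d[d < 0] <- 0
      attr(d, "clamped") <- clamped
      d
    },
    and = , or = , xor = {
      if (!all(a$counts %in% c(0L, 1L)) || !all(bc %in% c(0L, 1L)))
        stop("logic operations require binary operands")
      switch(op,
             and = a$counts * bc,
             or = pmax(a$counts, bc),
             xor = (a$counts + bc) %% 2)
    },
    apply_mask = {
      if (!all(bc %in% c(0L, 1L))) stop("'b' must be a binary mask")
      mask <- a$mask * bc
      a$counts * bc
    })
  clamped <- isTRUE(attr(counts, "clamped"))
  attr(counts, "clamped") <- NULL
  out <- detector_image(counts, a$geometry, mask = mask,
                        exposure = a$exposure)
  attr(out, "clamped") <- clamped
  out
}

#' Write a detector image as 32-bit TIFF
#'
#' Counts are stored as unsigned 32-bit integers.  TIFF carries no
#' geometry; keep the geometry alongside and pass it to [read_image()].
#'
#' @param image a [detector_image()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "detector_image"))
  tiff::writeTIFF(round(image$counts) / (2^32 - 1), path,
                  bits.per.sample = 32L)
  invisible(path)
}

#' Read a detector image from 32-bit TIFF
#'
#' @param path TIFF file written by [write_image()].
#' @param geometry the [detector_geometry()] of the image.
#' @param mask,exposure optional mask and exposure metadata to attach.
#' @return A [detector_image()].
#' @export
read_image <- function(path, geometry, mask = NULL, exposure = NULL) {
  counts <- tiff::readTIFF(path, as.is = TRUE)
  detector_image(matrix(as.numeric(counts), nrow(counts), ncol(counts)),
                 geometry, mask = mask, exposure = exposure)
}
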