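#' 1D scattering curve
#'
#' Container for a one-dimensional small-angle scattering profile: momentum
#' transfer `s = 4*pi*sin(theta)/lambda`, intensity `I(s)` and an optional
#' per-point error estimate `sigma`.  All curves are stored internally with
#' `s` in reciprocal Angstrom; curves supplied in reciprocal nanometre are
#' converted on construction (an exact factor-of-10 change of `s`).
#'
#' @param s numeric, strictly increasing momentum transfer values.
#' @param I numeric intensities, finite, same length as `s`.
#' @param sigma optional numeric error estimates, `>= 0`, same length as `s`.
#' @param s_unit unit of the supplied `s` values, `"A^-1"` (default) or
#'   `"nm^-1"`.
#' @param scale `"relative"` (arbitrary units, e.g. electrons squared) or
#'   `"absolute"` (cm^-1 per unit concentration in mg/ml).
#'
#' @return An object of class `saxs_curve`: a data frame with columns `s`,
#'   `I` and optionally `sigma`, `s` in reciprocal Angstrom, plus a `scale`
#'   attribute.
#' @examples
#' crv <- saxs_curve(s = c(0.01, 0.02, 0.03), I = c(100, 90, 81))
#' crv
#' @export
saxs_curve <- function(s, I, sigma = NULL,
                       s_unit = c("A^-1", "nm^-1"),
                       scale = c("relative", "absolute")) {
  s_unit <- match.arg(s_unit)
  scale <- match.arg(scale)
  s <- as.numeric(s)
  I <- as.numeric(I)
  if (length(s) < 2L)
    stop("a scattering curve needs at least 2 points")
  if (length(I) != length(s))
    stop("'s' and 'I' must have the same length")
  if (s_unit == "nm^-1")
    s <- s / 10
  if (any(!is.finite(s)) || any(!is.finite(I)))
    stop("'s' and 'I' must be finite")
  if (any(diff(s) <= 0))
    stop("'s' must be strictly increasing")
  out <- data.frame(s = s, I = I)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(s))
      stop("'sigma' must have the same length as 's'")
    if (any(!is.finite(sigma)) || any(sigma < 0))
      stop("'sigma' must be finite and >= 0")
    out$sigma <- sigma
  }
  structure(out, class = c("saxs_curve", "data.frame"), scale = scale)
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("SAXS curve: %d points, s in [%.5g, %.5g] A^-1, %s scale, %s\n",
              nrow(x), min(x$s), max(x$s), attr(x, "scale"),
              if (is.null(x$sigma)) "no errors" else "with errors"))
  invisible(x)
}

#' @export
format.saxs_curve <- function(x, ...) format.data.frame(x, ...)

has_sigma <- function(curve) !is.null(curve$sigma)

curve_scale <- function(curve) attr(curve, "scale")

#' Read a 1D scattering curve from a 3-column ASCII file
#'
#' Parses the whitespace-separated `.dat`/`.abs` convention: columns
#' `s I [sigma]`, any number of leading header or comment lines (lines whose
#' first field is not a number, or that start with `#`) are skipped, as are
#' trailing non-numeric lines.
#'
#' @param path path to the file.
#' @param s_unit unit of the `s` column in the file; values are converted to
#'   reciprocal Angstrom on read.
#' @param scale scale flag to attach to the curve; files written by
#'   [write_curve()] with `kind = "abs"` are absolute-scale.
#' @return A [saxs_curve()].
#' @export
read_curve <- function(path, s_unit = c("A^-1", "nm^-1"),
                       scale = c("relative", "absolute")) {
  s_unit <- match.arg(s_unit)
  scale <- match.arg(scale)
  if (!file.exists(path))
    stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(strsplit(lines, "[ \t,]+"), function(f) {
    v <- suppressWarnings(as.numeric(f))
    if (length(v) >= 2L && !anyNA(v[1:2])) v else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) < 2L)
    stop("fewer than 2 numeric rows in ", path)
  ncol <- min(vapply(rows, length, integer(1)))
  m <- t(vapply(rows, function(r) r[seq_len(min(ncol, 3L))], numeric(min(ncol, 3L))))
  sigma <- if (ncol >= 3L && !anyNA(m[, 3L])) m[, 3L] else NULL
  saxs_curve(m[, 1L], m[, 2L], sigma, s_unit = s_unit, scale = scale)
}

#' Write a 1D scattering curve as 3-column ASCII
#'
#' Values are written in scientific notation with 6 significant digits, so
#' that a read/write round trip preserves the curve to printed precision.
#'
#' @param curve a [saxs_curve()].
#' @param path output file path.
#' @param kind `"dat"` for relative-scale data, `"abs"` for absolute-scale
#'   data (requires the curve's scale flag to be `"absolute"`).
#' @return Invisibly, `path`.
#' @export
write_curve <- function(curve, path, kind = c("dat", "abs")) {
  kind <- match.arg(kind)
  stopifnot(inherits(curve, "saxs_curve"))
  if (kind == "abs" && curve_scale(curve) != "absolute")
    stop("kind = \"abs\" requires an absolute-scale curve")
  hdr <- sprintf("# %s  s [A^-1]  I%s%s",
                 if (kind == "abs") "absolute-scale intensities [cm^-1 ml mg^-1]"
                 else "intensities",
                 "", if (has_sigma(curve)) "  sigma" else "")
  fmt <- if (has_sigma(curve)) "%.6e %.6e %.6e" else "%.6e %.6e"
  body <- if (has_sigma(curve))
    sprintf(fmt, curve$s, curve$I, curve$sigma)
  else sprintf(fmt, curve$s, curve$I)
  writeLines(c(hdr, body), path)
  invisible(path)
}

## Check that two curves share a common s grid (relative tolerance per point).
check_common_grid <- function(a, b, tol = 1e-6) {
  if (nrow(a) != nrow(b))
    stop("curves have different numbers of points (", nrow(a), " vs ",
         nrow(b), ")")
  ref <- pmax(abs(a$s), abs(b$s), .Machine$double.eps)
  if (any(abs(a$s - b$s) / ref > tol))
    stop("curves are not on a common s grid (relative tolerance ", tol, ")")
  invisible(TRUE)
}

## Linear interpolation of a curve onto new s values; NA outside the range.
curve_interpolate <- function(curve, s_new) {
  approx(curve$s, curve$I, xout = s_new, rule = 1)$y
}
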