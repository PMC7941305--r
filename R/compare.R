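#' Standardized residuals between two scattering curves
#'
#' `r_i = (I1_i - I2_i) / sqrt(sigma1_i^2 + sigma2_i^2)` on a common `s`
#' grid; a curve without error estimates contributes 0 to the pooled
#' variance.  For two profiles identical up to well-estimated noise the
#' residuals follow a standard normal distribution, so about 99% of them
#' should fall within +/-3.
#'
#' @param a,b [saxs_curve()] objects on identical grids; at least one must
#'   carry error estimates.
#' @return An object of class `saxs_residuals`: numeric residual vector
#'   with attribute `frac_within_3`.
#' @export
residuals_curves <- function(a, b) {
  stopifnot(inherits(a, "saxs_curve"), inherits(b, "saxs_curve"))
  check_common_grid(a, b)
  if (!has_sigma(a) && !has_sigma(b))
    stop("neither curve has error estimates")
  v <- (if (has_sigma(a)) a$sigma^2 else 0) +
       (if (has_sigma(b)) b$sigma^2 else 0)
  if (any(v == 0))
    stop("pooled error estimate is zero at ", sum(v == 0), " point(s)")
  r <- (a$I - b$I) / sqrt(v)
  structure(r, class = "saxs_residuals",
            frac_within_3 = mean(abs(r) <= 3))
}

#' @export
print.saxs_residuals <- function(x, ...) {
  cat(sprintf("Standardized residuals: n = %d, mean = %.3f, sd = %.3f, %.1f%% within +/-3\n",
              length(x), mean(unclass(x)), stats::sd(unclass(x)),
              100 * attr(x, "frac_within_3")))
  invisible(x)
}

#' Reduced chi-square test between two curves
#'
#' `chi2_red = (1/n) sum r_i^2` over the `n` standardized residuals
#' (degrees of freedom `nu = n`: a pure two-curve comparison fits no
#' parameters).  The p-value is the upper-tail probability of a
#' chi-square variable with `nu` degrees of freedom at `nu * chi2_red`.
#'
#' @inheritParams residuals_curves
#' @return List with `statistic`, `p`, `n`.
#' @export
reduced_chi2 <- function(a, b) {
  r <- unclass(residuals_curves(a, b))
  n <- length(r)
  stat <- mean(r^2)
  list(statistic = stat, p = pchisq(n * stat, df = n, lower.tail = FALSE),
       n = n)
}

#' Exact null probability of the longest run (CorMap test)
#'
#' Probability that the longest run of identical outcomes in `n`
#' independent fair Bernoulli trials is at least `C`.  Computed by the
#' exact composition recursion: the number of length-`n` binary sequences
#' whose longest run is at most `m` equals twice the number of
#' compositions of `n` into parts of size at most `m`, evaluated on a
#' probability scale for numerical stability.
#'
#' @param n number of trials (points compared).
#' @param C run length.
#' @return `P(longest run >= C)`, exact to double precision.
#' @examples
#' cormap_pvalue(2652, 13)
#' @export
cormap_pvalue <- function(n, C) {
  n <- as.integer(n); C <- as.integer(C)
  stopifnot(n >= 1L, C >= 1L)
  if (C <= 1L) return(1)
  if (C > n) return(0)
  m <- C - 1L
  ## p[k+1] = (#compositions of k into parts <= m) / 2^k
  p <- numeric(n + 1L)
  p[1L] <- 1
  w <- 2^-(1:m)
  for (k in 1:n) {
    j <- 1:min(m, k)
    p[k + 1L] <- sum(p[k - j + 1L] * w[j])
  }
  1 - 2 * p[n + 1L]
}

#' CorMap longest-run test between two curves
#'
#' Error-independent comparison: the test statistic is the length `C` of
#' the longest run of consecutive points at which the difference
#' `I1 - I2` keeps the same sign (a zero difference counts as positive;
#' exact ties have measure zero on real data).  Under the null hypothesis
#' that the two curves differ only by symmetric noise, the signs are
#' independent fair Bernoulli trials and the p-value is the exact
#' longest-run probability of [cormap_pvalue()].
#'
#' @param a,b [saxs_curve()] objects on identical grids (no error
#'   estimates required).
#' @return List with `statistic` (longest run `C`), `p`, `n`.
#' @export
cormap <- function(a, b) {
  stopifnot(inherits(a, "saxs_curve"), inherits(b, "saxs_curve"))
  check_common_grid(a, b)
  d <- a$I - b$I
  sgn <- ifelse(d >= 0, 1L, -1L)
  C <- max(rle(sgn)$lengths)
  list(statistic = C, p = cormap_pvalue(length(d), C), n = length(d))
}

## Asymptotic CDF of the Anderson-Darling statistic for a fully specified
## null distribution (case 0).  Classic series representation of the
## limiting distribution; each term needs a one-dimensional quadrature.
## Accurate to ~1e-8 over the range of practical interest.
ad_cdf_asymptotic <- function(z) {
  if (z <= 0) return(0)
  if (z > 32) return(1)
  tot <- 0
  for (j in 0:12) {
    cj <- (-1)^j * gamma(j + 0.5) * (4 * j + 1) / (gamma(0.5) * factorial(j))
    aj <- (4 * j + 1)^2 * pi^2 / (8 * z)
    if (aj > 700) break  # exp underflow; remaining terms negligible
    intg <- integrate(function(w) exp(z / (8 * (w^2 + 1)) - aj * w^2),
                      0, Inf, rel.tol = 1e-12)$value
    term <- cj * exp(-aj) * intg
    tot <- tot + term
    if (abs(term) < 1e-14 * max(abs(tot), 1e-300)) break
  }
  min(max(tot * sqrt(2 * pi) / z, 0), 1)
}

#' p-value of the Anderson-Darling A-squared statistic (case 0)
#'
#' Upper-tail probability of the asymptotic Anderson-Darling distribution
#' for a fully specified (standard normal) null: no parameters estimated
#' from the data.  For `A2 > 12` the survival probability underflows the
#' asymptotic series and 0 is reported.
#'
#' @param A2 observed A-squared statistic.
#' @return `P(A^2 >= A2)` under the asymptotic null distribution.
#' @examples
#' ad_pvalue(0.320)
#' @export
ad_pvalue <- function(A2) {
  stopifnot(is.numeric(A2), length(A2) == 1L)
  if (A2 > 12) return(0)
  1 - ad_cdf_asymptotic(A2)
}

#' Anderson-Darling test of standardized residuals between two curves
#'
#' Tests the goodness of fit of the distribution of standardized
#' residuals to the standard normal distribution (fully specified, case
#' 0).  `A2 = -n - (1/n) sum (2i-1)[ln Phi(r_(i)) + ln(1 - Phi(r_(n+1-i)))]`
#' on the sorted residuals; the p-value comes from the asymptotic A-squared
#' distribution ([ad_pvalue()]).  The asymptotic approximation is poor for
#' fewer than ~8 points (a warning is issued).
#'
#' @inheritParams residuals_curves
#' @return List with `statistic` (A-squared), `p`, `n`.
#' @export
anderson_darling <- function(a, b) {
  r <- sort(unclass(residuals_curves(a, b)))
  n <- length(r)
  if (n < 8L)
    warning("Anderson-Darling asymptotic p-value is unreliable for n < 8")
  ## clamp Phi away from 0/1 to keep the logs finite
  u <- pmin(pmax(pnorm(r), 1e-300), 1 - 1e-16)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  list(statistic = A2, p = ad_pvalue(A2), n = n)
}

#' All three pairwise comparison statistics
#'
#' Runs the CorMap longest-run test, the reduced chi-square test and the
#' Anderson-Darling test on a pair of curves and collects statistics and
#' p-values.  The CorMap test is error-independent; the other two require
#' error estimates on at least one curve.
#'
#' @inheritParams residuals_curves
#' @return An object of class `saxs_comparison` with fields `n`,
#'   `cormap_C`, `cormap_p`, `chi2_red`, `chi2_p`, `ad_A2`, `ad_p`.
#' @export
datcmp <- function(a, b) {
  cm <- cormap(a, b)
  c2 <- reduced_chi2(a, b)
  ad <- anderson_darling(a, b)
  structure(list(n = cm$n,
                 cormap_C = cm$statistic, cormap_p = cm$p,
                 chi2_red = c2$statistic, chi2_p = c2$p,
                 ad_A2 = ad$statistic, ad_p = ad$p),
            class = "saxs_comparison")
}

#' @export
print.saxs_comparison <- function(x, ...) {
  cat(sprintf("Pairwise comparison (n = %d)\n", x$n))
  cat(sprintf("  %-18s %10s %10s\n", "", "statistic", "p"))
  cat(sprintf("  %-18s %10d %10.4g\n", "CorMap (run length)", x$cormap_C,
              x$cormap_p))
  cat(sprintf("  %-18s %10.4f %10.4g\n", "Reduced chi-square", x$chi2_red,
              x$chi2_p))
  cat(sprintf("  %-18s %10.4f %10.4g\n", "Anderson-Darling", x$ad_A2,
              x$ad_p))
  invisible(x)
}

#' Parametric resampling of a scattering curve
#'
#' Generates replicate curves by drawing each intensity from a normal
#' distribution centred on the observed intensity with standard deviation
#' `scale * sigma_i`; the recorded `sigma` is carried over unchanged.
#' Used to attach variability estimates to point-estimate quantities
#' (e.g. the spread of Guinier radii over replicates) or to augment
#' training data.
#'
#' @param curve a [saxs_curve()] with error estimates.
#' @param n number of replicates.
#' @param scale multiplier on `sigma` for the sampling width; default 1.
#' @param seed integer RNG seed (deterministic output).
#' @return List of `n` [saxs_curve()] replicates.
#' @export
resample_curve <- function(curve, n, scale = 1, seed) {
  stopifnot(inherits(curve, "saxs_curve"), n >= 1, scale >= 0)
  if (!has_sigma(curve)) stop("'curve' has no error estimates")
  set.seed(as.integer(seed))
  npt <- nrow(curve)
  lapply(seq_len(n), function(i) {
    saxs_curve(curve$s, curve$I + rnorm(npt, 0, scale * curve$sigma),
               sigma = curve$sigma, scale = curve_scale(curve))
  })
}
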