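---
title: "Methods: simulating, reducing and validating SAXS data with saxskit"
author: "saxskit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, reducing and validating SAXS data with saxskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxskit)
```

`saxskit` closes the loop that a small-angle X-ray scattering (SAXS)
experiment traverses: from atomic coordinates to a 1D scattering curve, from
that curve to a simulated 2D photon-counting detector image, back to a
reduced 1D curve with honest error estimates, and on to statistical
comparison and model-free structural parameters.  Because every stage is
available in one place, each stage can be cross-validated against the
others — the reduced curve against the source model, error estimates against
replicate scatter, real-space distributions against their reciprocal-space
origin.  This vignette explains the models behind each stage, the tunable
parameters and their defaults, and the design decisions taken where the
methods left genuine freedom.

## Scattering intensities from coordinates

The 1D intensity of a particle in vacuo is computed by the Debye double sum
over atoms,

$$I(s) \;=\; \sum_{j}\sum_{k} \mathrm{Re}\!\left[f_j(s,E)\,f_k^*(s,E)\right]
w_j w_k \,\frac{\sin(s\,r_{jk})}{s\,r_{jk}},$$

with $s = 4\pi\sin\theta/\lambda$ (reciprocal &Aring;ngstr&ouml;m
throughout), $r_{jk}$ the interatomic distance, and $w_j$ the occupancy,
which enters as a linear weight on the form factor.  The sum is exact for
point models — there is no multipole truncation order to choose — at
$O(N^2 \cdot |s|)$ cost, which is practical for desk-scale models up to a
few thousand atoms (the pair loop is compiled code).  Two deliberate
simplifications: no hydration shell and no excluded-volume solvent term are
applied, so curves are vacuum intensities.  Fitting calculated curves to
experimental data is out of scope.

Atomic form factors are
$f(s, E) = f_0(s) + f'(E) + i\,f''(E)$.  The wavelength-independent part
$f_0$ uses the 4-Gaussian-plus-constant Cromer–Mann coefficients of the
International Tables for Crystallography (shipped as a plain-text table,
provenance in the file header; the package validates $f_0(0) = Z$ within
0.1 electron for every element from H to U).  The anomalous corrections
$f'$, $f''$ are linear interpolations on (energy, $f'$, $f''$) tables.
Built-in theoretical Cromer–Liberman tables cover common absorption-edge
elements between 1.0 and 29.4 keV on energy grids refined around the edges;
a user table in the same two-or-three-column ASCII format overrides the
built-in one through the identical lookup path, so experimentally calibrated
edge values can be dropped in without code changes.  Linear interpolation
was chosen deliberately: the tables are dense near edges, where higher-order
schemes risk overshooting the sharp $f'$ dip.  In anomalous mode the
correction is applied to every atom of the one designated element; all
other elements scatter normally.  The full complex modulus
$|f|^2 = (f_0 + f')^2 + f''^2$ is kept, including the $f''^2$ term.  With
$f' = f'' = 0$ the anomalous path is bit-identical to the regular path,
which the test suite asserts.

Absolute-scale output (cm$^{-1}$ per mg/ml) multiplies the
electrons$^2$ curve by $r_e^2 N_A \cdot 10^{-3} / \mathrm{MW}$, with
$r_e^2 = 7.9407\times10^{-26}\,$cm$^2$ the squared Thomson scattering
length.

## Detector image simulation

Image simulation is purely statistical: systematic instrument effects
(polarization, point-spread, dead time, self-absorption) are deliberately
omitted, so that the reduced 1D data have exactly the statistical properties
the downstream tests assume.  The expected count in pixel $(i,j)$ of a flat
detector normal to the beam is

$$\mu_{ij} = I_{\mathrm{abs}}(s_{ij})\; c\,\Phi\, t\, T\, \eta\;
\Delta\Omega_{ij},\qquad
\Delta\Omega_{ij} = \frac{p^2}{D^2}\cos^3\psi_{ij},$$

with concentration $c$, flux $\Phi$, exposure $t$, transmission $T$,
quantum efficiency $\eta$, pixel size $p$, sample–detector distance $D$ and
$\psi$ the angle off the detector normal; $s_{ij}$ follows from
$2\theta = \arctan(r/D)$.  The $\cos^3\psi$ solid-angle factor is the
standard flat-detector geometry (one $\cos^2$ for distance, one $\cos$ for
obliquity).  $I_{\mathrm{abs}}$ is interpolated linearly in $s$; pixels
outside the curve's range are masked with a warning.  Counts are then
independent Poisson draws, fully determined by one integer seed.  Image
arithmetic (add/sub) and mask logic (AND/OR/XOR, permanent mask
application) allow the classic consistency check of summing frames before
versus after reduction; subtraction clamps at zero since counts are
non-negative, recording that clamping occurred.  Images interchange as
32-bit TIFF; multi-frame HDF5 stacks are not supported (no suitable R
package is available), which is the one format limitation versus the usual
beamline toolchain.

## Radial averaging and outlier rejection

Reduction collapses an image into rings of constant $s$: equal-width bins
between the smallest and largest $s$ of unmasked pixels.  Each pixel
belongs to exactly one ring — no pixel splitting — because splitting would
correlate neighbouring intensity estimates in ways that cannot be tracked
through later error propagation.  A consequence worth noting is that ring
estimates are statistically independent, which the tests exploit.

Within a ring, outliers (hot or dead pixels, zingers) are detected on the
raw counts: the Anscombe transform $y = 2\sqrt{x + 3/8}$ brings Poisson
counts close to unit-variance normality, a median-based robust $z$ score
$z = 0.6745\,(y - \mathrm{med}\,y)/\mathrm{MAD}(y)$ is formed, and values
with $|z| > 4$ are rejected.  When the MAD is zero (a degenerate, constant
ring) nothing is rejected.  Rejection is two-sided by default — a dead
pixel among bright ones is as suspicious as a hot one — with a one-sided
option.  The ring intensity is the mean of kept counts, each normalized by
its per-pixel factor $c\,\Phi\,t\,T\,\eta\,\Delta\Omega_{ij}$ when the
image carries exposure metadata (recovering absolute units), and the error
estimate follows Poisson counting statistics,
$\sigma = \sqrt{\textstyle\sum c_i / g_i^2}\,/\,N$ for normalization
factors $g_i$, which reduces to $\sqrt{\sum c_i}/N$ for bare counts.  The
ring's $s$ is the unweighted mean $s$ of its kept pixels
(intensity-weighting would couple the abscissa to the noise); empty rings
are omitted.

## Comparing scattering curves

Three complementary two-sample tests operate on curves sharing a grid
(relative tolerance $10^{-6}$ per point), all built on the standardized
residuals $r_i = (I^{(1)}_i - I^{(2)}_i)/\sqrt{\sigma_{1,i}^2 +
\sigma_{2,i}^2}$ where errors are involved:

* **Reduced $\chi^2$** — $\chi^2_\nu = \frac1n \sum r_i^2$ with $\nu = n$
  degrees of freedom: nothing is fitted in a pure two-curve comparison.
  The $p$-value is the upper tail of the $\chi^2_\nu$ distribution at
  $\nu \chi^2_\nu$.  It requires well-estimated errors.
* **Longest-run (CorMap) test** — error-independent.  The statistic is the
  length $C$ of the longest run of same-sign differences; zero differences
  count as positive (exact ties have measure zero on real data).  The
  $p$-value is exact: the number of length-$n$ binary sequences whose
  longest run is at most $m$ equals twice the number of compositions of $n$
  into parts $\le m$, and the recursion is evaluated directly on the
  probability scale so that $n$ in the thousands costs microseconds and no
  big-number arithmetic.
* **Anderson–Darling test** — the empirical distribution of the $r_i$
  against the standard normal, fully specified (case 0, no estimated
  parameters).  The $p$-value evaluates the asymptotic distribution of
  $A^2$ through its classical series representation, each term requiring
  one one-dimensional quadrature; the implementation was verified against
  an independent evaluation of the same distribution by numerical inversion
  of its characteristic function (agreement to about $10^{-6}$), and that
  oracle ships in the test suite.  Above $A^2 = 12$ the survival
  probability underflows and 0 is reported.  Below about 8 points the
  asymptotic approximation is unreliable and a warning is issued.

For two profiles identical up to well-estimated noise the residuals are
standard normal, so roughly 99% should fall within $\pm 3$; the residual
container reports that fraction.  Parametric resampling draws replicate
curves $I^*_i \sim N(I_i, (k\sigma_i)^2)$ to attach variability estimates
to point-estimate quantities (the spread of Guinier radii over replicates
against the regression standard error is one of the package's tests).  The
$\sigma$ scale factor $k$ defaults to 1 and is exposed, since different
error-calibration conventions exist.  No multiple-testing correction is
applied to the three $p$-values.

## Real-space distributions

The pair distance distribution is obtained by a direct Fourier transform —
no regularization —

$$p(r) = \frac{r}{2\pi^2}\int_0^\infty s\,I(s)\,\sin(sr)\,\mathrm{d}s,$$

split into three segments.  Below the first measured point the curve is
continued with the Guinier model $I_0 e^{-s^2 R_g^2/3}$, which is why $R_g$
and $I_0$ are required inputs.  Over the measured range the integral is a
trapezoid sum on the data's own grid (no resampling; the method works best
on low-noise, oversampled, equidistant data).  Beyond the last point the
curve is extrapolated as $A\,s^{-n}$ with selectable exponent ($n = 4$ for
globular particles, 2 for flexible chains) and integrated numerically to a
cutoff of 10 times the last measured $s$ on a grid fine enough to resolve
$\sin(sr)$ at $r = D_\mathrm{max}$; the amplitude $A$ is fitted over the
top 10% of the $s$ range by linear least squares, which — unlike a log-log
fit — is not dragged down by near-zero intensities at form-factor minima.
The cutoff and window are exposed parameters since no canonical values
exist.  The result is reported on 101 points (default) over
$[0, D_\mathrm{max}]$, with $p(0) = 0$ automatically, the endpoint pinned
to zero, and evaluation beyond $D_\mathrm{max}$ returning zero.  Derived
quantities come from moments: $I(0) = 4\pi\int p\,\mathrm{d}r$ and
$R_g^2 = \int r^2 p\,\mathrm{d}r / (2\int p\,\mathrm{d}r)$, a useful
cross-validation of the Guinier estimates because they use the whole curve
rather than the lowest angles.

The forward transform
$I(s) = 4\pi \int_0^{D_\mathrm{max}} p(r)\,\mathrm{sinc}(sr)\,\mathrm{d}r$
closes the pair, allowing any distribution — computed or modelled — to be
checked against measured data with the comparison statistics.

**Known limitation.** The tail continuation suppresses termination ripples
by an order of magnitude for curves whose high-angle tail genuinely follows
a smooth power law (the package tests this on an exponential-correlation
model with an exact $s^{-4}$ tail).  For an ideal sphere the tail
*oscillates* about its Porod envelope, and the oscillatory component —
which a smooth $A s^{-4}$ model cannot represent — resonates at
$r \approx 2R$, leaving a residual deviation near $D_\mathrm{max}$ of
order 1% of the peak that the continuation cannot remove.  Real particles
are less pathological than the mathematical sphere, but deviations near
$D_\mathrm{max}$ should not be over-interpreted.

## Model-free invariants

The Guinier fit is a weighted linear regression of $\ln I$ on $s^2$ over
the largest window satisfying $s R_g \le$ `srg_limit`, iterated to
self-consistency since the window depends on the answer.  The default limit
is 1.3 (conventional for globular particles; the approximation itself is
usually quoted for $s < 1/R_g$) and is exposed.  Weights are
$(I/\sigma)^2$ — the variance of $\ln I$ — or $I^2$ when no errors are
recorded (the same formula with homoscedastic absolute error).  The linear
Guinier estimator carries a small systematic bias on strongly curved
profiles: for the ideal sphere at `srg_limit = 1.0` it overestimates
$R_g$ by about 1%, which bounds what the sphere-based tests can assert.

The Porod invariant $Q_p = \int s^2 I\,\mathrm{d}s$ and the volume of
correlation denominator $\int s I\,\mathrm{d}s$ are trapezoid sums plus an
analytic continuation of the fitted Porod tail ($A/s_{\max}$ and
$A/2s_{\max}^2$ respectively).  The tail amplitude is the mean of $s^4 I$
over the last 25% of the $s$ range — wider than the 10% window used in the
transform module because the amplitude, unlike a fitted-exponent shape, is
phase-sensitive when the window covers less than a form-factor oscillation
period.  The continuation is skipped with a warning when the window means
of $s^4 I$ over the last two quarter-windows disagree by more than 40%,
a deliberately oscillation-tolerant test that still catches $s^{-2}$
chain-like tails and flat backgrounds.  From these,
$V_p = 2\pi^2 I_0/Q_p$, $V_c = I_0/\int sI\,\mathrm{d}s$, and two
concentration-independent molecular weight estimates:
$\mathrm{MW}_{V_p} = V_p \cdot 10^{-24} N_A/\bar v$ (pure unit bookkeeping
at partial specific volume $\bar v = 0.74\,$cm$^3$/g by default — no
empirical shrinkage correction is applied, a documented difference from
tools that divide by an effective 1.6–1.7) and the published
volume-of-correlation power law
$\mathrm{MW}_{V_c} = (V_c^2/R_g/c)^k$ with the Rambo–Tainer constants for
protein ($c = 0.1231$, $k = 1$) or RNA ($c = 0.00934$, $k = 0.808$).
Every invariant is strictly unchanged under $I \mapsto kI$, which the test
suite asserts over random scalings.  The Bayesian consensus MW estimate
combining several methods is not implemented; the report carries the
individual estimates.

## Synthetic data and what the tests do and do not show

All tests run on generated data; nothing is downloaded.  The oracles are
closed forms: the solid-sphere intensity
$I_0 [3(\sin x - x\cos x)/x^3]^2$ and its distance distribution
$N r^2 (1 - \tfrac32 u + \tfrac12 u^3)$, uniform points in a ball
(radial inverse-CDF sampling), Gaussian noise with recorded $\sigma$, and
an exponential-correlation model with an exact $s^{-4}$ tail.  The
simulation round-trip testbed images a 25 &Aring; sphere (30 kDa,
$I(0) = 2.5\times10^8$ e$^2$, matching the $\approx 0.53\,e/\mathrm{Da}$
rule) with a 1% flat buffer-like background on a 1024$^2$ detector
(0.172 mm pixels, $D = 6$ m, $\lambda = 1$ &Aring;, beam in a corner so a
full radial range of ~2600 rings is available), at $10^{13}$ ph/s, 1 s,
5 mg/ml — per-pixel expectations between roughly 160 and 16500 counts.
The repeated-calibration test uses a 512$^2$ detector at proportionally
shorter distance, a size chosen so that 100 repeats complete in well under
a minute.  The background term matters: without it, Poisson expectations
vanish at the sphere's form-factor zeros and the error model degenerates.

These conditions emulate counting statistics, geometry and solid-angle
effects — not detector point-spread, flat-field error, beam polarization,
parasitic scattering or radiation damage.  A passing round trip therefore
shows that reduction and error propagation are *statistically calibrated*
(reduced $\chi^2 \approx 1$, uniform $p$-values, 99% of residuals within
$\pm3$) under ideal instrument behaviour; it does not certify robustness
to systematic instrument artefacts, which is exactly the property the
original method claims and no more.

## Numerical choices

Grid matching for 1D operations uses relative tolerance $10^{-6}$ per
point.  The CorMap recursion is exact in double precision (verified against
complete enumeration for $n \le 20$).  Normal CDF values inside the
Anderson–Darling statistic are clamped away from 0 and 1 to keep logs
finite.  Curve files are written in scientific notation with 6 significant
digits, making write/read round trips lossless to printed precision.  PDB
serial numbers beyond 99999 are renumbered modulo with a warning
(hybrid-36 encoding is intentionally not attempted; the toolkit targets
desk-scale structures), and mmCIF parsing is a header-driven reader of the
`atom_site` category only — first model, altloc blank or `A`, waters
removable by flag.  Element symbols fall back to the atom-name convention
when the element column is absent.
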