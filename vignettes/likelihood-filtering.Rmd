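---
title: "Likelihood-based filtering of single-event particle imaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-based filtering of single-event particle imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In proton and helium CT every detected particle is recorded individually:
its position and direction at a front and a rear tracker plane, and its
residual energy, converted to a water-equivalent path length (WEPL). The
reconstructed quantity is the relative stopping power (RSP) map of the
object. Most detected particles interacted only electromagnetically -
multiple Coulomb scattering (MCS) and energy straggling - and their WEPL
carries clean information. A minority underwent nuclear interactions:
elastic scatters to large angles, inelastic collisions that degrade or
destroy the projectile, and (for helium) fragmentation into lighter
products. These histories carry WEPL values unrelated to the traversed
material and inflate image noise; for multi-nucleon ions like helium they
are frequent enough to dominate the noise budget. Filtering them out
before reconstruction is therefore essential.

`ionct` implements and compares two filters:

* the **sigma filter** (baseline): events are binned into transverse
  pixels; per pixel, the mean and standard deviation of WEPL and of the
  scattering angle are estimated from the values within 0.7x to 1.3x the
  bin mode, and events farther than `sigma_t` standard deviations from
  the bin mean are removed. With `sigma_t = 3` this is the common
  "3-sigma filter".
* the **likelihood (prior) filter**: each particle is compared against an
  electromagnetic-model prediction computed through a *prior* RSP map -
  a previous reconstruction, or the known phantom in simulation studies.
  The prediction supplies an expected exit position/direction (straight
  transvection of the entrance vector) with a Fermi-Eyges covariance, and
  an expected WEPL (line integral of the prior along a most-likely path)
  with a Tschalar straggling width. An event whose measured residual lies
  outside the `Pt`-coverage region of any of the three components
  (lateral plane, vertical plane, WEPL) is rejected.

## The electromagnetic model

**Stopping power.** The Bethe formula for water,
$SP(E) = z^2 \frac{K}{\beta^2}\left[\ln\frac{2 m_e c^2 \beta^2}
{I_w (1-\beta^2)} - \beta^2\right]$,
with $I_w = 75$ eV and no shell, density or Barkas corrections. The
coefficient $K = 4\pi N_A r_e^2 m_e c^2 (Z/A)\rho = 0.1704$ MeV/cm for
water (sometimes quoted in keV/cm; `stopping_power(200)` returns
0.4491 MeV/mm, matching reference tables to better than 0.1%). CSDA
ranges come from a cached 1 keV-resolution integration of $1/SP$; WEPL
arithmetic is range differences, so the fixed low-energy cutoff
(0.5 MeV) cancels.

**Multiple Coulomb scattering.** Fermi-Eyges moments with Highland's
correction,
$\sigma_\theta^2 = f^2 \int (z E_0/pv)^2\, dx/X_0(x)$ with
$E_0 = 14.1$ MeV, $f = 1 + \ln(T)/9$ and $T$ the total path length in
radiation lengths (natural logarithm; the bracket is clamped at 0.25 far
outside Highland's validity range, which only ever matters for
vanishingly thin air paths). First and second moments use $(x_1 - x)$ and
$(x_1-x)^2$ weights, giving a symmetric positive-semidefinite covariance
shared by both transverse planes. Radiation lengths follow the
two-material approximation: water (36.1 cm) wherever the local RSP
exceeds 0.1, air (3.5e4 cm) elsewhere. The integrals are evaluated by
per-segment 5-point Gauss-Legendre quadrature on the profile's
piecewise-linear energy interpolant, which is exact for practical
purposes and lets the moments be validated against adaptive quadrature
to below 1e-6 relative error.

**Energy straggling.** Tschalar's thick-absorber variance
$\sigma_E^2(E_{out}) = k_1^2(E_{out}) \int_{E_{out}}^{E_{in}}
k_2/k_1^3\, dE$, where $k_1$ is the stopping power and
$k_2 = z^2 \eta_e K m_e c^2 (1-\beta^2/2)/(1-\beta^2)$ is the
relativistic Bohr straggling rate (the extra factor $m_e c^2$ makes the
rate dimensionally MeV^2 per length; with it, the predicted WEPL spread
of 200 MeV protons behind 20 cm of water is 2.6 mm, in line with
published Monte Carlo noise floors). $\eta_e$, the electron-density
ratio to water, defaults to 1: the medium is approximated as water, and
heterogeneity enters only through the RSP line integral.

**Paths.** Between the trackers the particle travels in straight lines
through air; inside the convex hull of the object support it follows a
phenomenological cubic spline: a Hermite segment interpolating the
hull-boundary crossings of the entrance/exit rays, with tangents along
the measured directions scaled by the hull chord length. The chord-length
tangent scale is the main fidelity knob of this path model; the cited
phenomenological splines add WET-dependent direction scalings that this
package deliberately omits (their parameters are not reproducible from
the sources at hand), at a cost that is second order for filtering
because the WEPL prediction only needs the path to stay inside the right
material. Paths are sampled at about 1 mm along the beam axis and arc
length is approximated by the axial coordinate (small-angle optics;
deflections are tens of mrad).

## The filter decision

Residuals are mapped to *coverage probabilities*: univariate
$p = \mathrm{erf}(|\Delta|/\sigma\sqrt{2})$ for WEPL, and for each
transverse plane the chi-square(2) CDF of the Mahalanobis radius of
$(\Delta y, \Delta\theta)$ under the Fermi-Eyges covariance. Under a
correct model each coverage is uniform on [0, 1], so the acceptance rule
"reject when coverage exceeds `Pt`" keeps exactly a fraction `Pt` of
ideal primaries per component and reproduces the published
threshold-to-sigma mapping (1 sigma corresponds to `Pt = 0.68`). This
coverage reading is the only dimensionally consistent interpretation of
thresholding a "likelihood" against a pure number, and it is the one the
package implements; a product rule over the three components is
available as an option (`combine = "product"`).

Two floors are applied after model evaluation, both 3 mm: on the
positional standard deviation and on the WEPL standard deviation. They
guard against unreasonably narrow envelopes for particles crossing
little material and stand in for the unmodelled measurement resolution.
Working points follow the published choices: `Pt = 0.6` for protons,
`Pt = 0.4` for helium.

Note a consequence of the coverage rule that matters when comparing
noise numbers: with an ideal prior, cutting at `Pt = 0.4` retains only
events within about 0.5 floored sigma of the WEPL prediction, so the
*retained* WEPL spread is a strongly truncated version of the straggling
width. The filtered helium radiograph noise this package measures
(~0.8-0.9 mm WET centrally) is therefore *below* the published ~2 mm,
which is only compatible with a looser effective cut; see the README's
reproduction notes for the full discussion.

## The synthetic-data generator

The simulator is a condensed-history Monte Carlo sharing its
electromagnetic models with the filter - by construction, parameter
recovery (simulated spreads matching Fermi-Eyges and Tschalar within a
few percent at n = 1e5) ties the two together and is asserted in the
test suite. Its conditions emulate the reference setup: 200 MeV/u
beams, uniform parallel field with no angular spread, a 20 cm water
cylinder centred between ideal tracker planes with 5 cm air gaps, 1 mm
steps. Per step it applies Bethe mean loss, Gaussian straggling with the
local Bohr rate scaled by RSP, and a Highland angular kick; the
full-path logarithmic correction is applied as a per-history aggregate
factor computed from the straight-ray object chord (exact only in
aggregate, validated by the recovery tests).

Nuclear interactions are a parameterised stand-in for full
nuclear-physics transport, sampled per mm of WEPL:

* default total interaction probabilities over 20 cm of water: ~20% for
  protons, ~35% for helium, in line with the magnitudes quoted for these
  beams;
* **elastic** events get a single large-angle kick (30 mrad protons,
  15 mrad helium) and keep their WEPL - truth-labelled secondary, per
  the convention that hadron-elastic scatters count as secondaries;
* **inelastic** events destroy the projectile in 98% of cases; the rare
  survivors carry an exponential energy-loss excess (mean 30/60 MeV) and
  a 100 mrad-scale kick;
* **fragmentation** (helium) yields, in 35% of cases, a single detected
  charge-1 product (proton-, deuteron- or triton-like with
  probabilities 0.35/0.40/0.25) at the parent's velocity scaled by a
  uniform per-nucleon energy fraction U(0.65, 1), plus a 15 mrad kick;
  otherwise no charged product reaches the detector.

Detected fragments are assigned WEPL through the *helium* calibration,
like a real single-channel energy detector would: proton-like products
read as extreme (250-260 mm) WEPL and are largely removed by the hard
cuts and the 3-sigma envelope, while deuteron/triton-like products
overlap the primary WEPL peak, skew the per-pixel statistics and inflate
the 3-sigma-filtered helium noise to the published several-mm level.
This composition - not the interaction rate - is the calibrated part of
the nuclear model: rates were fixed first from the literature
magnitudes, and the fragment-spectrum shape parameters were then chosen
once so that the labelled simulation reproduces Monte-Carlo-grade
filtered noise (central helium 3-sigma noise ~7 mm WET). All of it
lives in `nuclear_model()` as configuration, never hard-coded in the
transport.

What the generator does **not** emulate: detector pile-up and dead time,
tracker resolution (planes are ideal), beam divergence and spot
structure, genuine nuclear secondary spectra (multiplicities, neutral
particles - electrons, neutrons and gammas are never emitted, matching
the reference analysis which removed them), and anatomical phantoms.
Passing tests therefore demonstrate internal consistency of filter and
physics and qualitative fidelity of the noise phenomenology, not
detector-level realism.

## Reconstruction and noise maps

`ddb_reconstruct()` implements distance-driven binning with filtered
backprojection in parallel geometry: per projection, each event's WEPL
is deposited along its spline path into depth-resolved lateral bins
(1 mm depth, lateral bins matching the 0.625 mm output grid at the
default 320-pixel/200 mm field of view); each depth row is convolved
with a spatial-domain Ram-Lak kernel and backprojected with
$\pi/n_{proj}$ weighting, each image pixel reading from the row at its
own depth. Only a central 2D slice is reconstructed. The Ram-Lak kernel
uses the closed-form taps with the truncation residual removed at the
outermost taps so its DC response is exactly zero.

The companion noise map backprojects, per depth row, the squared
standard error of the binned WET (sample variance over the bin count)
convolved with the squared kernel, and returns the square root of the
summed variance. Where the printed normalisation of this estimator is
ambiguous ("standard error" wording plus an explicit division by the
count), the package defaults to the reading consistent with sampling
theory - numerator `sd^2/N` - which is the one that makes the noise map
scale as $1/\sqrt{N}$ with event count and match the homogeneous
closed form; the literal double-normalised reading is available as
`variance_mode = "per-count"`.

## Numerical choices and degenerate inputs

* Pixel statistics: WEPL modes on 1 mm histogram bins, scattering-angle
  modes on 2 mrad bins, lowest bin on ties; bins with fewer than 3
  in-window events never reject; a scattering-angle mode below 1 mrad
  degenerates the multiplicative window and falls back to plain
  per-pixel statistics. Rejection is strict (`>` threshold), so
  zero-variance bins keep all their members.
* Hull: threshold RSP > 0.1 on the central slice, convex polygon of
  supra-threshold voxel centres; tangent rays count as misses; events
  missing the hull use straight-line paths and the floors dominate
  their envelopes.
* Covariance floors: the 3 mm positional floor raises the (y, y) entry;
  the off-diagonal is clipped to keep the matrix positive definite.
* Tomography: problem sizes in the shipped tests are chosen for
  desk-scale runs - 1e6-history single projections for the noise
  study, 90 x 3000-history projections on a 160-pixel grid for the
  reconstruction accuracy check; the same code runs the full-size
  setting unchanged.

## Known limitations

* The nuclear model is phenomenological; sensitivity/specificity values
  depend on its composition, so only orderings and qualitative shapes
  (the likelihood filter's ROC dominating the sigma filter's for
  helium) are asserted, not absolute rates.
* The spline path omits the cited WET-dependent tangent scalings, and
  path uncertainty is not propagated into the covariance.
* The coverage thresholds assume Gaussian cores; genuinely heavy-tailed
  single-scatter events inside the acceptance region are retained by
  design, mirroring the truth-labelling convention.
* Helium energies are accepted per nucleon at the interfaces and
  converted to total internally; fragments are transported with their
  own rest mass and charge.
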