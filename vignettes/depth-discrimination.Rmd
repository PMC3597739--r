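---
title: "Depth discrimination from paired off-axis detector scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth discrimination from paired off-axis detector scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(dotdepth)
```

## The measurement and the model

In parallel-plate transmission diffuse optical imaging (the geometry of
scanning optical mammography), a source fiber on one plate and detector
fibers on the other are scanned in tandem over the compressed tissue, and
the transmitted continuous-wave intensity is recorded as a 2D raster
image. A single projection image carries no depth information. This
package implements a depth-discrimination method based on *paired*
detectors separated by an in-plane offset vector of length deltaD: an
absorbing structure at depth z appears laterally displaced between the two
detector images, by a shift alpha * deltaD with alpha in [0, 1]. The
offset parameter alpha grows monotonically from 0 (structure on the source
plate) to 1 (structure on the detector plate), so measuring alpha measures
depth.

The quantitative link between alpha and z/d0 (depth over plate separation)
is the *depth curve*, computed from a first-order Born perturbation model
in the infinite-medium diffusion approximation. The CW fluence Green's
function is G(r) = exp(-mu_eff r) / (4 pi D r), with D = 1/(3 mu_s') and
mu_eff = sqrt(3 mu_a mu_s') in the default convention (a
mu_a-inclusive variant is available through
`optical_medium(convention =)`; for the weakly absorbing media of interest
the two differ by well under a percent, and the convention in force is
recorded in every output). The relative intensity perturbation of a point
absorber of strength V * delta_mu_a is

dI/I0 = -V delta_mu_a G(|s-p|) G(|p-d|) / G(|s-d|),

negative for an absorber, and extremal (over lateral translation) when the
defect sits on the source-detector line. Because the constant prefactor
cancels in any extremum localization, the depth curve depends on the
medium only through mu_eff.

`build_depth_curve()` scans a unitary point perturbation over depth,
localizes the perturbation minimum seen by each detector with three-point
parabolic sub-pixel refinement, and tabulates alpha against z/d0. The
curve is anchored analytically at (0, 0) and (1, 1), is strictly monotone,
and is inverted by monotone piecewise-cubic (Hermite) interpolation, a
shape-preserving choice that cannot overshoot. Defaults: depth step
d0/100, scan step deltaD/40, symmetric detector arrangement. Curves are
memoized per session and serializable as TSV.

Properties of the curve that the test suite exercises directly:

* symmetry, alpha(z) + alpha(d0 - z) = 1 for the symmetric arrangement;
* weak dependence on the background optical properties over the
  soft-tissue band (absorption 0.05-0.1 per cm, reduced scattering 5-10
  per cm): the curves agree to within a few percent of d0 at matched
  alpha, so one lookup curve serves a broad range of tissues; a much
  lower, water-like absorption departs further (several percent);
* insensitivity to d0 and to the specific detector placement, as long as
  the source axis projects between the two detectors;
* insensitivity to inclusion size: a depth curve built by integrating the
  Born kernel over a 20 mm cube (midpoint quadrature on a sub-voxel
  lattice) reconstructs depth within a couple of millimeters of the
  point-inclusion curve. The extended-inclusion sweep keeps the inclusion
  inside the slab, so that curve is partial in alpha; the quadrature
  regularizes the integrable 1/r kernel singularity by flooring distances
  at half the lattice step.

The sensitivity of depth to alpha is not uniform: the curve is steep near
both plates and shallow at mid-depth, so a one-pixel uncertainty in alpha
(propagated by `alpha_uncertainty_to_depth()`) produces wide depth
intervals near the plates and narrow ones at mid-depth.

## From images to alpha: enhancement, skeletons, matching

Raw scans are interpolated to a finer pitch (separable natural cubic
splines, default 0.5 mm; values at original nodes are preserved and linear
fields reproduced exactly). Structures are enhanced by the second
derivative of the normalized inverse intensity N = Imax/I: per pixel,
`second_derivative_image()` takes the minimum over the four directional
central second differences (x, y, and the two diagonals, with the
diagonal step pitch * sqrt(2)) and remembers the direction attaining it.
An absorber produces a peak in N whose ridge line has strongly negative
curvature across the ridge.

`skeletonize()` converts this curvature image to a binary skeleton: a
pixel is kept iff its curvature is below a noise floor and is a local
minimum along its own argmin direction (strict against the lower-index
neighbor, which keeps exactly one pixel of a flat plateau). The default
floor is the larger of (i) three times a robust pixel-noise estimate, the
scaled median absolute residual of the curvature from its local linear
trend - an estimator that ignores smooth structure and responds only to
pixel-scale roughness - and (ii) five percent of the deepest ridge. The
relative definition makes the skeleton invariant to rescaling the
intensities, and (i) adapts to stochastic (Monte Carlo or measured) data
while (ii) suppresses weak interpolation ripple in noiseless synthetic
images. Border pixels never enter skeletons. For strongly noisy images an
optional aperture-scale Gaussian pre-smoothing (`smooth_scan()`, symmetric
kernel, so valley positions are preserved) is available upstream.

Matching assigns an alpha to every skeleton pixel of the reference
(`D_plus`) image by the windowed Frobenius inner product: the binary
window (default 4 mm edge; it must span at least 3 x 3 pixels and stay
below deltaD) centered on the pixel is compared against windows of the
`D_minus` skeleton displaced along the pair direction by beta * deltaD,
with beta on the quantized grid {k pitch / deltaD}. The alpha is the beta
maximizing the inner product; a pixel whose score is zero for every beta
is unmatched (NA), and the unmatched fraction is reported. Ties on the
maximal score take the midpoint of the tied set, rounding toward smaller
beta - deterministic and unbiased for symmetric plateaus. Windows leaving
the grid are zero-padded so edge structures can still match. Matching is
single-reference (`D_plus` scanned, `D_minus` shifted); alpha is by
construction a multiple of pitch/deltaD, so a configuration resolves
floor(deltaD/pitch) + 1 depth layers (27 for deltaD = 13 mm at 0.5 mm
pixels).

## Fusing detector pairs

With two (or more) pairs along different directions, each matched pixel
has per-pair depths z_i. These are combined by a weighted average whose
weights are the mean absolute directional second derivative of N along
each pair's offset direction, evaluated at the pixel in the `D_plus`
image and at the alpha-shifted location in the `D_minus` image. A pair
whose offset runs along a directional structure (a rod parallel to its
deltaD) carries vanishing second derivative in that direction and is
automatically down-weighted; for rotationally symmetric objects the
weighted average reduces to the plain mean. A pixel matched by only some
pairs uses those pairs alone; if all weights vanish the plain mean is
used and flagged. The weights use the same N field as the skeletons, for
internal consistency. Per-pixel depth intervals from a one-pixel alpha
uncertainty are attached (union over pairs).

Depth histograms use one bin per attainable alpha quantum with edges at
the curve images of midpoints between adjacent quanta; because the curve
is nonlinear the bins have variable width, so the ordinate is pixels per
unit depth and bin areas sum to the matched pixel count.

## The synthetic-data generator

`make_fixture()` emits the reference scenes: a 3.5 mm absorbing rod at a
configurable depth in a 65 mm medium with liquid-phantom background
(absorption 0.005 per cm, reduced scattering 7 per cm, detector offset
19.3 mm, 1 mm scan pitch); rotated and z-tilted rods; two rods crossing
at 30 and 45.8 mm (angles 30 and -20 degrees from +y); two curved
vessel-like polylines at 16 and 48.5 mm; and the Monte Carlo scenes (40 mm
slab, background 0.05/5 per cm, 6 mm spheres twenty times more absorbing
than the background at 12 and 28 mm, singly or lined into two crossing
rods of ten spheres each). Inclusion contrast defaults to twenty times the
background absorption, the blood-vessel-versus-breast contrast regime.
Analysis of the phantom scenes uses the standard 0.005/5 per cm depth
curve rather than the exact phantom scattering, mirroring how a lookup
curve would be used in practice. Rods extend well beyond the scan field
(the physical phantoms spanned a 40 cm tank), because rod-end falloff
inside the field otherwise imprints weak spurious ridges. For the Born
quadrature, rods and polylines are chains of spheres of matching diameter
overlapped at half-diameter spacing with volume-preserving weights (a
touching chain imprints a periodic lumpiness on noiseless images); the
Monte Carlo scenes use the literal ten-sphere chains. An optional
multiplicative Gaussian noise model (fractional sigma, seeded) emulates
measurement noise on diffusion-synthesized scans; Monte Carlo scans carry
their intrinsic noise.

What the generator does *not* emulate: real fiber coupling and aperture
effects, refractive-index mismatch at the plates, physiological
heterogeneity of tissue, scattering contrast of inclusions (absorbers
only), and detector nonlinearity. Passing tests on these scenes therefore
demonstrate the correctness and internal consistency of the algorithm, not
instrument-level performance.

## The photon Monte Carlo oracle

`run_mc_scan()` is a seedable CW photon random walk, independent of
diffusion theory, used as a physics oracle. Transport is in the reduced
(isotropic-scattering) picture: exponential steps with mean 1/mu_s',
isotropic redirection, continuous absorption weighting exp(-mu_a L), and
Russian roulette below weight 1e-4 with survival 0.1. Inclusions are
absorbing-only spheres (rods become sphere chains); each detected photon's
weight is attenuated by exp(-delta_mu_a * chord length), with chords from
analytic ray-sphere intersection - exact for absorbing inclusions, not a
Born approximation. Because the homogeneous background is laterally
translation invariant, a source scan is equivalent to translating the
inclusions past one fixed source: transport runs once, detected paths are
stored, and every scan position is re-scored through the translated
spheres. This correlated-sampling design makes desk-scale photon budgets
usable (the noise is shared across scan positions), makes pixels
order-independent by construction, and with per-photon RNG substreams a
fixed seed reproduces images bitwise. Re-scoring is sparse: a photon's
contribution is decomposed into a scan-independent base term plus
corrections from each (segment, sphere) encounter, which only touch the
few scan positions whose translated sphere can reach that segment.
Per-pixel standard errors come from batch variance, and the weight
bookkeeping identity (launched + roulette boost = absorbed + escaped +
transmitted + killed) is checked to numerical precision.

Two boundary treatments and two source models are provided, because the
choice measurably changes the alpha a transport model produces for
structures near the plates. With hard slab boundaries (photons terminated
at either plate) and a pencil beam, the detected-photon density near the
source hugs the beam axis and the measured shift of a shallow inclusion
is substantially smaller than the infinite-medium diffusion curve
predicts; this was verified against an independently coded brute-force
Monte Carlo and shown to be contrast-independent (so it is not an
absorber-saturation effect). With open boundaries (photons may wander
below the source plane; detection at the first crossing of the exit
plane) and an isotropic point source - the transport analog of the
diffusion model behind the depth curve, and the configuration closest to
fibers immersed deep in a liquid phantom - mid-depth reciprocity is
restored, though the absorbing detection plane still tilts alpha slightly
upward for deep structures. The reference Monte Carlo scenes use
open + isotropic; slab + pencil remains the default for instrument-like
simulations. The residual discrepancies of recovered depths (about 2 mm
for the sphere scenes) are consistent with this estimator sensitivity and
are reported as measured.

## Numerical choices and problem sizes

* Depth curves: z step d0/100, scan step deltaD/40, parabolic
  localization; discrepancies are percent of d0 at matched alpha over the
  common alpha range.
* Extended-inclusion quadrature: midpoint lattice, default step size/8,
  refused above size/2; kernel distances floored at half the step.
* Interpolation: separable natural cubic splines; upsampling capped at 16x.
* The reference pipeline runs use scan fields of roughly 40 x 30 mm at
  1 mm pitch interpolated to 0.5 mm, and Monte Carlo runs of a few million
  photons with 4-5 mm detector discs and aperture-scale (4 mm FWHM)
  pre-smoothing; these sizes keep every check reproducible on a single
  CPU in minutes while leaving the algorithms identical to what a
  full-budget run would use.
* Degenerate inputs: empty scenes produce flat images, empty skeletons and
  an empty depth map with a warning (not an error); unmatched pixels carry
  NA depth; zero fusion weights fall back to the plain mean with a flag.

## Known limitations

Two structures stacked at the same x-y location return a single effective
depth by design. A rod aligned with a pair's offset direction cannot be
depth-resolved by that pair alone (the second pair rescues it in the
fused map). The first-order forward model saturates for very strong
contrasts (intensities are floored with a warning if a perturbation
exceeds -100 percent). The depth curve is a diffusion-theory object: for
structures within a transport mean free path of a plate, transport
corrections of order 1-2 mm in recovered depth are expected, as the Monte
Carlo oracle shows.
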