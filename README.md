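# dotdepth

Depth discrimination for parallel-plate, transmission-mode diffuse optical
imaging (scanning optical mammography and tissue-like phantoms).

A single 2D projection scan of transmitted near-infrared light carries no
depth information. If, however, the scan is acquired with a *pair* of
detector fibers separated by an in-plane offset **δD**, an absorbing
structure at depth *z* appears laterally shifted between the two detector
images by α·δD, with the offset parameter α ∈ [0, 1] growing monotonically
from the source plate (α = 0) to the detector plate (α = 1). `dotdepth`
implements the full chain that turns this parallax into depth maps:

* **Forward model** — infinite-medium CW diffusion Green's functions
  G(r) = exp(−µ_eff r)/(4πDr) and the first-order Born perturbation
  ΔI/I₀ = −V·Δµ_a · G(|s−p|)G(|p−d|)/G(|s−d|) for point and extended
  absorbers (spheres, cubes, rods and vessel-like polylines by midpoint
  volume quadrature), used to synthesize paired detector scans.
* **Depth curve** — the lookup relationship z/d₀ versus α, built by
  forward-simulating a unitary point perturbation over depth and
  localizing the perturbation extrema with sub-pixel parabolic
  refinement; monotone piecewise-cubic inversion translates measured α
  into depth, with one-pixel uncertainty propagation. The curve is only
  weakly sensitive to the background optical properties, the plate
  separation, the detector placement, and the inclusion size.
* **Image enhancement** — spline interpolation to a finer pitch, the
  minimum over four directional second derivatives of the normalized
  inverse intensity (N″), and binary skeletonization of its ridge lines.
* **Structure pairing** — per skeleton pixel, the offset α maximizing the
  windowed Frobenius inner product between the two detector skeletons,
  quantized to multiples of pitch/δD (e.g. 27 depth layers for
  δD = 13 mm at 0.5 mm pixels).
* **Depth fusion** — per-pair depths combined across detector pairs by a
  weighted average whose weights are directional second-derivative
  magnitudes, so a pair whose offset runs along a directional structure is
  down-weighted; variable-bin depth histograms and depth-class summaries.
* **Photon Monte Carlo** — a seedable random-walk transport model (Rcpp)
  with absorbing spherical inclusions, exact chord-length attenuation,
  correlated sampling across scan positions, and selectable boundary and
  source models; used as a physics oracle independent of diffusion theory.
* **Scenes and fixtures** — YAML scene files, TSV/TIFF image formats with
  metadata headers, reference phantom fixtures (single/rotated/tilted
  rods, crossing rods, vessel pairs, Monte Carlo spheres and rods), and a
  one-call pipeline (`run_pipeline()`) with a complete run manifest.

## Worked example

A 3.5 mm absorbing rod at 32.5 mm depth in a 65 mm medium (liquid-phantom
optical properties, detector pair offset 19.3 mm along x, 1 mm scan pitch
interpolated to 0.5 mm):

```r
library(dotdepth)

scene <- make_fixture("single_rod_depth")   # depth 32.5 mm by default
res <- run_pipeline(scene)
res
#> <pipeline_result> scene 'single_rod_depth' (diffusion)
#>   match fraction: 1.000
#> <depth_map> 57 x 81 px, 57 with depth (d0 = 65 mm)
#>   depth range 33.3 - 33.3 mm, median 33.3 mm

median(res$depth_map$z, na.rm = TRUE)
#> [1] 33.26357
```

Every skeleton pixel of the rod matched (match fraction 1.000), all at the
same quantized offset α, and the recovered depth of 33.3 mm is within
0.8 mm of the true 32.5 mm — comfortably inside the few-millimeter
accuracy expected at mid-depth, where the depth curve is least sensitive
to α errors. The depth curve behind the inversion:

```r
cv <- build_depth_curve(optical_medium(per_cm(0.005), per_cm(5)), 65, 19.3)
invert_alpha(cv, 0.5)          # mid-depth by symmetry
#> [1] 32.5
alpha_uncertainty_to_depth(cv, 0.5, pixel_pitch = 0.5)
#>     z_lo     z_hi
#> 31.40884 33.59116
```

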