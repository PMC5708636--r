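---
title: "Log-polar magnitude descriptors: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-polar magnitude descriptors: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpmatch)
```

## The problem

Registering two images of the same scene - a pair of micrographs taken at
different times or magnifications, or two photographs of a planar scene -
is classically solved by matching local features: detect distinctive
circular regions in both images, encode each region as a numeric vector,
pair up vectors that are close in descriptor space, and robustly fit the
geometric transform that the pairs imply. `lpmatch` implements a complete
pipeline of this kind around a short, rotation-, scale- and
illumination-invariant descriptor built from the Fourier magnitude spectrum
of a log-polar resampling of each feature's neighbourhood.

The design premise is detector independence: the descriptor consumes only a
center and a radius. Orientation is never estimated - rotation invariance
comes from the representation itself - so very simple detectors (Harris
corners, determinant-of-Hessian blobs, or any external detector's
coordinates) work as well as elaborate ones.

## The descriptor

### Log-polar transform

A feature is a disc of radius $R$ centered at $(x_0, y_0)$. The disc is
resampled onto an $N \times N$ grid (default $N = 32$, alternatively 16):

$$x = \rho \cos\theta + x_0, \qquad y = \rho \sin\theta + y_0,$$

with $\rho_i = R^{\,i/(N-1)}$, $i = 0,\dots,N-1$ (log-uniform in $[1, R]$:
geometric spacing is the unique log-uniform choice once both endpoints are
pinned) and $\theta_j = 2\pi j / N$ on $[0, 2\pi)$. Rows of the resulting
square image are rings; following the convention that the innermost ring is
the bottom row, row 1 holds the outermost ring. A rotation of the image
about the feature center becomes a circular shift of the columns.

Sub-pixel values are interpolated as a Gaussian-weighted mean of the 5x5
integer-pixel window centered on the pixel nearest the sample point, with
weights $\exp(-d^2/2\sigma_w^2)$, $\sigma_w = 1$, normalized to sum 1
(so constants are preserved exactly and intensity maps $aI + b$ commute
with sampling). The only image-level precomputation is Gaussian smoothing
with variance 1 ($\sigma = 1$, kernel truncated at $4\sigma$, reflective
borders); detection and description both run on the smoothed image, a
single shared pass.

The log spacing serves two purposes: it emphasizes pixels near the feature
center, making the descriptor tolerant to errors in the radius estimate,
and it converts a common rescaling of image and radius into an approximate
shift along the ring axis, which the magnitude spectrum largely ignores.
Keeping $N$ points on every ring subsamples the outer rings; the
low-frequency mask below deliberately discards the high-frequency content
this aliases into.

### Magnitude spectrum and frequency mask

The 2-D DFT of the log-polar image is taken and the descriptor reads
magnitudes at a fixed set of DC-centered coordinates $(u, v)$, $u$ indexing
radial and $v$ angular frequency. Magnitudes are invariant to circular
shifts of the input, hence to feature rotation - and no orientation
normalization is ever needed. The default mask is a double rectangle

$$\{(u, v) : u \in \pm[1, r_N],\; v \in [1, 4]\},$$

with $r_{16} = 6$ and $r_{32} = 7$, giving vectors of length 48 and 56.
Three exclusion rules shape it:

* **DC excluded.** The $(0,0)$ component is the mean intensity; dropping it
  (together with unit normalization) makes the descriptor exactly invariant
  to affine intensity changes $aI + b$.
* **The $v = 0$ line excluded.** The top and bottom rows of the log-polar
  image (outermost/innermost rings) are unrelated, and the DFT's implicit
  periodicity turns that discontinuity into artifact energy along the
  purely-horizontal-frequency line. The image *is* continuous left-to-right
  (the rings are closed curves), so no corresponding vertical artifact
  exists.
* **Half spectrum only.** The input is real, so $|F(u,v)| = |F(-u,-v)|$;
  one member of each conjugate pair carries all the information.

More radial than angular indices are kept (6-7 vs 4): intensity structure
from the center outward is coded more finely than structure along the
rings. Custom masks (any coordinate list satisfying the three rules) can be
supplied via `lpm_mask()` or a JSON file, which is the supported route for
specializing the descriptor to an application.

The selected magnitudes are normalized to unit Euclidean length. A patch
whose selected magnitudes are all zero (a constant patch has only DC
energy) is flagged degenerate and dropped: a zero vector would match every
other zero vector at distance 0 and poison matching.

## Matching

Matching is exhaustive: every descriptor of the transformed image is
compared to every descriptor of the reference by the sum of squared
differences. A query is matched to its nearest neighbour when

* SSD < 1% of the maximum achievable SSD between two unit-length
  non-negative vectors. That maximum is 2 (orthogonal vectors), so the
  default cutoff is 0.02. Expressing the threshold as a percentage of a
  fixed reference makes it independent of vector length, so descriptors of
  different lengths can be compared under identical settings.
* The Lowe ambiguity condition holds: $d_1 / d_2 < \tau_L$ with
  $\tau_L = 0.6$, i.e. the second-nearest neighbour is a density estimate
  of false matches and the nearest must beat it decisively. An exact
  duplicate ($d_1 = 0$) is accepted outright.

One query never matches more than one reference, but several queries may
share a reference: one-to-many matches are allowed by design, because under
a large scale difference several fine-scale features legitimately
correspond to one coarse-scale feature.

## Verification

Candidate matches are verified by seeded RANSAC with Hartley-normalized
DLT fits, scored by symmetric transfer error (the RMS of the forward and
backward reprojection distances; the symmetric form stays meaningful under
the large scale differences that one-to-many matching targets). Hypotheses
alternate between two generators: minimal 4-point homography samples, and
2-point similarity samples solved in the complex plane. The similarity
generator is what lets verification dig correct matches out of sets where
they form only a few percent of the total - a pure 2-point inlier sample is
~w^2 likely versus ~w^4 for 4 points - and is exact for the rigid, zoom and
rotation transforms that dominate microscopy registration; local
optimization upgrades every promising hypothesis to a full DLT homography,
so projective transforms are still found through the 4-point generator and
the final model is always a full homography. The inlier tolerance defaults to 3 px,
comfortably above the ~1 px localization noise of interpolated sampling.
Hypotheses at least as good as the incumbent are locally optimized by
re-estimating the homography on their full consensus set and recomputing
the set to a fixed point (at most 10 rounds) - the iterated re-estimation
that makes the optimal consensus stable in heavily contaminated sets. The
iteration budget adapts to the best inlier ratio and the generator mix
(the 2-point rate counts only while the incumbent transform is itself
numerically a similarity), confidence 0.999, capped at 10,000 by default;
raise the cap for inlier rates near 5%. All
randomness flows from one seed, matches are canonically sorted before
sampling, and a fixed seed yields bit-identical output regardless of input
order.

## Evaluation metrics

Ground truth for synthetic or benchmark pairs is a known homography $H$.
Two features correspond when their overlap error
$1 - |A \cap B| / |A \cup B|$ is below $\epsilon_0 = 0.4$, with the second
disc mapped through $H^{-1}$ and areas counted in pixels on a common
integer raster (a closed-form circle-lens formula serves as the test oracle
for the identity case). No feature-scale normalization is applied before
the overlap - raw radii are used, matching how the pipeline would behave in
an application where true scales are unknown. The matching score divides
correct matches by the smaller count of features fully visible in both
images ("fully visible" operationalized as: own disc inside own frame, and
the mapped disc's bounding box inside the other frame). The inlier ratio
divides verified by candidate matches, 0/0 defined as 0.

## Scale pyramid

When the zoom difference between two images may exceed a factor ~2 (beyond
what log-polar sampling plus detector radii absorb), five scenarios are
compared: A vs B, A vs 0.5B, 0.5A vs B, A vs 0.25B, 0.25A vs B. Each
scenario resizes one image (bicubic), reruns detection through matching,
and the scenario with the most raw candidate matches wins - false matches
included, because verification would cost five RANSAC runs and the raw
count is already a reliable proxy for scale agreement. Ties prefer no
resize, then the milder resize. Winning-scenario coordinates are divided by
the resize factor back into native frames before verification. With no
scale difference the unresized scenario wins and results are identical to
not using the pyramid. Detector parameters are kept fixed across scenarios
(not rescaled with the image).

## Synthetic data

The generator exists so that every claim is testable without external
datasets:

* `blobs` places 30-80 Gaussian spots (sigma 2-6 px, amplitudes 120-255
  over background 10) on a jittered grid with ~16 px minimum separation,
  emulating the bright dots of fluorescence micrographs while guaranteeing
  each spot stays a distinct local maximum. On images much smaller than
  256 px the grid may hold fewer spots than drawn.
* `noise` low-pass filters white Gaussian noise at sigma = 2 and stretches
  it to 0-255, emulating band-limited transmission-electron-microscopy
  texture.
* `lpm_make_pair()` composes rotation/scale/translation about the image
  center (exact ground-truth homography returned), then an affine intensity
  map, Gaussian blur and additive Gaussian noise. Warping is inverse-mapped
  Catmull-Rom bicubic; an identity transform is bit-exact.

Transforms are similarities, not full projective maps: every invariance the
descriptor claims (rotation, scale, illumination, blur, translation) is
exercised without confounding viewpoint distortion, which circular features
handle poorly regardless of descriptor. What the generator does *not*
emulate: microscope optics (PSF anisotropy, depth effects), Poisson/shot
noise, stain bleaching gradients, JPEG artifacts, or non-rigid tissue
deformation. A green test suite on these fixtures therefore demonstrates
correctness of the implementation and its invariances, not performance on
any particular instrument's data.

## Numerical choices and edge cases

* **Ring radii** include both endpoints ($\rho_0 = 1$, $\rho_{N-1} = R$);
  a radius below 1 px is rejected (the log range degenerates). $R = 1$
  collapses all rings to the unit circle, which is valid.
* **Row order** (outermost ring = top row) is fixed for testability; the
  descriptor is unaffected by a global row flip since the magnitude
  spectrum is flip-symmetric.
* **Angle origin** is the positive x axis, counterclockwise in array
  coordinates (y down). Any fixed origin is equivalent by rotation
  invariance; this one is frozen for regression tests.
* **Interpolation bias.** Centering the 5x5 window on the *nearest* pixel
  makes the effective kernel jump as samples cross half-pixel boundaries;
  the induced sub-pixel position bias (order 0.01 px, coupled to the local
  gradient) does not cancel between two images whose sample windows are
  quantized differently. Raw log-polar patches of a rotated image therefore
  equal the column-shifted original only to ~0.5% for general grid angles
  (exactly, to machine precision, for quarter turns, whose windows map onto
  each other). After the magnitude spectrum and unit normalization the
  effect is negligible: descriptor SSD under rotation is ~1e-6.
* **Rounding ties**: a feature centered on a half-integer coordinate puts
  samples exactly on .5 boundaries where round-half-to-even breaks
  rotational symmetry; tests use integer centers, and in practice the
  measure-zero ties are harmless.
* **Degenerate RANSAC samples** (any 3 of 4 points nearly collinear in
  either image) are skipped; a DLT fit whose homography is numerically
  singular (which arises when 3 source points are collinear even though the
  linear system has a unique solution) is rejected.
* **Matcher edge cases**: a single-candidate reference list has no second
  neighbour (ratio treated as infinite, match accepted if under threshold);
  nearest-neighbour ties break to the lowest index for determinism.
* **Grayscale conversion** is the unweighted channel mean and intensities
  are never rescaled on load - the descriptor's illumination invariance
  makes absolute scale irrelevant, and microscopy data should not be
  perceptually weighted.

## Problem sizes in the test suite

The suite builds everything it needs at run time: 128-320 px textures,
feature counts in the tens to low hundreds, and RANSAC problems of 40-100
correspondences (the contaminated stress case runs with the iteration cap
raised to 1e5). These sizes keep the full suite under a couple of minutes
on one CPU while still exercising every code path at realistic feature
densities; nothing in the implementation is specific to them.

## Known limitations

* Circular features cannot follow strong viewpoint (affine) distortion;
  beyond roughly 25 degrees of out-of-plane rotation matching degrades for
  any descriptor of this family. Elliptical, affine-adapted features are
  out of scope.
* Scenes containing several independent motions, or non-rigid deformation,
  violate the single-homography model; RANSAC will lock onto (at best) the
  dominant motion.
* The verification stage assumes a planar scene or rotation-only camera;
  calibrated stereo would call for fundamental-matrix fitting instead.
* Features with radius < 1 px cannot be log-sampled and detector radii
  must leave a 2 px interpolation margin inside the image, so very small
  images yield few or no usable features.
* Mask optimization (searching coordinate sets tuned to an application) is
  deliberately not implemented; custom masks are consumed as data.
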