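---
title: "Methods: stereo-vision surface-area yield estimation for hanging kelp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stereo-vision surface-area yield estimation for hanging kelp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Sugar kelp (*Saccharina latissima*) grown on suspended rope lines hangs
vertically in dense ribbon-like bundles, growing from a few centimeters to
several meters over a season. Because most of that growth happens within
the 2-D plane spanned by the rope line and gravity, the bundle is well
approximated by a flat vertical sheet, and a useful yield proxy is the
sheet's surface area in m². `kelpyield` estimates that area from a single
underwater frame set — one RGB image plus a rectified grayscale stereo
pair — in three steps:

1. **Segmentation** of the RGB image into seaweed / not-seaweed pixels,
   giving a pixel area \(n_{px}\).
2. **Range** \(Z\) to the sheet from the stereo pair, via semi-global
   block matching and a robust central-crop median.
3. **Conversion**
   \(\hat A = n_{px} \cdot \frac{Z}{f_h}\cdot\frac{Z}{f_v}\),
   where \(f_h, f_v\) are the focal lengths in pixels: each pixel observes
   a \(Z/f\)-sized patch of a fronto-parallel surface, so the footprint
   area scales as \(Z^2\).

A synthetic scene generator with exact ground truth makes every stage —
and the full chain — testable without field imagery.

## Camera model and triangulation

The camera model is an in-air pinhole over a rectified stereo rig:
disparity is purely horizontal and depth follows

\[ Z = \frac{b\,f}{d} \]

with baseline \(b\) (meters), focal length \(f\) (pixels) and disparity
\(d\) (pixels). Refraction is ignored by construction: the model targets
housings whose camera axes are orthogonal to the housing and water
interfaces, so rays cross at normal incidence. Lens distortion and
rectification from raw extrinsics are out of scope — pairs are assumed
rectified upstream (consumer stereo cameras ship factory calibration).

Pixel coordinates are 0-based, origin top-left, x rightward, y downward,
with pixel centers on integer coordinates. Square pixels
(\(f_h = f_v\)) are the default; a manifest can override per axis.

`min_viewing_distance()` gives the closest fronto-parallel distance at
which a centered object of extent \(e\) fully fits a frame with vertical
field of view \(\theta\): \(e / (2\tan(\theta/2))\). For a 4 m plant and
a 65° field of view this evaluates to about 3.14 m.

## Synthetic scenes: what is emulated, what is not

`render_stereo_set()` renders flat, fronto-parallel sheets at constant
depth (1–4 m is the intended envelope), viewed by a left/RGB camera at
the origin and a right camera at \(+b\). Sheet radiance is a band-limited
procedural texture evaluated in *world* coordinates — smooth blotches
plus high-frequency vertical ribbon streaks with 3–50 cm wavelengths — so
the left and right views sample the same physical pattern and the true
disparity \(b f / Z\) holds to sub-pixel accuracy. Water is modeled by
single-scattering haze,

\[ I = J\,e^{-\beta Z} + A\,(1 - e^{-\beta Z}), \]

with attenuation \(\beta\) (1/m) and airlight \(A\) (a blue veil in RGB,
a flat gray level in the monochrome pair); open water is pure airlight.
Additive Gaussian sensor noise (clipped, rounded to 8-bit) is applied per
image with seeds derived deterministically from a single scene seed.

The defaults encode the study conditions the package is tested under:
ranges 1.5–3.5 m, sheet areas 0.5–6 m², \(\beta \le 0.3\)/m, noise
\(\sigma \le 5\). `random_scene()` draws a single sheet from those
ranges and keeps it fully in frame, near the frame center (placement
jitter is a quarter of the free slack): the acquisition protocol aims
the camera at the plant and frames it top to bottom, and the central-crop
range estimator below assumes exactly that.

The default synthetic rig (`default_camera()`: 640×480 px, \(f = 380\),
\(b = 95\) mm) reproduces the field camera's geometry at half
resolution — ~65° vertical field of view and \(f \approx W/2\) — so
disparity magnitudes and range resolution behave like the real rig's.

Deliberately not modeled: surface-wave caustics and lighting flicker,
fish and fouling distractors, slanted or curved sheets, wavelength-
dependent attenuation, and the wild lighting variation of real field
imagery. Passing tests on these scenes therefore demonstrate the
*geometric and statistical* correctness of the chain, not segmentation
robustness on real underwater photographs — that burden falls on the
pluggable segmenter (below).

## Stereo depth: semi-global block matching

The matching cost is the sum of absolute differences (SAD) over a square
block; the default block of 16 px follows the underwater protocol, where
single-pixel matching is hopeless against haze and noise. Blocks may be
even: a block of size \(B\) covers offsets \(-\lfloor (B-1)/2 \rfloor
\dots \lfloor B/2 \rfloor\), truncated at image borders. Candidates whose
match falls off the right image carry a sentinel cost. Costs are integer
throughout, so results are exactly reproducible and the whole pipeline
can be compared pixel-for-pixel against a plain-R brute-force reference
(the test suite does this on 100 small random pairs).

Aggregation follows the standard semi-global recurrence along each of 8
(default) scan directions,

\[ L_r(p,d) = C(p,d) + \min\big(L_r(p{-}r,d),\; L_r(p{-}r,d{\pm}1)+P_1,\;
   \min_k L_r(p{-}r,k)+P_2\big) - \min_k L_r(p{-}r,k), \]

with the common block-area penalty scaling \(P_1 = 8B^2\),
\(P_2 = 32B^2\). The source protocol does not report path counts or
penalties; these are conventions, not reproductions. Winner-take-all
selection breaks ties toward the lower disparity (deterministic), and
parabolic interpolation over the three aggregated costs around the winner
refines to sub-pixel.

Three validity checks guard the estimate:

* **Uniqueness ratio** (default 10%): the winner must beat every
  non-adjacent candidate by the margin; equal-cost flats (featureless
  input) fail it.
* **Left-right consistency** (off by default): winner disparities from
  the two views must agree within 1 px.
* **Texture threshold** (default 6 intensity units): pixels whose block
  standard deviation in the left image is below the threshold are
  invalid. This one matters for open water: the smoothness term happily
  extends the sheet's disparity across the featureless background, and
  those confidently-filled pixels would otherwise pass the uniqueness
  test and bias the scene median. A flat block's deviation is just the
  sensor noise (\(\approx\sigma \le 5\)), while lit blade texture sits
  well above; 6 separates the two across the working envelope.

`median_scene_distance()` reduces the map to one range: the 2-D median
of valid disparities over a centered 600×400 px crop (the optically
best-corrected image region), then triangulation. The median is taken
over *disparity*, not depth, because matching noise is approximately
symmetric in the disparity domain; a switch to depth-domain reduction
would be a one-line change and is documented as such. The median
tolerates up to 49% corrupted pixels and ignores invalid ones; an empty
or all-invalid crop yields an explicit range-unavailable flag rather
than a number.

## Segmentation

Ground truth comes from polygon annotations rasterized with even-odd
fill under a half-open pixel-centers rule — an axis-aligned \(W\times H\)
rectangle covers exactly \(W H\) pixels, and the rasterizer is tested
against an independent point-in-polygon oracle. CVAT XML 1.1 polygons
import read-only into a plain JSON schema. Masks score with
intersection-over-union; two empty masks score 1.0 and empty-versus-
nonempty scores 0.0 (documented conventions, tested).

`classical_segment()` is a deterministic, training-free stand-in for a
learned segmenter, tuned to the generator's optics: kelp blades reflect
more red than blue while the airlight veil is strongly blue, so a
red-minus-blue index threshold (default −60, between the water index and
the fully hazed blade index) separates the classes; box-kernel opening
and closing remove noise flips, and components under 50 px are dropped.
Haze moves both classes toward the airlight index but preserves their
order, which is why a fixed threshold survives the working envelope —
and why this segmenter makes no claim on real imagery, where lighting
varies far beyond a fixed color index. Real models plug in through
`external_segmenter_hook()`, a subprocess contract (frame PNG in, binary
mask PNG out) with size and binarity validation; a failing hook flags
the frame and the run continues.

Only the nearest line's seaweed counts as foreground: the generator
marks sheets beyond a configurable depth as negative class, mirroring
the labeling policy used for field annotation.

## Yield, repeatability and the error budget

`estimate_yield()` applies the single median range uniformly to all mask
pixels — consistent with the flat-sheet model; per-pixel depth weighting
is a documented extension. A useful sanity property follows directly:
moving the camera back doubles \(Z\), quarters \(n_{px}\), and leaves
\(\hat A\) unchanged up to discretization. Frames are never mosaicked or
overlap-corrected; per-frame yields are the deliverable.

`stationary_repeatability()` reproduces the field robustness protocol:
repeated captures of a fixed scene differing only in per-frame sensor
noise, summarized by `repeatability_stats()` (mean, sample SD, half
range — both spread measures are reported because "variation" is
ambiguous in field reports — and a Freedman–Diaconis histogram).

The per-image error budget combines the two dominant sources linearly:

\[ \varepsilon_{yield} = (1 - \mathrm{IoU}) + 2\,\varepsilon_Z . \]

The segmentation term takes \(1-\mathrm{IoU}\) as the relative pixel-area
error (the mapping is a modeling choice; IoU does not uniquely determine
an area error). The range term is doubled because area scales as
\(Z^2\). Linear addition rather than quadrature is deliberate: the two
sources are not established to be independent, so the budget is the
conservative worst-case sum — quadrature would report about 13% for the
reference inputs, linear addition gives
\((1-0.9) + 2\cdot0.044 = 0.188 \approx 18\%\), matching the reference
deployment's published budget.

## Numerical choices and degenerate inputs

* Integer SAD costs, 32-bit safe for blocks ≤ 16 and 8 paths; sub-pixel
  offsets computed in double from integer costs, identically in the fast
  path and the reference.
* Argmin ties break to the lowest disparity; `d = 0` is a *valid* value
  (infinite range is then reported as unavailable at the median step);
  invalidity is a flag, never a sentinel value.
* Rasterization and rendering share the half-open centers rule, so
  projected rectangles and rasterized rectangles agree exactly.
* Disparity maps persist as fixed-point 16-bit TIFF (1/16 px units,
  0 = invalid) with a JSON parameter sidecar.
* Degenerate inputs fail loudly with context: sheets behind the camera
  or projecting to zero area, polygons with fewer than 3 vertices or
  self-intersecting rings (frame id in the message), non-positive
  disparities at triangulation, crops larger than the frame (clipped
  with a warning and flag).
* All randomness descends from explicit integer seeds; per-stage seeds
  derive deterministically from the scene seed, and generators restore
  the caller's RNG state.

## Problem sizes used by the test suite

The shipped tests run the full chain at sizes chosen to exercise every
code path while keeping the suite quick on one core: the 640×480
half-resolution rig for end-to-end work (20 recovery scenes spanning the
study conditions; a 100-frame stationary series), a 160×120 rig for
plumbing tests, and ≤16×16 pairs with ≤8 disparities for pixel-exact
comparison against the brute-force reference. The stationary series
check asserts: segmented-area relative SD within 6%, the range median
within the depth equivalent of half a disparity step of the truth (the
engine's resolution limit), mean and median within one IQR of each
other, and no values beyond three IQRs — the concrete form of "evenly
distributed about the truth" used throughout.

## Known limitations

* Fronto-parallel constant-depth sheets only (v1); slanted sheets would
  spread the disparity distribution and bias the median toward the
  sheet's dominant depth.
* The classical segmenter is calibrated to the generator's reflectance
  and will not transfer to field imagery; it exists so the geometry and
  statistics of the chain are testable end to end.
* Sub-pixel refinement by parabola over SAD costs shows the usual
  pixel-locking bias (up to ~0.3 px toward integers for an adversarial
  fractional disparity), worth ~2% in range at the default geometry;
  the end-to-end recovery tests measure its real effect.
* No refraction or distortion modeling; housings must honor the
  orthogonal-interface assumption.
* Yield is a surface area, not biomass; converting m² to kg needs
  harvest calibration data.
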