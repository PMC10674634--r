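# kelpyield

Stereo-vision surface-area yield estimation for vertical seaweed farms.

Sugar kelp (*Saccharina latissima*) cultivated on suspended rope lines
hangs vertically in dense ribbon-like bundles that are well approximated
by flat 2-D sheets. `kelpyield` estimates the surface area of those
sheets, in m², from underwater frame sets consisting of one RGB image
and one rectified grayscale stereo pair — the acquisition unit of a
low-cost monitoring rig sailed along the lines. It is aimed at
aquaculture monitoring work that needs a per-image, metrically scaled
crop-size proxy without divers or harvest sampling.

The per-frame estimate is

```
Â = n_px · (Z / f_h) · (Z / f_v)        with   Z = b · f / d
```

where `n_px` is the segmented seaweed pixel count, `Z` the scene range
obtained by triangulating `d`, the 2-D median disparity over a centered
600×400 px crop of a semi-global block-matching (SGM) disparity map,
`b` the stereo baseline (95 mm for the reference rig) and `f` the focal
length in pixels. The accompanying first-order error budget is

```
rel_yield_error = (1 − IoU) + 2 · rel_range_error
```

(the range term doubled because the pixel footprint scales as `Z²`);
with the reference deployment's measured segmentation IoU of 0.9 and
4.4% relative range precision this evaluates to 0.188 ≈ 18%.

The package provides:

* a pinhole stereo camera model (triangulation, metric pixel footprint,
  framing distances, manifest I/O);
* an SGM disparity engine (integer SAD block costs, 8-path aggregation,
  uniqueness / left-right / texture validity checks, parabolic
  sub-pixel refinement) with an Rcpp core and a robust central-crop
  median range reducer;
* segmentation utilities: polygon rasterization (CVAT XML import),
  IoU scoring, a deterministic classical segmenter for synthetic
  scenes, and a subprocess hook contract for trained models;
* a ground-truthed synthetic underwater scene generator (flat hanging
  sheets, turbidity haze, sensor noise) so the whole chain is testable
  without field data;
* the per-frame yield pipeline with repeatability statistics, error
  budget, CSV/JSON reporting and a `kelpyield` command-line wrapper.

## Worked example

Render a known scene — a 1×2 m sheet, fronto-parallel at 2.5 m, with
turbidity and sensor noise — and run the three stages:

```r
library(kelpyield)

cam <- default_camera()           # 640x480 px, f = 380 px, b = 95 mm
scene <- scene_spec(
  sheets = list(sheet_spec(c(-0.5, -1, 2.5), width_m = 1, length_m = 2)),
  camera = cam, water_attenuation_beta = 0.2, noise_sigma = 3,
  rng_seed = 42
)
iset <- render_stereo_set(scene)
iset
#> <image_set> frame_0001: 640x480 px, truth area 2.000 m2, 46208 mask px

disp  <- compute_disparity(iset$left_gray, iset$right_gray, sgm_params())
range <- median_scene_distance(disp, cam)
range
#> <scene_range> 2.548 m (median d = 14.170 px over 52785 valid px)

seg <- classical_segment(iset$rgb_image, frame_id = iset$frame_id)
iou(seg, iset$truth_mask)
#> [1] 1

est <- estimate_yield(seg, range$range_m, cam,
                      rel_error = propagate_error(0.9, 0.044))
est
#> <yield_estimate> frame_0001: 46208 px at 2.548 m -> 2.077 m2
```

Reading the numbers: the true disparity at 2.5 m is
`0.095 · 380 / 2.5 = 14.44 px`; the engine's median lands at 14.17 px
(sub-pixel interpolation over SAD costs shows its usual fraction-of-a-
pixel locking bias), so the range is overestimated by 1.9% and the
2.00 m² sheet is reported as 2.08 m² — a 3.9% error, inside the 18%
per-image budget and typical of the ~2% median error the test suite
measures over 20 randomized scenes. Open-water pixels are invalidated
by the texture check rather than contaminating the median.

The same run from a shell:

```sh
Rscript inst/cli/kelpyield simulate --frames 5 --out data/ --seed 1
Rscript inst/cli/kelpyield run --manifest data/manifest.json --out results/
Rscript inst/cli/kelpyield repeatability --series results/yields.csv
```

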