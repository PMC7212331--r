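# patellometry

Fully automatic measurement of patellar dislocation on ordered stacks of
knee CT slices, for radiologists' workflows and medical-image-analysis
research. Given an axial slice sequence through the patellofemoral joint
(superior slices first), the package segments the femur and the patella on
every slice, fits each bone's central plane to per-slice key points, and
reports the two clinical quantities used for diagnosis:

* **PTA** — patellar tilt angle (degrees), the angle between the two central
  planes' normals;
* **PLS** — patellar lateral shift (mm), the distance between a pair of
  jointly fitted parallel central planes (measured only when PTA ≤ 15°).

Diagnosis follows the clinical thresholds: normal if PTA ≤ 10°, patellar
subluxation if 10° < PTA < 30°, dislocation if PTA ≥ 30°, with a
4.5 mm shift threshold refining the fuzzy 5°–15° band.

## Method at a glance

Segmentation is the hard part: bones are internally inhomogeneous (cortical
shell vs. marrow), soft tissue and noise clutter the slices, and the two
bones can be a couple of pixels apart across the sutura. The pipeline runs,
per slice *n + 1*:

1. **Local contrast enhancement** — each pixel is scaled by
   `exp(alpha - 0.45)` where `alpha` is its 3×3 neighbourhood mean relative
   to 255, iterated twice: bright (bone) neighbourhoods are amplified, dark
   (soft tissue, noise) ones suppressed.
2. **Bone-region prediction** from the previous slice's segmentation:
   dilation overlap regions predict the sutura (`Q1`) and local bone (`Q2`);
   enhanced pixels in `Q = Q1 ∪ Q2` are reverted to the original; dark
   pixels are fused with the previous binary mask
   (`0.4·I_seg + 0.6·I_enh` below `0.5·255`); sutura pixels below an
   intensity threshold are weakened (`mu1 = 0`, `mu2 = 0.5`); and a thin
   separating layer `B` between the bones is cleared to 0.
3. **Chan–Vese two-phase level-set segmentation** of the modified image,
   warm-started from the previous accepted masks, followed by hole filling,
   labeling (anterior component = patella, with continuity override) and
   outlier rejection.
4. **Measurement** — per slice, three key points per bone (trochlear valley
   curvature minima / patellar corner maxima plus the leftmost–rightmost
   midpoint) in mm coordinates; least-squares planes `z = a·x + b·y + c`;
   PTA from the normals, PLS from the parallel joint fit.

A synthetic phantom generator (`generate_phantom()`) reproduces the
challenge structure of knee CT — near-touching bones, marrow inhomogeneity,
soft-tissue clutter, noise, a bright partial-volume sutura band — with
analytically exact ground-truth masks, key points, tilt and shift, and the
standard segmentation metrics (overlap rate, false-positive rate, Dice,
separation rate) are built in.

## Worked example

```r
library(patellometry)

ph  <- generate_phantom(phantom_spec(tilt_deg = 8, shift_mm = 3, seed = 1))
res <- run_pipeline(ph$stack)      # segment + measure
res$report
#> <measurement_report> PTA = 7.82 deg, PLS = 2.92 mm, normal (refined by PLS) (30 slices)

glance(res$report)
#> # A tibble: 1 x 6
#>   pta_deg pls_mm diagnosis refined n_slices_used n_qc_flags
#>     <dbl>  <dbl> <chr>     <lgl>           <int>      <int>
#> 1    7.82   2.92 normal    TRUE               30          0

summary(segmentation_metrics(res$masks, ph$truth)$dice)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9873  0.9921  0.9938  0.9937  0.9955  1.0000
```

The report reads: the patella is tilted 7.82° against the femur (true value
8°) and shifted 2.92 mm (true 3.09 mm for this phantom's geometry); since
the tilt lies in the fuzzy 5°–15° band the shift refines the call, and
2.92 mm ≤ 4.5 mm confirms **normal**. Dice against the phantom's ground
truth stays above 0.98 on all 30 slices.

Real image sequences are read with
`read_stack("slices/", pixel_pitch_mm = 0.95, slice_spacing_mm = 0.5)`; a
thin command-line front end is installed under `inst/cli/patellometry.R`
(`segment`, `measure`, `run`, `phantom` subcommands).

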