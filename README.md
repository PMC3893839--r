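# flowseg

Dense optical-flow motion segmentation for medical image sequences.

flowseg is for researchers who have a short grayscale image time series —
typically a dynamic MRI study (e.g. six 256 × 256 measurements around
contrast injection) or a small fMRI slide series — and want to know
*where* apparent motion occurs and *how much* of a region of interest it
covers. It estimates dense per-pixel motion, segments the moving zone
automatically, and renders colour overlays and flow-vector maps.

## Method

For each consecutive frame pair, the brightness-constancy constraint
`Ix·u + Iy·v + It = 0` is solved in the least-squares sense over an
odd-sided window *V* (Lucas–Kanade), via the per-pixel 2 × 2 normal
equations

```
A = [ Σ Ix²   Σ IxIy ]      B = [ −Σ IxIt ]      A [u v]ᵀ = B
    [ Σ IxIy  Σ Iy²  ]          [ −Σ IyIt ]
```

with derivatives from separable Gaussian derivative filters. Pixels
where the smallest eigenvalue of `A` falls below a threshold τ are
aperture-degenerate (1-D structure: edges, gratings, flat areas) and are
flagged invalid rather than solved. The per-pair flow magnitudes
`√(u² + v²)`, aggregated by per-pixel maximum and restricted to an
adjustable rectangular **attention window**, are quantised to L = 256
levels and split by Otsu's threshold — the level `k*` maximising the
between-class variance `σ_B²(k) = [μ_T w(k) − μ(k)]² / (w(k)(1 − w(k)))`
— and the high class is reported as the moving region, summarised by its
**motion density** (fraction of the attention window moving).

A phantom generator (translating textures, moving blobs, gratings, all
with exact ground truth) makes every stage testable without clinical
data. See the methods vignette (`vignettes/motion-segmentation.Rmd`) for
the full model, parameter rationale and limitations.

## Worked example

```r
library(flowseg)

# a synthetic "lesion": static textured background, a blob of radius 10 px
# moving at 1 px/frame, six 256 x 256 measurements
ph <- phantom_sequence("moving-blob", shape = c(256, 256), frames = 6,
                       velocity = c(1, 0), seed = 7)
seg <- segment_motion(ph$sequence)
seg
#> motion_segmentation: 256 x 256, 5 frame pairs (window 7, L = 256)
#>   attention window: rows 1..256, cols 1..256
#>   Otsu threshold k* = 58; motion density 0.0079
```

The density 0.0079 says 0.79 % of the frame is moving — the blob's swept
area. The mask overlaps the true moving region (the union of the blob
discs over the study) with a Jaccard index of 0.72:

```r
sum(seg$mask & ph$truth$moving_mask) / sum(seg$mask | ph$truth$moving_mask)
#> [1] 0.7217069
```

The window-size study of the vicinity *V* (5/7/9):

```r
sweep_windows(ph$sequence)
#> window_sweep:
#>  window k_star     density
#>       5     41 0.007064819
#>       7     58 0.007949829
#>       9     66 0.008056641
```

Larger windows pool gradients over more pixels, detecting slightly more
of the low-magnitude blob fringe (density rises from 0.71 % to 0.81 %).
Flow fields are first-class objects:

```r
seg$flows[[3]]
#> flow_field: 256 x 256, frame 3, window 7
#>   valid pixels: 65504 / 65536 (100.0%)
#>   |flow| over valid pixels: median 0.000, max 1.436 px/frame
```

`plot(seg)` draws the red-tinted overlay, `plot(seg$flows[[3]])` the
quiver map, and `save_outputs(seg, out_dir = "out")` writes the mask
PNG, overlay, raw flow planes and a manifest. Real data loads with
`load_sequence(path, "png-dir" | "tiff-stack" | "raw-array" |
"dicom-series")`; a restricted diagnostic zone is
`segment_motion(seq, attention = attention_window(row0, col0, h, w))`.

A thin command-line wrapper ships in `inst/cli/flowseg`
(`flowseg segment <input> --window 7 --attention 60,60,128,128`,
`flowseg flow`, `flowseg synth`).

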