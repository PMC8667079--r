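# sliscat — Scattered Light Imaging scatterometry analysis

Unstained histological brain sections scatter transmitted light
anisotropically: a bundle of parallel nerve fibers produces an elongated
scattering reflex perpendicular to the fiber direction, and crossing
bundles superimpose several reflexes. Scattered Light Imaging (SLI)
scatterometry measures this per image pixel by scanning a small square
kernel of LEDs (n × n lit LEDs) across a display below the specimen
(m × m positions) and recording one camera image per position. Pivoting
the resulting image series — pattern entry (i, j) of pixel p is the value
of p in the image recorded at kernel position (i, j) — yields an m × m
*scattering pattern* for every image pixel at once, from which the
in-plane directions of up to four crossing nerve-fiber bundles per pixel
can be recovered.

`sliscat` implements the full analysis chain in R, plus a forward phantom
simulator that renders synthetic measurements with known ground truth:

1. **geometry** — illumination angles θ = arctan(d/H) from display layout
   (defaults: 256 × 256 LEDs, 1.8 mm pitch, H = 130 mm, giving a maximum
   illumination angle of ≈ 60.6°), gnomonic ring radii `scale·tan θ`, and
   the diffusor calibration curve.
2. **assembly** — shot averaging, the series → pattern-cube pivot, and a
   chunked on-disk cube store.
3. **profiles** — unscattered-center detection (centroid of
   maximum-brightness pixels, plus subpixel refinement), circular
   cropping, and azimuthal profiles
   `I(φ) = Σ_{r=1..⌊R⌋} pattern(center + r·(−cos φ, +sin φ))`
   via bilinear interpolation (φ = 0 at top, clockwise).
4. **smoothing** — the tanh Fourier low-pass filter
   `M(g) = 1 − [0.5 + 0.5·tanh((g − cutoff)/width)]`, `g = |f|/f_Nyquist`,
   with presets `sli-1deg` (0.04, 0.125) and `sli-5deg` (0.40, 0.225),
   prominence-based peak counting, and the detection-rate grid search that
   selects filter parameters over reference fiber constellations.
5. **orientation** — centroid refinement of peak positions, peak pairing
   at 180° ± 35°, and the reflex-to-fiber +90° rotation giving direction
   angles in [0°, 180°).
6. **visualization** — hue-coded fiber orientation maps (2 × 2 subpixels
   per image pixel, hue = 2·angle) and fiber orientation distribution maps
   (block-wise overlays of low-alpha unit vectors, drawn only where at
   least 8 % of the block has a defined direction).

## Worked example

Render the scattering pattern of two crossing fiber bundles (30° and
120°) with shot noise, and recover their directions:

```r
library(sliscat)

geom <- display_geometry(kernel_size = 4, kernels_per_side = 48)
geom
#> <display_geometry> 256 x 256 LEDs, pitch 1.80 mm
#>   H = 130.0 mm (source-sample), L = 400.0 mm (sample-camera)
#>   kernel 4 x 4 LEDs, 48 x 48 positions, 3.00 um/px
#>   max illumination angle: 60.6 deg

bundles <- list(fiber_bundle(30), fiber_bundle(120))
pat <- render_pattern(bundles, geom, noise = noise_model(seed = 7))
fd <- analyze_pixel(pat)
fd$angles
#> [1]  29.91411 120.16740
```

The two recovered directions are within 0.2° of the ground truth. The
intermediate smoothed profile shows the four significant peaks sitting
perpendicular to the fiber directions (reflexes at direction + 90°):

```r
ctr <- refine_center(pat)
prof <- azimuthal_profile(scattering_pattern(pat$values, ctr,
                          crop_radius(dim(pat$values), ctr)), delta_phi = 1)
round(find_significant_peaks(lowpass(prof, "sli-1deg"))$phi_deg)
#> [1]  30 120 210 299
```

A full synthetic measurement — TIFF series, pattern cube, direction CSV,
and orientation maps — runs from the shell:

```sh
Rscript inst/cli/sli.R run-all --preset crossing3 --seed 3 \
    --out /tmp/demo --size 12 --kernels 48
```

Subcommands `simulate`, `assemble`, `profiles`, `smooth`,
`optimize-filter`, `orientations`, `visualize` and `calibrate` expose the
individual stages; every run writes a JSON manifest. Configuration is a
single YAML file (see `inst/extdata/example-config.yaml`).

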