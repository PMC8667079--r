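---
title: "SLI scatterometry: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SLI scatterometry: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sliscat)
```

## The measurement and its analysis chain

Scattered Light Imaging (SLI) scatterometry illuminates a thin, unstained
tissue section from many directions and records the transmitted light at
normal incidence. A square kernel of n × n LEDs is scanned over an LED
display below the specimen (m × m positions; one camera image each). Since
every kernel position corresponds to one illumination direction, pivoting
the image series gives, for every image pixel, an m × m *scattering
pattern*: its entry (i, j) is that pixel's intensity in the image recorded
with the kernel at display position (i, j). The pattern shows the angular
distribution of scattered light on a plane (a gnomonic projection — rings
of constant polar angle θ drawn every 10° lie at radius `scale·tan θ` and
grow farther apart outward).

The analysis chain per pixel is:

1. find the *unscattered center* — the region of maximum brightness where
   undeflected light hits the camera (`find_center()`: centroid of all
   pixels attaining the maximum; `refine_center()`: subpixel refinement);
2. crop to the largest circle around the center that fits in the pattern
   (`crop_radius()`), so every azimuth integrates over the same radial
   range;
3. integrate radially per azimuth with bilinear interpolation
   (`azimuthal_profile()`), giving the periodic profile I(φ), φ = 0 at the
   top, clockwise, in steps Δφ;
4. smooth I(φ) with a tanh-windowed Fourier low-pass (`lowpass()`);
5. find significant peaks by prominence on the min–max-normalized profile,
   refine their positions by the centroid of the peak tip, pair peaks
   separated by 180° ± 35°, and rotate each pair's axis by +90° to get the
   in-plane fiber direction (`analyze_pixel()`).

The key physical fact behind step 5 is that in-plane nerve fibers scatter
light predominantly *perpendicular* to their orientation, so a bundle
produces a reflex band through the pattern center at (direction + 90°),
and a pixel containing two or three crossing bundles shows four or six
profile peaks.

## Azimuth and coordinate conventions

One convention is used everywhere: φ = 0 points to the top of the
display/pattern/image and increases clockwise as displayed. In (row, col)
matrix coordinates the unit step along azimuth φ is
(Δrow, Δcol) = (−cos φ, +sin φ). Direction angles of fibers are axial
(mod 180°). Kernel scan order on disk is row-major from the display's
upper left, so the first recorded image fills the upper-left entry of
every pattern; kernel centers sit on half-integer LED offsets when m is
even.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `delta_phi` | 1 | deg | azimuthal profile step; 360 must be divisible |
| `filter` | `sli-1deg` (0.04, 0.125) | — | low-pass cutoff (fraction of Nyquist) and window width; preset `sli-5deg` = (0.40, 0.225) for 5° profiles |
| `prominence_threshold` | 0.08 | normalized | minimum peak prominence on the min–max-normalized profile |
| `tip_fraction` | 0.06 | of prominence | height band below the peak top defining the tip used for centroid refinement; chosen so a symmetric peak discretized at 15° refines to sub-degree accuracy |
| `pair_tolerance_deg` | 35 | deg | allowed deviation from 180° when pairing opposite reflex peaks |
| `reflex_rotation` | 90 | deg | reflex-axis-to-fiber rotation; switchable to 0 for toolchains that rotate internally |
| `min_radius_px` | 4 | pattern px | border-pixel guard: patterns whose crop circle is smaller are flagged invalid instead of analyzed (this is how the package avoids the asymmetric-illumination artifacts that plague fixed-angle SLI at image borders) |
| `min_contrast` | 0.1 | relative | profiles whose modulation (max − min)/max is below this yield no direction: min–max normalization would otherwise blow interpolation ripple of isotropic (gray-matter-like) pixels up to full scale |

The smoothing filter multiplies the Fourier coefficient at normalized
frequency g = |f|/f_max by `M(g) = 1 − [0.5 + 0.5·tanh((g − cutoff)/width)]`,
where f_max is the Nyquist frequency of the sampled profile (length/2
cycles per turn). The multiplier is applied literally to every
coefficient, including f = 0; the uniform DC attenuation is harmless
because all peak logic runs on min–max-normalized profiles. A window
width of exactly 0 is rejected (the expression is undefined there); a
step filter must be requested explicitly via a tiny width, and the
default optimizer grid therefore starts at 0.025.

## Numerical choices and degenerate inputs

* **Radial integration** starts at r = 1 (the center sample is excluded,
  so the constant value of the bright unscattered blob is not repeated in
  every bin) and ends at ⌊R⌋ in unit steps; the final fractional step is
  dropped rather than weighted. Bin positions are bin starts (φ = k·Δφ).
* **Center refinement.** The maximum-brightness centroid is quantized to
  the pixel grid under noise, and a half-pixel center error tilts the
  profile measurably: the steep unscattered blob leaks unevenly into the
  first radial samples and can change opposite reflex arms by tens of
  percent, dropping weak peaks below the prominence threshold.
  `refine_center()` therefore takes the intensity-weighted centroid of
  the bright core (pixels above 75 % of the min–max range, weighted by
  their excess): exact for a symmetric blob at any fractional position,
  and the reflex bands stay below the threshold.
* **Peak counting** uses strict circular local maxima; plateaus count
  once, at their (floor) midpoint. Prominence walks each way until a
  strictly higher value appears; tied global maxima thus get the full
  height above the global minimum. A flat profile has zero peaks; an
  all-equal pattern returns its geometric center with a degenerate flag.
* **Peak pairing** maximizes the number of pairs with circular separation
  within 180° ± 35° and, among maximal matchings, minimizes the total
  deviation from 180° (found by recursive search with a count bound;
  exhaustive for the ≤ 8 peaks that occur in practice). Leftover unpaired
  peaks contribute no direction — a single reflex arm without its mirror
  is treated as inconclusive.
* **Grid-search normalization**: each region's detection-rate matrix is
  divided by its own maximum before summing, so every fiber constellation
  weighs equally; all-zero regions are excluded with a warning, and
  argmax ties break to the lowest cutoff, then the lowest width.
* **Filter optimization vs. reporting**: `optimize_filter()` emits the
  full rate grid as CSV so the selected optimum can be recomputed
  independently from the artifact.

## The phantom simulator

`render_pattern()` is a descriptive forward model, not an electromagnetic
simulation: a Gaussian unscattered blob (σ = 1.5 px, amplitude
2 + 2·Σweights so the center always dominates), one anisotropic Gaussian
reflex band per bundle through the center at (direction + 90°) (width
2.5 px, truncated at 0.45 m), an out-of-plane inclination model that
displaces the band along the fiber by `(m/8)·tan(inclination)` px and
bends it into an arc (qualitative only — inclination is *not* estimated
by the analysis), a `cos⁴θ` illumination falloff standing in for the
1/r² distance increase and limited LED view angle seen in diffusor
calibration, and Poisson shot noise plus Gaussian read noise with shot
averaging and post-average gain. `render_stack()` drifts each pixel's
pattern center linearly across the field of view (the center follows the
kernel directly beneath the pixel). Reflex width and half-length are not
measurable from published material and are explicitly arbitrary; they
were fixed once to make peaks resolvable at Δφ = 1°.

Fixture suites (`region_fixture()`) draw randomized constellations —
parallel in-plane, out-of-plane (50–75° inclination), two crossings
(70–110° apart), three crossings (60° ± 8) — with weights 0.7–1.3,
widths 2–3 px, and shot noise at 1000 photons per intensity unit.

**What passing tests do and do not show.** The phantom reproduces the
*geometry* of the method (reflex perpendicularity, four/six-peak
crossings, center drift, vignetting, shot noise), so green tests validate
the analysis chain's correctness and its noise robustness. The phantom
does **not** emulate the high-frequency angular structure that real
profiles inherit from fiber substructure, nor speckle, tissue
heterogeneity, or polarization. One consequence is measured honestly by
the test suite: on synthetic profiles the raw (unsmoothed) 1° detection
rate for three-crossing regions is already near its ceiling, so low-pass
smoothing — which on real, rough profiles greatly increases detection
rates — can only merge closely spaced peaks there, and the
smoothing-benefit check passes for three of the four synthetic regions
but fails for the three-crossing suite. This is a limitation of the
smooth Gaussian-band phantom, not of the filter implementation, whose
gains match the closed form to machine precision.

## Scope and limitations

* Out-of-plane inclination is rendered qualitatively but never estimated;
  only in-plane directions are reported.
* No lens model, refraction, wavelength separation, or flat-field
  correction; shots are averaged raw.
* The cube store is a simple chunked float32 container (one pattern read
  = one chunk read) with a JSON index — adequate for the package's scale;
  very large cubes would warrant a standard hierarchical format.
* Problem sizes in the shipped tests (48 × 48 patterns, 1600-profile
  suites, 500-pixel recovery runs) were chosen to keep the full suite
  around a minute on one core while leaving every statistical margin
  comfortable.
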