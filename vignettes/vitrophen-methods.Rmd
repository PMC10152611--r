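---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitrophen)
```

vitrophen processes the four sensor streams of a gantry-based phenotyping
system for plant in vitro cultures: top-down RGB images, laser distance
scans, micro-spectrometer fluorescence readouts and radiometric thermal
frames, all acquired through closed, aseptic culture vessels. This vignette
is the package's own account of the models behind each pipeline, the
tunable parameters, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The synthetic scene model

No public image corpus of vessel scans exists at the scale needed for
testing, so the package ships a generator (`scene_truth()`, `render_*()`)
whose output is the single source of ground truth for every pipeline test.
A scene is a flat cultivation surface at height 0 carrying a raised
circular medium disk (radius 37 mm, the vessel bottom radius; height
default 20 mm, the nominal fill) with optional plane tilt, and
rotationally symmetric plant blobs standing on the medium. Hemisphere
blobs emulate compact rosettes; cones emulate pointed shoots.

What the generator emulates, with defaults and units:

* **Depth noise**, Gaussian per point, `noise_sd_mm = 0.1` — the laser
  sensor's specified linearity (±100 µm).
* **Depth dropout on steep surfaces.** A reflection-based sensor loses the
  return beam on strongly inclined leaves. A point is invalid when the
  *analytic* slope of the ideal surface exceeds
  `dropout_slope_threshold = 2.2` (≈66°). For a hemisphere of apex height
  $h$ and radius $r$ the lost fraction of projected pixels is
  $1/(1+(t r/h)^2)$; averaged over the default blob population
  ($r \sim U(5,8)$ mm, $h \sim U(6,14)$ mm) the threshold 2.2 yields a mean
  loss of one third, the regime reported for scanning-laser depth imaging
  of such cultures. The analytic (not finite-difference) slope is used so
  that the height discontinuity at the medium rim — which a nadir-viewing
  sensor sees as two flat surfaces, not a slope — does not drop out.
* **Illumination**: night frames are the day render scaled by 0.05 before
  the additive sensor noise (`sd = 2` on the 0–255 scale).
* **Fluorescence**: dark-current baseline (60 counts, sd 3) plus an
  excitation leak Gaussian at 375 nm (the UV LEDs imperfectly blocked by
  the 420 nm long-pass filter) and, when a plant is in the detection spot,
  chlorophyll emission Gaussians at 690 and 735 nm with width 15 nm, the
  sensor's resolution.
* **Thermal**: plant and background at set temperatures, quantised to the
  radiometric raw scale; imaging through the sealing foil compresses
  contrast toward the frame mean (×0.3) and adds a warm offset (+1.5 °C,
  sensor self-reflection).

One scene seed drives an independent substream per renderer, so
regenerating one sensor's data never shifts another's. All renders are
bit-reproducible.

What the generator does **not** emulate: water condensation, total internal
reflection, specular highlights, mirror images of plantlets on the vessel
wall, leaf texture and colour gradients, overlapping canopies, or
registration error between sensors. Passing tests therefore demonstrate
the correctness of the *computations* under controlled conditions, not
segmentation robustness on real imagery — the classifier's 0.97+ accuracy
on synthetic day scenes is a regime check, not a field claim.

## Calibration

Two pixel pitches are kept as independent `pixel_metric` objects: 37.7
px/mm measured at the 20 mm media height (used for plant area) and 46.7
px/mm at the 41 mm reference-object height (used for repositioning
repeatability). The camera is not telecentric, so the pitch depends on
object height; with only two measured heights we do not interpolate a
height-dependent scale model.

The laser calibration is an ordinary least-squares line from raw readout
to caliper-measured height (`fit_laser_calibration()`); robust fitting is
deliberately not used since the calibration target is clean. Heights are
referenced per scan to a zero plane estimated from the four 10×10 corner
blocks of the scan area, where only the bare cultivation surface is seen.
Heights above 72 mm are outside the sensor's reliable distance and
flagged invalid; negative heights are kept but indicate noise, since media
shrinkage cannot go below the vessel floor.

### Detection-spot-size determination

The spectrometer's spot diameter is estimated by scanning the spot in
1 mm steps across white squares of side 30 down to 21 mm and classifying
each square's intensity peak as *plateau* (≥2 adjacent positions within a
flatness tolerance of the maximum — the spot fits inside) or *sharp*; the
first sharp square's side is the estimate. The simulation places square
centres on scan positions and models the readout as the white area covered
by the spot.

The flatness tolerance is the one genuinely delicate number. From
closed-form circle-segment areas: a square that just contains the spot can
drop up to 1.09% of the peak one step off-centre (side 22 against a
21.5 mm spot), while a square that just fails to contain it always drops
at least 1.20% (side 29 against a 29.5 mm spot). The default
`flatness_tol = 0.0115` sits inside that forced window, making the
plateau rule agree exactly with the containment oracle (first sharp side
= ⌊diameter⌋) across the series. A tighter, more intuitive tolerance such
as 0.5% misclassifies containing squares and is wrong by construction. At
1 mm sampling the procedure cannot resolve diameters within ~0.2 mm of an
integer side — an intrinsic resolution limit, not an implementation one.

## RGB pipeline

Processing follows: per-channel histogram stretch (1st/99th percentiles to
0/255 — percentile-based to resist specular pixels), area-average
downscaling by 4 (4054×3040 → 1014×760; the trailing partial tile
averages the pixels it covers, and tile means round half-to-even to
8 bits), pixel classification, nearest-neighbour mask upscale (preserves
binarity), and 8-connected component labelling.

The classifier is a random forest over a fixed, versioned bank of 14
per-pixel features: R, G, B; hue, saturation, value; Gaussian-smoothed
intensity at scales 1, 3.5 and 10 px; gradient magnitude of the smoothed
intensity at 1.6 and 5 px; its Laplacian at 1.6 and 5 px; and a 1.6−5 px
difference of Gaussians. This bank is an explicit stand-in chosen from
standard trainable-segmentation practice (the size, 14, is fixed; the
exact features used by the original toolkit model are not published in
machine-readable form and are not asserted to be identical).

Traits per object: area (pixel count), perimeter as the 8-connected
boundary contour length with diagonal steps weighted √2, convex hull area
as an equivalent pixel count (hull of pixel centres corrected by Pick's
theorem, so a filled 10×10 square has hull area exactly 100), solidity =
area/hull area, stockiness = 4πA/P². Note a property of the chain metric:
it overestimates a circle's circumference by ~5%, so an ideal rasterised
disk scores stockiness ≈0.91, not 1.0. We keep the plain √2 weighting
rather than bias-corrected (Kulpa-style) weights because the definition is
simpler and the bias is systematic and documented; stockiness should be
compared within, not across, perimeter conventions.

Plant positions come from Otsu thresholding (exhaustive between-class
variance maximisation over 256 bins, ties to the smallest threshold) of
the hue channel; the 4 largest components' centroid offsets from the image
midpoint, converted to mm, are added to the gantry position. Night frames
are detected by mean intensity strictly below a threshold (default 30/255).

## Depth pipeline

For each scan: corner zero level → calibration conversion → medium circle
by a circle Hough transform on gradient-magnitude edges (radii 30–45 px
bracketing the 37 mm radius; edge threshold 5 mm/step, far above noise
and far below the ~20 mm medium step; these Hough parameters are package
defaults, exposed as configuration) → rim shaved by 3 px → RANSAC plane
(distance threshold 1.5 mm, sample size 3, 10000 iterations, seeded;
consensus-maximal plane refit by least squares on its inliers) → plane
subtraction. The circle is detected on the first (day-0) scan of a vessel
and reused afterwards, since the rim may later be overgrown.

Interpretation choices: the printed RANSAC distance threshold 1.5 is
taken as millimetres (heights are in mm after calibration); the same band
is used as the medium/plant cut after plane correction, which is
self-consistent with "inliers = medium". Mean canopy height averages
*nonzero* plant pixels only (the zeroed medium pixels would otherwise
dominate the mean); maximum plant height is the mean of plant heights at
or above their 90th percentile (linear-interpolation percentile).
Invalid (dropout) points are excluded from every mean and never imputed.
Medium volume uses the circular conical frustum
$V = \tfrac{1}{3}\pi h (r_1^2 + r_1 r_2 + r_2^2)$ with $r_2 = 37$ mm and
$r_1$ the pitch-converted detected top radius; it reduces to the cylinder
at $r_1 = r_2$ and the cone at $r_1 = 0$.

Error budget used by the recovery tests: the medium-height estimate
combines the plane fit over $N$ inliers with the corner zero level over
400 points, so the test tolerance is
$3\sigma\sqrt{1/N_{\text{inliers}} + 1/400}$ with $\sigma$ the depth noise
sd; canopy metrics get $3\sigma$. With defaults this is ±0.016 mm for
medium height.

## Spectral, thermal and haze processing

Spectrometer channels map to integer wavelengths by a 5th-degree
polynomial in the channel index (device-specific factory coefficients;
the package ships a documented synthetic linear default spanning
340–850 nm over 288 channels), rounded half-up; a non-monotone map is
flagged. Fluorescence spectra are corrected by the channel-wise mean of
all dark readouts, with negative differences clipped to zero (counts are
physical). The 400–660 nm band is masked (residual room light and
excitation leak). F690, F730 and F740 are read at the channel nearest the
nominal wavelength — no interpolation, the resolution is 15 nm — and both
F730 and F740 are reported because the literature uses F690/F740 as the
chlorophyll-content index while emission maxima are conventionally
labelled F690/F730; the index choice is left to the user. A ±10 nm
local-maximum check (within 5% of the window maximum, since the sampled
apex may sit one channel off) is attached as a quality flag.

Thermal raws convert as $T = \mathrm{raw}/100 - 273.15$ °C, exactly
invertible over the 14-bit range; histograms default to the sensor's
0.05 °C sensitivity as bin width; the contrast index is the P95−P5
temperature spread (so plants must cover >5% of the frame to register).
All-equal frames are flagged as probable mid-flat-field captures.

The haze index is $(\mathrm{diffuse}/\mathrm{total} - s)\times 100$,
clipped below at 0, with $s$ the instrument's relative scattered
transmittance — unpublished for the reference instrument, so it defaults
to 0 and reported haze values carry that caveat.

## Problem sizes

The test suite and acceptance script run entirely on generated data at
the sizes the package treats as its reference desk scale: 100×100 mm
scans at 1 mm pitch (10,000 points), RGB renders at 3.77 px/mm (377×377
px, one tenth of the full-system pitch — the classification resolution
after downscaling, ~94 px, keeps the largest feature scale meaningful),
four training scenes with 2000 sampled labels per class, twelve held-out
scenes for the segmentation regime check, and twenty seeded scenes for
depth parameter recovery. Full-resolution frames change none of the
arithmetic, only the pixel counts.

## Known limitations

* The feature bank, synthetic colours and noise models are stand-ins;
  accuracy numbers on synthetic scenes do not transfer to real vessels.
* Per-explant height requires connected components in depth data and is
  out of scope, as is RGB–depth registration.
* The Hough accumulator assumes one dominant circle; media fully
  overgrown at day 0 will defeat it.
* Stockiness values are tied to the √2-weighted perimeter convention
  (disk ≈ 0.91).
* The spot-size procedure inherits the 1 mm scan resolution.
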