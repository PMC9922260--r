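---
title: "Quantifying actin cytoskeleton chirality in confined cells and microcultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying actin cytoskeleton chirality in confined cells and microcultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the measurement
models, the sign and unit conventions, the tunable parameters, the numerical
choices made where the design was genuinely open, what the synthetic data
emulate, and the known limitations. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The single-cell model: radial-fibre tilt

A fibroblast confined to a circular adhesive island organises its actin
cytoskeleton into radial fibres (RFs), anchored at focal adhesions on the
cell edge and growing towards the centre, and transverse fibres that move
centripetally along them. Chirality manifests as a consistent signed tilt of
the RFs away from the exact radial direction.

The measurement proceeds in annular coordinates. The cell mask (Gaussian
blur with `gaussian_sigma_px = 3`, threshold at `otsu_fraction = 0.4` of the
automatic Otsu value, closing, hole filling, one erosion, largest component)
gives the centroid and the spread area. The **corrected radius**
`R = sqrt((area − area_inflation_um2)/π)` compensates the systematic
segmentation halo around the 1800 µm² pattern; the default inflation
constant is 63.353 µm². Cells whose *uncorrected* area falls outside
[1700, 2000] µm² are rejected (QC applies to the measured spread area; the
correction only enters R). Both QC bounds are read inclusively — the weaker
filter, since only an open interval was specified.

Eight annuli of width `annulus_width_um = 4` at `annulus_step_um = 2`
increments cover edge distances 0–18 µm. Distance from the edge is the
Euclidean distance transform of the actual mask, not of the idealised
circle, so irregular cells keep honest ring geometry; the best-fit circle
enters only through R in the projection formula.

Each fibre segment clipped to an annulus gets a total-least-squares line
fit; the line's continuation is intersected with the annulus boundary
contour nearer the cell edge (for annulus 0, the cell edge itself), and the
vector r̄ from the centroid to that intersection defines the local signed
angle θr and its length r. The edge-projected tilt is

θ = sign(θr) · arcsin( min(|r·sin θr| / R, 1) ).

Two geometric facts shape this design:

* Because the intersection point lies on the fitted line, r·sin θr equals
  the line's perpendicular distance from the centroid, so θ is **exactly
  annulus-independent for straight fibres**. This is the package's main
  internal consistency check (the chord-consistency test).
* Choosing the *centroid-proximal* ring boundary instead would make the
  intersection degenerate in the deep annuli, where the boundary radius
  approaches the chord's tangent radius and θr is driven to ±90°. The
  edge-proximal boundary always exists for a chain inside the ring. Its
  price is that r can slightly exceed the corrected R in annulus 0 (the
  mask edge sits outside the corrected circle by construction of the
  inflation correction); the arcsin argument stays valid there because the
  perpendicular distance, not r itself, is what enters the formula, and
  requiring r ≤ R would silently empty the outermost annulus. Hence no
  r-based exclusion is applied: the only exclusion is |θr| ≥
  `theta_r_max_deg` (68°, read sign-symmetrically — the mirror-antisymmetry
  contract forces a symmetric filter), marking near-tangential segments
  that are unlikely to be radial fibres.

Sign convention, used identically everywhere (single cells, directors,
nuclei, ellipses, and the generators): angles are measured in the displayed
image (row index increasing downwards) and are positive for an
anticlockwise rotation as displayed. θr is positive when the fibre direction
is rotated anticlockwise from the outward radius. Consistency between
analysis and generator — not absolute handedness — is the testable contract.

Per-cell profiles average θ over included measurements per annulus (empty
annuli are `NA`, never 0); the report value is the mean in the configured
report annulus (6–10 µm by default, 8–12 µm selectable). Population
summaries average across cells (SEM over cells, never over segments) and
histogram the report values in 5° bins with 0° as a bin edge, so the sign
classes never straddle a bin.

## The fibre-extraction chain and its free parameters

The first stage — turning an actin image into a fibre-probability map — is
pluggable (`classical`, `external_mask`, `external_model`-style maps via
`fibre_probability_from_map()`). The classical default is a multi-scale
ridge (tubeness) filter: the scale-normalised negative principal curvature
of the Gaussian-smoothed intensity, maximised over scales of 1–3 px,
multiplied by cos² of the axial difference between the local
structure-tensor orientation and the radial direction. The cos² weight
suppresses transverse (circumferential) fibres. Inputs are
contrast-stretched with 0.35% total saturation first. Three support rules
keep the map honest: the response is zeroed outside the cell, within a thin
(~1.6 µm) boundary band — the cell outline's own intensity step is not a
fibre — and deeper than 19 µm below the edge, just past the measured 0–18 µm
domain, where RFs end and their converging tips carry no radial-fibre
signal. A confidence floor of 0.01 (relative to the map maximum) removes
the faint response shoulders that flank bright fibres.

The fixed post-processing chain: rolling-ball background subtraction
(radius 30 px, realised as grayscale opening with a disc — the morphological
formulation of the rolling ball), then Niblack local thresholding with a
15×15 window, k = −0.3 and offset −0.01 on the [0, 1] scale. The offset is
**subtracted** from the threshold (T = μ + kσ − c), the common MATLAB
parameterisation: the default constant −0.01 then raises the threshold
by 0.01, which is also what makes the degenerate cases deterministic — a
constant image yields no foreground, and zeroed regions can never switch
on. With the alternative additive reading, every positive-valued pixel of a
flat region would be foreground, which no working pipeline can mean.
Zero-valued pixels are additionally never foreground: with negative k, a
window holding a few bright pixels in an otherwise empty region can push T
below zero.

Skeletonisation uses Guo–Hall thinning (cleaner than Zhang–Suen on diagonal
strokes, which that algorithm braids into two-pixel staircases). Branch
points are pixels whose crossing number (0→1 transitions around the 8-cycle)
exceeds 2 — a neighbour count would wrongly flag ordinary stair-step pixels
— and are removed iteratively; the remaining branch-free chains (≥ 3 px) are
traced in order.

Linking reconnects fragments of one fibre broken at branch points: chains
merge when their fitted directions differ by ≤ 30°, their closest endpoints
are ≤ 30 px apart, *and* each chain's centre lies within 4 px of the other's
line. The collinearity gate is essential: radial fibres converge near the
cell centre, where distinct fibres satisfy the angle and distance rules and
would otherwise be bridged sideways into segments whose direction belongs
to neither fibre. Merging is transitive; each merged fibre refits its line
over all member pixels. Merged segments shorter than `min_segment_px = 15`
are discarded — below the minimum the measurement stage can use
(`min_clip_px = 7` plus a 4 px trim at each free end, where thinning leaves
small sideways hooks). Finally, segments lying essentially along the
circumference (≥ 80° from radial at their centre) are dropped before
measurement; the fibre stage's contract is radial fibres, and the 68° rule
would exclude all their in-ring measurements anyway — except when a deep
tangential chain is measured against a much shallower ring boundary, the
one leak in the θr filter that this segment-level rule closes.

## The collective model: directors and nuclei

Microculture segmentation runs entirely on texture: Wiener adaptive
denoising (20×20 neighbourhood; even sizes are rounded up to the next odd
size for a centred window), local Shannon entropy over the 3×3 structural
element (32 grey bins — with 9 pixels per neighbourhood, finer quantisation
adds nothing), grayscale opening with a 9×9 disc, Otsu binarisation, and
selection of the largest component reaching a small central box. QC demands
bounding-box width 225–375 µm, height > 550 µm and mask coverage > 80% of
the box; QC rejection is data, not failure, and is logged with the failing
value.

The nematic director field tiles the centred 200×500 µm ROI with 60×60 µm
windows at 70% overlap (stride 18 µm, giving 8×25 = 200 windows; placement
is computed in micrometres so the count is pixel-size independent, and the
grid is centred so mirroring the image maps windows onto windows). Each
window accumulates Gaussian-derivative gradients into a structure tensor;
the dominant axial orientation relative to the rectangle's long (vertical)
axis and the coherence (λ1−λ2)/(λ1+λ2) are recorded, zero-gradient windows
dropped.

Nuclei are segmented with a Wiener filter (9×9) and NICK adaptive
binarisation, `T = m + k·sqrt((Σp² − m²)/NP)` with k = −0.2 over a 51 px
window (the window size is not dictated by the model; ~1.3× the nucleus
major axis makes the local statistics near a nucleus raise the threshold and
detach the nucleus from the large dim background component). Components
larger than 10000 px — the background — are removed *before* splitting;
cutting the background component could only carve spurious nucleus-sized
fragments out of it. Touching nuclei are separated by concave-point
splitting: contour points whose turning angle opposes the contour's winding
by more than 60° are paired by shortest mutual distance and cut along the
connecting line, recursively, one cut per object per pass. Objects outside
[500, 10000] px or with centroids outside the culture bounding box are
discarded; orientations come from second image moments (ellipse fit).
Microcultures with fewer than 50 nuclei lose their nuclei readout.

Alignment uses axial circular statistics: orientations are doubled before
averaging, which is what makes a {0°, 90°} pair cancel exactly — the
behaviour any orientation statistic must have — and the mean resultant
length of the doubled angles is compared against 0.5 (directors) or 0.35
(nuclei, a less coherent readout). The per-culture mean is the axial
circular mean. No coherence floor is applied to director windows beyond
dropping exactly-zero-gradient ones; none was needed on clean or noisy
synthetic textures.

## Elliptical micropatterns

For single cells on 1:2 (34×68 µm) or 1:3 (27.5×84 µm) elliptical patterns,
the stress-fibre tilt relative to the long axis (vertical by convention;
rotate inputs first) is the dominant orientation of a *single* whole-mask
structure tensor — gradient-energy weighting over all pixels of the
pattern-shaped mask centred on the intensity centroid. This is the
whole-ROI statistic of the standard orientation-measurement approach, not a
windowed average; gradient-energy weighting is the documented answer to
whether orientations should be coherence-weighted. Time courses apply a
trailing moving average over 4 sequential frames (output length n−3).

## Statistics

Bimodality: the sample is histogrammed (5° bins, 2° for stress-fibre tilt
histograms, 0° always a bin edge) and one Gaussian versus a sum of two is
fitted to the *counts* by unweighted least squares (Levenberg–Marquardt).
The nested models are compared by the extra-sum-of-squares F test at
α = 0.05. The double fit is seeded deterministically from a k-means split at
the sample quartiles, plus a second start that embeds the single-Gaussian
solution (which guarantees the double fit cannot end above the single fit's
residual sum of squares, keeping the F statistic non-negative). Amplitudes
and widths are unconstrained. "Bimodal" additionally requires the ordered
component means to straddle zero — the signature of a population split
between dextral and sinistral states; two same-sign means are a shape
feature, not chirality. Non-convergence falls back to the single model with
a flag.

Group comparisons are the two-tailed Mann–Whitney U, Kruskal–Wallis with
Dunn's post-hoc (rank-sum z statistics with tie correction and Bonferroni
multiplicity adjustment, the conventional "multiplicity adjusted P" for this
test), and the one-sample Wilcoxon signed-rank against zero — always on
per-cell or per-culture summary values, never on segments pooled across
cells. The individual-versus-collective correlation is Pearson's r with a
two-tailed p, plus Spearman's rank correlation, over per-condition pairs of
mean RF tilt (6–10 µm annulus) and mean nematic director angle.

## The synthetic data: what it emulates and what it does not

Generators are pure functions of (parameters, seed); the caller's RNG
stream is untouched and every image is paired with a ground-truth manifest.

* `make_cell()` renders a soft-edged disc of 1800 µm² at 0.138502 µm/px
  (512×512, 16-bit) with 20 radial fibres by default: anti-aliased Gaussian
  cross-section of ~0.5 µm FWHM, fibre peaks ~4× the cytoplasm level,
  cytoplasm ~20× the camera background, Gaussian read noise of 150 counts
  (Poisson shot noise optional), fibre lengths 18–21 µm so that all eight
  annuli are populated. The `chord` model draws straight fibres crossing
  the edge circle at the signed ground-truth angle — the projection formula
  is exact for chords, making the oracle analytic. The `spiral` model draws
  constant-angle logarithmic spirals, for which θr equals the ground truth
  at every radius and θ therefore varies across annuli — exercising
  annulus dependence. Negative-tilt scenes are exact horizontal mirrors of
  their positive counterparts (verified bit-wise at zero noise).
* `make_microculture()` renders a 300×600 µm rectangle at 0.5 µm/px: the
  phase channel carries 10 µm sinusoidal stripes (or cell-like soft-edged
  elliptical blobs, elongated or isotropic) plus fine speckle — the
  organelle-scale graininess the entropy filter keys on; broad smooth
  texture would be flattened by the Wiener stage and fail segmentation, as
  real featureless regions would. The nuclei channel holds ~250 soft-edged
  ellipses (~20×12 µm, matching the 500–10000 px gates at this pixel size)
  with axial orientations normal around the ground-truth angle (SD 15°, a
  realistic spread that still leaves the mean resultant length well above
  the 0.35 cutoff).
* `make_nuclei_pairs()` places nucleus pairs on a jittered grid with a
  stated fraction drawn overlapping (centre separation 1.5× the semi-minor
  axis: a clear dumbbell waist), for exercising the splitting step;
  `nucleus_scale` shrinks objects below the 500 px gate for the size-filter
  cases.
* `make_ellipse_cell()` fills the elliptical pattern with 3 µm-period
  stripes at the ground-truth tilt.
* `make_condition_table()` draws per-condition (RF tilt, director angle)
  means from a bivariate normal with the stated correlation (SDs 8° and 9°
  around small positive centres, the scale of real condition spreads).

What passing tests on these data do **not** show: robustness to uneven
illumination, optical aberrations or out-of-focus light; to cells that
deviate from the pattern; to nuclei intensity heterogeneity (the dim
interstitial background can contribute occasional nucleus-sized fragments —
a known limitation visible as a few percent of spurious detections on dense
fields, without measurable effect on orientation means); or to the
difference between a trained segmentation model's fibre probabilities and
the classical ridge stage. The classical stage is a first-class analysis
path, not a reimplementation of any trained model; external probability
maps can be substituted at `binarize_fibres()`.

## Numerical choices and degenerate inputs

* Orientation mathematics is done in y-up coordinates (x = column,
  y = −row) so positive angles are anticlockwise as displayed; axial values
  wrap to (−90°, 90°].
* Line fits are total least squares (principal axis of the pixel scatter),
  robust to the direction quantisation of short chains; clips shorter than
  7 px are not measured at all, and clips with RMS perpendicular residual
  above 1.5 px (V-shaped pixel sets straddling a crossing) are rejected as
  having no single orientation.
* The annulus-boundary intersection is found by sampling the fitted line at
  0.25 px steps through the bilinear-interpolated distance map and
  interpolating the crossing; if no crossing exists (degenerate fit), the
  line's deepest point is used, which lands in the 68° exclusion.
* Ties and multiple crossings resolve to the crossing nearest the clipped
  sub-chain.
* Mirror "exactness" for the collective readout is exact up to raster
  parity: ROI extraction and window placement can differ by half a pixel
  between an image and its mirror; the residual is orders of magnitude
  below any biological signal (the acceptance script reports it).
* Problem sizes in the tests and the acceptance script — 10 cells per tilt
  level across five levels, single microcultures per texture, 30 nucleus
  pairs per field, 20 bimodality replicates per class, 200 correlation
  replicates at 35 conditions — were chosen as the smallest sets that
  estimate each quantity stably.

## Configuration

All constants live in `pipeline_config()`: micrometre thresholds are applied
in micrometres and converted per image through its pixel size; pixel
thresholds (rolling-ball radius, Niblack window, link distance, nucleus
areas) are applied in pixels and are therefore resolution-dependent — they
match the acquisition scales above. The pixel size of collective-culture
images is always an explicit user input. Configurations round-trip through
YAML exactly, command-line flags override file values, and every run
summary embeds the full effective configuration.
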