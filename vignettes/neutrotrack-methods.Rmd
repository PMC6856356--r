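---
title: "Quantifying receptor internalization and neutrophil wound migration"
author: "NeutroTrack authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying receptor internalization and neutrophil wound migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeutroTrack)
```

## Scope

NeutroTrack quantifies two aspects of neutrophil biology at wounds from
time-lapse fluorescence microscopy of 2D maximum-intensity projections:

1. **Chemokine receptor internalization**, scored per cell as the
   gray-level co-occurrence (GLCM) contrast of a GFP-tagged receptor
   within a segmented cell surface. Receptor that relocates from the
   plasma membrane into endosomal vesicles produces a punctate intensity
   pattern and therefore a high contrast; receptor retained at the
   membrane produces smooth intensity variation and a low contrast.
2. **Migration behaviour relative to the occupied wound area (owa)**, the
   polygon covered by the neutrophil cluster: forward/reverse track
   classification, instantaneous speed against distance and approach
   angle, track straightness, net reverse traffic (dispersal), wound
   recruitment counts and cluster sizes.

Because raw wound movies are rarely shareable, the package ships a
synthetic-scene generator with exact ground truth. Everything the
analysis modules compute can therefore be validated end to end.

## The internalization score

For a segmented cell, intensities inside the surface mask are linearly
quantized to $N = 8$ gray levels over the mask's own min..max range and
pair frequencies $p(i,j)$ are accumulated for the right-neighbour offset
$(0,1)$, using only pairs with both pixels inside the mask. The contrast
is

$$C = \sum_{i,j=0}^{N-1} |i-j|^2 \, p(i,j),$$

a dimensionless quantity in $[0, (N-1)^2]$. Because quantization uses the
mask's own range, $C$ is invariant to affine transforms of the cell's
intensities (illumination gain and offset drop out) — this is asserted by
a property test.

**Quantization and pair-handling choices.** The gray-level count, offset
and quantization range are conventions, not measurements; we use the
common defaults ($N=8$, single right-neighbour offset, non-symmetric
accumulation, per-mask min..max) and expose all of them in the
configuration. Pairs that cross the mask edge are excluded by default so
the score reflects intracellular heterogeneity rather than the
cell/background boundary; a zero-fill variant (out-of-mask pixels set to
intensity zero, edge pairs retained) is available behind a flag for
sensitivity analysis. Because conventions differ between toolchains, all
claims the package validates are ordering and monotonicity properties,
never absolute contrast values.

**Quality gates.** Manual exclusion of unusable cells is replaced by two
explicit, logged gates: a cell is dropped if more than 1 % of its pixels
sit at the saturation value, or if its intensity range spans fewer than 4
of the 8 quantization levels of the (unsaturated) image range.

**Normalization.** Two reference schemes are implemented: division by the
mean contrast of non-mobilized reference cells (the CHT, the caudal
hematopoietic tissue that serves as the resting-cell reservoir), used
when resting cells are present in the same movie; and division by the
per-movie maximum, used when all imaged cells are mobilized. The mode and
divisor are recorded with every value.

**Gradient profiling.** Each cell's centroid is assigned its minimum
Euclidean distance to the wound-margin polyline (exact point-to-segment
minimum); normalized contrast is binned by distance (default 25 µm bins)
with the mean, SEM across cells, and n per bin. A three-parameter
exponential $A e^{-d/L} + B$ fitted by Levenberg–Marquardt least squares
summarizes the decay length $L$ of the internalization gradient.

## Trajectory analysis

Tracks are $(t, x, y)$ sequences in seconds and micrometres, as exported
by spot-tracking software. Ingestion drops points outside the fin polygon
(movement in the CHT is not interstitial migration), then removes tracks
with fewer than three time points; a 3-point track is retained.

The owa is a simple polygon in micrometres. Points exactly on its
boundary count as inside, which makes entry/exit detection deterministic.
Classification follows the entry/exit rules: a track that starts outside
and intersects the owa yields a *forward* segment from its first point to
the last point before first entry; if points exist after its last in-owa
residence it also yields a *reverse* segment from the last in-owa point
to the track end. Non-intersecting tracks are forward- or away-moving
according to whether the end point is closer to the owa than the start.
Tracks that never appear outside the owa are reported separately as
`unclassified_inside`.

Per step (consecutive point pair), the package computes speed
$v_t = |\Delta r| / \Delta t$ in µm/min, the distance $d_t$ from the
step's start point to the nearest owa-perimeter point (0 inside), and the
approach-angle cosine $\cos\theta_t$ between the step displacement and
the vector to the nearest perimeter point. $\cos\theta$ is undefined (and
excluded from binning) for zero-displacement steps and in-owa starts;
$\theta$ is defined at the step origin, matching the instantaneous usage
of the other step quantities. Default bins are 25 µm for distance and
0.25 for the cosine, both configurable; speed–orientation statistics are
restricted to a zone within 50 µm of the owa perimeter, the region where
the wound signalling gradient is strongest.

Track straightness restricts a track to its points within the 50 µm zone
(in-owa points count as distance 0), in temporal order, and divides net
displacement by cumulative path length; tracks whose restricted path is
shorter than 10 µm are excluded as too immobile to characterize.
Net reverse traffic is the count of reverse segments divided by the count
of owa-intersecting forward tracks; non-intersecting tracks are excluded
from both counts. Aggregation units (per cell step, per cell, per larva)
are explicit parameters, never inferred.

Recruitment is counted as centroids inside a closed 200 × 200 µm square
around the wound centre. Cluster sizes drop segmented surfaces below
60 µm² (spurious detections) and average the rest over a stated time
window; both the 50 px and 60 µm² filters remove objects *strictly*
below the threshold, so objects exactly at the threshold are retained.

## Segmentation

Seeded segmentation mirrors an active-contour (Chan–Vese) workflow: a
manually supplied seed point is expanded into a square core (half-width
5–15 px), a two-phase Chan–Vese level set evolves from that core
(range-normalized image, so evolution is invariant to uniform intensity
scaling; curvature weight 0.2; at most 200 iterations; convergence when
the binary mask is unchanged over 5 consecutive iterations), and the
connected component containing the seed is returned with holes filled.
The explicit update is step-normalized by the 95th percentile of the
driving force so that boundary pixels flip within a few iterations and a
stray hot pixel cannot stall the evolution. The whole-image threshold
variant labels connected components above an intensity threshold — these
may be multi-cell clusters, which is intended for dense time-lapse data —
and applies the 50 px size filter. Contours are the surface minus its
box-erosion by a configurable thickness (default 1 px).

## The synthetic-scene generator

The generator is first-class, tested code; its defaults define the
conditions under which the package validates itself.

**Cell phantoms.** A phantom emulates a maximum-intensity projection of a
round cell of radius 10 µm at 0.5 µm/px. Membrane-localized receptor
projects to a smoothly shaded disk — the projection passes through the
membrane cap over the whole footprint — modelled as a plateau with a
central dome (amplitude 2× the plateau, width 0.6 r) plus a modest
membrane rim band (30 % boost, 1 µm thick). The blurred cell edge sits
0.75 µm outside the nominal mask radius, so the ground-truth surface mask
is conservative with respect to the fluorescent footprint, as an
active-contour mask is in practice. Internalized receptor is rendered as
PSF-sized Gaussian puncta (σ = 0.5 µm) at Poisson-disk-sampled sites
(minimum spacing 1.8 µm, endosomes are spatially dispersed) inside the
interior eroded by two membrane thicknesses. A fixed 40 % of flux is a
smooth cytosolic pool shared by both phenotypes.

The vesicular fraction controls the *number* of active puncta at fixed
per-punctum brightness (the last punctum takes the fractional remainder),
not their amplitude. This choice keeps total flux exactly conserved
across the membrane/vesicular split and makes the contrast response
near-linear in the fraction, which is what lets a three-parameter
exponential fit identify the gradient decay length. Gaussian noise
defaults to σ = 0.5 % of the image maximum: we found empirically that 2 %
noise, while preserving the membranous-vs-vesicular ordering, saturates
the contrast response at high vesicular fractions and destroys decay
length identifiability, so the default was set at 0.5 % — representative
of a well-exposed confocal acquisition — before the validation suite was
frozen.

**Gradient scenes.** Cells are placed without overlap at distances
uniform in [0, 500 µm] from a straight wound margin; the true vesicular
fraction of a cell at distance $d$ is $e^{-d/200\,\mu m}$, emulating the
observed internalization gradient with its 200 µm decay length. The
500 µm span (2.5 decay lengths) was chosen so the exponential fit is well
identified; profiling a shorter window leaves $L$ and the baseline $B$
confounded.

**Walker cohorts.** Tracks are biased persistent random walks sampled at
30 s intervals (the standard acquisition interval for these movies), with
von Mises headings: within 200 µm of the owa the heading concentrates
(κ = 4 by default) toward the nearest owa-perimeter point, otherwise the
turn angle concentrates around zero with a concentration matched to the
persistence parameter (expected turn cosine 0.6). Speeds are
$N(8, 2^2)$ µm/min truncated at zero, typical of zebrafish neutrophils.
On entering the owa a walker dwells 10 frames, then with probability
`pReverse` disperses: its first post-dwell heading points away from the
owa centroid, after which it performs an unbiased persistent walk that
does not re-enter the owa; otherwise it performs a confined walk inside
the owa. The fin polygon is a reflecting boundary. Ground-truth labels
are recorded from the realized geometry (entered/exited), so label
soundness — forward labels have an in-owa point, non-intersecting labels
have none — holds by construction, and the dispersal kick makes the
realized reversal fraction match the nominal probability (exactly 0 and
exactly 1 at the extremes). An optional speed–orientation coupling
$v = v_0 (1 + a \cos\theta)$ (default $a = 0$) provides a recoverable
effect size for the speed–cosine analysis.

**What the generator does not emulate.** No photobleaching, stage drift,
z-dimension, receptor biochemistry, cell shape change, division or death,
track fragmentation or mis-linking. Passing tests therefore demonstrate
correctness of the measurement chain, not robustness to every real-data
artifact; in particular real tracking errors (switched identities) would
enter the classifier unmodelled.

## Numerical choices and degenerate inputs

- Boundary semantics: points on the owa boundary are inside; the 200 µm
  recruitment square is closed; size filters remove objects strictly
  below threshold.
- A constant masked region maps all mass to $p(0,0)$ (contrast 0); a
  constant whole image is a segmentation failure (no boundary exists).
- Zero divisors (empty references, zero movie maximum, zero transplant
  signal) raise errors rather than producing silent NaNs.
- SEM is reported only for $n \ge 2$; empty scopes yield empty profiles
  with warnings; every excluded cell or track is logged with its reason.
- All randomness flows through explicit integer seeds; a fixed
  configuration and seed reproduce every output byte-for-byte.

## Validation problem sizes

The shipped test suite validates the oracle equivalence of the GLCM on
100 random 16×16 masked images; phenotype ordering over 50 phantom seeds;
gradient recovery on 20 scenes of 40 cells (Spearman > 0.8 against truth,
fitted decay length within ±30 % of 200 µm); classification agreement and
net-reverse-traffic recovery on cohorts of 520 walkers; and byte-level
determinism of the full pipeline. These sizes were chosen as the smallest
cohorts at which the binomial and correlation criteria are comfortably
powered.

## A worked example

```{r example}
# a vesicular and a membranous phantom at matched flux
mem <- renderCellImage(scenePhantomParams(vesicularFraction = 0, seed = 1))
ves <- renderCellImage(scenePhantomParams(vesicularFraction = 1, seed = 1))
c(membranous = glcmContrast(coocMatrix(mem$image, mem$surfaceMask)),
  vesicular  = glcmContrast(coocMatrix(ves$image, ves$surfaceMask)))
```

```{r tracks}
fin <- owaPolygon(cbind(c(-300, 300, 300, -300), c(-300, -300, 300, 300)))
owa <- owaPolygon(cbind(c(-20, 20, 20, -20), c(-20, -20, 20, 20)))
tr <- simulateTracks(walkerParams(nTracks = 100, nFrames = 120,
                                  pReverse = 0.3, startDistance = 80,
                                  finPolygon = fin, seed = 2), owa)
cl <- classifyTracks(suppressMessages(loadTracks(tr)), owa)
netReverseTraffic(cl)
```

## Known limitations

- The contrast score is a texture proxy for internalization; it does not
  count vesicles or measure their depth, and it is sensitive to the
  quantization convention (hence the ordering-based validation).
- The Chan–Vese implementation is a compact two-phase level set intended
  for single-cell seeds on projected images; it is not a general-purpose
  segmenter and does not separate touching cells.
- The walker model is phenomenological: it reproduces the geometry and
  statistics the trajectory analyses consume, not the underlying
  signalling dynamics.
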