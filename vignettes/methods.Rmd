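---
title: "Counting cattle in UAV imagery: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting cattle in UAV imagery: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdcount)
```

`herdcount` counts light-coated cattle in 8-bit RGB frames captured at
roughly 1 cm/pixel ground sample distance, where an adult animal covers
about 13,000 px. This vignette explains the model behind each stage, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open and a
choice had to be made.

## Assumptions

The whole rule set leans on three facts about this imaging regime:

* the coat (white to light beige) is *darker than its surroundings in the
  C, M, Y and pseudo-CIELAB channels*, so binarization always keeps pixels
  below a threshold;
* animal size in pixels is predictable up to terrain-induced GSD drift,
  so area and solidity rules are meaningful;
* consecutive frames overlap by ~70% and the scene is approximately
  static between neighbouring exposures, so de-duplication can reason
  about world positions via frame-to-frame translations.

When these fail — dark breeds, oblique imagery, strongly moving herds —
the constants must be retuned, and the rule logic itself may not carry
over.

## The quadrant color stage

Each frame's region of interest (224-px grid tiles accepted by a
pluggable classifier; everything else zeroed) is split into four
quadrants processed independently, so a cloud shadow over one corner of
the frame does not poison the thresholds of the rest.

Per quadrant:

* **Correction factor** `cf = 85 / mean(Pi)`, `Pi` the values of all
  three channels of the ROI pixels. 85 is the intensity of a mid-exposed
  pasture; `cf` rescales the fixed thresholds between over- and
  under-exposed frames.
* **Activity floor**: quadrants with fewer than 50,000 Y-channel pixels
  above zero carry too little usable content and are discarded outright
  (they contribute black to every mask and no Y threshold).
* **Channels**: C, M, Y from the standard CMYK conversion with black
  extraction, each rescaled to 0–255; plus the *custom* channel, the blue
  output of the CIELAB→sRGB formulas applied to (R, G, B) reinterpreted
  as (L, a, b). The transform is perceptually meaningless but darkens the
  warm, bright coat colors dramatically.
* **Thresholds**: C at `min(100, 40·cf)`, M at the constant 30 (aimed at
  reddish soil, which otherwise leaks into the masks), custom at
  `min(150, 120·cf)`. The Y channel gets the histogram machinery below.

### The Y histogram rule chain

The Y channel separates coat from background best, and also varies the
most across capture conditions, so its threshold is estimated per
quadrant from a 256-bin histogram of the ROI pixels smoothed by a
length-25 moving average:

1. *Dark test*: if the smoothed mass of bins 0–9 exceeds that of bins
   100–255, the quadrant is deemed very dark and the threshold is 10.
   (The 156 "top" bins deliberately ignore the middle of the histogram.)
2. *Peaks*: strict local maxima of the smoothed curve; peaks separated by
   fewer than 30 bins are merged keeping the larger. At least two must
   remain — one for the animals, one for the background — otherwise the
   quadrant contributes no threshold.
3. *Valley*: between the two lowest-index peaks, among bins with
   amplitude below 10% of the second peak's, the bin closest to the
   second peak wins; failing that, the argmin between the peaks.

The *smallest* threshold over the quadrants is applied to the whole
image — a deliberately conservative choice — and then again divided by 2
and by 4, yielding three nested Y masks. Because "white" means *below*
threshold, the full-threshold mask is the most permissive and the
quarter-threshold mask the most restrictive: `final_T4 ⊆ final_T2 ⊆
final_T` after fusion. The three variants hedge against conditions that
shift the Y histogram; the final arbitration (below) picks among them.

Numerical conventions, fixed once and tested against a bin-by-bin oracle
transcription of the rules: smoothing uses symmetric (mirrored) boundary
padding; plateau peaks take their leftmost bin and curve endpoints may be
peaks (outside counts as −∞); equal-height peaks closer than 30 bins keep
the lower index; T/2 and T/4 round down to integer bins; all threshold
comparisons are strict (`value < T`); both `cf` and the histogram are
computed over ROI pixels only, since the zeroed non-cattle tiles would
otherwise flood bin 0 and spuriously trigger the dark test.

## Fusion and object rules

For each Y variant the masks combine as
`restore(Y ∧ M) ∨ C ∨ custom`, where `restore` reverts the blackened
pixels of any Y object that intersects M somewhere but lost area in the
AND: M's role is to veto entire false objects (reddish soil), not to
erode true ones. Objects are 8-connected throughout, so diagonally
touching fragments stay one animal.

Counting then runs per fused mask:

* drop objects with area < 2000 px (noise specks) and objects with
  area < 5000 px *and* solidity < 0.7 (small ragged debris); boundary
  values survive, "smaller than" being read strictly;
* the elevation factor `ev` is 1 / 1.25 / 1.5 for mean object area
  < 8000 / < 15,000 / ≥ 15,000 px, compensating GSD drift from terrain
  elevation (zero objects ⇒ `ev = 1`, there being nothing to rescale);
* objects with area > 15,000·ev, solidity < 0.65, or area > 12,000·ev
  with solidity < 0.7 are candidate clusters: their footprint is thinned
  (topology-preserving Zhang–Suen, `round(20·ev)` iterations) and eroded
  once with a 3×3 square, severing the one-pixel necks the thinning
  leaves between member cores; with `Ah` fragments of area > 100 and
  `Sl` fragments of solidity < 0.5 (a fragment may count in both), the
  object contributes `N = Ah + Sl − 1`.

The `N` formula is the one place the source rules are arithmetically
ambiguous: on a clean two-fragment split it yields 1, not 2. Both
readings are shipped — the default `n_mode = "pooled"` takes
`max(1, N)` as the object's total, `"additive"` takes `1 + max(0, N)` —
and golden tests pin the default. In practice the pooled reading
undercounts clean pairs by one, which is why the synthetic two-animal
recovery criterion is "within ±1" rather than exact. An object whose
footprint is entirely erased by the morphology still counts 1 by default;
`strict_empty = TRUE` reproduces the complete-removal undercount instead.

The per-image count is the highest of the three mask estimates unless it
exceeds the second highest by more than 3, in which case the runner-up is
taken — a guard against one mask shattering into fragments.

## Registration and de-duplication

Neighbouring frames are registered by correlating a grid of
high-variance patches of one frame against the other (phase-normalized
FFT correlation); the consensus displacement's supporter count is the
match count, and below 6 supporters a global phase correlation takes
over; below a significance floor registration fails loudly. A
truth-transform backend serves synthetic surveys. Transforms are stored
as 3×3 planar matrices, though both estimators recover pure
translations — which is exactly what the strip-survey generator produces;
rotating or projective flight geometries would need a richer estimator
behind the same interface.

De-duplication walks frames chronologically, mapping object centroids
through chained transforms into the first frame's coordinates. Border
objects (footprint within 10 px of a frame edge) are excluded and, if
seen on fresh ground, deferred by storing their world position; interior
objects on covered ground are excluded unless they match a deferred
entry (within 150 px ≈ 1.5 m), which credits the object once. The bare
statement of these rules can double-count or lose animals in specific
orderings, so three refinements make the bookkeeping exactly
conservative on static surveys: entries stored in a frame only become
consumable in later frames; within a frame, covered-ground crediting
runs before fresh-ground counting; and matching is a greedy
distance-ordered assignment, so an object standing exactly on its own
deferred position always claims it before a nearer-by neighbour can
steal it. With these, running the tally on ground-truth objects of 100
static synthetic surveys returns the registry count every time; the
remaining approximation is granularity — a removed cluster removes its
whole multi-animal count, as the rules operate on objects, not animals.

## What the synthetic generator does and does not emulate

Scenes are built from a base pasture color (green, dry, bare-soil or
mixed), low-frequency multiplicative blotches, per-pixel Gaussian noise
(sd 6), and anti-aliased elliptical animals with semi-axes 80–100 ×
40–50 px (mean area ≈ 12,700 px), one flank darkened up to 25% to mimic
shading, coats jittered ±5%. Calves render at a quarter of adult area
and attach to an adult of their cluster. Clusters grow by attaching
members side-by-side (perpendicular to the reference member's major
axis, roughly parallel orientation — how cattle actually bunch — which
also keeps clusters compact), each new member overlapping its
neighbour's support radius so footprints genuinely touch. Placement
keeps ellipse *support-function* separations positive between clusters
and a 16-px margin to every frame edge. Surveys render one world mosaic
and crop frames stepping `round(W·(1−overlap))` px along a strip, so
exact inter-frame translations and a world registry exist by
construction; optional per-frame jitter stresses the de-duplication's
static-scene assumption.

What this does *not* emulate: perspective and lens distortion, realistic
grass texture (our background is spectrally much cleaner than real
pasture), occlusion by trees, animals at frame corners of 2-D flight
grids (the generator flies strips), legs/heads breaking the elliptical
outline, and herd movement between frames beyond Gaussian jitter.
Passing the synthetic suites therefore demonstrates that the *rules are
implemented faithfully and behave as designed under their own
assumptions* — not that the tuned constants transfer to any particular
real deployment, where the classifier quality and color statistics
dominate.

The edge margin deserves a note: an animal whose footprint never leaves
the border bands of every frame it appears in would be deferred forever
and lost. The 16-px world margin (wider than the 10-px band) makes this
impossible in generated surveys; on real flights the analogous loss can
occur at the survey's outer boundary.

## Problem sizes and runtime choices

The test suite exercises: oracle equivalence on 1000 random histograms
and all 3792 fixed polyominoes of ≤ 8 cells; mask nestedness on 100
scenes; count recovery on 200 isolated-adult scenes (3 animals each) and
100 two-animal-cluster scenes at 512 × 512 px; and de-duplication
conservation on 100 five-frame surveys at 640 × 640 px with 20 animals.
512-px scenes are the smallest comfortably above the 50,000-active-pixel
quadrant floor (256² = 65,536) while exercising the full 3 × 3 tile
grid; survey frames stay at 640 px so the 70% overlap leaves a 192-px
step, several animal widths. Scene generation and the full single-frame
pipeline run in well under a second at these sizes.

## Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `tile_size` | 224 | px | ROI grid square |
| `cf_target` | 85 | intensity | brightness normalizer numerator |
| `min_active_pixels` | 50,000 | px | quadrant activity floor |
| `c_thresh_scale/cap` | 40 / 100 | intensity | C threshold `min(cap, scale·cf)` |
| `m_thresh` | 30 | intensity | fixed M threshold |
| `custom_thresh_scale/cap` | 120 / 150 | intensity | custom threshold |
| `hist_smooth_window` | 25 | bins | Y histogram moving average |
| `dark_threshold` | 10 | bin | Y threshold for dark quadrants |
| `peak_min_separation` | 30 | bins | peak merge distance |
| `valley_fraction` | 0.10 | — | valley amplitude cutoff |
| `min_area` | 2000 | px | object floor |
| `small_area` / `small_solidity` | 5000 / 0.7 | px / — | ragged-object filter |
| `ev_breaks` / `ev_values` | 8000, 15000 / 1, 1.25, 1.5 | px / — | elevation factor |
| `cluster_area(2)` / `cluster_solidity(2)` | 15000, 12000 / 0.65, 0.7 | px / — | cluster predicate |
| `thinning_base` | 20 | iterations | thinning depth per `ev` |
| `fragment_area` / `fragment_solidity` | 100 / 0.5 | px / — | fragment census |
| `final_gap` | 3 | animals | estimate arbitration |
| `border_band` | 10 | px | de-dup border width |
| `match_tolerance` | 150 | px | deferred-entry matching |
| `min_matches` | 6 | matches | registration fallback trigger |

All size rules scale with GSD: halve the resolution and every area
constant must shrink fourfold. The solidity rules are scale-free.

## Known limitations

* Clusters of 3+ animals census below their true count more often than
  pairs; position variation (lying animals, calves pressed against their
  mothers) is the dominant error source, and calves touching adults are
  frequently absorbed by the thinning — the generator reproduces this
  failure mode rather than hiding it.
* On uniformly warm backgrounds (dry pasture, bare soil) the C channel
  degenerates — wherever red is the maximal channel, C is identically
  zero and its mask turns all white within the ROI — so segmentation
  there rests on the Y and custom channels and on the classifier keeping
  the ROI tight.
* De-duplication assumes a static herd between overlapping exposures;
  its error grows with animal movement, and tracking is out of scope.
* The registration estimators recover translations only.
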