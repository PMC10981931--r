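---
title: "Quantifying root periderm from whole-slide fluorescence images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying root periderm from whole-slide fluorescence images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

In *Arabidopsis thaliana*, the periderm replaces the epidermis as the outer
protective tissue of the mature root. The simplest quantitative readout of
periderm development is **periderm (phellem) length**: how far down from the
hypocotyl the root is covered by phellem. Roots stained with Fluorol Yellow
(FY), a lipophilic dye for suberin, show two confusable suberized tissues in
the green fluorescence channel: the periderm, with small irregularly shaped
cells, and the endodermis, with long rectangular cells. Measuring the
periderm therefore means (i) classifying every pixel of a stitched
whole-slide micrograph (up to ~14,000 x 10,800 px, up to 6 mounted root
fragments) as background, periderm, endodermis or lateral root, and
(ii) converting the periderm-labeled extent of each root into a length in
micrometers.

`peridermR` implements this as a batch pipeline: tile the slide into
patches, segment each patch with a convolutional network, stitch the patch
masks back to slide scale, clean the mask with biologically motivated
bridging rules, and measure lengths along each root's centerline.

## Segmentation model

The segmenter is a nested-skip encoder-decoder ("UNet++ style", two pooling
levels) with residual encoder blocks, written from first principles on
single-precision matrices: 3x3 convolutions are evaluated as nine shifted
GEMMs, so memory stays bounded at slide-scale patch sizes. The loss is the
sum of per-pixel multiclass **cross-entropy on the raw logits** and
**1 - mean soft Dice** over the non-background classes present in the
target, weighted 1:1; both terms are reported separately in the training
history. Optimization is Adam; the model with the highest validation IoU is
kept (`restoreBest = TRUE`; with very small validation splits the IoU
estimate is noisy and the final-epoch weights can be kept instead).

Conventions worth knowing:

* **IoU** is averaged over the non-background classes *present in the
  target*; a class the prediction misses entirely scores 0, and classes the
  target lacks are skipped. (Averaging over classes present in either mask
  lets a handful of stray wrong-class pixels collapse the score to ~0.5 on
  otherwise perfect single-tissue patches, which makes validation-based
  model selection erratic.)
* The patch split is at **patch level** (60/20/20 by default), matching how
  the training corpus was described; patches from one slide can land in
  different splits, so a leakage note is logged.
* Defaults (`trainConfig()`): learning rate 1e-4, 40 epochs, batch 4,
  1024-px patches. These are the full-scale settings; the test suite and
  the acceptance script use a scaled-down schedule (below).

## Postprocessing: from noisy masks to one periderm run per root

Roots are the 8-connected components of the non-background mask (components
under `minRootArea`, default 5,000 px, are discarded as staining debris; at
the test scale we use 500 px). Each root gets a **centerline**: the
Zhang-Suen skeleton pruned to its single longest geodesic (edge weights 1
and sqrt(2)), ordered from the hypocotyl end (the endpoint nearest the
configured slide edge, default top). Every root pixel is then assigned to
its nearest centerline position by **multi-source Dijkstra** with the same
weights. The weighting matters: plain 8-connected BFS measures Chebyshev
distance, which makes the implied cross-sections 45-degree diagonals and
biases the periderm/endodermis transition by up to half the root width.

A centerline position is periderm if the majority of its assigned
cross-section pixels are periderm. Scanning the resulting runs from the
hypocotyl end:

* gaps of **at most 150 px** between consecutive runs are bridged (the gap's
  cross-section is relabeled periderm) — mispredicted patches inside a
  contiguous periderm should not split the measurement;
* at the **first gap larger than 150 px**, all distal periderm is relabeled
  endodermis: biologically the phellem is contiguous from the hypocotyl
  down, so isolated distal fragments are false positives;
* interior non-periderm pockets of **area < 20 px** fully enclosed by the
  periderm are closed.

Boundary conventions: a gap of exactly 150 px is bridged; a hole of exactly
20 px is kept. Both thresholds are configuration (`postprocessConfig()`).
The scan-from-the-hypocotyl rule makes the operation idempotent and leaves
at most one run, anchored at the hypocotyl.

## Length measurement

Whole-root length is the arc length of the centerline; periderm length is
the arc length of the sub-path covered by the (single) periderm run. Three
numerical corrections keep these within ~1% of ground truth:

1. **Chord resampling** (`chordStep = 9`): summing raw unit/sqrt(2) steps
   along a digital curve overestimates its length by up to 8% depending on
   orientation; summing chords between every 9th centerline point removes
   this bias (`polylineLength()` with `step = 1` still gives the raw
   definition, which the unit tests pin down on axis-aligned runs and
   staircases).
2. **Tip extension**: thinning stops a few pixels short of the region tip;
   each end is extended by the axial distance to the region boundary minus
   the local half-width (the rounded cap), clamped at zero.
3. **Sub-position boundary refinement**: where the tissue cut crosses the
   centerline obliquely, the cross-section periderm fraction ramps from 1
   to 0 over a few positions; the measured run boundary is placed at the
   area-weighted midpoint of that ramp rather than the majority flip.

Pixel lengths convert to micrometers via the slide calibration
(`scaleConfig()`, default 0.5299 px per 1.00 um, the 4x-objective export
setting); non-square pixels are rejected rather than silently handled.
Bridged gaps count toward periderm length — the run is contiguous after
bridging; the alternative (excluding bridged spans) would make the trait
depend on segmentation noise rather than root anatomy.

## Synthetic slides and what they do (not) show

The generator (`generateRoot()`, `generateSlide()`) emulates the features
that make the classification problem what it is: elongated, gently curving
ribbons (a sinusoidally perturbed vertical axis swept with the root width);
a hypocotyl-proximal zone textured with a jittered lattice of small bright
cell walls (periderm); a distal zone of long rectangular cells with rare
transverse walls (endodermis); optional short lateral-root stubs; a
green-dominant palette; Gaussian blur and sensor noise applied to the image
only. The mask and the analytic truth lengths (arc length of the generating
curve and its periderm fraction) are exact by construction, so every stage
of the pipeline can be trained and tested without microscope data, and
`corruptMask()` plants gaps and holes with known sizes for the
postprocessing truth table.

What the synthetic data does **not** model: staining variability and
understaining, out-of-focus blur that varies across a slide, touching or
crossing roots, debris, and the gradual periderm-to-endodermis transition
zone of real roots (the synthetic cut is sharp). Passing the synthetic
recovery tests therefore shows the pipeline's machinery is correct and
well-calibrated, not that the bundled fixture model generalizes to real
micrographs — on real data the network must be retrained on annotated
slides, exactly as the full-scale protocol prescribes.

## Problem sizes used by the tests and the acceptance script

Desk-scale settings, chosen once so the whole suite runs on one CPU in
minutes: roots ~620-680 px long and 14 px wide (curvature amplitude 18 px,
period 400 px; periderm cells 8 px; endodermis cells 40 x 9 px), slides of
704 x 512 px with 6 roots, 64-px patches, and a base-8-channel encoder.
Training uses 352 patches from four slides (training split 211, 60/20/20)
for 16 epochs at learning rate 1e-3 (batch 4) — the from-scratch small-encoder regime needs a larger step
size than the full-scale default of 1e-4. Held-out evaluation uses a
768 x 512 slide with six roots at periderm fractions 0.30-0.62. At these
sizes, truth-mask measurement recovers the analytic lengths to well under
2%, and the full train-segment-postprocess-measure loop recovers periderm
length with a median absolute relative error of a few percent.

## Known limitations

* Lateral-root stubs are detected as a class but not measured; their
  segmentation quality is the weakest of the three tissues (they are small
  and rare in the training corpus) and does not affect the length trait.
* Roots that touch are not split; the area floor plus the
  at-most-6-well-spaced-roots mounting convention is assumed.
* The QC stage is deliberately human-in-the-loop: the pipeline writes
  transition-zone crops and consumes a plain-text selection list; no
  automated blur scoring is attempted.
* `runStep("segment")` on full-scale slides with the default 1024-px patch
  is CPU-feasible but slow; at desk scale use smaller patches matching the
  trained model.
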