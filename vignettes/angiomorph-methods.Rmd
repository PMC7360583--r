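---
title: "Morphometry of in vitro angiogenesis assays: models and methods"
author: "angiomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of in vitro angiogenesis assays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Two standard in vitro models of angiogenesis are quantified from
phase-contrast micrographs:

* **Endothelial tube formation assay (ETFA).** Endothelial cells seeded
  on a gel align into a two-dimensional pseudo-capillary network with
  closed loops ("meshes"). One image per field is analyzed.
* **Fibrin bead assay (FBA).** Endothelial cells coat ~200 µm
  microcarrier beads embedded in a fibrin gel and sprout tree-like
  pseudo-capillaries from the bead surface. Each bead is a small
  independent experiment, which is the statistical strength of the assay.

Phase contrast makes both assays non-destructive and suitable for
kinetics, at the cost of difficult images: thin objects are flanked by
paired bright/dark halo bands, the culture-medium meniscus imposes a
smooth multiplicative shading field, and beads appear as dark disks with
a bright envelope.

`angiomorph` segments these images, reduces the network to a one-pixel
skeleton, converts the skeleton into a vectorial object model — circles
(bead envelopes), junctions, extremities, branches, segments, anchorage
junctions, isolated elements and meshes — and measures the standard
morphometric parameters: mean mesh size (MMS), total mesh area (TMA),
total segment length (TSL), junction count (JN), total length of
branches plus segments (TL), and, per bead, the anchorage junction count
(AJN/S) together with the per-sphere versions TSL/S, TL/S, JN/S. All
lengths and areas are in pixels unless a pixels-per-micron calibration is
applied at output time.

## Bead detection

Bead detection runs in three passes:

1. **Coarse mask.** The image is divided by a Gaussian-smoothed copy of
   itself (the *pseudo flat field*; the scale `sigma` is the average bead
   diameter), log-transformed, and passed through a local variance filter
   whose radius matches the apparent thickness of the bead envelope. The
   result is thresholded with the IsoData rule and closed, hole-filled and
   opened into a solid disk mask per bead.
2. **Interior mask.** The difference of the coarse mask and the
   normalized edge response is bright inside the beads and dark on their
   envelopes; after a grey-level maximum filter (radius 2) and a
   Minimum-method threshold it yields one connected component per bead
   interior — this is what separates touching beads without a watershed.
   The edge response is normalized by its 0.75 quantile *within the
   coarse mask* rather than by the global maximum: the global maximum
   depends on the strongest edge anywhere in the field and was observed
   to move the threshold valley (hence the apparent bead radius) by
   several pixels between otherwise identical fields.
3. **Circle fit.** Each interior component's boundary is fitted with an
   algebraic least-squares (Kåsa) circle; the radius is enlarged by
   `edge_thickness` to reach the middle of the bead envelope. Components
   outside the `[min_diameter, max_diameter]` window or with an RMS
   residual above a quarter of the radius (dirt, crescents) are dropped.

On rendered reference scenes the interior boundary sits at a constant
6.1 ± 0.15 px below the envelope mid-line, so `edge_thickness` should be
the apparent envelope thickness including optical blur (6 px for the
bundled renderer's 4 px envelope); centers are recovered to ~0.1 px and
radii to ~1%.

A field whose IsoData threshold, in the squared-relative-contrast units
produced by flat-field correction plus log transform, falls below 0.02
(~14% rms local contrast) contains no bead envelope; the mask is then
empty rather than a random partition of the noise.

## Network segmentation and skeletonization

The filament mask is produced by flat-field correction, an FFT band-pass
(difference of two frequency-domain Gaussians with sigma 0.4 times the
structure size, mirror-padded; `v1 = 1.5` px removes pixel noise and
`v2 = sigma` removes shadows at the bead/meniscus scale), a variance
filter of radius 2 that merges the halo's paired bright/dark bands into
one ridge, subtraction of the histogram modal value, a Mean threshold,
one closing and one dilation. The same no-structure guard applies: if the
strongest enhanced response is within a factor 20 of the mean threshold,
the field is noise and the mask is empty. The outermost 8 px of the
mask are always cleared (the Fourier filters see a mirrored image beyond
the frame, and under strong shading the crease responds like an edge),
and a hysteresis step keeps a raw-threshold component only if it
contains at least one strong pixel (5 times the threshold): flat-field
division amplifies noise wherever illumination was low, and such
barely-above-threshold patches are noise (real filaments run an order of
magnitude above the threshold). The hysteresis runs before closing and
dilation, which would otherwise bridge noise patches onto the network.

The mask is thinned with Zhang–Suen parallel thinning. Two cleanups make
the skeleton usable for object extraction:

* **Redundant-pixel removal.** Parallel thinning leaves staircase corner
  pixels; under 8-neighbour counting each reads as a false bifurcation.
  Any simple pixel (Yokoi connectivity number 1) with three or more
  neighbours, and any corner pixel whose two neighbours are mutually
  adjacent, is deleted. True bifurcations have connectivity ≥ 2 and are
  untouched. Without this step a rendered scene shows 50–100 false node
  pixels; with it, exactly the true bifurcations remain.
* **Twig pruning.** Ragged mask boundaries leave terminal spurs. Twigs
  that reach a bifurcation within `twig_length` steps (default 10) are
  walked in from every endpoint and deleted.

Mask holes smaller than 64 px² are filled before thinning: they are halo
pinholes, two orders of magnitude below any real mesh, and would
otherwise appear as spurious loops.

In FBA mode the detected bead disks are filled into the mask so sprouts
join their bead; floating components that touch no circle are removed;
and finally all skeleton pixels deeper than `clear_inset` (4 px) inside a
circle are erased, cutting each sprout at the bead boundary. Thinning can
route the last stretch of a sprout through the bead interior, so after
clearing an endpoint may stop short of the ring; because every surviving
component is known to have been bead-connected, an endpoint within 16 px
of a ring whose straight radial corridor to the ring lies entirely inside
the mask is reattached with a one-pixel line.

## The vectorial model

Skeleton pixels are classified by their 8-neighbour count: ≥ 3 node,
2 path, 1 extremity. Each node is replaced by a 7-px-diameter dot;
overlapping dots (centre distance ≤ 6) form one junction blob, which
absorbs the pixel-level ambiguity of a bifurcation. Chains of path pixels
between terminals become edges: junction–extremity = branch,
junction–junction = segment, extremity–extremity = isolated element;
lengths accumulate 1 per axial and √2 per diagonal step. A closed chain
with no node is emitted as a self-loop segment on a synthetic junction.

Model cleanup:

* **Fusion.** Junctions joined by a segment shorter than 20 px whose
  centroids are less than 20 px apart are merged (a tube shorter than two
  aligned cells is not a tube). Self-loops below the fusion scale — both
  sides of a collapsed pinhole — are deleted under the same rationale.
* **Pruning.** Branches strictly shorter than `prune_min_branch` are
  removed iteratively; a junction left with degree 2 dissolves and its
  two edges concatenate (the gap across the blob is bridged with the
  Euclidean step), degree 1 becomes an extremity, degree 0 is dropped.
* **Ordering.** Pruning runs before fusion, and the pair is iterated to a
  joint fixed point. The reverse order lets skeleton spurs chop real
  tubes into sub-20 px segments that fusion then wrongly collapses into
  giant junctions. Both operations are idempotent at their fixed points.
* **Anchorage (FBA).** Edges running along a circle (≥ 80% of pixels
  within 5 px of a ring) are residual envelope arcs and are deleted.
  Junctions whose blob reaches a ring, and edge endpoints on a ring,
  become anchorage junctions — the sprout initiation marks, counted
  separately from ordinary junctions. Anchored branches shorter than the
  fusion scale are envelope residues, not sprouts, and are removed; a
  final pruning pass then tidies the result. Anchorage junctions are
  never dissolved.
* **Isolated elements.** Elements bounded by two extremities and shorter
  than `min_object_size` (10 px, the size of a single cell) are removed —
  strict inequality, so a 10 px element is kept.
* **Meshes (ETFA).** Bounded faces of the planar skeleton: 4-connected
  components of the complement that do not touch the image border. Areas
  are measured on the complement of the 1-px skeleton so they do not
  depend on how fat the segmentation mask was. The mesh count equals the
  cyclomatic number E − V + C of the vectorial graph; every cleanup
  operation above preserves that identity.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `sigma` | image-scale | average bead diameter (px); flat-field scale and band-pass `v2` |
| `edge_radius` | 3–4 | apparent bead envelope thickness (px) |
| `edge_thickness` | `edge_radius` | circle enlargement; use envelope + blur width |
| `fft_v1` / `fft_v2` | 1.5 / `sigma` | band-pass structure-size window (px) |
| `tree_variance_radius` | 2 | filament variance radius (px) |
| `node_dot_diameter` | 7 | junction dot diameter (px) |
| `junction_fusion_distance` | 20 | two-cell scale (px) |
| `min_object_size` | 10 | single-cell scale for isolated elements (px) |
| `prune_min_branch` | 10 | artifact branch scale (px) |
| `twig_length` | 10 | skeleton spur scale (px) |
| `clear_inset` | 4 | interior margin kept inside the ring (px) |

## The synthetic scene renderer

Because no reference micrographs are distributed with the assays, the
package ships a renderer that draws scenes with exact vectorial ground
truth: beads as dark disks (intensity 0.28) with a 4 px bright envelope
(0.90) on a 0.55 background; filaments as a difference-of-Gaussians
ridge (core width 1.4 px, flank weight 0.45) reproducing the
phase-contrast halo; a multiplicative linear shading ramp (default
±25%); optical blur (Gaussian, sigma 0.7 px); and additive Gaussian
noise (sd 0.02). FBA scenes draw 1–4 beads of radius 34–44 px with 2–4
sprouts each (trunks 40–55 px, arms 25–45 px, bifurcation probability
0.5); ETFA scenes draw jittered rectangular tilings of 1–12 cells
(55–70 px), with prime cell counts reached by removing interior walls of
a larger grid, plus optional dangling branches and floating fragments.

Scene generation enforces recoverability: beads at least one radius
apart, sprout centrelines of different sprouts at least 20 px apart
(tubes closer than the width of their segmented ribbons merge optically
and are not separable by any pipeline), and all geometry clear of the
image border. All randomness flows from one explicit seed; a spec
renders bit-identically every time.

What the renderer does *not* emulate: cell-body texture, the fibroblast
feeder layer, out-of-focus depth variation, bead clusters in contact,
and curved tubes. Passing the recovery suite therefore demonstrates that
the object model and its cleanup rules are implemented correctly under
realistic optics, noise and shading — not that segmentation thresholds
are optimal for any particular microscope.

Analysis of rendered scenes in the package's own tests uses
`prune_min_branch = twig_length = 12`: the renderer's shortest true
edges are 25 px, while noise spurs up to ~12 px were observed, so the
threshold sits between the two scales. Likewise `min_object_size = 16`
for rendered scenes: halo blobs broaden every skeleton fragment by about
6-10 px, so the single-cell cutoff must sit above that floor (sub-cell
debris measures ~11-14 px, real fragments >= 23 px). On 50 held-out scenes this
configuration recovers all object counts exactly on 96%; the residual
failures lose one bifurcation where two arms diverge at a narrow angle
and their ribbons overlap past the prune scale.

## Numerical choices and degenerate inputs

* Epsilon floors for division and log: 10⁻⁶ of the image maximum.
* Histograms for modal subtraction and the Minimum/IsoData thresholds use
  256 bins over the intensity range (the 8-bit convention); thresholded
  pixels are strictly above the threshold, ties to background.
* The variance filter uses a discrete circular neighbourhood (centre
  distance ≤ r; 13 pixels at r = 2) with edge replication.
* IsoData iterates on the continuous intensities, making it exactly
  affine-invariant; Minimum smooths the 256-bin histogram by a 3-bin
  moving average until exactly two maxima remain and errors out
  ("histogram not bimodal") after 10 000 iterations.
* Junction fusion measures centroid distance; candidates are processed
  shortest-segment-first with id tie-breaks, so results are
  deterministic.
* Degenerate inputs: an all-zero image is an error; a blank noise field
  yields empty masks (contrast guards above); an empty skeleton yields an
  empty graph; a bead with no sprouts yields a record of zeros and is
  kept, since each bead is an independent replicate.

## Problem sizes

The validation batches used by the tests and the acceptance script are
50 FBA scenes of 512² px and 50 ETFA scenes of 448² px, sizes at which a
full analysis takes a few seconds per image; they match the assays'
4x-objective fields scaled to one bead cluster or tiling patch per
image.

## Known limitations

* Trees touching two beads are assigned to the nearest bead and flagged;
  the assays' plating density makes this rare, but dense cultures would
  need a splitting rule.
* Tube width, tortuosity and hierarchical (Strahler) ordering are not
  measured.
* The FBA analysis assumes beads are round; deformed or cut-off beads
  fail the residual filter and are dropped rather than approximated.
* Mesh areas are planar; overlapping tubes in thick gels are projected.
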