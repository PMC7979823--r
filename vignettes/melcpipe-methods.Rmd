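---
title: "Methods: from cyclic immunofluorescence stacks to spatially resolved cell phenotypes"
author: "melcpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cyclic immunofluorescence stacks to spatially resolved cell phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement model

Multi-epitope ligand cartography (MELC) images one tissue section through
repeated stain–image–bleach cycles: each cycle couples up to three
fluorescence-labeled antibodies (PE, FITC and a DAPI-like channel), acquires
a z-stack per channel, photobleaches, and acquires a post-bleach z-stack
under identical conditions. The stage re-positions between cycles, so a
phase-contrast reference taken at the start of the run anchors all cycles in
one coordinate frame. `melcpipe` models a cycle-`i` image of marker `m` in
channel `ch` as

    fluo_i   = illum * shift_i( blur_z(S_m + R_ch) + af ) + noise
    bleach_i = illum * shift_i( blur_z(rho * (S_m + R_ch)) + af ) + noise

where `S_m` is the marker's true signal scene, `R_ch` the residual signal
carried over in that channel (updated as `R' = rho * (S + R)` with `rho` the
bleach-residual fraction), `af` flat tissue autofluorescence, `illum` a
camera-fixed multiplicative vignette and `shift_i` the integer stage
displacement. Two consequences drive the pre-processing design:

* subtracting the **previous same-channel bleach** from a registered stain
  image removes both autofluorescence and carry-over exactly, leaving
  `illum * S_m` (the first cycle of a channel uses the pre-run blank);
* the **bleach image of the same cycle** is a stain-free view of
  `illum * af`, so the illumination surface can be estimated from its
  per-block minimum intensities.

# Pre-processing chain

The fixed stage order is register → bleach-subtract → illumination-correct →
extended-depth-of-field project → rolling-ball normalize. Subtraction must
happen between like-registered, like-illuminated images, which pins the
first three stages; projection before normalization keeps the rolling ball
on a single 2D image per marker.

**Registration.** Integer-pixel translation maximizing the FFT
cross-correlation of mean-subtracted images within `maxShiftPx`; ties break
to the smallest `|dr|+|dc|`, then lexicographically. The per-cycle
phase-contrast image is the moving image when available (as on the
instrument); otherwise the summed central stain planes stand in. The
autofocus hardware corrects displacement before acquisition, so sub-pixel
refinement is deliberately out of scope. Because the illumination field is
fixed to the camera, not the sample, the field is estimated in the camera
frame and then translated into the registered frame (with neutral padding
that the edge crop removes).

**Illumination.** The bleach mean-projection is split into
`splineGrid x splineGrid` blocks (default 16); per block a minimum-intensity
statistic is taken together with its pixel position, and a tensor-product
cubic regression spline (`mgcv::gam`, REML) is evaluated at every pixel,
normalized to mean 1, and clipped below at `illuminationFloor` (0.05). Two
numerical choices matter. First, the sample point is the *location of the
minimum*, not the block center: a smooth vignette drops appreciably across a
32 px block, and pairing the minimum value with the center biases the
surface by more than the 2% recovery the package guarantees on noiseless
fields. Second, the per-block statistic is a small quantile (default 0.1)
rather than the strict minimum: the minimum of a thousand noisy pixels sits
~3 standard deviations below the background level, which after mean
normalization *inflates* the estimated vignette amplitude; a low quantile
keeps the bias at a constant offset that normalization mostly cancels. With
`prob = 0` the strict-minimum behavior is available.

**Extended depth of field.** Per pixel, the plane with the largest local
variance in an `edfWindowPx` window (default 9) wins; the selection-index
map is median-filtered with the same window, and ties go to the lowest z.
Variance-based selection is the standard focus measure when no specific
projection algorithm is prescribed.

**Normalization.** An ImageJ-style rolling-ball background (grayscale disc
opening on a 4x-downscaled image, radius 50 px) is subtracted, the edges are
cropped by the largest observed shift (removing the zero-filled registration
bands), and intensities are stretched linearly to the 16-bit range. Cell
tables are computed on the 0–1 rescale of these images.

# Pixel classification and segmentation

Only two images enter the classifier: the DAPI-like nuclear image and the
*sum-membranes* composite (pixel-wise sum of all membrane-localized markers,
rescaled by its maximum). Features are an interactive-classification
default: per image and per scale (0.7, 1.0, 1.6, 3.5, 5.0 px), the Gaussian
smooth, gradient magnitude, Laplacian of Gaussian and both structure-tensor
eigenvalues — 50 features. A 100-tree random forest is trained on
class-balanced labeled pixels (~6% of one image suffices; for synthetic runs
labels are sampled from the eroded ground-truth class regions) and applied
to further runs without retraining. Probabilities are renormalized to sum to
one pixel-wise.

Nuclei are primary objects: threshold the nuclei map at 0.5 (the
probability scale is calibrated by construction, so Otsu adds nothing),
split touching nuclei by a watershed on the distance transform, filter to
[40, 5000] px. Cells are secondary objects grown from nucleus seeds against
the membrane probability in two stages of constrained propagation
(`EBImage::propagate`, the CellProfiler propagation algorithm): first
through sub-threshold membrane probability within a hard Euclidean cap of
12 px (~3.9 um) beyond the nucleus boundary, then annexing the contiguous
above-threshold membrane band reachable from the first stage. Growth
therefore stops at the far edge of a membrane ridge and never descends into
background; with no membrane evidence it degenerates to an exact
distance-capped dilation. Cell labels equal their seed labels, so the
nucleus–cell bijection is structural, not statistical.

# Quantification, gating, niches and compartments

Per cell, nuclear markers are averaged over the nucleus mask and
membrane/structure markers over the cell mask; centroids are 0-based so
micrometer coordinates are `centroid_px * 0.325`. Default thresholds are
Otsu on each marker's per-cell MFI distribution over a 256-bin histogram
(clipped to [0.05, 0.95]); when the between-class variance plateaus across
an empty gap between populations the *middle* split is taken, which places
the threshold mid-gap rather than hugging the negative population. Manual
thresholds override per marker. Gating rules are YAML-configurable
conjunctions of required positives/negatives plus disjunctive `any_of`
clauses, evaluated in priority order with ILC first (its lineage-exclusion
gate makes it independent of later rules) and fall-through to "others";
positivity is threshold-inclusive. The shipped tonsil rule set encodes
ILC = Lin⁻CD45⁺CD127⁺, B = CD45⁺CD19⁺, T helper = CD45⁺CD3⁺CD4⁺, cytotoxic
T = CD45⁺CD3⁺CD8⁺, plasma = CD138⁺, myeloid (CD11c/CD14/CD56⁻CD16⁺/CD141
disjunction) and endothelial = CD31⁺; markers not stained in a run are
trimmed from negative lists and unsatisfiable clauses at load time.

Niches are the 10 um Euclidean dilation of a seed cell's mask
(31 px at 0.325 um/px), computed by exact distance transform so the region
matches a brute-force pixel-distance oracle identically. Membership defaults
to centroid-in-region (inclusive boundary); any-overlap is available.
Composition excludes the seed; enrichment compares pooled niche frequencies
with whole-tissue frequencies excluding the seed cells. Structure proximity
is the fraction of seed-type cells whose mask lies within 10 um of a
structure mask (binarized structure-marker image or ECM probability).
Compartments are the arg-max of Gaussian-smoothed (20 um) sums of binarized
defining markers above a 0.1 floor, with a 10 um `follicle_border` band
carved around the follicle; cells inherit the compartment of their centroid,
and "unassigned" cells are excluded from distribution denominators.

# Phenotype clustering

MFIs are transformed as `asinh(x / 0.2)` (the flow-cytometry cofactor
convention; the alternative reading `asinh(0.2 x)` is monotone-equivalent
and only rescales dynamic range), optionally dropping cells whose maximum
MFI is below 0.1 (the colon-mode filter). PCA (centered, unscaled — arcsinh
already compresses scale) reduces to 52 components for tonsil panels and 48
for colon, capped at the number of markers when the panel is smaller (the
12-marker synthetic panel uses all 12). t-SNE runs at perplexity 30 for
1000 iterations with a fixed seed.

Cluster selection on the map is deliberately *not* silhouette-maximizing
k-means, although that method remains available: on mixtures containing
rare populations, mean-silhouette model selection systematically merges
small distinct blobs into their neighbors (measured purity 0.86 against
0.99 for the correct partition), because a handful of misplaced points
barely dents the average. The default is a deterministic density cut:
single-linkage components at five times the 90th percentile of
nearest-neighbor distances, which separates every density-connected blob on
the map, keeps duplicated-point clouds as one cluster, and requires no
seed. Cluster annotation uses the cluster-by-marker mean-MFI matrix with
each marker rescaled to [0,1] across clusters (constant markers map to 0),
and cluster-vs-gate agreement reports the fraction of a focus cluster
carrying a focus gated type plus the full confusion table.

One resolution limit deserves emphasis: a population much smaller than the
perplexity cannot form its own t-SNE blob. At the default synthetic scale
(150 cells, ILC floor of two cells) the two ILCs embed inside their nearest
neighbors, so cluster-level ILC isolation is assessed on a mixture that
keeps the *absolute* ILC count near the regime where cluster-based ILC
identification operates in practice (26 of 400 cells) rather than the
fraction; the imaging-scale scenes assert gating recovery and clustering
purity instead.

# The synthetic generator as test oracle

`tonsilSceneSpec()` emulates a miniature run: 512 x 512 px at 0.325 um/px,
150 non-overlapping disk cells (nucleus radius 3 um, cell radius 5 um,
membrane shell between them), eight cell types at tonsil-like frequencies
with ILCs at 0.5% floored at two cells, a 12-marker panel over 7 cycles,
vessel- and fiber-like structure curves, a radial vignette of amplitude
0.3, autofluorescence 0.08, bleach residual 0.15, per-cycle integer stage
shifts up to 8 px, defocus blur of 1.2 px per z plane and configurable
Gaussian noise. Stacks carry 5 z-planes (z half-range 2): a miniature
stand-in for the instrument's +-7 that exercises the projection logic at a
fraction of the memory. Every corruption has a switch, so degenerate
no-corruption runs give exact end-to-end oracles (cell counts, per-cell
MFIs, shifts, the illumination field, class images, structure masks).

What the generator does *not* emulate — irregular cell morphology,
spatially varying autofluorescence texture, chromatic shifts, antibody
off-target binding, 3D tissue thickness — bounds what green tests mean:
they certify the computational contracts of each stage under the stated
acquisition model, not performance on real tonsil sections, whose
reproduction requires the deposited image sets plus manual classifier
training and manual thresholds.

Problem sizes used by the test-suite and the acceptance script: 160 px /
8-cell scenes for registration sweeps, 256 px / 25-cell scenes for module
checks, the full 512 px / 150-cell default for segmentation and the
end-to-end run, and 400-cell profile mixtures for clustering — all
regenerated from seeds at run time.

# Known limitations

* Integer-pixel registration only; sub-pixel stage drift aliases into the
  membrane shell at the ~0.3 px level and is not modeled.
* The illumination estimate assumes the bleach image is cell-poor at the
  block scale; dense tissue with >50% bright coverage per block would bias
  the field upward.
* The ECM class doubles as "background" (all pixels that are neither
  nuclei nor membrane), as in the original three-class design; an explicit
  fourth background class would be needed for sparse tissue.
* Compartment segmentation is a reproducible stand-in for a step the
  original workflow performed by eye; its smoothing scale (20 um) and score
  floor (0.1) are design defaults, not fitted values.
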