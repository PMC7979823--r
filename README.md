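# melcpipe

Single-cell analysis of multiplexed cyclic immunofluorescence (MELC)
imaging, for labs that profile dozens of protein markers on one tissue
section through repeated stain–image–bleach cycles and need to turn the raw
per-cycle z-stacks into registered marker images, segmented single cells,
gated immune cell types — including rare populations such as
Lin⁻CD45⁺CD127⁺ innate lymphoid cells (ILCs) — and spatial statistics of
their tissue microenvironments.

## What the pipeline computes

Starting from one phase-contrast reference plus, per cycle, a fluorescence
z-stack and a post-bleach z-stack per channel:

1. **Registration** — integer-pixel alignment of every cycle to the
   reference by FFT cross-correlation (tie-break: smallest |dr|+|dc|, then
   lexicographic).
2. **Background subtraction** — `max(fluo_i − bleach_prev, 0)` with the
   previous same-channel bleach (or the pre-run blank, or a secondary-only
   image for indirect stains), removing autofluorescence and cycle
   carry-over.
3. **Illumination correction** — a tensor-product cubic spline through
   per-block minimum intensities of the same cycle's bleach image,
   normalized to mean 1 and divided out.
4. **Extended depth of field** — per-pixel selection of the
   maximum-local-variance plane, median-filtered selection map.
5. **Normalization** — ImageJ-style rolling-ball background removal, edge
   crop by the largest observed shift, linear stretch to the 16-bit range.
6. **Pixel classification** — a 100-tree random forest on Gaussian /
   gradient / Laplacian / structure-tensor features of the DAPI image and
   the sum-membranes composite, yielding nuclei / membrane / ECM
   probability maps that sum to one per pixel; trained once on ~6% of one
   image, reused across runs.
7. **Segmentation** — nuclei as primary objects (0.5 threshold +
   distance-transform watershed, size filter), cells as secondary objects
   grown from nucleus seeds against the membrane map with a ridge-stop rule
   and a 12 px expansion cap; exactly one cell per nucleus.
8. **Quantification and gating** — per-cell mean fluorescence intensity
   (MFI, 0–1 scale; nuclear markers over the nucleus mask), Otsu default
   thresholds with manual overrides, and priority-ordered YAML gating rules
   (ILC = Lin⁻CD45⁺CD127⁺, B = CD45⁺CD19⁺, T helper = CD45⁺CD3⁺CD4⁺,
   cytotoxic T = CD45⁺CD3⁺CD8⁺, plasma = CD138⁺, myeloid, endothelial =
   CD31⁺, fall-through "others").
9. **Spatial analysis** — 10 µm niches around seed cells (exact Euclidean
   dilation, 31 px at 0.325 µm/px) with composition and enrichment versus
   the whole tissue; distance-to-structure fractions (vessels, fibers);
   smoothed-marker tissue compartments (follicle / follicle border /
   T zone / septum) and per-compartment distributions.
10. **Phenotype clustering** — `asinh(MFI / 0.2)`, PCA (52 components for
    tonsil panels, 48 for colon, capped at the panel size), t-SNE
    (perplexity 30, 1000 iterations, seeded), density-based cluster
    selection on the map, mean-relative-expression heat-maps, and
    cluster-vs-gate agreement with full confusion tables.

A synthetic MELC generator (`tonsilSceneSpec()`, `simulateRun()`) renders
miniature runs — disk cells with nuclear/membrane footprints, structure
curves, vignetting, autofluorescence, bleach residual, stage shifts,
defocus and noise — with complete ground truth, so every stage above has an
exact oracle.

## Worked example

```r
library(melcpipe)

sim <- simulateRun(tonsilSceneSpec(seed = 42, noiseSd = 0.02))
labs <- labelsFromClassImage(sim$truth@classImage, fraction = 0.06, seed = 1)
res <- runPipeline(sim$run, labels = labs, seed = 1)

res$counts
#>          type count  frequency
#> 1           B    44 0.29333333
#> 2 endothelial    12 0.08000000
#> 3         ILC     2 0.01333333
#> 4     myeloid    18 0.12000000
#> 5      others    19 0.12666667
#> 6      plasma     7 0.04666667
#> 7 T_cytotoxic    15 0.10000000
#> 8    T_helper    33 0.22000000

all(res$shifts == sim$truth@shifts)   # every stage shift recovered exactly
#> [1] TRUE

res$enrichment[, c("type", "whole_tissue_freq", "niche_freq")]
#>          type whole_tissue_freq niche_freq
#> 1           B            0.2973        0.4
#> 6      plasma            0.0473        0.2   # plasma over-represented near ILCs
#> ...

res$structureProximity   # fraction of ILCs within 10 um of each structure
#>         SMA Fibronectin
#>         0.5         0.5
```

The 150 simulated cells are recovered one-for-one and gated back to their
ground-truth types; the two ILCs seed 10 µm niches whose composition is
tallied against the whole tissue, and `res$clustering` carries the t-SNE
embedding, cluster ids and the cluster × marker heat-map.

A thin command-line wrapper over the same functions ships in
`inst/scripts/melcpipe-cli.R` (verbs: `simulate`, `preprocess`,
`classify-pixels`, `segment`, `quantify`, `gate`, `niche`, `compartments`,
`cluster`, `run-all`).

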