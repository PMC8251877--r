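# codexr

An R toolkit for processing and analysing **CODEX** (CO-Detection by
indEXing) multiplexed tissue imaging data. CODEX reveals dozens of
DNA-barcoded antibodies over repeated imaging cycles: in each cycle up to
three dye-bearing reporter oligonucleotides are hybridised to their
antibody-bound barcodes, the tissue is imaged in three reporter channels
plus a nuclear (Hoechst) channel, and the reporters are stripped before the
next cycle. Turning the resulting stack of multicycle, multichannel, tiled
images into single-cell biology requires a chain of computational steps,
all of which this package provides:

* **Preprocessing** — inter-cycle drift compensation (windowed phase
  cross-correlation with subpixel refinement on the nuclear channel),
  tile stitching with optional phase-correlation placement refinement,
  blank-cycle background subtraction, optional Richardson–Lucy
  deconvolution, and concatenation of all cycles into one registered
  multichannel mosaic.
* **Segmentation** — nuclear-seeded watershed single-cell segmentation,
  optionally shaped by a membrane marker (e.g. CD45), with per-cell
  quantification into a cell table (CSV and FCS 3.1 export).
* **Clustering** — X-shift-style unsupervised clustering: exact kNN density
  estimation, mode seeking, and merging of over-fragmented density basins,
  over arcsinh-transformed, z-scored marker intensities.
* **Barcode QC** — top-3 rank images, per-barcode positive-cell gating,
  pairwise intersection-over-union (IoU) matrices for cross-reactivity
  screening, and on/off cycle-reproducibility statistics for the
  annealing/stripping chemistry.
* **Spatial analysis** — cell-type composition inside follicle masks and in
  a surrounding ring scaled from the follicle's cell diameter, and Spearman
  correlation of cell-type densities over randomly sampled image windows.
* **Phantom generator** — a seeded synthetic data generator producing
  multicycle, tiled images of disk-shaped cells with complete ground truth
  (positions, types, expression, drift, background, cross-talk), so that
  every stage can be validated quantitatively without microscope data.

## Core methods in brief

*Registration.* Stage drift between cycles is modelled as a pure
translation. For cycle *c* against the reference cycle, the shift
maximising the cross-correlation of the nuclear images is located on the
integer grid via the FFT cross-power spectrum and refined to 1/20 px by
evaluating the correlation surface with a matrix-multiply DFT around the
peak.

*Watershed segmentation.* The nuclear plane is Gaussian-smoothed,
thresholded (Otsu), and transformed into a Euclidean distance map `D`.
Seeds are local maxima of `D` separated by a minimum seed distance;
basins grow by priority flooding of the elevation map
`−D + w · |∇membrane|` inside the foreground (weight `w = 0.3` by
default), followed by an area filter.

*kNN density mode seeking.* Each cell's density is `1 / mean(distance to K
nearest neighbours)` (exact, all-pairs). Cells link to the densest of
their K neighbours that is denser than themselves; link trees rooted at
density modes form basins, and basins whose centroids lie within 3.5
pooled within-basin standard deviations are merged. The number of clusters
is discovered, not specified.

*Barcode IoU.* Cells positive for barcode *i* form the set `A_i` (2-component
Gaussian-mixture gate on `log1p` intensity by default); cross-reactivity of
a pair is `IoU(i, j) = |A_i ∩ A_j| / |A_i ∪ A_j|`, near zero for orthogonal
barcodes.

*Density correlation.* Cell-type counts are taken in `100 × 100` px windows
sampled uniformly inside a domain; Spearman's rank correlation over windows
quantifies co-localisation (positive) or spatial exclusion (negative) of
cell-type pairs.

## Worked example

A complete round trip on a synthetic phantom — generate a 2 × 2-tile,
3-cycle experiment with planted drift, register, stitch, background-subtract,
segment, quantify, and cluster:

```r
library(codexr)

cfg <- phantom_config(
  tile_size = 200, grid_rows = 2, grid_cols = 2, n_cycles = 3,
  cell_types = data.frame(type = c("T", "B"),
                          CD3  = c(100, 5),
                          CD19 = c(5, 100),
                          CD45 = c(80, 80)),
  n_cells = 150, drift = rbind(c(0, 0), c(3.5, -2.25), c(-1, 4)),
  membrane_markers = "CD45", seed = 7)
ph <- generate_tissue_phantom(cfg, blank_cycles = 3)

pr <- process_stack(ph$stack)        # register + stitch + subtract + concat
subset(pr$drift, tile == 1)
#>   cycle tile   dy    dx     score
#> 1     1    1  0.0  0.00 1.0000000
#> 5     2    1  3.5 -2.25 0.9658000
#> 9     3    1 -1.0  4.00 0.9807752
```

The planted drifts (3.5, −2.25) and (−1, 4) are recovered exactly to the
0.05-px resolution of the estimator. Segmentation and quantification:

```r
labels <- segment_cells(pr$mosaic[, , "nuclear"], pr$mosaic[, , "CD45"])
attr(labels, "n_cells")
#> [1] 150
cells <- quantify_cells(labels, pr$mosaic)
head(cells[, c("id", "y_px", "x_px", "area", "CD3", "CD19")], 3)
#>   id   y_px   x_px area   CD3  CD19
#> 1  1 228.18 156.90  108  4.94 98.44
#> 2  2 235.00  47.24  116 98.66  5.24
#> 3  3  74.77 310.29   97 97.98  5.22
```

All 150 planted cells are found, and the background-subtracted per-cell
means sit close to the planted expression (100 / 5). Clustering recovers
the two planted populations:

```r
feats <- prepare_features(cells, markers = c("CD3", "CD19"))
cl <- xshift_cluster(feats, K = 25)
cells$cluster <- cl$labels
profile_clusters(cl, cells, markers = c("CD3", "CD19"))[, 1:4]
#>   cluster size       CD3      CD19
#> 1       1   76  4.958906 98.347391
#> 2       2   74 98.344894  5.002976

match_to_truth(cells, ph$truth$cells, max_dist = 5)$f1
#> [1] 1
```

The same chain is available non-interactively: `run_pipeline(run_config(...))`
orchestrates phantom → process → segment → cluster from one configuration
with a machine-readable run report, and `inst/cli/codex.R` exposes each
stage as a shell subcommand (`phantom`, `process`, `segment`, `cluster`,
`qc-barcodes`, `follicle`, `density`, `run`).

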