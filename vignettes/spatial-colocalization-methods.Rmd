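---
title: "Methods: colocalization fields, transition ordering and synthetic skin tissue"
author: "skinspatial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalization fields, transition ordering and synthetic skin tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinspatial)
```

# Scope

`skinspatial` analyses imaging-based spatial transcriptomics (seqFISH-style)
sections of human skin: per-cell transcript counts with pixel-unit centroids,
one row per segmented cell. It provides four analyses that together
characterize how CD14^+^ myeloid cells behave in inflamed skin:

1. a **directional colocalization metric** between cell types, built from
   Gaussian kernel density fields;
2. **diffusion-map ordering** of the CD14^+^ LYVE1 → MMP9 state transition,
   with equal-size binning for heatmaps;
3. **neighborhood expression** statistics (local expression within a radius,
   kernel-smoothed expression surfaces with quantile-anchored contour levels,
   rolling means along a continuous score);
4. **distance-to-structure profiling** (minimum distance to basal
   keratinocytes as a proxy for the epidermis, to CD4/CD8 T cells as a proxy
   for immune aggregates; depth distributions).

A seeded synthetic-tissue generator with complete ground truth exercises the
whole pipeline, so every guarantee in the test suite is computed, not assumed.

# Coordinate conventions and units

All geometry is computed in pixels. The y axis increases *downward* from the
keratinized outer surface into the dermis, with the origin at the top-left of
the section; depth is therefore `y_px`. Physical units enter only at
reporting time through a per-dataset pixel scale (`um_per_px`). The default
scale is 0.1 µm/px, consistent with a 15 px segmentation expansion spanning
roughly 1.5 µm; an alternative implied scale of 0.103 µm/px (400 px ≈ 41.2
µm) is equally expressible, and the two conversions disagree by 3%, so the
scale is always explicit and overridable. Instruments do not report the pixel
origin or axis orientation in their tabular outputs, so the depth convention
is an assumption the user must check against their data.

# The directional colocalization metric

Each cell of a *reference* type R contributes an unnormalized Gaussian kernel
centred at its centroid. The colocalization score of a query point $p$ is

$$ s_R(p) \;=\; \sum_{r \in R,\; \lVert p - r\rVert \le \rho}
   \exp\!\left( -\frac{\lVert p - r \rVert^2}{2\sigma^2} \right), $$

with bandwidth $\sigma$ = 400 px by default and a hard truncation radius
$\rho = 3\sigma$. Averaging $s_R$ over all cells of a query type Q gives the
aggregate entry (Q within R). The metric integrates both the density and the
proximity of R around Q cells and is deliberately **asymmetric**: three A
cells at distance $\sigma$ from one B cell give (B within A) $= 3e^{-1/2}$
but (A within B) $= e^{-1/2}$.

Design choices worth stating:

* **Kernel scale.** The kernel maximum is 1 rather than the bivariate normal
  density $1/(2\pi\sigma^2)$; the affine normalization below cancels any
  global kernel scale, so this only affects raw scores. A `normalized_pdf`
  switch provides the density convention.
* **Mean, not sum, over query cells.** The per-type aggregate is the mean of
  the per-cell scores, which is invariant to query-type abundance. Summing
  instead would scale each row by the query-type cell count; after the
  normalization below the two conventions differ only by that per-row
  constant. The mean is also what makes "the total score of all cells is
  zero" equivalent between sum and mean statements.
* **Self scores include the cell's own kernel.** A reference cell evaluated
  in its own field keeps its own contribution (+1 at distance zero). A
  leave-one-out switch exists and is off by default.
* **Truncation.** The "defined radius" of the metric is implemented as hard
  truncation at $3\sigma$ (configurable). Beyond it a kernel contributes
  exactly zero.

## Normalization: all-cell mean 0, self 100

Raw scores depend on $\sigma$, cell density, and section size. Per reference
column R (within each sample), scores are affinely rescaled:

$$ s' = 100 \cdot \frac{s - \overline{s}_{\text{all}}}
   {\overline{s}_{R} - \overline{s}_{\text{all}}}, $$

where $\overline{s}_{\text{all}}$ is the mean raw score over *all* cells in
the sample (including R cells, reading "all cells" literally) and
$\overline{s}_R$ the mean over cells of type R. After rescaling, the mean
normalized score over all cells is exactly 0 and the self aggregate
(R within R) exactly 100; both identities are algebraic and the test suite
asserts them to 1e−9. Columns with $\overline{s}_R = \overline{s}_{\text{all}}$
(e.g. a type coincident with the global mean field — in practice only
degenerate toy sections) are flagged and left unnormalized. Multi-sample
datasets are normalized within each sample first, then the normalized
aggregates are averaged across samples; per-sample matrices are retained.

## Exact versus gridded evaluation

`coloc_score_exact()` is the brute-force definition and the oracle.
`create_field()` evaluates it on a regular grid covering the reference
bounding box padded by the truncation radius, at spacing at most $\sigma/4$
(enforced); `evaluate_field()` interpolates the grid with separable
cubic-convolution (Keys) interpolation, which reproduces grid nodes exactly.
Plain bilinear interpolation was rejected: its worst-case error at
$\sigma/4$ spacing is $h^2/(4\sigma^2) = 1/64 \approx 1.6\%$ of an isolated
kernel's maximum, which already exceeds the 1%-of-max accuracy contract the
package promises for gridded evaluation. With cubic interpolation the
residual error is dominated by the truncation discontinuity itself — the
kernel value jumps by $e^{-4.5} \approx 1.1\times10^{-2}$ at $d = 3\sigma$ —
so the 1% contract is stated relative to the *section* maximum and holds
whenever kernels overlap at tissue-like densities (measured worst case
≈ 0.5% over random 100-reference sections). Exact mode is the default for
sections below 50k cells; grids exist for very large sections and for
map-style outputs.

# QC and normalization

Cells with fewer than 50 detected transcripts are excluded. Keratinocytes at
the skin surface transcribe progressively less as they differentiate, so
cells flagged as surface cells face a more lenient minimum of 10. Both
thresholds are inclusive minima (a non-surface cell with exactly 50 is kept;
a surface cell with exactly 10 is kept), and the lenient threshold may not
exceed the strict one. The filter is idempotent and reports removal counts
per reason. The surface rule is driven by a per-cell flag; generators or
readers may derive that flag from a y-band if the instrument does not
provide one.

Expression is log-normalized as $\log(1 + c \cdot 10^4 / C)$ for count $c$
in a cell with total $C$ — the ecosystem-standard library-size
normalization; the scale total is configurable. Zero maps to zero, the
transform is strictly monotone per cell, and it is invariant to per-cell
rescaling of counts.

**Variable genes** are ranked by excess variance over a mean–variance trend:
per-gene mean and variance of the *raw counts* are computed, a robust
(degree-1, symmetric-family, wide-span) loess of log10 variance on log10
mean is fitted, and genes are ranked by residual, ties broken
lexicographically. The trend is fitted on counts rather than log-normalized
values because library-size normalization shifts the means of overdispersed
genes and lets a flexible trend absorb exactly the excess variance the
method is meant to find; the robust, low-degree fit prevents boundary genes
(whose sample means are noisiest) from dominating their own local fit.
Constant genes rank last and are never selected ahead of varying ones.

**Joint row scaling** for heatmaps that juxtapose blocks (e.g. spatial bins
next to dissociated cell types): each gene row is z-scored across the
concatenation of all blocks' columns with the *population* standard
deviation (divide by $n$; the convention is stated because sample-sd would
change values by $\sqrt{n/(n-1)}$), then split back. Zero-variance rows map
to zeros.

# Transition ordering

The CD14^+^ subset is embedded (log-normalize, top-100 variable genes,
5 centered PCs via SVD with a deterministic sign convention), then a
diffusion map is built:

* symmetric (union) kNN graph, `k = 200` by default, capped at $n-1$;
* adaptive Gaussian kernel
  $w_{ij} = \exp\!\big(-d_{ij}^2 / (\sigma_i^2 + \sigma_j^2)\big)$ with
  per-cell bandwidth $\sigma_i$ = distance to the $\lceil k/3 \rceil$-th
  neighbor;
* density normalization with $\alpha = 1$ (divide by the degree at both
  endpoints), removing sampling-density effects;
* eigen-decomposition of the resulting Markov operator through its symmetric
  conjugate; the trivial constant eigenvector is discarded and diffusion
  component $i$ is the $(i{+}1)$-th right eigenvector scaled by its
  eigenvalue, sign fixed so the largest-magnitude entry is positive.

A dense symmetric `eigen()` is used up to $n = 2000$ and a Lanczos solver
(`igraph::arpack`) on the sparse kernel above that; both are deterministic.
A disconnected graph is an error advising a larger `k`. One known numerical
property: with *per-cell* bandwidths, the first component on a finite
uniform line shows a one-to-two-point inversion at each boundary (the
endpoint bandwidths are larger, pulling them slightly inward); an exactly
monotone DC1 would require a global bandwidth. The package keeps the
adaptive kernel — it is what makes the embedding robust to variable sampling
density — and the test suite asserts Spearman $|\rho| \ge 0.999$ on the line
and strict interior monotonicity.

**Orientation and ranks.** The sign of DC1 is arbitrary, so it is anchored:
the orientation is chosen so MMP9 (the inflammatory end) has higher mean
expression in the top DC1 quartile than the bottom; if MMP9 is
uninformative, LYVE1 decides in reverse; if both are flat, the error asks
for an explicit sign. Cells are ranked 1..n along oriented DC1 (ties broken
by cell id), and the rank — not the raw eigenvector value — is the
transition score; a `rank01` column rescales it to [0, 1].

**Equal-size binning.** Rank-ordered cells are split into contiguous blocks
whose sizes differ by at most one, larger blocks first (any fixed rule
works; this one is documented): 7,200 cells into 50 bins gives exactly 144
per bin, and 100 cells into 30 bins gives ten bins of 4 then twenty of 3.
Per-bin gene means feed the binned heatmaps; joint ordering across pooled
conditions is the default, with per-condition binning available by
subsetting first.

# Neighborhood expression

`local_expression()` reports, per focal cell, the *mean* normalized
expression of a gene over neighbors within a radius (default 400 px ≈ 41
µm), optionally restricted by neighbor type. The focal cell is excluded by
default — the statistic describes the neighborhood, not the cell — and a
switch includes it. The mean (not the sum) keeps the statistic independent
of local cell density, which the colocalization metric already measures;
this is a documented divergence risk against convention in other toolkits.
Cells with no neighbor in radius get `NA` with a neighbor count of 0 rather
than a silent zero.

`smooth_expression_map()` is a Nadaraya–Watson surface: at each grid node,
the Gaussian-weighted mean of all cells' values (sd 400 px default,
truncated at $3\sigma$); nodes with zero total weight are masked. Being a
convex combination, the surface is bounded by the input range.
`contour_levels()` returns `n_levels` (default 6) values evenly spaced
between the empirical `threshold` quantile (default 0.9, type-7/linear
interpolation — the dominant convention) and the maximum of the unmasked
surface.

`rolling_mean_by_score()` sorts cells by a continuous score and applies a
centered moving average with window `max(1, round(window_prop * n))`,
shrinking (clipping) the window at the edges; for even windows the extra
element goes to the right. The package default is `window_prop = 0.1`; a
full-window setting of 1 is honored but nearly flattens curves to the global
mean, so callers wanting visible trends should use fractions well below 1.
Whether a "window proportion of 1" in other toolkits means the same unit is
ambiguous; this package implements proportion-of-cells semantics and says
so.

# Distances and depth

`min_distance_to_type()` computes, per focal cell, the minimum Euclidean
centroid-to-centroid distance to the union of the target types (taking the
union is equivalent to the minimum of per-type minima), exactly — the
chunked computation is algebraically identical to the brute-force pairwise
minimum, and a test asserts equality. Distances are reported in px and µm.
Cell boundaries are not used, only centroids. `depth_profile()` returns
per-type Gaussian KDEs of depth on a grid shared across types (so ridgeline
comparisons align) plus quartiles; the KDE integrates to 1 on the grid to
1e−3. `transition_distance_table()` inner-joins an ordering with a distance
table on cell id (warning if cells are lost) and attaches marginal rolling
means of the transition score along each distance axis.

# The synthetic tissue generator

The generator emulates the statistical structure the analyses assume, with
fixed defaults that are the package's study conditions:

* **Geometry.** A 6,000 × 9,000 px section (0.6 × 0.9 mm at 0.1 µm/px):
  cornified/suprabasal epidermis (y 0–550), basal band at the
  dermal–epidermal junction (550–700), papillary dermis (700–2,700),
  reticular dermis (2,700–9,000). Layers must partition [0, height].
* **Populations.** Homogeneous Poisson processes per layer: suprabasal and
  basal keratinocytes in the epidermis; pro-inflammatory fibroblasts,
  CD14^+^ myeloid cells, CD4/CD8 T cells and endothelium in the papillary
  dermis; mesenchymal fibroblasts and deeper populations in the reticular
  dermis. Three isotropic Gaussian immune aggregates (sd 300 px) sit beneath
  the junction, each expected to hold ~80 CD4 T, ~40 CD8 T, ~50 CD14 and ~30
  pro-inflammatory fibroblast cells. Expected total ≈ 4,700 cells; realized
  counts are Poisson around that.
* **Expression.** 51 genes: per-type marker programs, a 15-gene
  housekeeping set, and the transition/chemokine genes below. Counts are
  negative-binomial with per-type dispersion (size 2) — seqFISH counts are
  overdispersed, and Poisson data would make the normalization and
  variable-gene steps look better than they are. Infinite dispersion
  degenerates to Poisson exactly.
* **Transition.** Each CD14 cell carries a latent
  $t = \mathrm{clamp}(a - b\,\cdot\,\mathrm{depth} + \varepsilon)$, depth
  normalized by section height, $a = 1.1$, $b = 1.15$,
  $\varepsilon \sim N(0, 0.07^2)$: superficial CD14 cells are high-$t$
  (MMP9-skewed), deep ones low-$t$ (LYVE1-skewed). Marker means are linear
  in $t$: MMP9 $= 25t + 0.3$, LYVE1 $= 25(1-t) + 0.3$, plus an M1 program
  (IL1B, CXCL9, CD86, TNFAIP6; $8t + 0.3$) and an M2 program (MRC1, CD163,
  F13A1, STAB1, FOLR2; $8(1-t) + 0.3$). Because aggregates sit superficially
  and the same latent $t$ couples to depth, aggregate-embedded CD14 cells
  are high-$t$ — the constructed contrast behind the colocalization
  recovery tests.
* **Chemokine gradient.** Fibroblast CCL2/CCL8 means are
  $0.3 + 18\exp(-d^2/2\lambda^2)$ with $d$ the distance to the nearest
  aggregate center and $\lambda = 600$ px.
* **Surface cells.** Keratinocytes with y < 250 px are flagged as surface
  cells and their expected library is scaled by 0.35, producing cells in the
  10–50 transcript range that exercise the lenient QC path.
* **Determinism.** The RNG kind is pinned (Mersenne-Twister / inversion /
  rejection); identical (config, seed) pairs give identical datasets, and
  the caller's RNG state is restored afterwards.

What the generator does **not** emulate: segmentation errors, optical
crowding, transcript misassignment between adjacent cells, batch effects
across sections, irregular tissue boundaries, and cell-shape anisotropy.
Passing recovery tests therefore show the *methods* are implemented
correctly and are self-consistent at realistic densities and noise levels —
not that real sections will reach the same effect sizes.

# Numerical choices and degenerate inputs

* Quantiles: type 7 everywhere. z-scores: population sd. Ties in rankings:
  lexicographic by gene or cell id, so all outputs are deterministic.
* PCA signs: largest-magnitude loading positive per component.
* Empty reference sets score 0 (not an error); empty datasets write valid
  empty files; a type with fewer than 3 cells cannot be diffusion-mapped and
  the pipeline skips the stage with a logged reason rather than failing.
* Degenerate normalization columns are flagged and left raw, with a warning.
* Problem sizes in the shipped tests: sections of ~700–4,800 cells, 100
  random field configurations with 1,000 query points each, 5-seed recovery
  runs on the full-size default section and a 100-seed colocalization
  contrast — sizes chosen so the full suite documents the claims while
  remaining quick to run routinely.

# Known limitations

* The colocalization metric has no significance model; the package reports
  effect sizes (normalized scores), not p-values, and a permutation test is
  deliberately out of scope.
* Batch integration is out of scope: diffusion maps on multi-patient data
  should be fed batch-corrected embeddings from elsewhere; the synthetic
  data are single-batch, which is exactly why this omission is testable
  there.
* Distances are 2-D centroid distances within a section; z-planes and cell
  boundaries are ignored.
* `window_prop = 1` rolling means are near-constant by construction; that
  setting reproduces a published convention but is rarely what an analyst
  wants.

# A worked demo

```{r, eval = FALSE}
res <- run_pipeline(default_run_config(seed = 1), out_dir = "demo_out")
res$report$qc               # cells kept / removed per reason
res$results$coloc$normalized["Myeloid_CD14", "T_CD4"]  # directional score
head(res$results$transition)  # cell_id, dc1, rank, rank01, bin
```

The same chain is scriptable from a shell through
`inst/cli/skinspatial.R` (`demo`, `simulate`, `run` subcommands), and
`scripts/acceptance.R` recomputes the normalization constants from a fresh
synthetic section.
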