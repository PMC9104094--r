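---
title: "Methods: niche dynamics in environmental space and reciprocal distribution models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: niche dynamics in environmental space and reciprocal distribution models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicheshift)
```

## The scientific problem

When a species invades a new region, has its *realized niche* — the set of
environmental conditions it actually occupies — shifted relative to the native
range, or is the species filling the same niche in new geography? The
distinction matters: distribution models transferred between ranges are only
trustworthy under niche conservatism, and the apparent "shift" must be
separated from mere differences in which environments are *available* in each
range.

`nicheshift` implements the standard ordination-space workflow for this
question, plus a reciprocal ensemble-modelling cross-check, plus a synthetic
scenario generator whose true niche shift is known exactly, so every stage can
be validated against ground truth.

## Environmental space and occupancy surfaces

All comparisons happen in a two-dimensional environmental space: a principal
component analysis of the **pooled** background environments of both ranges
(each variable standardized; axis signs fixed so the dominant loading of each
axis is positive). Occurrences and backgrounds are projected onto the first
two axes and gridded on an $R \times R$ lattice (default $R = 100$) spanning
the pooled scores with 5% padding; grid coordinates are cell centres.

For each range we estimate, by kernel density estimation:

* $o(z)$ — density of occurrences at environment $z$;
* $e(z)$ — density of available environments (the background);

and form the availability-corrected occupancy

$$ z(z) \;=\; \frac{o(z)}{e(z)}, $$

rescaled to a maximum of 1, with $z = 0$ wherever $e = 0$. This correction is
what distinguishes "the species avoids these conditions" from "these
conditions do not exist in the range".

### Kernel choice: truncated Gaussian

The KDE uses a product-Gaussian kernel with per-axis Silverman bandwidths
(`stats::bw.nrd0`), **truncated at 3 bandwidths per axis** and not
renormalized. Truncation is a deliberate design choice, not an optimization:
an untruncated Gaussian is strictly positive everywhere, so every surface
would overlap every other surface and the binarized supports used by the
expansion/unfilling indices ($z > 0$) would degenerate to the whole grid.
Truncation gives occupancy surfaces a genuine finite support at the cost of a
slight (≤ 1.1%) mass deficit, which cancels in all normalized statistics.
Availability values below $10^{-12} \times \max e$ are floored to zero to
keep the ratio $o/e$ stable.

Within a temporal series the bandwidth is estimated **once**, from the full
occurrence set, and reused for every cumulative subset — otherwise early
years with few records would be smoothed much harder than late years and the
yearly indices would not be comparable.

## Overlap, equivalency and similarity

Niche overlap is Schoener's $D$ on the normalized occupancy surfaces,

$$ D = 1 - \tfrac12 \sum_{z} \lvert p_1(z) - p_2(z) \rvert \in [0, 1], $$

optionally restricted to a mask of analogue environments.

Two permutation tests accompany it (default `n_perm = 99`; p-values use the
add-one convention $p = (1 + \#\{D^\* \le D_{obs}\})/(n_{perm} + 1)$, so no
p-value is ever zero):

* **Equivalency** — pooled occurrences are randomly reallocated between the
  two entities, keeping each sample size; the availability surfaces are held
  fixed. The observed $D$ is compared against this null from below
  ("lower": are the niches *less* equivalent than random relabelling?). For
  tiny samples the full reallocation set can be enumerated exhaustively.
* **Similarity** — one entity's occupancy surface is translated so its
  centroid sits on a uniformly random available cell of its own background,
  and compared from above ("higher": do the niches overlap *more* than a
  randomly placed niche would?).

## Expansion, stability, unfilling and the analogue mask

Within the analogue mask $m$ (cells available in **both** ranges; at
intersect quantile $q > 0$, cells where each range's availability exceeds its
own $q$-quantile over positive cells), with native support
$N = \{z_{nat} > 0\}$ and invasive support $I = \{z_{inv} > 0\}$:

* **Expansion** — share of invasive occupancy (summed $z_{inv}$) in analogue
  cells outside $N$;
* **Maximum niche stability** — its complement, $1 - $ expansion;
* **Unfilling** — share of native occupancy in analogue cells outside $I$.

If the invasive niche has no occupancy at all inside the mask, expansion and
unfilling are reported as 1 (complete shift) with a warning. The
`marginality_sweep()` helper recomputes the indices across a vector of
intersect quantiles (default 0, 0.1, 0.2), exposing how much of an apparent
shift lives in marginal climates. `temporal_dynamics()` recomputes them on
cumulative yearly subsets of the invasion, which for a spreading invasion
shows unfilling decaying toward zero.

Binarization of supports uses the threshold $z > 0$ by default (`threshold`
argument); with a truncated kernel this is meaningful, since $z$ is exactly
zero beyond 3 bandwidths from every occurrence.

## MESS

`mess()` computes the multivariate environmental similarity surface: for each
target point and variable, the familiar piecewise formula in the percentage
$f$ of reference values strictly below the target value, taking the minimum
over variables. Negative values flag environments outside the reference range
(novel climates); the reported `fraction_nonnegative` summarizes how much of
the target range is analogue.

## Reciprocal ensemble distribution models

The geographic cross-check trains an ensemble per range and projects it onto
the other range:

* pseudo-absences: 5 per presence, uniformly from valid non-presence cells,
  redrawn each repetition;
* per repetition, a stratified 75/25 train/test split preserving the class
  ratio;
* three learners per split: gradient-boosted trees (`xgboost`), probability
  random forest (`randomForest`), and an L1-regularized logistic model on
  linear + quadratic features (`glmnet`) — a declared surrogate for maximum
  entropy modelling, to whose solution it is closely related; the learner
  interface is pluggable;
* each of the 10 × 3 runs records its held-out rank AUC, derives its own
  max-sensitivity+specificity (TSS-maximizing) threshold on the training
  scores, and binarizes its map; the ensemble keeps a cell only on a
  **strict majority** of runs.

Projecting the native ensemble onto the invaded range and overlaying it with
the invaded-range ensemble yields four risk categories per cell — `both`,
`native_only`, `invasive_only`, `neither` — with `neither` the only low-risk
class under reciprocal modelling. A conserved niche shows each ensemble
recovering most of the other range's presences; a shifted niche shows the
invaded-trained model missing most native occurrences.

## Synthetic scenarios and ground truth

`make_invasion_scenario()` generates paired ranges with a known truth:
environmental layers are planar gradients at distinct orientations plus
smoothed seeded noise (`noise_scale = 1` by default, which keeps pairwise
layer correlations comfortably below the 0.7 collinearity screen — with
five planar gradients in two spatial dimensions, near-zero correlation for
all pairs is geometrically impossible without noise); optional
`correlation_pairs` force $|r| \ge 0.9$ for testing the screen. The true
niche is product-Gaussian in the layer values; occurrences are sampled with
probability proportional to true suitability. Key controls:

* `shift_delta` / `shift_delta_sd` — the true niche-centre shift (absolute,
  or in units of each layer's realized standard deviation);
* `identical_stacks` — reuse the native range as the invaded range, making
  "no shift" scenarios exactly conserved;
* `native_breadth_sd`, `breadth_factor` — niche specialism;
* `years`, `introduction_cell`, `spread_rate` — a radial invasion front, so
  early-year occurrence sets under-fill the niche by construction.

Sampling uses private, seeded RNG streams, so scenarios never perturb (and
are never perturbed by) the session's global random state.

Two generator conventions are worth stating explicitly. First, "no shift"
benchmarks use `identical_stacks = TRUE`; with independently generated
stacks, availability differences alone depress overlap, which is a fact
about the ranges, not an estimator error. Second, the reciprocal-model
benchmark uses a specialist niche (`native_breadth_sd = 0.3`): for a broad
generalist niche even the *true* suitability model binarized at its own
optimal threshold leaves a material share of presences below threshold, so
≥ 90% presence coverage is only a meaningful bar for a specialist. These are
properties of the benchmark design, chosen from the generative model itself.

## The pipeline

`run_pipeline()` (and the `nicheshift_cli()` entry point with subcommands
`synth`, `preprocess`, `envspace`, `niche`, `sdm`, `report`, `run`) executes
the whole workflow from a closed-schema YAML config: synthesize or ingest
ranges; rarefy occurrences to one per grid cell and drop collinear layers
($|r| \ge 0.7$); build the shared space and occupancy surfaces; compute
overlap, permutation tests, the marginality sweep and yearly dynamics; fit
the reciprocal ensembles and risk overlay; and assemble `report.yml`. Every
stage persists plain CSV/YAML/ASCII-grid artifacts; an SDM failure never
discards completed niche-dynamics outputs; stages derive fixed child seeds
from the config seed, so single stages rerun reproducibly.

## A worked example

```{r example, eval = FALSE}
sc <- make_invasion_scenario(list(seed = 1, identical_stacks = TRUE,
                                  n_native = 500, n_invasive = 500))
nat_bg <- stack_values_table(sc$native_stack)[sc$native_stack$layer_names]
inv_bg <- stack_values_table(sc$invaded_stack)[sc$invaded_stack$layer_names]
pca <- fit_pca_env(list(nat_bg, inv_bg))
scores <- list(
  nat_occ = project_env(pca, extract_env_at_points(sc$native_stack, sc$native_occ)),
  inv_occ = project_env(pca, extract_env_at_points(sc$invaded_stack, sc$invasive_occ)),
  nat_bg = project_env(pca, nat_bg), inv_bg = project_env(pca, inv_bg))
grid <- env_grid(list(scores$nat_bg, scores$inv_bg))
g_nat <- build_density_grid(scores$nat_occ, scores$nat_bg, grid, entity = "native")
g_inv <- build_density_grid(scores$inv_occ, scores$inv_bg, grid, entity = "invasive")
mask <- analogue_mask(g_nat, g_inv, 0)
esu_indices(g_nat, g_inv, mask)          # expansion ~ 0 for a conserved niche
schoener_d(g_nat$z, g_inv$z, mask$mask)  # high overlap
equivalency_test(scores$nat_occ, scores$inv_occ,
                 rbind(scores$nat_bg, scores$inv_bg), seed = 1)
```

## Problem sizes and limitations

Default problem sizes (40 × 40 ranges, 5 layers, hundreds of occurrences,
$R = 100$, 99 permutations, 30 ensemble runs) are chosen so the complete
workflow runs in seconds to a couple of minutes on one CPU; all are
configurable upward.

Limitations to keep in mind:

* the ordination space is fixed at two axes; variance beyond PC2 is ignored;
* raster I/O is plain ESRI ASCII grid (one file per layer, unprojected
  coordinates); no GeoTIFF/CRS handling;
* the `maxent_like` learner is a regularized logistic surrogate, not a true
  MaxEnt engine;
* occurrence rarefaction is grid-based (one record per cell), not
  distance-based thinning;
* permutation p-values are resolution-limited to $1/(n_{perm} + 1)$.
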