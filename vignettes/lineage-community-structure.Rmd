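---
title: "Lineage-specific phylogenetic community structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-specific phylogenetic community structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineacom)
```

## The problem

Community phylogenetics asks whether the species that co-occur in local
communities are more closely related than chance (phylogenetic clustering,
the classic signature of environmental filtering acting on conserved
niche traits) or less closely related (overdispersion, the signature of
limiting similarity or of convergent traits). Treewide summaries of entire
floras often find nothing: lineages that split tens of millions of years
ago under different ecological regimes are averaged together, and opposing
signals cancel. `lineacom` decomposes the question **lineage by lineage**:
every internal node of a dated phylogeny is analysed separately, using only
the species descending from that node as its pool, so a clustered grass
clade and an overdispersed primrose clade no longer mask each other.

The package targets plot-based vegetation surveys along environmental
gradients — the motivating setting is an alpine elevation gradient
(roughly 375–3200 m, plots of a few m², cover recorded in ordinal
classes) — but nothing in the machinery is specific to mountains.

## Statistics implemented

**Pairwise co-occurrence (global analysis).** For species $S_1, S_2$ with
occupancy counts $N_{S_1}, N_{S_2}$ and $N_{S_1 \cap S_2}$ shared plots,

$$C(S_1,S_2) = \frac{N_{S_1 \cap S_2}}{\min(N_{S_1}, N_{S_2})} \in [0,1],$$

i.e. the shared-plot count normalised by the rarer species' occupancy
(1 = the rarer species never occurs without the other; 0 = never
together). The treewide test correlates $C$ with patristic distance over
all species pairs (Spearman, upper triangle) and assesses it by permuting
the species labels of the **distance** matrix. The source analysis does not
state what its randomizations permuted; we permute distance labels because
it preserves the occupancy structure — and hence the marginal distribution
of $C$ — exactly. The permutation p-value uses the add-one rule
$(1 + \#\{|\rho^*| \ge |\rho_{obs}|\})/(1 + n_{rand})$ and is two-sided,
since both signs are ecologically interpretable.

**Node-restricted NRI.** For a community (plot) holding $k \ge 2$ species
of the focal node's pool,

$$\mathrm{NRI} = -\,\frac{\mathrm{MPD}_{obs} - \overline{\mathrm{MPD}}_{null}}
{\mathrm{SD}(\mathrm{MPD}_{null})},$$

where MPD is the mean patristic distance over unordered pairs. Null
communities hold richness fixed at $k$ and draw species from the node's
pool without replacement, with weights proportional to each species'
occurrence frequency. This is our reading of a null that "maintains
species richness and prevalence": richness is preserved exactly,
prevalence in expectation. The published phrase is ambiguous between this
frequency-weighted draw and matrix-wide swap algorithms
(independent/trial swap); we implement the former and flag the
difference — swap algorithms preserve both margins exactly but mix slowly
and are not reproducible draw-by-draw.

A node's summary is the mean NRI over all its qualifying plots, classified
clustered ($> 0.5$), overdispersed ($< -0.5$) or random (the closed band
$[-0.5, 0.5]$). The band is treated as a fixed global convention; because
it has also been read as a per-node 95 % CI criterion, the node table
additionally reports each node's mean $\pm 1.96\,\mathrm{SD}/\sqrt{n}$ so
either reading can be applied. Nodes whose usable pool has $\le 2$ species
are `not_estimable` (with 2 pool species every null draw is the same pair
and the null SD is zero), matching the ~31 % of cherries that field
analyses of ~230 nodes cannot score.

**Gradient and age models.** Per node, ordinary least squares of per-plot
NRI on elevation (slope t-test, $n-2$ df); across nodes, a Gaussian
identity-link GLM `mean_nri ~ community_size + node_age`, where community
size is the node's clade richness — the paper's "community size (or
species richness) at nodes" — plus a per-node Spearman correlation between
NRI and within-plot clade richness as a scale-artefact diagnostic.
Robustness across posterior trees repeats the scan per tree and matches
nodes by **descendant tip-set identity**, the only correspondence that
survives topology changes; clades recovered in under half the trees are
flagged unstable rather than averaged.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_occurrences` | 20 | plots | species kept if present in *strictly more* plots ("more than 20 times") |
| `min_cover_fraction` | 0.8 | — | plots kept when retained species hold $\ge$ 80 % of total cover (inclusive) |
| cover-class midpoints | 0.05 … 82.5 | % | midpoints of the 8-class alpine cover scale |
| `zone_breakpoints` | 900/1500/2200 | m | colline/montane/subalpine/alpine; **not field-derived** — configuration values only |
| `n_null` | 999 | draws | desk-scale default; field analyses used 9999 — set it explicitly for publication runs |
| `n_rand` | 999 | permutations | same consideration |
| `band` | 0.5 | NRI | classification band half-width |
| `alpha` | 0.05 | — | per-node significance; no multiple-testing correction by default (raw per-node significance is what the motivating analyses report), BH adjustment available and logged |

## The synthetic world

Field plot data are rarely redistributable, so the generator is a
first-class module, not a fixture. It states one world:

* **Tree**: Yule (pure birth) with rate $\lambda = 1$/Myr, default 200
  tips — the scale of a regional flora phylogeny. The simulator waits
  $\mathrm{Exp}(k\lambda)$ between events and cuts a final
  $\mathrm{Exp}(n\lambda)$ after the $n$-th lineage, so
  $E[\text{height}] = \lambda^{-1}\sum_{k=2}^{n} 1/k$ exactly; the test
  suite uses this closed form as its oracle (this is also why we did not
  reuse an off-the-shelf simulator whose conditioning has no simple
  closed-form height).
* **Trait**: an optimum elevation evolving by Brownian motion,
  $\sigma^2 = 10^5\ \mathrm{m^2/Myr}$ from a root at 1800 m, chosen so tip
  optima spread over the full 375–3200 m gradient on a height-5 tree.
* **Plots**: 500 plots on an even elevation grid, Poisson mean richness 15
  (floored at 2). Filtering selects species with weight
  $\exp(-f\,(\text{trait}-\text{elev})^2/s^2)$, $s = 300$ m — the simplest
  kernel that produces elevation-dependent clustering. Competition picks
  species sequentially, down-weighting a candidate by
  $\exp(-c/d_{min})$ with $d_{min}$ its patristic distance to the species
  already selected (nearest-neighbour limiting similarity). Strengths
  $f = 10$ / $c = 20$ are the package's definition of "strong": at $f=10$
  a species one kernel width off its optimum is effectively excluded; at
  $c=20$ a candidate 5 Myr from a resident keeps $e^{-4}$ of its weight.
* **Covers**: log-normal, rescaled to 100 % per plot. Covers are
  deliberately decoupled from assembly because every core statistic here
  is presence-based.

What a green test does establish: the index algebra, the null model
(checked against exhaustive enumeration), type-I error control, parameter
recovery, and that strong filtering/competition are detected where they
act. What it does not: real floras have phylogenetically clumped
prevalence, spatial autocorrelation between plots, observer error in cover
classes, and non-Brownian trait evolution — none of which the generator
emulates. A green suite is a statement about the machinery, not about any
mountain.

## Numerical choices

* Null MPD mean/SD depend, within one node, only on community size $k$;
  `node_nri_scan` therefore draws one null distribution per
  $(\text{node}, k)$ from a deterministic substream of the master seed.
  This is what makes full scans at `n_null = 999` run in seconds, and it
  leaves results reproducible and order-independent. The per-community
  operation `nri_community` still draws its own nulls.
* The null SD uses the sample SD ($n-1$); the exhaustive-enumeration
  oracle returns the population SD of the exact subset distribution, and
  the equivalence test compares them within Monte-Carlo error.
* Ultrametricity is checked at relative tolerance $10^{-6}$ of tree
  height and violations warn rather than error (consensus trees are
  ultrametric by construction, but serialised precision varies); node age
  remains defined as height minus depth.
* Boundary conventions, fixed once: species filter strictly $>$;
  cover-fraction filter inclusive $\ge$; vegetation zones half-open
  $[low, high)$; classification band closed on both sides (a mean NRI of
  exactly $\pm 0.5$ is "random").
* Degenerate inputs: a community that saturates its pool has a
  deterministic null (SD 0) and is not estimable; constant elevation has
  no identifiable slope and errors; constant clade richness makes the
  Spearman diagnostic undefined and is flagged, not imputed.

## Open design points, decided

* **Node count**: whether published node counts include the root is never
  stated; we enumerate every internal node including the root (a
  bifurcating $N$-tip tree yields $N-1$ rows) and report the count.
* **Strata**: whether monocot/eudicot strata re-computed co-occurrence on
  subsetted plots or merely restricted pairs is not stated; we restrict
  pairs within the full-plot co-occurrence matrix, which keeps $C$
  identical across strata and isolates the pairing effect.
* **Config format**: the run configuration is JSON rather than YAML — the
  target environment ships no YAML parser and the format carries no
  semantics here.
* **Outgroups** are pruned by explicit label (`prune_tips`), never
  auto-detected.

## Known limitations

Plots are treated as exchangeable: no spatial autocorrelation correction
in either the global permutation test or the per-node regressions, and no
phylogenetic autocorrelation correction across nodes (parent and child
nodes share species and are not independent — per-node p-values are
descriptive, which is also why BH adjustment is optional rather than
default). Alternative structure indices (NTI, PSV, phylogenetic
beta-diversity) and swap-based null models are out of scope by design;
abundance-weighted MPD is not the default because the motivating analyses
are membership-based.
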