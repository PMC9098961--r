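---
title: "Metabolic covariance network analysis with mcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance network analysis with mcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcnet)
```

## The model

mcnet analyses *group-level metabolic covariance networks* built from
regional FDG-PET uptake. The data are a subjects × regions table of mean
regional intensities (90 regions in the default whole-brain parcellation,
45 per hemisphere). For one group of subjects, the connection between
regions $i$ and $j$ is the Pearson correlation of their intensities across
the group's subjects,

$$ r_{ij} = \frac{\sum_s (x_{si} - \bar x_i)(x_{sj} - \bar x_j)}
  {\sqrt{\sum_s (x_{si} - \bar x_i)^2 \sum_s (x_{sj} - \bar x_j)^2}}, $$

giving one symmetric network per group (not per subject). Self-connections
are excluded. This is a *covariance* network: an edge means two regions'
metabolism rises and falls together across people, which is read as
functional association.

Because a correlation matrix has no natural edge set, the network is
binarized in two ways:

* **Sparsity sweep** — keep the $\lfloor s \cdot N(N-1)/2 \rfloor$
  strongest correlations for each sparsity $s$ on a grid from 5% to 50% in
  1% steps. Matching edge counts across groups makes topology, not overall
  correlation level, the object of comparison. Metrics are summarized by
  their trapezoidal area under the curve (AUC) over the grid, a
  threshold-independent quantity.
* **Absolute cutoff** — an edge wherever $r > 0.5$ (strictly), used for the
  hemispheric connectivity maps.

On each binary graph the package computes the standard parameters:
characteristic path length $L$ (mean hop distance over reachable pairs),
clustering coefficient $C$, global efficiency $E_{glob}$ (mean inverse
distance, with $1/\infty = 0$ so disconnection is handled natively), local
efficiency $E_{loc}$ (global efficiency of each node's neighbour-induced
subgraph), and their nodal variants plus betweenness centrality (BC,
Brandes' exact algorithm, unnormalized — the hub rule below is invariant
to scaling).

**Small-worldness** is assessed against degree-preserving random graphs
(Maslov–Sneppen double-edge swaps, 100 nulls per sparsity point, 10 swap
attempts per edge): $\gamma = C/C_{rand}$, $\lambda = L/L_{rand}$,
$\sigma = \gamma/\lambda$; a small-world network shows $\gamma \gg 1$,
$\lambda \approx 1$, $\sigma > 1$.

**Hubs** are regions whose betweenness exceeds the group mean plus one
sample standard deviation (strict inequality; a constant BC vector
therefore yields no hubs). The BC basis is the AUC of nodal BC over the
sparsity grid, giving one hub set per group.

**Group inference** is nonparametric: subjects are randomly reassigned to
groups (sizes preserved), *both covariance networks are rebuilt from
scratch inside every permutation*, the sweep re-run and re-integrated, and
the two-sided p-value computed with the add-one estimator
$p = (\#\{|d^\ast| \ge |d|\} + 1)/(B + 1)$, which can never be zero.
Rebuilding inside the permutation is essential: the networks are group
properties, so only subject labels are exchangeable — permuting edges or
comparing fixed networks would not give a valid null. Region-wise
comparisons apply Benjamini–Hochberg FDR across the 90 regions at
$q = 0.05$. The default is 1,000 permutations.

**Laterality**: the network is split into two 45-node intra-hemispheric
networks (hemisphere read from the `.L`/`.R` region-name suffix, with an
odd/even-label fallback). Edge counts at $r > 0.5$ and the left-minus-right
AUC differences of $C$, $E_{glob}$, $E_{loc}$, $L$ are reported. Left and
right networks come from the *same* subjects, so group-style permutation is
not available; inference uses a subject bootstrap (resample subjects with
replacement, rebuild both hemispheric networks, two-sided sign-based
add-one p). This choice is an interpretation of the laterality comparison,
not a canonical test.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| sparsity grid | 0.05–0.50 by 0.01 | proportion of possible edges kept |
| `negative` | `"zero"` | negative correlations zeroed before ranking (`"absolute"` folds them in); the dominant convention in covariance-network tools |
| `n_perm` | 1000 | label permutations per comparison |
| `n_null` | 100 | rewired nulls per sparsity point |
| `n_rewires_per_edge` | 10 | swap attempts per edge per null |
| `r_min` | 0.5 | strict cutoff for hemispheric maps |
| hub rule | mean + 1 sample SD | strict inequality, per group |
| `fwhm_mm` | 8 | Gaussian smoothing width for volumes (mm) |
| normalization | proportional | each subject's row scaled to grand mean 100 |

Intensity normalization deserves a note: without it, inter-subject global
differences (injected dose, body weight) dominate every inter-regional
correlation. Proportional scaling to the subject grand mean is the common
practice in FDG covariance work and is the default; `none` is available
for pre-normalized tables.

## The synthetic-data generator

No subject-level data accompany the analysis this package operationalizes,
so validation rests on simulation with known ground truth. A
`synth_spec()` describes two groups of (by default) 17 subjects × 90
regions — the study-sized configuration — drawn from a multivariate normal
whose correlation matrix is an edge-wise target: `r_connected` (default
0.6) on the edges of a planted `base_network`, `r_background` (default
0.1) elsewhere. The default base network is modular (6 equal blocks,
complete within), which yields a clustered, small-world-like covariance
topology. Regional intensity is `region_mean + region_sd * signal + noise`
(defaults 100, 10 and 1 arbitrary uptake units); the independent additive
noise slightly attenuates planted correlations (by a factor
`region_sd^2 / (region_sd^2 + noise_sd^2)`, about 1% at the defaults).
Group 2 can differ in means or in its covariance target (`group_effect`).

Edge-wise targets are usually indefinite, so the target is repaired to the
nearest positive semi-definite correlation matrix by eigenvalue clipping
(floor `1e-8`) with rescaling to unit diagonal, iterated to convergence.
Repair has a consequence worth understanding: **a correlation matrix
cannot contain a high-degree node with uniformly strong edges.** If a
region correlates at $r$ with $k$ mutually near-uncorrelated partners,
PSD-ness forces $r \lesssim 1/\sqrt{k}$, and the repair implements exactly
that shrinkage. A "hub" planted as a raw high-degree node therefore ends
up with *weaker* edges than background regions. The generator instead
plants hubs as *bridges*: `planted_hub_modular_network()` wires hub
regions to every module of the modular background, so cross-module
shortest paths run through them — which is precisely what makes a region a
betweenness hub. Degree-sequence networks with exact hub degrees remain
available via `planted_network()` (backed by a configuration sampler over
graphical degree sequences).

Toy labelled volumes (`make_toy_volumes()`) host each subject's regional
values in a rectangular block parcellation plus Gaussian voxel noise, to
exercise smoothing and extraction against known values. What the generator
does *not* emulate: anatomy, PET physics, partial-volume effects, scanner
differences, non-normal subject variation, or spatially correlated noise.
Passing tests demonstrate that the pipeline recovers planted structure
under the stated sampling model — not that any particular real-data
finding is correct.

## Numerical choices and degenerate inputs

* FWHM converts to the Gaussian $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$
  per axis in voxel units; smoothing is separable with the kernel
  truncated at $4\sigma$ and boundary weights renormalized per output
  voxel, so constant fields are preserved exactly and interior mass is
  conserved.
* Ties at a sparsity cut are broken deterministically in lexicographic
  (row, column) order after sorting by weight, so runs are reproducible.
* $L$ is computed over reachable pairs only, with the unreachable count
  reported; at low sparsity graphs are routinely disconnected and the
  efficiency metrics handle this natively via $1/\infty = 0$.
* Zero-variance regions make the correlation undefined and raise an error
  naming the region; permutations that produce one are redrawn and
  counted.
* Graphs that admit no double-edge swap (stars, complete graphs) rewire to
  themselves with a warning and a recorded swap count; their small-world
  indices are exactly 1 against such null sets.
* All randomness flows through R's RNG; every simulation, permutation and
  rewiring sequence is reproducible from a single seed, and the pipeline
  derives per-stage streams from its master seed.

## Open design points, resolved

* *Negative correlations* — the analysis convention is unstated in the
  literature this follows; zeroing before ranking is the default, with
  `absolute` exposed.
* *Sparsity step* — only the 5–50% range is conventional; 1% steps (46
  points) are the default grid.
* *Order of smoothing and parcellation* — smoothing precedes extraction,
  matching standard PET preprocessing order.
* *Hub SD* — sample (n−1) standard deviation.
* *Nodal comparison basis* — AUC over the grid rather than per-sparsity
  tests, with per-sparsity sweeps available from the lower-level
  functions.
* *"Medial centrality"* in the hub rule's source description is read as
  the betweenness centrality values themselves.

One inferential caveat discovered in validation: with add-one permutation
p-values the smallest attainable value is $1/(B+1)$, so the smallest
attainable BH-adjusted p across $m$ regions is $m/(B+1)$. At $m = 90$ and
$B = 1000$ that is 0.09 — a *single* differing region can essentially
never clear $q = 0.05$ alone; detectable regional effects in practice
involve several regions with small p-values. Raise `n_perm` if strict
single-region FDR detection is required.

## Problem sizes used in the validation suite

The test suite runs the full 90-region, 17-per-group configuration for
the structural, small-world and hub-recovery checks (100 nulls per
sparsity, 50 recovery simulations). Calibration-style checks that need
hundreds of replicates (type-I error of the permutation test: 500
datasets at 200 permutations) use 20-region networks and a 5-point grid —
sizes chosen so the suite exercises every code path at study scale where
it matters and at reduced scale where only sampling behaviour is being
measured. Metric correctness is verified exactly against exhaustive
enumeration on all 995 connected graphs of up to 7 nodes.

## A worked example

```{r example, eval = FALSE}
library(mcnet)

spec <- synth_spec(seed = 1)          # 2 x 17 subjects, 90 regions
ds   <- simulate_dataset(spec)

net  <- covariance_network(ds$table, "g1")
sw   <- metric_sweep(net)             # L, C, GlobE, LocE over 5-50%
sw$auc

smw  <- small_world_sweep(net, n_null = 100, seed = 2)
smw$mean_sigma                        # > 1: small-world

hubs <- hub_analysis(net)
subset(hubs, is_hub)

cmp  <- compare_global(ds$table, metric = "GlobE", n_perm = 1000, seed = 3)
cmp$p

asym <- compare_hemispheres(ds$table, "g1", n_boot = 1000, seed = 4)
asym
```

## Known limitations

* Binary, undirected graphs only; no weighted or partial-correlation
  variants.
* Group networks mean there is one network per group — individual-level
  covariates cannot be adjusted for within this framework.
* The bootstrap laterality test is approximate; its null calibration is
  verified in simulation, not derived.
* Registration, skull stripping and scanner harmonization are out of
  scope: volumes are assumed pre-registered to a common space.
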