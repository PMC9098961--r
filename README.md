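# mcnet — metabolic covariance brain network analysis

`mcnet` is an R package for group-level **metabolic covariance network**
analysis of regional FDG-PET intensities, for researchers studying how
brain glucose metabolism is functionally organized in patient and control
groups. It implements the complete pipeline: regional mean-intensity
extraction from labelled volumes, inter-regional Pearson correlation
networks per group, sparsity-sweep graph theory with small-world null
models, betweenness-based hub detection, permutation inference with FDR
correction, and hemispheric laterality analysis — together with a
synthetic-data generator with planted ground truth used to validate every
stage.

## The model in brief

For a group of subjects, the connection between regions *i* and *j* is
the Pearson correlation of their mean regional intensities across the
group's subjects:

    r_ij = Σ_s (x_si − x̄_i)(x_sj − x̄_j) /
           √( Σ_s (x_si − x̄_i)² · Σ_s (x_sj − x̄_j)² )

One symmetric 90×90 network per group (45 regions per hemisphere in the
default parcellation). Networks are binarized over a 5–50% sparsity sweep
(equal edge counts across groups) or at an absolute cutoff r > 0.5, and
characterized by characteristic path length (L), clustering (C), global
and local efficiency (GlobE, LocE), betweenness centrality (BC), and the
small-world indices γ = C/C_rand, λ = L/L_rand, σ = γ/λ against 100
degree-preserving rewired null graphs per sparsity. Hubs are regions with
BC above the group mean + SD. Group differences in metric AUCs over the
sweep are tested by label permutation (networks rebuilt inside every
permutation) with Benjamini–Hochberg FDR across regions.

## Worked example

```r
library(mcnet)

spec <- synth_spec(seed = 1)     # two groups of 17 subjects, 90 regions,
ds   <- simulate_dataset(spec)   # modular planted covariance
ds$table
#> Regional intensity table: 34 subjects x 90 regions
#> Groups: g1 (n=17), g2 (n=17)
#> Regions: roi001.L, roi001.R, roi002.L, roi002.R, ...

net <- covariance_network(ds$table, "g1")
net
#> Metabolic covariance network [g1]: 90 regions, n = 17 subjects
#>   r: median 0.150, range [-0.590, 0.945], 729 pairs with r > 0.5

round(metric_sweep(net)$auc, 4)  # AUC of each metric over 5-50% sparsity
#>      L      C  GlobE   LocE
#> 1.0482 0.3241 0.2418 0.3796

small_world_sweep(net, n_null = 20, seed = 2)
#> Small-world sweep [g1]: 46 sparsity points, 20 nulls each
#>   grid means: gamma = 3.055, lambda = 1.247, sigma = 2.346

compare_global(ds$table, metric = "GlobE", n_perm = 200, seed = 3)
#> Permutation test (global): GlobE AUC, g1 - g2
#>   observed difference = -0.0215, p = 0.0547 (200 permutations)
```

Reading the output: the planted modular covariance produces a clustered
network whose clustering far exceeds its rewired nulls (γ ≈ 3.1) at near
null-like path length (λ ≈ 1.2), hence σ ≈ 2.3 — a small-world topology,
as expected for a modular generative structure. The two groups here are
drawn from the *same* spec, and the permutation test correctly finds no
significant GlobE difference (p ≈ 0.05 boundary noise at 200
permutations).

`run_pipeline(table, out_dir, seed = ...)` executes every stage and
writes networks, sweeps, small-world profiles, hub sets, comparisons and
laterality results as CSV/TSV; a fixed seed reproduces all files
bit-identically.

See `vignettes/metabolic-covariance-networks.Rmd` for the model,
parameter and design documentation.

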