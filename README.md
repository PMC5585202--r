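# annet — anatomical network analysis of musculoskeletal systems

`annet` implements the Anatomical Network Analysis (AnNA) workflow for
comparative anatomy: it models a musculoskeletal system — for example a
primate forelimb — as a simple undirected graph whose nodes are bones and
muscles and whose links are physical contacts (articulations, attachments),
and then quantifies the organization of that graph so it can be compared
across species. It is aimed at morphologists and evolutionary biologists who
code anatomy as binary adjacency matrices and want reproducible network
statistics, module detection, and phylogenetic comparative tests on top of
them.

## What it computes

**Network parameters.** For a network with `N` nodes and `K` links:
density `D = 2K / (N(N−1))` (complexity), mean local clustering coefficient
`C` (integration), characteristic path length `L` (effective proximity of
parts, links as unit distances), and degree heterogeneity
`H = sd(k)/mean(k)` (anisomerism), via `network_parameters()`.

**Connectivity modules.** Walktrap community detection (Pons–Latapy random
walks, default `t = 3`, hand-implemented with deterministic tie-breaking),
scored with Newman–Girvan modularity

    Q = Σ_m ( e_m / K − (d_m / 2K)² )

with a delete-one-link jackknife standard error of `Q` and a one-sided
per-module Wilcoxon rank-sum test of internal versus external connections
(`walktrap_modules()`, `jackknife_q_se()`, `module_wilcoxon()`).

**Phylogenetic signal and ancestral states.** Network parameters as tip
traits on a time-calibrated tree: Pagel's λ by profile maximum likelihood
with a likelihood-ratio p-value, Blomberg's K with a seeded tip-permutation
test, and Brownian-motion ancestral state reconstruction with 95% CIs plus
phenogram (time × trait) export (`fit_pagel_lambda()`, `blomberg_k()`,
`ancestral_states()`, `phenogram_export()`).

**Synthetic data.** A limb-like network generator with planted modules
(bone scaffold with digit rays, muscles attached within/between regions
with `p_in`/`p_out`), pure-birth tree simulation, and Brownian trait
simulation, so the whole pipeline is testable without any dissection data
(`generate_limb_network()`, `generate_yule_tree()`, `simulate_bm()`).

`run_full_pipeline()` ties these together over a set of adjacency CSVs and
an optional Newick tree, writing a per-taxon parameter table (Taxa, N, K,
D, C, L, H, M), module reports (JSON + CSV), a phylogenetic-signal table
and phenogram segment files.

## Worked example

```r
library(annet)

out <- generate_limb_network(limb_config(seed = 42))
network_parameters(out$network)
#>                   taxon   N   K          D         C        L         H
#> 1 synthetic_limb_seed42 100 432 0.08727273 0.2426752 2.512929 0.2702094

part <- walktrap_modules(out$network)
part
#> module partition: M = 5, Q = 0.5685 (jackknife SE 0.0203)
#>  module size internal external   wilcoxon_p
#>       1   20       65       41 1.895636e-07
#>       2   20       65       44 5.473615e-08
#>       3   20       69       33 3.134427e-08
#>       4   20       69       38 3.658678e-08
#>       5   20       64       44 5.653564e-07

adjusted_rand_index(part$assignment, out$truth)
#> [1] 1
```

The generator planted five anatomical regions; walktrap finds exactly five
modules (`M = 5`) at modularity `Q = 0.57` — inside the 0.3–0.7 band
typical of strongly modular networks — each module's internal links
dominate its external ones (Wilcoxon p ≪ 0.05), and the detected partition
matches the planted truth perfectly (adjusted Rand index 1).

On the phylogenetic side, with a simulated 22-tip tree and a Brownian
trait:

```r
tree <- generate_yule_tree(22, birth_rate = 1, seed = 1)
x <- simulate_bm(tree, sigma2 = 1, root = 0, seed = 2)
fit_pagel_lambda(x, tree)
#> phylogenetic signal (Pagel's lambda): estimate = 1.0000, p = 3.242e-10 (n = 22)
blomberg_k(x, tree, n_perm = 1000, seed = 3)
#> phylogenetic signal (Blomberg's K): estimate = 1.8203, p = 0.000999 (n = 22)
```

Both statistics recover the Brownian regime they were simulated under
(λ ≈ 1; K near/above 1 with a significant permutation p).

The package also ships the published summary table of forelimb network
parameters for 22 taxa (19 primate genera + 3 outgroups) for consistency
checks and group comparisons:

```r
tab <- forelimb_parameter_table()
s <- summarize_group(tab, "group")
subset(s$summary, parameter == "H")[, c("group", "n", "mean", "sd")]
#>            group n      mean         sd
#>       outgroup 3 0.9296667 0.08394244
#>  strepsirrhine 4 0.9215000 0.01811997
#>        tarsier 1 0.9310000         NA
#>            NWM 4 0.9130000 0.01437591
#>            OWM 4 0.9407500 0.01247330
#>       hominoid 6 0.8230000 0.05688233
```

Hominoids have the lowest mean heterogeneity (0.823), the published
contrast with non-hominoid primates.

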