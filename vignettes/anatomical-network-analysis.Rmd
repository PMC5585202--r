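---
title: "Anatomical network analysis with annet: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anatomical network analysis with annet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annet)
```

## The model

Anatomical network analysis (AnNA) treats a musculoskeletal system as a
simple, undirected, unweighted graph: bones and muscles are nodes, and any
physical contact between two structures — an articulation between bones, or
the attachment of a muscle onto a bone — is a link. The model deliberately
discards geometry (size, shape, position) and keeps only the topology of
contacts, so it complements morphometric analyses of covariation rather than
replacing them. Ligaments, vessels and nerves are outside the node set by
construction; `annet` enforces the two-class bone/muscle typing and rejects
self-contacts, directed links and weights at the data layer.

Networks enter the package as square binary adjacency matrices
(`read_adjacency_csv()`): identical row and column labels, cells in {0, 1},
zero diagonal, exact symmetry. Any violation is a hard error naming the
offending cell, because silently symmetrizing or thresholding a coding error
would corrupt every downstream statistic. Tissue classes come from
`"bone:"`/`"muscle:"` label prefixes or a side-car table; label matching is
whitespace- and case-tolerant because hand-coded matrices rarely agree on
either.

## The six network parameters

For a network with $N$ nodes and $K$ links, `network_parameters()` reports:

* **Density** $D = 2K / (N(N-1))$ — the fraction of possible contacts that
  are realized; a proxy for anatomical complexity.
* **Clustering coefficient** $C$ — the mean over nodes of the local
  coefficient $c_i = 2t_i / (k_i(k_i-1))$, where $t_i$ counts links among
  node $i$'s neighbours; a proxy for local integration. Nodes of degree
  below 2 have no defined $c_i$; the default counts them as 0
  (`low_degree = "zero"`), which keeps $C$ defined on every network, and the
  alternative of dropping them is exposed because published summary tables
  do not record which convention produced them.
* **Characteristic path length** $L$ — the mean shortest-path distance over
  unordered pairs, each link one unit; a proxy for effective proximity of
  parts. A disconnected network is an error, not an `Inf` silently averaged
  away: path length has no agreed meaning across components.
* **Heterogeneity** $H = \mathrm{sd}(k) / \mathrm{mean}(k)$ — the
  coefficient of variation of the degree sequence; a proxy for anisomerism
  (how differentiated serially arranged parts are). The prose definition of
  this parameter in the comparative literature (sd/mean) conflicts with the
  tabulated one (variance/mean); `annet` defaults to sd/mean with the
  population (divide-by-$N$) standard deviation, and exposes the sample
  estimator via `sd_type = "sample"`. Neither choice can be discriminated
  against published tables without the underlying matrices, which is why
  both are kept.

Report tables round to three decimals half-away-from-zero
(`round_half_up()`), the behaviour implied by published densities such as
$490/9702 = 0.0505 \rightarrow 0.051$; base R's round-half-even would print
0.050.

## Module detection

Connectivity modules — groups of structures more densely linked among
themselves than to the rest of the limb — are found with the walktrap
algorithm (`walktrap_dendrogram()`): short random walks tend to stay inside
the walker's module, so the $t$-step walk profile of a node characterizes
its module. The implementation follows the Pons–Latapy formulation: a
self-loop is added to every node (the lazy, aperiodic walk of the reference
implementation), node distance is the degree-weighted Euclidean distance
between rows of $P^t$, and communities merge greedily — adjacent pairs only
— by minimal Ward-style increase $\Delta\sigma$ in within-community squared
distance, with ties broken toward the lowest community indices so results
are reproducible. The default $t = 3$ is appropriate for ~100-node
anatomical networks; it is an argument, not a constant. The merge heights
reported are cumulative $\Delta\sigma$, hence non-decreasing.

`best_partition()` evaluates Newman–Girvan modularity

$$Q = \sum_m \left( \frac{e_m}{K} - \Big(\frac{d_m}{2K}\Big)^2 \right)$$

at all $N$ cut levels of the dendrogram and keeps the maximum, breaking ties
toward fewer modules. Strongly modular networks typically score
$Q \in [0.3, 0.7]$; the synthetic limb networks below land in 0.52–0.62.

Two inferential companions:

* **Jackknife SE of Q** (`jackknife_q_se()`): every link is treated as an
  independent observation; each is deleted in turn and $Q$ of the *same*
  partition is recomputed. The partition is held fixed deliberately:
  re-running detection after each deletion would change the statistic being
  resampled and make the link-as-observation logic incoherent. The
  re-detection variant exists behind `redetect = TRUE` for comparison.
  Deleting a bridge may disconnect the network, but $Q$ needs only link and
  degree counts, so no special-casing is required.
* **Per-module Wilcoxon test** (`module_wilcoxon()`): for each node of a
  module, its internal and external link counts form the two samples of a
  one-sided rank-sum test of "internal > external". We read "internal vs.
  external connections of every module" as per-node counts — the
  alternative, pooling links, has no natural second sample. For combined
  sample sizes up to 20 the permutation null of the rank sum is enumerated
  exactly (count data are full of ties, and the exact enumeration is valid
  under ties, unlike the textbook exact Mann–Whitney distribution); larger
  modules use the tie-corrected normal approximation. Singleton modules are
  reported as `NA` — not testable — rather than $p = 1$.

### A known limitation, quantified

Walktrap is a heuristic restricted to the $N$ partitions on its dendrogram.
On small random connected graphs (4–8 nodes, where the global maximum-$Q$
partition can be found by enumerating all set partitions), the best
dendrogram cut attains the global optimum in roughly 72–80% of cases
depending on edge density — and the reference igraph implementation returns
*identical* partitions and the same rate, so this is a property of the
algorithm, not of this implementation. On modular networks (the regime the
method is meant for) the best cut recovers the planted structure reliably;
see the recovery results below.

## Phylogenetic comparative layer

Network parameters become tip traits on a user-supplied time-calibrated tree
(any Newick with branch lengths; the package deliberately ships no real
primate phylogeny and generates its own test trees).

* **Brownian-motion machinery.** `bm_covariance()` builds the BM tip
  covariance (shared root-to-MRCA path lengths) by accumulating edge
  lengths over descendant tip sets. `fit_bm()` uses the closed-form GLS/ML
  estimates $\hat\mu = (1'C^{-1}x)/(1'C^{-1}1)$,
  $\hat\sigma^2 = (x-\hat\mu)'C^{-1}(x-\hat\mu)/n$, via Cholesky solves.
* **Pagel's λ** (`fit_pagel_lambda()`) scales the off-diagonal covariances;
  the profile likelihood is maximized over $[0, 1]$ by bounded 1-D
  optimization at tolerance $10^{-8}$, with the interval ends checked
  explicitly. The p-value is a likelihood-ratio test against $\lambda = 0$
  on $\chi^2_1$. At the $\lambda = 0$ boundary the plain $\chi^2_1$
  convention is the default — matching the standard comparative-methods
  software, so p-values are comparable with the literature — and the 50:50
  boundary mixture is available via `boundary = "mixture"`. λ is capped at
  1 by default: values above 1 are only defined while the transformed
  covariance stays positive definite, and near that boundary the likelihood
  surface degenerates.
* **Blomberg's K** (`blomberg_k()`) is the observed $MSE_0/MSE$ ratio over
  its BM expectation $(\mathrm{tr}(C) - n/\Sigma_{ij}(C^{-1})_{ij})/(n-1)$.
  Significance comes from tip-label permutations: signal makes the GLS
  $MSE$ small, so $p$ is the fraction of permutations with $MSE$ at most
  the observed, the observed arrangement counted among them (hence
  $p \ge 1/(n_{perm}+1)$). The seed is a required argument so reported
  p-values are reproducible; permutations are evaluated by vectorized
  matrix algebra, which keeps 1000 permutations cheap even across
  thousands of simulated tests.
* **Ancestral states** (`ancestral_states()`) are the GLS/ML estimates
  $\hat\mu + w_a'V^{-1}(x - \hat\mu)$ at each internal node, with variance
  including the root-estimate uncertainty term and a 95% CI of
  $\pm 1.96$ SD; estimates agree with the standard re-rooting ML
  implementation to $10^{-8}$, CIs differ only in the variance convention.
  The phenogram export writes each branch as a straight segment in
  (time-from-root, trait) space plus the tip-value quartiles for the
  side box plot.

Taxon names are matched between trees and trait tables case-insensitively
with underscores treated as spaces, with a genus-only fallback that warns —
hand-curated comparative tables and Newick files almost never agree on
spelling conventions.

## What the synthetic data emulate — and what they do not

`generate_limb_network()` produces limb-like networks with planted ground
truth: serially ordered regions (proximal to distal) whose bones form
chains joined by one articulation per adjacent pair, the terminal region
branching from a base bone into up to five digit-like rays; muscles attach
to structures of their own region with probability `p_in` per candidate and
to other regions with `p_out`, including muscle–muscle (fascial) contacts,
and every muscle is guaranteed at least two bone attachments (origin and
insertion) by resampling. The defaults — 5 regions of 4 bones + 16 muscles,
`p_in = 0.3`, `p_out = 0.02` — give connected 100-node networks, inside the
90–110-node range of real forelimb musculoskeletal networks, with five
planted modules that walktrap recovers at adjusted Rand ≥ 0.9 in 50/50
seeds in the shipped tests.

What the generator does *not* emulate: real link counts (the defaults give
~450 links, several times denser than a dissected forelimb network at
~220); anatomically heterogeneous module sizes (real distal-limb modules
are smaller and more variable than proximal ones); any particular taxon's
matrix; and biomechanical constraints. Passing recovery tests on these
networks therefore shows that the detection machinery works where planted
structure exists at realistic scale — not that any particular dissection
dataset will yield the same modules.

`generate_yule_tree()` simulates a pure-birth tree forward in time
(exponential waiting times, uniformly chosen splitter, a final interval so
tips are contemporaneous), and `simulate_bm()` evolves traits by preorder
recursion (λ = 1) or a joint multivariate-normal draw on the λ-transformed
covariance (λ < 1). Both require an explicit seed.

## Problem sizes used in the shipped tests

The test suite chooses sizes that exercise each property at meaningful
scale while keeping a full run in a couple of minutes: 50 random graphs of
up to 60 nodes for the brute-force clustering/path-length oracles; 100
connected random graphs of 4–8 nodes for the exhaustive set-partition
comparison; 50 generator seeds for module recovery; 100 replicates each for
λ recovery on 64-tip trees, 200 for Blomberg's K, 200 for BM-rate recovery
on 128-tip trees, and 1000 runs for the permutation test's type-I error.
The same computations, re-derived from scratch, back the quantities in
`scripts/acceptance.R`.

## Worked example

```{r example, eval = FALSE}
out <- generate_limb_network(limb_config(seed = 42))
network_parameters(out$network)
part <- walktrap_modules(out$network)
part
adjusted_rand_index(part$assignment, out$truth)

tree <- generate_yule_tree(22, birth_rate = 1, seed = 1)
x <- simulate_bm(tree, sigma2 = 1, root = 0, seed = 2)
fit_pagel_lambda(x, tree)
blomberg_k(x, tree, n_perm = 1000, seed = 3)
```

## Known limitations

* Walktrap's dendrogram need not contain the maximum-modularity partition
  (quantified above); module *counts* can also differ between
  implementations on near-tie cuts, so cross-study comparisons should rest
  on the module compositions and Q, not on M alone.
* The Wilcoxon module test treats per-node counts within a module as
  independent, which network data only approximate.
* λ is profiled on $[0, 1]$; trees whose structure genuinely supports
  λ > 1 are reported at the cap.
* The permutation p-value for K is discrete; with few permutations it is
  conservative by construction.
* The package reads any user-supplied calibrated tree but performs no
  dating or tree inference, and reproducing published λ/K values for real
  taxa requires the original calibrated phylogeny those studies used.
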