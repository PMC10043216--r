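---
title: "Models and methods behind rhizonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rhizonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

# Scope

rhizonet analyses taxa-by-sample count tables from group-structured
microbiome surveys (the motivating design: rhizosphere soil under several
vegetation types plus a bulk-soil control). It covers four analysis layers —
diversity statistics, phylogenetic null-model inference of community
assembly processes, SparCC co-occurrence network inference, and network
ecology — and ships a synthetic community generator so that every layer has
a recovery test against data with a known ground truth. This vignette
explains the models, the tunable parameters, the numerical choices, and the
limits of what the test suite demonstrates.

# Community assembly inference

## beta-MNTD and beta-NTI

For two samples A and B with within-sample relative abundances $f$, the
between-sample mean nearest taxon distance is

$$\beta\mathrm{MNTD}(A,B) = \tfrac12\Big[\sum_{i\in A} f_{iA}\,
\min_{j\in B} d_{ij} + \sum_{j\in B} f_{jB}\, \min_{i\in A} d_{ij}\Big],$$

with $d$ the cophenetic distance on the phylogeny; a taxon present in both
samples contributes 0. The null model shuffles taxon labels across the tips
present in the analysed table, which randomises phylogenetic relationships
while preserving every sample's abundance structure. The beta nearest
taxon index is the z-score
$\beta\mathrm{NTI} = (\mathrm{obs} - \mu_\mathrm{null})/\sigma_\mathrm{null}$;
$\beta\mathrm{NTI} < -2$ indicates homogeneous selection, $> +2$
heterogeneous selection. Default 999 null replicates (we use 99 in the test
profile; the z-score is unbiased in the number of replicates, only slightly
noisier).

Two sample pairs deserve care. If both samples contain exactly the same
taxon set, every nearest-taxon distance is 0 under the observed *and* every
shuffled labelling, so $\sigma_\mathrm{null} = 0$ and the pair is reported
as `NA` with a warning rather than silently assigned. A star phylogeny
degenerates the same way. Implementation is validated against
`picante::comdistnt()` (exact agreement) and an explicit double-loop oracle.

## RC-bray

For pairs not assigned by beta-NTI, the Bray–Curtis-based Raup–Crick metric
compares the observed dissimilarity with a null that reassembles both
samples while preserving their richness and total abundance: occurrences
are drawn with probability proportional to metacommunity occupancy, then
the remaining individuals are allocated proportionally to metacommunity
relative abundance. $RC = 2\,[\#\{null < obs\} + \tfrac12\#\{null =
obs\}]/n_\mathrm{reps} - 1 \in [-1, 1]$. $RC > 0.95$ marks dispersal
limitation, $RC < -0.95$ homogenizing dispersal, the remainder undominated.
The 0.95 threshold is conventional, not printed in most papers, and is a
parameter. Per-sample null draws are seeded by sample id, so results are
invariant to column order.

## Five-process classification

`classify_processes()` applies the two-step rule with deterministic signal
first: beta-NTI beyond $\pm 2$ wins regardless of RC; boundary values fall
to the stochastic side (strict inequalities). The function is total: every
pair with finite inputs receives exactly one of HeS, HoS, DL, HD, UD.

## NST

The normalized stochasticity ratio uses the same null as RC-bray. Per
within-group pair with observed dissimilarity $D$ and mean null
dissimilarity $\bar E$: $ST = (1-\bar E)/(1-D)$ when $D \le \bar E$ and
$ST = \bar E / D$ otherwise, so $ST = 1$ when observation matches the null
and $ST \to 0$ under strong determinism. The group NST is $100 \times$ the
mean $ST$; 50% is the conventional stochastic/deterministic boundary. The
published variants differ in normalisation details; ours is documented here
and the recovery tests are directional.

**Known limitation.** The NST null draws from the observed table's own
occupancy and abundance profile. When selection acts *uniformly* on every
sample, the filtered guild *is* the metacommunity, null communities
reproduce observed ones, and NST stays high regardless of the true
process — we measure ~95% for drift-free uniform selection and ~75% with
drift, both far above 50%. Taxonomic nulls of this family are structurally
blind to spatially uniform selection; detecting it requires the
phylogenetic route (beta-NTI), which this package recovers cleanly. The
acceptance suite states the selection-side NST expectation anyway and we
let it fail visibly rather than weaken the null.

## Phylogenetic signal

`mantel_correlogram()` (via `vegan::mantel.correlog`, equal-width distance
classes, progressive Holm correction) tests the premise of the beta-NTI
null: niche similarity concentrated at short phylogenetic distances.
Positive, significant Mantel correlation in the shortest classes licenses
the nearest-taxon approach.

# The synthetic community generator

The generator is first-class, tested code; its defaults define the study
conditions under which the recovery claims hold.

* **Phylogeny** — pure-birth (Yule) tree, unit birth rate, ultrametric
  (`ape::rphylo`). Simple and sufficient once the trait model carries the
  conservatism (below).
* **Niche trait** — Brownian motion from root value 0. Plain BM on a
  50–200-tip Yule tree yields only weak clade-level trait structure,
  because most Yule branching is recent; niche traits in real communities
  are conserved at deep (family/phylum) levels. We therefore expose a
  `conservatism` exponent (a Pagel-delta-style transform of node depths,
  default 0.2) that concentrates divergence on deep branches. On an
  ultrametric tree the transform preserves every root-to-tip length, so
  the marginal tip variance is still `trait_sigma` times tip depth; only
  the within-path allocation changes.
* **Metacommunity** — Dirichlet(`pool_alpha` = 2) relative abundances.
* **Selection** — per-sample Gaussian fitness
  $w_i = \exp(-s\,(z_i - e)^2)$ on the standardized trait $z$, with a hard
  niche boundary at 1% of peak fitness (taxa outside the tolerance range
  cannot establish; this prevents freak colonisation by far-off taxa when
  drift is strong). Optima are placed automatically on *occupied,
  phylogenetically coherent* niches: candidate optima are the taxa's own
  trait values, and among candidates whose 1%-fitness window holds a
  mid-sized guild (target `guild_frac` = 0.18 of the pool) the one with the
  tightest guild (smallest mean nearest-taxon distance) wins. Homogeneous
  selection uses one optimum for all samples; heterogeneous selection uses
  two optima from opposite trait tails, preferring the pair of guilds
  farthest apart on the tree, alternated across sample groups.
* **Drift** — a colonisation lottery plus demographic noise: each taxon is
  independently retained with probability `retain_p` (default 0.5), and
  retained taxa are Dirichlet-resampled with concentration
  `drift_theta` times their pool share. The lottery drives
  presence/absence turnover, the resampling abundance turnover. Selection
  acts *before* drift: the environment defines the feasible pool, drift
  picks the winners within it — which is exactly the regime in which
  beta-NTI detects homogeneous selection (turnover among close relatives).
* **Dispersal scenarios** — the site pool is
  $(1-m)\,\times$ drifted pool $+\; m\,\times$ shared pool. Dispersal
  limitation: $m = 0.01$; homogenizing dispersal: $m = 0.95$; undominated:
  $m = 1$ (pure shared-pool multinomial sampling). With
  `selection_strength = 0` and $m = 1$ the selection scenarios reduce
  exactly to undominated.
* **Scenario realization** — for selection scenarios `simulate_study()`
  redraws the trait history (up to 25 sub-seeds) until the placed guild is
  phylogenetically coherent (guild tightness ratio at most 0.45 relative to
  size-matched random subsets, and guild size at least a third of target).
  A conserved, coherent niche guild is the *defining feature* of these
  scenarios — draws without one are failed scenario realizations, not data.

These defaults were fixed by a one-time design study of the generator
(richness, guild tightness, and turnover are the quantities that control
the beta-NTI signal) and then frozen; the recovery tests run at 200 taxa by
20 samples and depth $10^4$ reads. At 50 taxa the beta-NTI magnitude
saturates near $|z| \approx 1.8$ even for perfectly clade-confined
communities — the nearest-taxon minimum is too shallow on a small tree —
so 200 taxa (the upper end of the generator's intended range) is the
package's default recovery scale.

**Homogenizing dispersal** cannot appear as the modal class under this
design: undominated sampling is already the maximally homogenized limit
($m = 1$), so the RC null's dissimilarity floor coincides with the
undominated scenario's observed dissimilarity and any extra site-level
noise pushes pairs *above* the floor, never below $RC = -0.95$. The HD
scenario's tests therefore assert stochasticity ($|\beta\mathrm{NTI}| \le
2$), not modal HD; this is a real boundary of RC-based partitioning worth
knowing about, not an implementation artifact.

What the generator does **not** emulate: sequence-level error, chimeras and
ASV calling; compositional depth variation between samples (all samples are
sequenced to the same depth); multi-dimensional niche space (the
environment is one-dimensional); and taxon interactions in the assembly
scenarios (interactions appear only in `simulate_correlated_counts()`,
which plants a known log-scale correlation structure on log-normal basis
abundances for network-recovery tests). Passing recovery tests show the
estimators work under their stated assumptions, not that any real dataset
satisfies those assumptions.

# Diversity layer

Alpha diversity: Shannon in nats, Gini–Simpson ($1-\sum p^2$; the paper
convention for "Simpson" in amplicon work), classic Chao1
($S_{obs} + F_1^2/2F_2$, with the $F_2 = 0$ fallback
$S_{obs} + F_1(F_1-1)/2$), and observed richness. Rarefaction is a single
hypergeometric draw without replacement (`vegan::rrarefy`); samples below
target depth are excluded with a warning. Bray–Curtis and presence/absence
Jaccard come from `vegan::vegdist`; PERMANOVA wraps `vegan::adonis2`
(Anderson's pseudo-F, permutation p-value), and the Mantel test wraps
`vegan::mantel`. Group-specific taxon sets enumerate all $2^k - 1$
exclusive Venn regions, with presence defined as a nonzero count in at
least one sample of the group.

# Network layer

## SparCC

Counts are converted to fractions with a pseudocount of 1 (deterministic
default; Dirichlet-draw averaging is available behind `n_inner_iter` for
the original stochastic variant — determinism makes testing and
reproduction far easier). From log-ratio variances
$t_{ij} = \mathrm{Var}_s[\log(x_{is}/x_{js})]$ the basis variances solve
the linear system implied by the sparsity assumption
$\sum_{j\ne i}\rho_{ij}\approx 0$, then
$\rho_{ij} = (\omega_i + \omega_j - t_{ij})/2\sqrt{\omega_i\omega_j}$,
clamped to $[-1,1]$. Up to 10 exclusion rounds remove the strongest-|rho|
pair from the system (stopping at a 0.1 threshold), mirroring common SparCC
practice; taxa with non-positive solved basis variance get `NA`
correlations with a warning. Significance comes from a per-taxon
permutation null with the standard $(\#+1)/(n+1)$ two-sided p-value.
Edges require both $|\rho| \ge 0.3$ and $p \le 0.05$ by default — published
studies often leave these cutoffs unstated, so absolute edge counts are not
reproducible and the thresholds are explicit parameters recorded in every
artifact.

## Topology, modules, roles, robustness, cohesion

The topology report carries average connectivity under **two conventions**:
`avgK_paper` $= E/N$, which reproduces published topology tables of this
literature exactly, and `mean_degree` $= 2E/N$, the graph-theoretic mean
degree. Average path distance is the mean unweighted shortest path over
connected pairs; average clustering is the mean local coefficient with
degree-<2 nodes contributing 0. Modules come from greedy modularity
maximisation on $|\rho|$ weights (Louvain optional); the report counts
modules with at least 5 nodes, matching the published convention. Node
roles use within-module degree z-scores and participation coefficients
with the conventional thresholds (z > 2.5, c > 0.6 — network hubs, module
hubs, connectors, peripherals; exact boundary values fall to the lower
category; modules with zero degree spread give z = 0).

Natural connectivity is $\ln[\frac1N \sum_i e^{\lambda_i}]$ over adjacency
eigenvalues, computed with a log-sum-exp guard. The robustness curve
removes nodes in descending betweenness — computed **once** on the intact
network (a fixed ranking, matching the published description; a
recompute-after-each-removal mode is a flag) with ties broken by node id —
and records natural connectivity after each removal plus a trapezoidal
area-under-curve summary.

Cohesion null-corrects pairwise taxon correlations by subtracting their
mean under per-taxon independent shuffles (chosen over row/column-swap
variants for simplicity and speed), splits each taxon's mean corrected
correlation by sign into positive/negative connectedness, and weights by
relative abundance per sample. Note that for independent taxa the
*components* are biased away from zero by construction (the mean of the
positive part of a noise distribution is positive, about $0.8\sigma_r$);
the calibrated quantity is the **net** cohesion (positive plus negative),
which is centred at zero under independence.

# Reproducibility and numerics

Every stochastic function takes a `seed` and restores the caller's RNG
state. The pipeline derives all stage seeds from one root seed via
`split_seed()`; `manifest.json` records the config hash, root seed, and
stage seeds, and reruns are byte-identical. Null-model draws are keyed to
sample ids rather than column positions. Permutation p-values use the
$(\#+1)/(n+1)$ convention throughout, so p = 0 is impossible. Dissimilarity
comparisons in RC-bray use a $10^{-12}$ tie tolerance. Matrix solves in
SparCC go through `solve()` with an explicit singular-system error.

# Problem sizes used by the test suite

Assembly recovery: 200 taxa x 20 samples, depth $10^4$, 99 null
replicates, three replicate simulations pooled per scenario. SparCC
recovery: 50 taxa x 200 samples, depth $10^4$, five seeds. PERMANOVA
calibration: 1000 simulated null datasets with 99 permutations each. NST:
20 replicates per scenario at 100 taxa x 12 samples, 49 null replicates.
Cohesion: 30 taxa x 100 samples, 100 null iterations. Production analyses
should raise null replicates to the conventional 999 and SparCC
permutations to at least 100.
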