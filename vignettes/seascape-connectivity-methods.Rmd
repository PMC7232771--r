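---
title: "Methods: biophysical connectivity and population-genetic concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biophysical connectivity and population-genetic concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, the parameters that
matter, the numerical choices behind them, and what the synthetic study
systems do and do not establish about real data.

## The inference chain

The package connects two independent descriptions of a coastal seascape and
asks whether they agree:

1. **Physics.** A current field advects passive propagules released from
   shallow habitat; the settled fractions form a normalized connectivity
   matrix `M`, accumulated over generations as the stepping-stone sum
   `S_G = Σ_{g≤G} M^g` and screened for dispersal barriers.
2. **Genetics.** Diploid biallelic genotypes grouped into site samples are
   summarized as pairwise Weir–Cockerham `F_ST`, diversity (`He`, `F_IS`)
   and exact genic tests.
3. **Concordance.** Mantel permutation tests of `F_ST` against the
   symmetrized, log-transformed `S_G`; isolation-by-distance regressions
   split by flagged (isolated) sites; and `He ~ environment` multiple
   regression with collinearity screening.

Because the chain is exercised on synthetic seascapes with genotypes
simulated *from the tracked connectivity itself*, the package can test
parameter recovery end to end: structure put in through dispersal must be
recovered by the genetic statistics.

## The seascape and current model

A `SeascapeGrid` is a planar grid of square cells (no spherical correction:
the domain is abstract, a few hundred km across at most) with a land mask,
mean depth, and habitat defined as sea shallower than 30 m — the depth
envelope of the shallow vegetated habitat the target organisms occupy.
Cells are indexed by R's native 1-based column-major linear index; cell
`(ix, iy)` has its center at `((ix − 0.5)·c, (iy − 0.5)·c)` for cell size
`c` (km).

Current fields are sums of analytic streamfunction components (Gaussian
gyres, solid-body rotation, zonal jets, uniform drift, smoothed random
eddies) differenced centrally at cell centers, so the discrete divergence of
interior flow vanishes identically — particle ensembles are neither
artificially concentrated nor dispersed by numerics. Velocities are zeroed
on land. The field is stationary: monthly releases inside the reproductive
window (April–September by default) differ only in their seeded sub-cell
release jitter. Real shelf seas have seasonally varying circulation;
representing the season by one climatological surface field is the main
physical simplification, and it means release-month effects are not
resolvable here.

## Particle tracking and settlement

Trajectories use fixed-step RK4 (default `dt` = 3600 s) with bilinear
velocity interpolation, for a dispersive-phase duration of 5 days — a
drift-duration hypothesis appropriate for a brooding rafter with no larval
stage, not a measured trait. Numerical checks: halving `dt` moves endpoints
by < 1e-6 relative on smooth fields, and solid-body orbits conserve radius
to < 1e-3 over the full drift.

Boundary and settlement rules are the simplest that conserve particles:

* a step ending on land is cancelled (stick-in-place) — unbiased in
  direction, no reflection geometry to tune;
* a step ending outside the open boundary marks the particle LOST;
* a particle ending in habitat settles there; ending in sea but non-habitat
  it snaps to the nearest habitat cell among the 8 neighbours, else LOST.

`settled + lost = released` holds per source cell by construction and is
asserted in the tests. Desk-scale defaults (50 particles/cell/release, 6
monthly releases) put Monte-Carlo noise per matrix entry near
`3/√n ≈ 0.17`; the tests size their assertions to that bound.

## Connectivity algebra

`S_G` is computed by iterated multiplication and kept in two forms: the raw
sum, whose rows total exactly `G` for lossless row-stochastic matrices, and
the elementwise cap at 1, the default downstream because the quantity is
interpreted as a dispersal probability. Whether a stepping-stone sum should
be capped or renormalized per generation is genuinely open; producing both
and recording the flag was the package's resolution. `G = 64` spans
basin-scale stepping-stone dispersal at a few tens of km per generation.
Site-level matrices average the cell-level matrix over each site pair's
cell sets.

## Barrier clustering

Clustering is deterministic greedy agglomeration: starting from singletons,
repeatedly merge the cluster pair with the largest mean crossing probability
(mean of the symmetrized matrix over the cross block) while that maximum
exceeds the threshold `θ`; ties break on the smallest pair of cluster ids.
On return, every residual inter-cluster mean is ≤ `θ`, so boundaries are
partial barriers, and the cluster count is monotone non-decreasing in `θ`
(the default grid is {0.001, 0.002, 0.003}).

The exhaustive-search counterpart — the finest partition whose inter-cluster
means all satisfy `θ` — is well posed only when within-cluster connectivity
is strong relative to `θ` times the block sizes; otherwise the optimum can
"dilute" one strong crossing inside a large, weakly connected cross-block, a
partition with no barrier meaning. The oracle tests therefore compare greedy
and exhaustive search on block-structured matrices (within-block ≥ 0.1,
n ≤ 8), where the optimum is provably unique and equals the block
partition; on unstructured random matrices greedy is a heuristic and can
merge one step further than the dilution optimum.

## The genotype simulator

A diploid Wright–Fisher stepping-stone model on the site demes. Each
generation, deme `j` draws a fraction `m` of its gamete pool from donors in
proportion to the *column-normalized incoming* connectivity — the directed
source→destination matrix must be converted to an immigration mixture, and
column normalization keeps the sampling well defined when rows lose mass to
open boundaries — and the rest locally; allele frequencies then drift by
binomial sampling of `2N` gametes. Ancestral frequencies are shared across
demes, uniform on [0.1, 0.9] to avoid immediate fixation. Loci are
independent; there is no mutation or selection, so the model cannot
represent linked selection, salinity adaptation, or mutation–drift balance —
only drift, migration and founder history. Missing data are optional uniform
masking (0.2 mimics an 80% call-rate dataset). A deme whose incoming
connectivity is all zero is treated as isolated, with a warning.

Calibration anchors the simulator to theory: on a finite island model the
multilocus Weir–Cockerham estimate lands within ±30% of
`1/(1 + 4Nm·d/(d−1))` (observed within a few percent at `d = 8, N = 100,
m = 0.05`, 500 loci, 300 generations).

The serial-founder option colonizes demes along an order, each founded from
its predecessor through a bottleneck. The defaults — 5 diploid founders,
5 generations between colonizations — were chosen so the per-step
heterozygosity ratio `(1 − 1/(2·founderSize)) / (1 − 1/(2N))^{−interval}`
is ≈ 0.92, a clear cumulative decline; with weak bottlenecks or long
intervals, post-colonization drift in the older demes cancels the founder
losses and the front leaves no gradient. No field estimates exist for any
of these demographic values; they are free parameters of the study system,
fixed once.

## Statistical estimators

* **FST**: Weir–Cockerham (1984) variance components `a, b, c` per locus
  (sample sizes, frequencies and heterozygote fractions per site), combined
  across loci as the ratio of averages `Σa / Σ(a+b+c)` over loci with ≥ 2
  called individuals in both samples. Estimates are not clamped — small
  negative values are information about sampling noise — except before MDS,
  where a true distance is required. The tests verify the closed forms
  against a nested-ANOVA oracle evaluated by explicit loops over allele
  copies, to 1e-10.
* **He**: Nei's unbiased `(2n/(2n−1))(1 − p² − q²)` per locus, averaged over
  all loci (monomorphic loci contribute 0). **FIS** = `1 − Ho/He` averaged
  over polymorphic loci; under exact Hardy–Weinberg proportions this is
  `1/(2n)`, not 0, because of the unbiased correction — the tests assert
  that value rather than pretending exactness.
* **Genic tests**: per-locus two-sided Fisher exact tests on 2×2 allele
  counts (fully enumerable for biallelic loci, so no Markov-chain
  approximation is needed), combined by Fisher's method under the declared
  assumption of independent loci.
* **MDS**: classical scaling (`stats::cmdscale`); variance explained is each
  positive eigenvalue's share; requested axes beyond the positive spectrum
  are truncated with a warning.
* **Mantel**: Pearson correlation of upper-triangle vectors; null from
  jointly permuting rows and columns of the second matrix; two-sided
  `p = (1 + #{|r*| ≥ |r|})/(nPerm + 1)` (default 9999 permutations, seeded).
  Side and permutation count are declared choices; the type-I error at
  α = 0.05 is verified at 0.05 ± 0.02 over 1,000 null replicates. A constant
  off-diagonal vector yields an explicit degenerate result rather than NaN.
* **He ~ environment**: predictors are screened iteratively — the highest
  VIF ≥ 3 is dropped until all pass — then OLS with marginal (drop-one)
  F tests, which are order-invariant, unlike sequential ANOVA. VIFs come
  from auxiliary regressions so exact collinearity maps to infinity instead
  of a matrix-inversion failure. In the 1-D colonization-corridor fixture,
  cumulative along-coast distance *is* the salinity axis (r ≈ −0.99), so
  that fixture's model omits distance; the 2-D demo pipeline keeps it.

## Problem sizes and reproducibility

The bundled study systems are desk-scale by design: the channel seascape has
94 habitat cells and 20 sites (16,920 particles per dispersal run), the demo
configuration ~200 cells and 25 sites, simulations use 10³ loci × 20
individuals × 20 demes × 200 generations, and the recovery analysis uses 20
replicates — sizes chosen so the full chain, including 9,999-permutation
Mantel tests, completes in minutes on one CPU while keeping Monte-Carlo
error well inside every asserted tolerance. Every stochastic stage draws
from its own seeded RNG stream (derived from the configuration seed), and
the pipeline manifest records parameters, seeds and artifact checksums, so
reruns are byte-identical.

## What the synthetic systems do and do not show

Passing tests demonstrate internal consistency (estimators match independent
oracles; simulations match closed forms) and end-to-end identifiability
(connectivity-driven structure is recovered by Mantel tests with correctly
calibrated error rates). They do not validate the biology of any real
system: the current fields are stationary cartoons, demography is free, and
selection, mutation, linkage and seasonal circulation are all absent. On
real data the package's role is the analysis layer — VCF + site metadata in,
connectivity matrices from whatever dispersal model is trusted — and the
synthetic layer is the harness proving that layer correct.
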