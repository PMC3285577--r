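---
title: "Reconstructing cell lineage trees from microsatellite mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cell lineage trees from microsatellite mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslineage)
```

## The measurement and the model

Microsatellites are short tandem repeats whose repeat count slips during DNA
replication. In a mismatch-repair-deficient mouse the slippage rate is high
enough that every mitotic division leaves a measurable trace across a panel
of ~81 intergenic loci. A single cell's *genomic signature* is its vector of
repeat-count deviations from the putative zygote, one entry per parental
allele (the two strains of the cross are chosen so the two alleles of every
locus differ substantially in size and are never confounded).

The mutation process is modelled as a **symmetric stepwise model**: each
division, each allele mutates with probability $\mu$ and, when it does,
steps $\pm 1$ repeat unit with equal probability. After $t$ divisions the
net change $\Delta$ of an allele is a binomially thinned lazy random walk:

$$P(\Delta = d \mid t) \;=\; \sum_{m \ge |d|,\; m \equiv d \,(2)}
  \binom{t}{m}\mu^m(1-\mu)^{t-m} \cdot \binom{m}{(m+d)/2} 2^{-m}.$$

`step_diff_pmf()` evaluates this by dynamic programming over (division, net
step) on the full lattice $|d| \le t_{\max}$, so entries carry no truncation
error; the table is cached per $(\mu, t_{\max})$. The suite checks the DP
against independent brute-force enumeration over mutation counts to 1e-12
and verifies normalization, symmetry, and strictly increasing variance in
$t$.

Assumptions worth keeping in mind: all alleles share one rate (no
locus-specific or length-dependent rates), steps are $\pm 1$ only, and
mutations are replication-coupled. The >2-allele diagnostic (below) is the
package's internal check on the last assumption.

## From signatures to trees and depths

* **Pairwise distances.** The number of divisions separating two cells is the
  integer $t \in [0, t_{\max}]$ maximizing the log likelihood of the
  observed per-allele differences, using only alleles observed in both cells
  (pairwise-complete; no imputation). Ties take the smallest $t$
  (parsimony). The two branch lengths are pooled into a single separation
  $t$ rather than estimated jointly; the likelihood depends on the pair only
  through their difference, so the pooled formulation loses nothing at this
  sample size.
* **Root.** The putative zygote's signature is the per-allele median over
  all sampled cells. It competes in neighbor joining as an ordinary taxon
  (`root_median`); the tree is then re-rooted at its attachment node and the
  pseudo-leaf removed, so the root sits at depth 0 by construction.
* **Tree.** Standard Saitou–Nei neighbor joining on the ML distance matrix
  (delegated to `ape::nj`); input labels are canonicalized by sorted cell id
  so reconstruction is deterministic.
* **Depth.** Root-to-leaf branch-length sums. Neighbor joining can emit
  small negative branch lengths; because depths are division counts these
  are clamped to zero at readout time only — the tree object and any Newick
  export keep the raw reconstruction.

A comparison estimator, `squared_distance_depth()`, returns the mean squared
deviation from the root over shared alleles; its expectation is $\mu \cdot
\mathrm{depth}$, so $1/\mu$ converts it to divisions. The benchmark
(`estimator_benchmark()`) measures bias and SEM of both estimators on
simulated trees of known depth.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `mu` | 1/30 | mutations / allele / division | ex-vivo calibration of the MMR-deficient panel; `estimate_mutation_rate()` re-derives it from known-depth cells, and `mutation_rate_sweep()` checks conclusions across 1/10–1/200 |
| `t_max` | 500 | divisions | upper bound of the ML search; generous for desk-scale depths (≤ ~50 divisions means separations ≤ ~100) even at assumed rates as low as 1/200 |
| `min_overlap` | 10 | shared alleles | below this the ML separation is noise-dominated; pairs under the floor are *undefined*, signalled distinctly from zero |
| `min_alleles` | 25 | alleles / cell | cells retained only if **more than** 25 alleles amplified (strict reading of the inclusion rule) |
| `dropout` | 0.325 | probability | whole-genome-amplification allelic dropout measured at 32.5 ± 5% |
| FDR `q` | 0.2 / 0.05 | — | 0.2 for data analyses, 0.05 in the simulation studies |

The rate is interpreted **per allele per division** (the two parental
alleles mutate independently). The source material quotes "1/30 divisions"
without fixing per-allele vs per-locus; the choice rescales absolute depth
by ~2× and is mitigated by the calibration operation, which recovers
whatever rate the generator used. Generator and estimator here share the
per-allele convention, so depth recovery is internally consistent and the
sweep invariance shows the downstream conclusions do not depend on it.

## Enrichment analysis

For every internal branch of a rooted tree, the leaves of the subtree below
it (the side away from the root) are tested for enrichment of a population
with the one-sided hypergeometric tail; all branch × population p-values of
a tree enter one Benjamini–Hochberg family (per-population families are
available by simply passing a single population's records). Nested
significant subtrees are pruned to the single most significant record (ties
keep the larger subtree). `clustering_detected()` reports whether anything
survives; `ovary_mixing_report()` applies the same machinery to left/right
labels on the oocyte-only induced subtree.

## What the simulator emulates — and what it does not

`sim_scenario()` fixes the study conditions: trees of depth `Td = 25`
divisions (45 in the deeper benchmark), lineage restriction of the focal
population to `Np` progenitors at division `Tr = 8`, `s = 30` cells per
population, 81 diploid loci, `mu = 1/30`, 32.5% dropout. Cells are sampled
lazily as `Td`-bit division paths constrained to progenitor prefixes;
ancestry of any subset is the longest-common-prefix tree, so the $2^{25}$
full tree is never materialized (the suite checks the sampler against an
explicit small-depth tree). Mutations are simulated *along the induced
tree*, so shared lineage segments carry shared mutations. Measurement adds
independent per-allele dropout, optional PCR repeat cells (same genotype,
independent dropout), and GV-stage multiallele events — spontaneous
mutations at the four-chromatid oocyte stage that surface as >2-allele loci,
are flagged, and are excluded from deviations exactly as the reading
pipeline requires.

Cohort modes: `static` (all ages sample depth-`Td` cells), `renewal`
(progenitors keep dividing post-natally at `renewal_rate = 2` divisions per
100 days — a rate that spreads median depth by ~7 divisions across a
27–365-day cohort, comparable to the depth differences the method is meant
to resolve), and `production_line` (a fixed birth-time depth distribution
spanning `pl_span = 10` divisions; each mouse samples its age-rank quantile
band, while pre-antral-age mice ≤ 14 days sample the full range). Migration
modes give the focal population left/right ovary labels from disjoint
(`coherent_migration`) or shared (`incoherent_migration`) progenitor pools.

Not emulated: spatial geometry of progenitor migration, hormone physiology
(only the depth consequence of ovariectomy-accelerated recruitment),
capillary signal processing, PCR stutter, locus-specific rates. Passing
tests therefore demonstrate statistical correctness of the machinery under
the stated generative model, not fidelity to every artefact of real
capillary data.

## Numerical choices and degenerate inputs

* Likelihood zeros are floored at the smallest positive double before
  taking logs; a floored allele contributes ~−708 per allele, far below any
  feasible likelihood, so the argmax is unaffected while −∞ × 0 pathologies
  are avoided.
* `estimate_mutation_rate()` scans a 60-point log-spaced grid on
  [1e−3, 0.5] and refines with `optimize()` between the flanking grid
  points; a maximum at the lower bound (no mutations anywhere) returns the
  bound with a warning.
* Median ties at even counts take the middle value **closer to zero**
  (`tie = "zero"`, with `lower`/`upper` available). A fixed-side rule is
  directionally biased, and with a strongly clonal sample it absorbs the
  founder haplotype of the majority clone into the root; the nearest-zero
  rule is the least-mutated root estimate consistent with the deviation
  sign convention.
* Permutation p-values use the $(1+b)/(1+m)$ estimator and never return 0.
* The production-line test reports both tails; `p` is the "smaller"
  direction (the fraction of simulated statistics below the observed one),
  with the statistic (median or max) chosen by argument since both readouts
  are meaningful.
* Deterministic tie-breaks: cells are sorted by id before distance-matrix
  construction; `which.max` takes the smallest maximizing $t$; nested
  pruning orders by (p, −subtree size).
* Degenerate inputs are signalled, not silently absorbed: pairs under
  `min_overlap`, constant medians in the depth–age correlation, missing
  pseudo-leaf at rooting, unrooted trees at Newick export, fewer than three
  oocytes per side in the mixing report.

## Known limitations

* **Median root under monoclonality.** The root signature is the median of
  *all sampled cells*. When a single clone makes up half the sample (the
  `Np = 1` corner of the progenitor study), the median absorbs much of the
  founder haplotype: the allele-wise middle value lands inside the clonal
  block whenever that clone's observations happen to outnumber the rest.
  In roughly 0.5–1% of such trees the root pseudo-leaf then attaches one
  node *inside* the focal clade, the clade straddles the root, and clade
  enrichment — which tests the leaf set away from the root — misses an
  otherwise perfect cluster. This is inherent to the median-rooting rule,
  not to the enrichment test; real polyclonal populations (the study's
  oocytes, with an inferred 3–10 progenitors) are far from this regime.
* **Robustness benchmark under ±1 signal errors.** A ±1 repeat error is
  statistically indistinguishable from a genuine stepwise mutation, so
  corrupting a fraction $f$ of alleles shifts *both* depth estimators
  upward by ≈ $f/\mu$ divisions: the squared-distance statistic exactly, the
  tree-ML readout slightly more through the nonlinear inflation of pairwise
  separations. Under this error model the benchmark does not reproduce a
  robustness advantage for the tree-ML estimator at any symmetric error
  magnitude we examined; on clean signals tree-ML is the less biased of the
  two. The error model itself (magnitude, fraction) is a configuration
  choice, not a measured property of capillary data.
* **Problem sizes.** The simulation studies in the test suite use the study
  conditions (30 cells per population, 81 loci, 50 trees per grid point,
  200–400 replicates for null calibration) with smaller cohorts (6 mice ×
  10 cells) for the 400-cohort permutation-validity check — sizes chosen so
  the whole suite runs in minutes while keeping Monte Carlo error well
  inside the asserted tolerances.
* Real-data headline values (the published correlation of median oocyte
  depth with age and per-mouse medians) require the original undeposited
  single-cell signatures; the package reproduces them only as simulation
  analogues.
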