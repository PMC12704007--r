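---
title: "Models and methods for chromosome-scale ancestry-mosaic analysis"
author: "ancestryMosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for chromosome-scale ancestry-mosaic analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryMosaic)
```

## The problem

Hybridizing species complexes leave behind mosaic genomes: different
chromosomes (and regions within chromosomes) can carry ancestry from
different source lineages, so no single population tree summarizes the
history. A recurring empirical pattern is that sex chromosomes (the Z in
female-heterogametic taxa such as butterflies) behave more "species-like" —
more tree-like — than the autosomes. This package provides the statistical
machinery to quantify that kind of heterogeneity from pooled population
allele frequencies:

1. **Admixture-graph fitting** on the population allele-frequency covariance
   matrix, with the per-chromosome *proportion of covariance explained*
   (PCVE) as a tree-likeness statistic.
2. **Sliding-window four-taxon topology scores** from outgroup-polarized
   coded alleles.
3. A **SNP-permutation test** for among-chromosome heterogeneity of tree
   topologies, scored with the generalized (clustering-information)
   Robinson–Foulds distance.
4. **Partitioning of additive genetic variance (Va)** among chromosomes from
   per-SNP effect estimates and allele frequencies.

Every stage can be exercised on synthetic data with known ground truth; the
generator is first-class, tested code, and the test suite uses it as the
oracle throughout.

## The drift model and its covariance

A `PopulationGraph` is a rooted tree whose branches carry non-negative
drift parameters $c$, plus migration edges. Along a branch, the allele
frequency evolves as

$$p_{\text{child}} = \mathrm{trunc}_{[0,1]}\!\left(p_{\text{parent}} +
  \varepsilon\right), \qquad \varepsilon \sim
  N\!\big(0,\; c\, p_{\text{parent}}(1-p_{\text{parent}})\big),$$

the standard linear-Gaussian approximation to genetic drift. We use the
*parent's* $p(1-p)$ (a Markov approximation) because it keeps the
covariance algebra linear. A migration edge $(b, v, w)$ attaches the
midpoint of donor branch $b$ to destination node $v$: the frequency
entering $v$'s branch is $w\,p_{\text{mid}(b)} + (1-w)\,p_{\text{parent}(v)}$,
an instantaneous admixture mixture applied before the drift on $v$'s own
branch. Gaussian drift with truncation (rather than beta or logit drift)
was chosen deliberately: it is the generative counterpart of the linear
covariance model being fitted, so the simulator and the estimator agree by
construction rather than approximately.

Writing $u_i(b)$ for the expected fraction of leaf $i$'s ancestry that
drifted through branch segment $b$ (products of $w$ and $1-w$ along
migration alternatives; donor branches are split at their midpoint), the
expected covariance in drift units is

$$W = U\,\mathrm{diag}(c)\,U^{\top}.$$

`expectedCovariance()` also offers an exact *frequency-scale* version that
propagates second moments through the graph: drift multiplies the expected
heterozygosity by $(1-c)$ per branch, and the root distribution enters
through its first two moments. Double-centering (`centered = TRUE`)
reproduces the per-SNP across-population centering used by the estimator.

**Truncation caveat.** The propagation is exact for the *pre-truncation*
process. With mild drift (cumulative $c \lesssim 0.1$ and root frequencies
away from the boundaries) truncation affects well under 0.1% of SNPs and
the simulator matches the model to within sampling error; this is the
regime in which the model/simulator consistency test runs. At the strong
drift used in the tree-contrast experiments (cumulative $c \sim 0.8$)
truncation is substantial and the linear model is only an approximation —
which is fine there, because PCVE comparisons are scale-free and do not
rely on the frequency-scale model.

## Covariance estimation

`blockCovariance()` centers each SNP by its across-population mean (the
TreeMix convention — this removes the ancestral-frequency variance, leaving
a function of drift only) and computes the mean cross-product matrix in
consecutive blocks of 100 SNPs. Blocks never span chromosomes and a
trailing partial block is dropped, so blocks preserve local linkage
structure in real data. The point estimate is the mean over blocks; the
standard error is the between-block standard deviation over
$\sqrt{n_{\text{blocks}}}$. Missing entries (pools below the depth floor)
are handled pairwise-complete here, and by SNP-mean imputation in the PCA
only — two independent, simple policies.

**Identifiability.** After centering, drift on the two root-adjacent
branches enters only through its sum, so the non-negative least-squares
design deduplicates exactly collinear columns (the weight is reported on
the first branch of a duplicate group). The drift *distance*
$d_{ij} = W_{ii} + W_{jj} - 2W_{ij}$ is invariant to centering, which is
why neighbor joining on it recovers the topology regardless.

## Graph fitting and PCVE

`fitAdmixtureGraphs()` fits graphs with $m = 0, \dots, 8$ migration edges:

* the $m = 0$ topology comes from neighbor joining on the drift distance,
  rooted on the outgroup, with drift values by non-negative least squares
  (`pracma::lsqnonneg`);
* each restart perturbs the starting topology by $k \sim 1 +
  \mathrm{Poisson}(1)$ random NNI moves and the best objective is kept
  (the unperturbed start is always evaluated);
* for $m \ge 1$, the best $(m-1)$-edge graph seeds the search and *every*
  valid (donor branch, destination node) placement is evaluated in
  deterministic lexicographic order. At the problem sizes this package
  targets (5–25 populations) exhaustive placement enumeration dominates
  random restarting, so the stochastic restarts are confined to the
  topology search;
* given placements, the fit alternates non-negative least squares over
  drift with bounded one-dimensional searches over each $w \in (0,1)$,
  stopping when the objective changes by less than $10^{-10}$ or after 500
  sweeps. A least-squares objective (optionally SE-weighted) replaces the
  composite Gaussian likelihood; the two have the same optimum when SEs
  are equal, and least squares is simpler to test.

Because a weight near zero reproduces the previous graph exactly, PCVE is
non-decreasing in $m$ by construction. PCVE itself is

$$\mathrm{PCVE} = 1 - \frac{\sum_{i \le j} (\hat W_{ij} - W_{ij})^2}
  {\sum_{i \le j} (\hat W_{ij} - \overline{\hat W})^2},$$

summed over unique entries *including* the diagonal and clipped to
$[0, 1]$. The literature does not pin this formula down, so the
denominator convention is a documented package choice; an
off-diagonal-only variant is available (`offDiagonalOnly = TRUE`).
Tie-breaking in the edge search is lexicographic, for bit-reproducibility.

## Allele coding and the quartet scan

`codeAlleles()` applies the common-allele rule used for discrete
phylogenetic analyses of pooled data: a population is coded with the
common allele when its frequency is at least 0.95 (the comparison is
$\ge$; the threshold is configurable) and ambiguous (`N`) otherwise.

`snpVote()` is a fully specified site-pattern vote standing in for
tool-internal per-SNP scores: polarize by the outgroup, and if exactly two
of the three focal taxa carry the derived allele, the SNP votes for the
topology grouping them. `windowScores()` tallies votes in disjoint 10-kb
base windows anchored at position 1 of each chromosome, averages counts
across the base windows of each 50-kb sliding window (default step 10 kb;
the step is configurable since "overlapping" does not fix it), and
normalizes to sum to one. Averaging *counts* weights base windows by their
information; averaging per-window normalized scores first is available via
`normalizeFirst = TRUE`. Windows with no informative votes are reported
missing rather than zero. Score summaries use the population variance
convention (divide by $n$) for both the within- and among-chromosome
variances — the convention is a fixed, documented choice.

Because a vote requires near-fixation of all four taxa, informative SNPs
are rare under weak drift; simulated quartet studies in the test suite use
strong drift and a U-shaped root frequency distribution
(`beta(0.2, 0.2)`), emulating the skewed site-frequency spectra of real
panels. A freshly admixed 50/50 population sits at intermediate
frequencies and codes as `N`; in the symmetric-admixture study design the
admixed lineage therefore carries strong post-admixture drift, which
re-fixes alleles — and the direction of re-fixation samples the two
ancestries 50/50, which is exactly what makes the two competing topologies
statistically indistinguishable.

## Chromosome trees and the permutation test

`chromosomeTree()` estimates a per-chromosome topology from the proportion
of jointly coded SNPs at which two populations differ (`N` excluded
pairwise), followed by neighbor joining and outgroup rooting. This is a
deterministic, consistent stand-in for site-based species-tree estimators;
the permutation machinery is agnostic to the estimator.

`clusteringInfoDistance()` implements the generalized Robinson–Foulds
distance on mutual clustering information: each nontrivial split is a
two-cluster partition with entropy $H$ (bits); splits of the two trees are
matched one-to-one to maximize summed mutual information (a maximum-weight
assignment solved exactly by subset dynamic programming, checked against a
brute-force enumeration oracle in the tests), and

$$d(T_1, T_2) = \sum H(S \in T_1) + \sum H(S \in T_2) - 2 \cdot
  \text{matched shared information},$$

zero exactly when the split sets coincide. Only topologies enter; branch
lengths are ignored.

`permutationTest()` compares the observed mean pairwise distance among
chromosome trees with a null in which SNPs are reassigned to chromosomes
at random (preserving per-chromosome SNP counts; the multiset of counts is
asserted on every draw) and all trees re-estimated in full. The P-value
uses the +1 correction, $P = (1 + \#\{\text{null} \ge \text{obs}\}) /
(1 + n)$, so with the default $n = 50$ permutations the smallest attainable
value is $1/51 \approx 0.0196$ — consistent with reporting "P < 0.02".

**Calibration regimes.** $P$ is uniform on its 51 attainable values only
when the test statistic is effectively continuous, i.e. when the tree
estimates carry appreciable sampling noise. When homogeneous histories are
strongly resolved, every tree equals the truth, all distances tie at zero
and $P$ piles up at 1 — *conservative*, never anticonservative. The
calibration study therefore simulates a homogeneous genome whose internal
branches are unresolved (drift 0 on internal branches, strong pendant
drift), where exchangeability plus continuity make uniformity exact; the
power study uses strongly resolved histories (per-branch drift 0.3), where
informative opposite-fixation events are frequent enough that both the
observed and the 90/10-contaminated null trees are estimated without
error and the test attains $P = 1/51$ deterministically. Between these
regimes (e.g. per-branch drift 0.1), the discrete coding leaves only a
handful of informative events per split at 5000 SNPs and chromosome trees
are unstable; heterogeneity tests in that regime are underpowered, a
limitation of the coded-allele estimator documented here deliberately.

## Size regressions and Va partitioning

`pcveSizeRegression()` standardizes both PCVE and chromosome size and fits
a conjugate normal-inverse-gamma linear model analytically: coefficients
have prior $N(0, \sigma^2 I)$ — a standard-normal prior on the
standardized slope — with $\sigma^2 \sim \mathrm{Inv\text{-}Gamma}(2, 1)$.
The slope's marginal posterior is a scaled $t$, so equal-tail intervals
and $P(\beta < 0)$ are exact; no sampler is involved, and the Monte Carlo
cross-check in the tests draws from the same posterior. A constant
response is treated as the no-signal case (symmetric posterior,
$P(\beta<0) = 0.5$) rather than an error; a constant predictor is an
error. `slopeEdgeCorrelation()` is a plain Pearson correlation (Fisher-z
CI, t-test P) between the migration-edge count and the per-$m$ slope.

`estimateEffects()` is a deterministic ridge estimator with generalized
cross-validation, standing in for Bayesian sparse polygenic samplers: the
Va partition formula — the part that matters here — is estimator-agnostic,
and externally produced effect estimates can be supplied directly.
`partitionVa()` computes $V_{a,c} = \sum_{j \in c} 2 p_j (1-p_j)
\beta_j^2$ with linkage cross-terms ignored (matching computation "from
effect estimates and allele frequencies"); because the unstated
alternative includes within-chromosome linkage covariance, an empirical
variant (`method = "empirical"`) computes the variance of per-chromosome
genetic values from genotypes instead. Allele frequencies come from the
mapping sample (`colMeans(genotypes)/2`), not external pools.

## What the simulator does and does not emulate

The generator produces: chromosome-structured pooled allele counts under
chromosome-specific admixture graphs (e.g. a tree for the Z, a one-edge
graph for autosomes); two-stage pool-seq sampling (binomial allele
sampling in a pool of $2N$ chromosomes, Poisson depth, binomial reads,
zero-depth sites recorded missing); and sparse polygenic traits with a
target heritability. It does **not** simulate linkage (SNPs are
independent, so block resampling is exercised but not stressed),
selection, mutation, or reference bias. Passing tests therefore
demonstrate correctness of the estimators under the stated model, not
robustness to linked selection or alignment artifacts. Pool depths are
free parameters (defaults: depth 100, pools of 48 diploids, matching a
typical pooled study design).

## Problem sizes and numerical choices

The test suite runs 5-population covariance studies at $5 \times 10^4$
SNPs, 50-replicate genome experiments at 5 chromosomes $\times$ 2000 SNPs,
a 200-replicate permutation calibration at 4 chromosomes $\times$ 150
SNPs, and the heterogeneity study at 10 chromosomes $\times$ 5000 SNPs —
sizes chosen so each experiment's Monte Carlo error is well inside the
tolerance it asserts. Numerical details: alternation stops at objective
change $< 10^{-10}$; weights are searched on $(10^{-6}, 1 - 10^{-6})$;
entropies are in bits with $0 \log 0 = 0$; NNLS collinearity is resolved
by first-column assignment; all randomness flows from a single integer
seed via documented sub-seeding (chromosome $k$ uses `seed + k`).

## Known limitations

* The centered covariance leaves root-adjacent drift identified only in
  sum, and migration-edge attachment is restricted to branch midpoints
  and node destinations; attachment-position refinement is out of scope.
* The coded-allele tree estimator discards frequency information below
  the 0.95 threshold; in weak-drift regimes it is underpowered (see the
  calibration discussion).
* Ridge effect estimates are biased toward zero individually; the Va
  *proportions* are much better behaved than the absolute magnitudes, and
  only proportions are interpreted.
* No averaging of migration weights across chromosomes is provided: with
  differing edge placements across chromosomes there is no canonical
  averaging rule, so weights are reported per chromosome and per graph.
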