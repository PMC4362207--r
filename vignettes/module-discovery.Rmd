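---
title: "Discovering variant-transcript-trait modules: models and methods"
author: "triadnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering variant-transcript-trait modules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadnet)
```

## The problem

In a panel of homozygous recombinant-inbred individuals (for example BXD
mouse strains), many clinical traits map to the same genomic locus. Shared
mapping alone does not say *why* traits travel together: the interesting
case is a group of traits jointly controlled by one or more **driver
transcripts** whose expression mediates the effect of the locus. `triadnet`
searches for such three-layer modules — a single genomic interval
(a consecutive run of variants on one chromosome), a set of driver
transcripts, and the group of traits they affect — from three matrices over
a common strain panel: biallelic genotypes (0/1), transcript expression, and
trait values (missing entries allowed).

The search has three stages, each a filter for the next:

1. **Stage I** scores every (variant, trait) pair with a *link potential*
   and biclusters the resulting bipartite graph into candidate modules.
2. **Stage II** attaches *candidate transcripts* to each module using a
   rank-based Kolmogorov–Smirnov link score.
3. **Stage III** validates causality for every (candidate, trait) pair with
   a permutation likelihood-ratio test, combines evidence per transcript by
   Fisher's method, and iteratively removes non-causative transcripts and
   unaffected traits.

## Stage I: link potential and biclustering

For homozygous panels the **variant–transcript association score** is the
−log10 p-value of a pooled-variance two-sample t-test comparing a
transcript's expression between the two allele groups; the
**transcript–trait correlation score** is the absolute Pearson correlation
across strains (pairwise-complete observations throughout). The **link
potential** of a variant $v$ and trait $t$ asks whether transcripts strongly
associated with $v$ are also unusually correlated with $t$: association
scores over all transcripts are cut at their $1/6, \dots, 5/6$ empirical
quantiles (six equal-count groups, five cutoffs), each cutoff defines a
high/low split, a one-sided pooled t-test compares the correlation scores of
the two sides, and the link potential is the best −log10 p over the five
cutoffs. Equal-count rather than equal-width groups are used because the
−log p association scores are heavily right-skewed. Degenerate statistics
(empty side, zero variance) contribute 0, so all edge weights are finite and
non-negative; p-values are floored at 1e−320 before taking logs.

Bicluster search is seed-and-improve: every edge above a seed cutoff
$c_s$ starts a cluster, and a trait or variant belongs to a cluster iff its
average link potential over the opposite side strictly exceeds an
improvement cutoff $c_i$. Addition passes (traits first, then variants)
alternate with removal passes to a fixed point; all comparisons are strict,
so the procedure is invariant to adding a constant to every weight and to
both cutoffs. The variant side is kept a single consecutive run on one
chromosome: additions are restricted to run-adjacent positions and, after
removals, the heaviest consecutive run (by block mean weight, leftmost on
ties) is retained. Exact-duplicate modules are collapsed; overlapping
non-identical modules are all kept. Defaults: $c_s = 180$, $c_i = 90$, at
most 100 improvement iterations.

**Score scale and calibration.** Link potentials grow with the number of
transcripts in the background: with thousands of transcripts a strong pair
can reach scores in the hundreds, while with a few hundred transcripts the
attainable range tops out near 100. The default $c_s/c_i$ are operating
points for genome-scale expression data; for smaller (e.g. simulated)
datasets, `calibrateLinkCutoffs()` sets $c_s$ to the maximum edge weight
observed on transcript-reshuffled copies of the dataset — the same negative
control the permutation-FDR machinery uses — and $c_i = c_s/2$, preserving
the 2:1 ratio of the genome-scale defaults.

## Stage II: transcript link scores

For each transcript, its correlations with *all* traits and its associations
with *all* variants are ranked separately (rank 1 = strongest, average ranks
on ties). The ranks the transcript attains at the module's traits and
variants form the module sample; all its ranks form the background; a
two-sample K-S test compares the two, and transcripts with link-score
p-values below the cutoff become candidates. The asymptotic Kolmogorov
distribution is used for the p-value, switching to the exact (ties-aware)
distribution when the pooled sample has fewer than 30 values.

Two practical notes. First, the module sample is small (traits + variants of
one module), so the attainable significance is bounded — a module with three
traits and one variant cannot go below roughly 0.02 even with perfect ranks.
The default cutoff of 0.01 is therefore a simulation-scale operating point
for modules with a handful of members or more; genome-scale datasets with
large modules support far smaller cutoffs. Second, the rank construction is
per-transcript across traits/variants; scores are invariant to any strictly
monotone transform of the underlying association or correlation values.

## Stage III: causality testing and refinement

### The triplet models

For one variant $v$, transcript $g$ and outcome $p$, five linear-Gaussian
models are considered, each a product of regression conditionals with
maximum-likelihood residual variances ($n$ denominator):

* M1 (causal): $v \to g \to p$, i.e. $[g|v][p|g]$
* M2 (independent): $v \to g$, $v \to p$, i.e. $[g|v][p|v]$
* M3 (reactive): $v \to p \to g$, i.e. $[p|v][g|p]$
* M4: $v \to g \to p$ plus $v \to p$, i.e. $[g|v][p|v,g]$
* M5: $v \to p \to g$ plus $v \to g$, i.e. $[p|v][g|v,p]$

M4 and M5 are both factorizations of the saturated trivariate Gaussian and
are treated together. Broad-sense causality treats M1 *and* M4 as positives:
a transcript may causally affect a trait even when the variant also acts
through other paths. The **causality p-value** is the larger of the two
empirical p-values for the likelihood-ratio scores of M1 against M2 and of
M1 against M3, so both alternatives must be rejected.

### Empirical nulls

Each likelihood-ratio statistic is referred to a null generated by
reshuffling the transcript *under the corresponding null model*:

* LR(M1 vs M2): $g$ is reshuffled within genotype classes (separately among
  $v=0$ and $v=1$ individuals). Under M2, $g$ is exchangeable within allele
  groups given $p$, so this is an exact permutation test of
  "$g \perp p \mid v$".
* LR(M1 vs M3): $g$'s residuals from its regression on $p$ are reshuffled
  and added back to the fitted values (a Freedman–Lane scheme), preserving
  the transcript–outcome edge and destroying the conditional
  variant–transcript link — the null for "$g \perp v \mid p$".

The choice is forced by the algebra of the Gaussian likelihood: LR(M1 vs M3)
is *exactly invariant* to any within-class reshuffle (the $g \leftrightarrow
p$ direction terms cancel to a function of quantities such reshuffles
preserve), while an unconditional reshuffle destroys the variant–transcript
association and centres both nulls far below any correlated observation,
making every correlated transcript "significant". With the model-specific
nulls, the empirical type-I error under M2 sits at the nominal level.

P-values carry the add-one correction $(1 + \#\{LR^{perm} \ge
LR^{obs}\})/(1 + B)$ and can never be zero. The benchmarking default is
$B = 100$ reshuffles; refinement uses $B = 1000$ so that cutoffs near 0.005
are attainable under the add-one floor. One reshuffle index set per
transcript is shared across the traits of a module, which turns the whole
causality matrix into a handful of matrix products.

### Refinement

The **representative variant** of a module is the interval variant with the
best mean association score over the module's candidates (ties to the lowest
position); all causality tests in the module are anchored at it, and the
causality matrix is computed once and cached (it cannot change across
iterations because the representative variant is fixed). Refinement then
alternates two eliminations to a fixed point: (i) drop transcripts whose
Fisher-combined causality p-value over the surviving traits,
$\chi^2_{2k} = -2\sum_{j=1}^k \ln p_{ij}$, is at or above the transcript
cutoff (default 0.005); (ii) drop traits with no surviving transcript whose
pairwise causality p-value is below the trait cutoff (default 0.05). Each
iteration removes at least one member, so termination is guaranteed (a cap
of 50 iterations is kept as a safeguard). Fisher's method is applied to
correlated trait p-values without a dependence correction, favouring
fidelity to the procedure over conservatism.

**Why two cutoffs.** The transcript-level statistic pools $k$ traits into a
$2k$-degree-of-freedom combination with correspondingly fine resolution, and
0.005 is an appropriate stringent level for it. Trait retention, by
contrast, rests on a *single* pairwise permutation p-value; at 0.005 per
pair the reverse-causality component of the test has power near 0.25 under
the simulators' own low-noise settings, which collapses causal-trait
recovery. A conventional per-test level (0.05) restores the intended
behaviour (grouping-by-causality balanced accuracy ≈ 0.98 at noise 0.5)
while confusable traits are still excluded at high specificity. Both cutoffs
are configurable.

The same machinery scores **cis-mediation** (`mediationPvalue`): the outcome
is another transcript, testing whether a cis-associated gene is positioned
between a module's interval and a downstream module transcript.

## Synthetic data

Three generators emit datasets plus ground-truth labels; all are
bit-reproducible given a seed.

* **Triplets** (`simulateTriplets`): genotypes are Bernoulli(0.5) over 100
  individuals; $g$ and $p$ follow the M1–M5 structural equations with
  variant effect $\alpha = 0.5$, mediated effect $\lambda$, error sd
  $\sigma$, zero intercepts, one error term per equation; 250 triplets per
  model (1250 total).
* **Co-mapped sub-networks** (`simulateSubnetworks`): one variant, $m = 3$
  causal transcripts driving $k$ causal traits ($k + 2$ traits in total),
  one reactive transcript downstream of a reactive trait
  ($v \to p^R \to g^R$), and an independent transcript/trait pair. Every
  edge $a_i \to a_j$ is $a_j = \beta a_i + \varepsilon$,
  $\varepsilon \sim N(0, (q\beta)^2)$ with $\beta = 1.5$ for
  variant-to-anything edges and $\beta = 0.6$ for transcript/trait edges;
  $q$ is the relative noise level. A collection holds 100 sub-networks of
  100 individuals. The Net-2 and Net-3 wirings (duplicated confusable
  components; chained causal transcripts) are documented reconstructions of
  sketched variants and should be treated as approximate.
* **Composite networks** (`simulateNetwork`): five sub-networks embedded
  among background variants (independent Bernoulli(0.5)), background traits
  (standard normal) and background transcripts drawn from a multivariate
  normal whose covariance is, by default, a synthesized block-plus-noise
  matrix mimicking gene-expression correlation spectra (a user-supplied
  covariance is accepted and validated for positive semi-definiteness).
  Each background transcript is then coupled to a uniformly chosen
  sub-network transcript as $z = x + c\,y$ with $c = 1$, so background
  expression correlates with the planted modules, as real co-expression
  would.

What the simulators do *not* emulate: real linkage-disequilibrium structure
along chromosomes (background genotypes are independent), non-Gaussian
noise, batch structure, and the correlation spectrum of any particular real
expression compendium. Passing the synthetic benchmarks therefore
demonstrates the machinery under the stated generative assumptions, not
performance on any specific real panel.

## Evaluation

`causalityErrorMatrix` scores broad-sense calls (positive at $p \le
\alpha$; truth = M1 or M4). `balancedAccuracy` is $(TPR + TNR)/2$;
`balancedFdr` rescales false positives by
$\pi_0 = (FP + TN)/(TP + FN)$ before forming $FP^a/(FP^a + TP)$, so
imbalanced synthetic collections compare fairly. `aucBroadSense` is the
midrank Mann–Whitney AUC of $-p$. `groupingErrorMatrices` matches each
sub-network to the predicted trait group with the largest intersection
(ties: smaller group, then lexicographically first member) and pools counts
over sub-networks, scoring both naive grouping (all sub-network traits) and
grouping-by-causality (causal traits only). `permutationModuleFdr` reruns
the whole pipeline on transcript-reshuffled data and reports, per stage,
mean null module count over observed count.

## Known limitations

* **The broad-sense definition has an intrinsic false-positive mode.** M4
  and M5 are mirror parameterizations of the same saturated Gaussian family.
  At strong mediated effects ($\lambda > 1$) the second-moment asymmetry of
  M4 data points toward the reactive direction and M5 data toward the causal
  one; no likelihood-based triplet test can simultaneously detect M4 and
  reject M5 there. With $\lambda = 4$ and $\sigma = 0.6$ the transcript and
  outcome are nearly collinear ($r^2 \approx 0.95$) and the M1-vs-M3
  direction carries almost no information, so the triplet benchmark's AUC is
  intrinsically capped well below what the identifiable regime
  ($\lambda < 1$, as in the sub-network simulators where the
  transcript-to-trait coefficient is 0.6) delivers. The package reports
  measured values honestly rather than tuning around this.
* The K-S link score saturates for very small modules (see Stage II).
* Bicluster cutoffs are scale-dependent and should be calibrated per
  dataset (see Stage I).
* Stage III anchors each module at a single representative variant; with
  strong local linkage disequilibrium the representative is one of several
  statistically equivalent choices.
* No causal ordering *within* the driver layer is attempted: multiple
  drivers in one regulatory circuit are not distinguished from drivers in
  distinct circuits.

## Numerical choices and problem sizes

P-values are floored at 1e−320 before logs; residual sums of squares at the
same floor before MLE variances. Standard deviations use the $n - 1$
denominator except MLE residual variances ($n$). Strain order is normalized
lexicographically; all tie-breaks (seed ordering, largest-intersection
matching, representative variants) are deterministic and documented at the
function level. Sub-stream seeds are derived from the user seed by a fixed
linear congruential map, kept below $2^{31}$.

The shipped tests and the acceptance script exercise the pipeline at sizes a
laptop handles in minutes: the full 1250-triplet benchmark at $B = 100$;
sub-network collections of 100 at $B = 1000$ across five noise levels; the
100-variant × 200-transcript × 100-trait composite network end to end; and
40 pure-noise datasets of 40 × 80 × 25 for the null-behaviour checks. These
sizes were chosen to estimate each quantity stably while keeping a full run
fast enough to be part of routine development.
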