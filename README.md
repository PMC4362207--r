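# triadnet

Discovery of causal variant–transcript–trait modules in panels of
homozygous inbred individuals (e.g. recombinant-inbred mouse strains).

Many clinical traits map to the same genomic locus, but co-mapping alone
does not reveal *why* traits travel together. `triadnet` searches for
three-layer modules — a single genomic interval, the **driver transcripts**
whose expression mediates its effect, and the group of traits they affect —
from three matrices over a shared strain panel: biallelic genotypes
(variants × strains, 0/1), transcript expression, and trait values.

## The method

Three stages, each a filter for the next:

1. **Link-potential graph + biclustering.** For a variant *v* and trait
   *t*, every transcript gets an association score with *v* (−log10 pooled
   t-test p between allele groups) and a correlation score with *t*
   (absolute Pearson *r*). Association scores are cut at their 1/6 … 5/6
   quantiles (6 equal-count groups, 5 cutoffs); at each cutoff a one-sided
   t-test asks whether high-association transcripts have larger trait
   correlations, and the link potential is the best −log10 p over the
   cutoffs. A seed-and-improve bicluster search (seed cutoff `cs`,
   membership iff average link potential > `ci`) extracts **bipartite
   modules**: a consecutive variant run on one chromosome plus a trait set.
2. **Candidate transcripts.** Each transcript's correlations with all
   traits and associations with all variants are ranked; a two-sample
   Kolmogorov–Smirnov test compares the ranks it attains inside the module
   with all its ranks. Significant transcripts join the module
   (**tripartite module**).
3. **Causality validation.** Anchored at the module's representative
   variant, every (candidate, trait) pair gets a broad-sense **causality
   p-value**: likelihood ratios of the causal chain model v → g → p (M1)
   against the independence (M2) and reactive (M3) alternatives, each
   referred to an empirical null obtained by reshuffling the transcript
   under that null model, combined as the maximum of the two p-values.
   Per transcript the trait p-values are pooled by Fisher's method
   (χ² with 2k df); transcripts and traits are eliminated iteratively,
   leaving **driver modules**.

The package also ships the benchmark machinery: linear-Gaussian simulators
for causality triplets (models M1–M5), co-mapped sub-networks with causal /
reactive / independent components, and large composite networks with
covariance-structured background expression — each with ground-truth labels
— plus balanced accuracy, balanced FDR (false positives rescaled by
π₀ = (FP+TN)/(TP+FN)), rank AUC, trait-grouping error matrices and
whole-pipeline permutation FDR.

## Worked example

Simulate a small composite network with two planted sub-networks, calibrate
the bicluster cutoffs against a permutation null (the default `cs = 180`,
`ci = 90` are genome-scale operating points; simulated backgrounds are
smaller, so the score scale is too), and run the pipeline:

```r
library(triadnet)

net <- simulateNetwork(nVariants = 40, nTraits = 30, nTranscripts = 60,
                       nSubnetworks = 2, k = 4, noise = 0.5, seed = 7)
cal <- calibrateLinkCutoffs(net$dataset, nPerm = 2, seed = 7)
res <- runPipeline(net$dataset, pipelineConfig(cs = cal$cs, ci = cal$ci, seed = 7))
res
#> PipelineResult: 2 bipartite -> 2 tripartite -> 2 driver module(s)
res$modules[[1]]
#> DriverModule: chr2:4000000-4000000 (representative v012)
#>   drivers: s1_gC1
#>   traits:  s1_pC1, s1_pC2, s1_pC3, s1_pC4
net$truth$variants
#>   subnetwork variant
#> 1         s1    v012
#> 2         s2    v024
```

Both planted sub-networks are recovered: each driver module sits at the
planted variant (`v012` is sub-network s1's variant) and collects exactly
that sub-network's causal traits, while the planted reactive and
independent traits are filtered out by the causality stage.

A single triplet test, on a simulated causal chain:

```r
v <- rbinom(50, 1, 0.5)
g <- 1.5 * v + rnorm(50, 0, 0.4)          # transcript driven by the variant
p <- 0.6 * g + rnorm(50, 0, 0.3)          # trait driven by the transcript
causalityPvalue(v, g, p, B = 1000, seed = 1)
#> CausalityResult: LR2 10.838 (p 0.000999), LR3 11.987 (p 0.000999)
#>   -> causality p 0.000999 [B=1000]
```

Both alternatives (independence and reactivity) are rejected at the
permutation floor 1/(B+1), so the pair is called causal in the broad sense.

See `vignettes/module-discovery.Rmd` for the models, the permutation-null
design, parameter defaults and known identifiability limits.

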