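Package: triadnet
Title: Discovery of Causal Variant-Transcript-Trait Modules in Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies three-layer modules in panels of homozygous inbred
    individuals: a single genomic interval, the driver transcripts whose
    expression mediates its effect, and the group of traits they affect.
    A three-stage pipeline scores variant-trait link potential, finds heavy
    biclusters in the resulting bipartite graph, adds candidate transcripts
    by a rank-based Kolmogorov-Smirnov link score, and validates drivers with
    likelihood-ratio causality tests against empirical permutation nulls,
    combined across traits by Fisher's method. Ships linear-Gaussian
    structural-equation simulators (causality triplets, co-mapped
    sub-networks, large composite networks) with ground-truth labels, and
    evaluation metrics (balanced accuracy, balanced false discovery rate,
    AUC, permutation-based module FDR).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, MASS
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
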