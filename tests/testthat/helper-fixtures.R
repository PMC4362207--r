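# Shared fixture builders; everything is generated in code.

# Variant table with nv variants on one chromosome, genotypes supplied or
# Bernoulli(0.5).
makeVariantTable <- function(nv, strains, geno = NULL, chromosome = "chr1") {
  if (is.null(geno))
    geno <- matrix(rbinom(nv * length(strains), 1, 0.5), nv,
                   dimnames = list(sprintf("v%02d", seq_len(nv)), strains))
  VariantTable(geno, rep(chromosome, nv), seq_len(nv) * 1e6)
}

# Small aligned dataset with given matrices (features x strains).
makeDataset <- function(geno_vt, expr, traits) {
  new("TriadDataset", genotypes = geno_vt, expression = expr,
      traits = traits, strains = colnames(expr), metadata = list())
}

# Bipartite graph from an explicit weight matrix.
makeGraph <- function(W) new("BipartiteGraph", weights = W)

# Variant table whose coordinates match the rows of a weight matrix.
variantTableFor <- function(W, strains = sprintf("S%02d", 1:4)) {
  geno <- matrix(rep(c(0, 1), length.out = nrow(W) * length(strains)),
                 nrow(W), dimnames = list(rownames(W), strains))
  VariantTable(geno, rep("chr1", nrow(W)), seq_len(nrow(W)) * 1e6)
}

# Independent brute-force checker: does (variants, traits) satisfy both
# membership conditions at cutoff ci?
isValidBicluster <- function(W, vids, tids, ci) {
  sub_t <- colMeans(W[vids, tids, drop = FALSE])
  sub_v <- rowMeans(W[vids, tids, drop = FALSE])
  all(sub_t > ci) && all(sub_v > ci)
}

# Brute-force two-sample K-S statistic by ECDF sweep.
bruteKS <- function(x, y) {
  cuts <- sort(unique(c(x, y)))
  max(abs(vapply(cuts, function(q) mean(x <= q) - mean(y <= q), numeric(1))))
}

# Brute-force pooled two-sample t-test p-value.
bruteT <- function(x, y, one_sided = FALSE) {
  n1 <- length(x); n0 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n0 - 1) * var(y)) / (n1 + n0 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  if (one_sided) pt(tt, n1 + n0 - 2, lower.tail = FALSE)
  else 2 * pt(-abs(tt), n1 + n0 - 2)
}
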