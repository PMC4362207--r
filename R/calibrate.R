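# Dataset-scale calibration of the bicluster cutoffs. The seed and
# improvement thresholds act on -log10 link-potential scores, whose scale
# depends on the number of transcripts in the background (more transcripts
# give larger attainable t statistics). Rather than fixing genome-scale
# constants, the cutoffs can be calibrated against a permutation null of
# the whole graph, the same negative control the pipeline's FDR machinery
# uses: transcript values are reshuffled across strains, destroying both
# variant-transcript associations and transcript-trait correlations while
# preserving the marginals.

#' Calibrate bicluster cutoffs against a permutation null
#'
#' Builds \code{nPerm} link-potential graphs on transcript-reshuffled copies
#' of the dataset and sets the seed cutoff \code{cs} to the maximum null
#' weight observed (a seed must beat every null edge), with
#' \code{ci = cs / 2}, preserving the 2:1 seed:improvement ratio of the
#' genome-scale defaults.
#'
#' @param ds a \linkS4class{TriadDataset}.
#' @param nPerm number of null graphs (default 3; the null maximum is
#'   already an extreme statistic over all variant-trait pairs).
#' @param nGroups,oneSided passed to \code{\link{buildBipartiteGraph}}.
#' @param seed RNG seed.
#' @return list(cs, ci, nullMax = per-permutation maxima).
#' @export
calibrateLinkCutoffs <- function(ds, nPerm = 3, nGroups = 6, oneSided = TRUE,
                                 seed = 1) {
  stopifnot(nPerm >= 1)
  expr <- expressionValues(ds)
  null_max <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    set.seed(.deriveSeed(seed, b))
    perm <- t(apply(expr, 1, sample))
    colnames(perm) <- colnames(expr)
    ds_perm <- new("TriadDataset", genotypes = variantTable(ds),
                   expression = perm, traits = traitValues(ds),
                   strains = strains(ds), metadata = list())
    null_max[b] <- max(graphWeights(
      buildBipartiteGraph(ds_perm, nGroups = nGroups, oneSided = oneSided)))
  }
  cs <- max(null_max)
  list(cs = cs, ci = cs / 2, nullMax = null_max)
}
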