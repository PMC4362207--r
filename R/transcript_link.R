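# Stage II: transcript link scores. For each transcript we rank its
# correlations with all traits and its associations with all variants
# (separately, rank 1 = strongest, average ranks on ties), pool the ranks it
# attains at the module's traits and variants, and compare that sample with
# the pooled background of all its ranks by a two-sample K-S test. Driver
# transcripts should occupy the top ranks inside their module.

# Per-transcript rank vectors (descending: rank 1 = strongest score).
.descRanks <- function(x) rank(-x, ties.method = "average")

#' Transcript link score for one module
#'
#' @param transcript transcript id.
#' @param module a \linkS4class{BipartiteModule}.
#' @param ds a \linkS4class{TriadDataset}.
#' @param assocMat optional precomputed \code{\link{associationMatrix}}
#'   (variants x transcripts).
#' @param corrMat optional precomputed \code{\link{correlationMatrix}}
#'   (transcripts x traits).
#' @return the K-S p-value in (0, 1] comparing the module's rank sample with
#'   the background of all ranks.
#' @export
transcriptLinkScore <- function(transcript, module, ds,
                                assocMat = NULL, corrMat = NULL) {
  if (length(module@traitIds) < 1 || length(module@variantIds) < 1)
    stop("module must have at least one trait and one variant")
  if (is.null(assocMat))
    assocMat <- associationMatrix(expressionValues(ds), variantTable(ds))
  if (is.null(corrMat))
    corrMat <- correlationMatrix(expressionValues(ds), traitValues(ds))
  corr_ranks <- .descRanks(corrMat[transcript, ])
  assoc_ranks <- .descRanks(assocMat[, transcript])
  module_sample <- c(corr_ranks[module@traitIds],
                     assoc_ranks[module@variantIds])
  background <- c(corr_ranks, assoc_ranks)
  .ksPvalue(module_sample, background)$p.value
}

#' Extend a bipartite module with candidate transcripts
#'
#' Scores every transcript in the dataset against the module and keeps those
#' with link score strictly below \code{cutoff}, sorted by ascending score
#' (ties broken by transcript id).
#'
#' @inheritParams transcriptLinkScore
#' @param cutoff link-score p-value cutoff in (0, 1); 0.01 is a sensible
#'   operating point for simulation-scale backgrounds, while genome-scale
#'   datasets support far smaller values.
#' @return a \linkS4class{TripartiteModule}, or NULL if no transcript
#'   survives.
#' @export
extendToTripartite <- function(module, ds, cutoff = 0.01,
                               assocMat = NULL, corrMat = NULL) {
  stopifnot(cutoff > 0, cutoff <= 1)
  if (is.null(assocMat))
    assocMat <- associationMatrix(expressionValues(ds), variantTable(ds))
  if (is.null(corrMat))
    corrMat <- correlationMatrix(expressionValues(ds), traitValues(ds))
  ids <- rownames(expressionValues(ds))
  scores <- vapply(ids, function(g)
    transcriptLinkScore(g, module, ds, assocMat, corrMat), numeric(1))
  keep <- scores < cutoff
  if (!any(keep)) return(NULL)
  ord <- order(scores[keep], ids[keep])
  cand <- ids[keep][ord]
  new("TripartiteModule", base = module, candidates = cand,
      linkScores = setNames(scores[keep][ord], cand))
}
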