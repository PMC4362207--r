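# Stage-III pipeline: anchor each tripartite module at one representative
# variant, score every (candidate transcript, trait) pair with the
# permutation causality test, combine each transcript's p-values across the
# module's traits with Fisher's method, and iteratively drop non-causative
# transcripts and unaffected traits until a fixed point.

#' Representative variant of a module's genomic interval
#'
#' The interval variant with the best (largest) mean association score over
#' the module's candidate transcripts; ties go to the lowest physical
#' position.
#'
#' @param module a \linkS4class{TripartiteModule}.
#' @param ds a \linkS4class{TriadDataset}.
#' @param assocMat optional precomputed \code{\link{associationMatrix}}.
#' @return variant id.
#' @export
representativeVariant <- function(module, ds, assocMat = NULL) {
  cand <- module@candidates
  vids <- module@base@variantIds
  stopifnot(length(cand) >= 1, length(vids) >= 1)
  if (is.null(assocMat))
    assocMat <- associationMatrix(expressionValues(ds), variantTable(ds))
  mean_assoc <- rowMeans(assocMat[vids, cand, drop = FALSE])
  best <- mean_assoc == max(mean_assoc)
  if (sum(best) > 1) {
    pos <- variantInfo(variantTable(ds))[vids, "position_bp"]
    vids[best][which.min(pos[best])]
  } else vids[which(best)]
}

#' Fisher's method for combining causality p-values
#'
#' X = -2 sum(log p) referred to the chi-squared distribution with 2k
#' degrees of freedom, k = number of p-values. Applied per transcript over a
#' module's traits; trait p-values are correlated and no dependence
#' correction is attempted.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return combined upper-tail p-value.
#' @export
fisherTranscriptP <- function(pvals) {
  if (length(pvals) < 1) stop("need at least one p-value")
  if (any(pvals <= 0 | pvals > 1)) stop("p-values must be in (0, 1]")
  pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals), lower.tail = FALSE)
}

# Iterative elimination on a cached causality p-value matrix: (i) drop
# transcripts whose Fisher-combined p over surviving traits is at or above
# transcriptCutoff; (ii) drop traits with no surviving transcript whose
# pairwise causality p is below traitCutoff; repeat to a fixed point.
# Returns list(transcripts, traits, fisher) or NULL if a side empties.
.refineOnMatrix <- function(pmat, transcriptCutoff, traitCutoff,
                            maxIter = 50) {
  trans <- rownames(pmat)
  traits <- colnames(pmat)
  for (iter in seq_len(maxIter)) {
    fisher <- vapply(trans, function(g)
      fisherTranscriptP(pmat[g, traits]), numeric(1))
    trans_new <- trans[fisher < transcriptCutoff]
    if (length(trans_new) == 0) return(NULL)
    traits_new <- traits[vapply(traits, function(tr)
      any(pmat[trans_new, tr] < traitCutoff), logical(1))]
    if (length(traits_new) == 0) return(NULL)
    if (identical(trans_new, trans) && identical(traits_new, traits)) break
    trans <- trans_new; traits <- traits_new
  }
  fisher <- vapply(trans, function(g) fisherTranscriptP(pmat[g, traits]),
                   numeric(1))
  list(transcripts = trans, traits = traits, fisher = fisher)
}

#' Refine a tripartite module into a driver module
#'
#' Fixes the representative variant, computes the causality p-value of every
#' (candidate, trait) pair once (it does not depend on the surviving set, so
#' the matrix is cached across iterations), then alternates: (i) drop
#' transcripts whose Fisher-combined p over the surviving traits is at or
#' above \code{transcriptCutoff}; (ii) drop traits without any surviving
#' transcript whose pairwise causality p is below \code{traitCutoff}; repeat
#' to a fixed point.
#'
#' Two thresholds operate here: the transcript-level cutoff applies to the
#' Fisher combination over all module traits (a 2k-degree-of-freedom
#' statistic with correspondingly fine resolution), while trait retention
#' rests on a single pairwise permutation p-value, for which a conventional
#' per-test level is appropriate.
#'
#' @param module a \linkS4class{TripartiteModule}.
#' @param ds a \linkS4class{TriadDataset}.
#' @param transcriptCutoff cutoff on the Fisher-combined transcript
#'   causality p-value (default 0.005).
#' @param traitCutoff per-pair cutoff for trait retention (default 0.05);
#'   \code{B} must satisfy B >= 1/cutoff - 1 for both cutoffs so they are
#'   attainable under the add-one permutation correction.
#' @param B permutation count for the causality tests (default 1000).
#' @param seed RNG seed.
#' @param assocMat optional precomputed association matrix.
#' @return a \linkS4class{DriverModule}, or NULL if all transcripts or all
#'   traits are eliminated.
#' @export
refineModule <- function(module, ds, transcriptCutoff = 0.005,
                         traitCutoff = 0.05, B = 1000, seed = 1,
                         assocMat = NULL) {
  stopifnot(transcriptCutoff > 0, transcriptCutoff < 1,
            traitCutoff > 0, traitCutoff < 1)
  if (B < 1 / min(transcriptCutoff, traitCutoff) - 1)
    stop("B too small for the cutoffs: need B >= ",
         ceiling(1 / min(transcriptCutoff, traitCutoff) - 1))
  rep_v <- representativeVariant(module, ds, assocMat)
  v <- genotypes(variantTable(ds))[rep_v, ]
  G <- expressionValues(ds)[module@candidates, , drop = FALSE]
  Tm <- traitValues(ds)[module@base@traitIds, , drop = FALSE]
  ok <- !is.na(v)
  pmat <- .causalityMatrix(v[ok], G[, ok, drop = FALSE],
                           Tm[, ok, drop = FALSE], B = B, seed = seed)
  ref <- .refineOnMatrix(pmat, transcriptCutoff, traitCutoff)
  if (is.null(ref)) return(NULL)
  trans <- ref$transcripts; traits <- ref$traits; fisher <- ref$fisher
  base <- module@base
  new("DriverModule",
      chromosome = base@chromosome, startBp = base@startBp,
      endBp = base@endBp, representativeVariant = rep_v,
      drivers = trans, traitIds = traits,
      causalityMatrix = pmat[trans, traits, drop = FALSE],
      fisherP = fisher)
}
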