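# Benchmarking metrics: confusion matrices for broad-sense causality calls,
# balanced accuracy, the class-imbalance-corrected ("balanced") FDR, rank
# AUC, trait-grouping error matrices, and whole-pipeline permutation FDR.

#' Confusion-matrix counts with imbalance-corrected derivatives
#'
#' @param TP,FP,TN,FN non-negative counts.
#' @return an \code{"ErrorMatrix"} list; \code{print()}s the counts and the
#'   derived TPR, TNR, pi0 and adjusted FP (FP / pi0, where
#'   pi0 = (FP + TN) / (TP + FN) is the negative:positive class ratio).
#' @export
errorMatrix <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0)
  structure(list(TP = unname(TP), FP = unname(FP), TN = unname(TN),
                 FN = unname(FN)), class = "ErrorMatrix")
}

#' @export
print.ErrorMatrix <- function(x, ...) {
  cat(sprintf("ErrorMatrix: TP %d FP %d TN %d FN %d\n",
              x$TP, x$FP, x$TN, x$FN))
  if (x$TP + x$FN > 0 && x$TN + x$FP > 0)
    cat(sprintf("  TPR %.3f TNR %.3f pi0 %.3f\n", x$TP / (x$TP + x$FN),
                x$TN / (x$TN + x$FP), (x$FP + x$TN) / (x$TP + x$FN)))
  invisible(x)
}

#' Error matrix for broad-sense causality calls
#'
#' A triplet is called positive when its causality p-value is at or below
#' \code{alpha}; it is truly positive when its generating model is M1 or M4.
#'
#' @param pvals per-triplet causality p-values.
#' @param labels generating model labels in \code{"M1"}..\code{"M5"} (or a
#'   logical truth vector).
#' @param alpha significance threshold (default 0.05).
#' @return an \code{\link{errorMatrix}}.
#' @export
causalityErrorMatrix <- function(pvals, labels, alpha = 0.05) {
  truth <- if (is.logical(labels)) labels else labels %in% c("M1", "M4")
  stopifnot(length(pvals) == length(truth))
  call_pos <- pvals <= alpha
  errorMatrix(TP = sum(call_pos & truth), FP = sum(call_pos & !truth),
              TN = sum(!call_pos & !truth), FN = sum(!call_pos & truth))
}

#' Balanced accuracy: (TPR + TNR) / 2
#'
#' @param e an \code{\link{errorMatrix}}.
#' @return value in [0, 1].
#' @export
balancedAccuracy <- function(e) {
  if (e$TP + e$FN == 0 || e$TN + e$FP == 0)
    stop("both classes must be present")
  (e$TP / (e$TP + e$FN) + e$TN / (e$TN + e$FP)) / 2
}

#' Balanced false discovery rate
#'
#' FDR = FPa / (FPa + TP) with FPa = FP / pi0 and
#' pi0 = (FP + TN) / (TP + FN): false positives are rescaled by the
#' negative:positive class ratio so that methods can be compared on
#' imbalanced synthetic collections.
#'
#' @param e an \code{\link{errorMatrix}}.
#' @return value >= 0.
#' @export
balancedFdr <- function(e) {
  if (e$TP + e$FN == 0) stop("pi0 undefined: no actual positives")
  pi0 <- (e$FP + e$TN) / (e$TP + e$FN)
  fpa <- e$FP / pi0
  if (fpa + e$TP == 0) stop("FPa + TP must be > 0")
  fpa / (fpa + e$TP)
}

#' Rank AUC for broad-sense causality
#'
#' Area under the ROC curve of score = -p against the broad-sense truth,
#' computed from midranks (equivalent to Mann-Whitney U / (n1 n0)).
#'
#' @inheritParams causalityErrorMatrix
#' @return value in [0, 1].
#' @export
aucBroadSense <- function(pvals, labels) {
  truth <- if (is.logical(labels)) labels else labels %in% c("M1", "M4")
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(-pvals, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Naive and causal trait-grouping error matrices
#'
#' For each sub-network s, the predicted trait group with the largest
#' intersection with the sub-network's traits P(s) is matched to it (ties:
#' the smaller predicted group, then the lexicographically first). The
#' "naive" matrix scores membership against all of P(s) (grouping by
#' co-mapping); the "causal" matrix scores against the causal traits P^C(s)
#' only, so reactive and independent traits in a predicted group count as
#' false positives. Counts are pooled over sub-networks.
#'
#' @param predicted list of character vectors of trait ids (predicted
#'   groups); may be empty.
#' @param truth list with one element per sub-network, each a list with
#'   \code{traits} (P(s)) and \code{causalTraits} (P^C(s)).
#' @param universe character vector of all trait ids under evaluation.
#' @return list(naive = ErrorMatrix, causal = ErrorMatrix, matched =
#'   per-sub-network index of the matched predicted group or NA).
#' @export
groupingErrorMatrices <- function(predicted, truth, universe) {
  tally <- function(Q, pos) {
    c(TP = length(intersect(Q, pos)),
      FP = length(setdiff(Q, pos)),
      FN = length(setdiff(pos, Q)),
      TN = length(setdiff(setdiff(universe, Q), pos)))
  }
  naive <- causal <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  matched <- integer(0)
  for (s in seq_along(truth)) {
    Ps <- truth[[s]]$traits
    if (length(predicted)) {
      inter <- vapply(predicted, function(q) length(intersect(q, Ps)),
                      numeric(1))
      size <- vapply(predicted, length, numeric(1))
      first_id <- vapply(predicted, function(q)
        if (length(q)) sort(q)[1] else "", character(1))
      ord <- order(-inter, size, first_id)
      best <- ord[1]
      Q <- if (inter[best] > 0) predicted[[best]] else character(0)
      matched[s] <- if (inter[best] > 0) best else NA_integer_
    } else {
      Q <- character(0)
      matched[s] <- NA_integer_
    }
    naive <- naive + tally(Q, Ps)
    causal <- causal + tally(Q, truth[[s]]$causalTraits)
  }
  list(naive = errorMatrix(naive["TP"], naive["FP"], naive["TN"], naive["FN"]),
       causal = errorMatrix(causal["TP"], causal["FP"], causal["TN"],
                            causal["FN"]),
       matched = matched)
}

#' Whole-pipeline permutation-based module FDR
#'
#' Reruns the pipeline on datasets in which every transcript's values are
#' independently reshuffled across strains, and reports, per stage, the
#' ratio of the average permuted module count to the observed count.
#'
#' @param ds a \linkS4class{TriadDataset}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param nPerm number of permutations (default 100).
#' @param seed RNG seed.
#' @return list(observed, nullMean, fdr, nullCounts); FDR entries are NA
#'   where the observed count is 0 (undefined).
#' @export
permutationModuleFdr <- function(ds, config = pipelineConfig(), nPerm = 100,
                                 seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  observed <- runPipeline(ds, config)$summary
  stages <- c("bipartite", "tripartite", "driver")
  null_counts <- matrix(0, nPerm, 3, dimnames = list(NULL, stages))
  expr <- expressionValues(ds)
  for (b in seq_len(nPerm)) {
    set.seed(.deriveSeed(seed, b))
    perm <- t(apply(expr, 1, sample))
    colnames(perm) <- colnames(expr)
    ds_perm <- new("TriadDataset", genotypes = variantTable(ds),
                   expression = perm, traits = traitValues(ds),
                   strains = strains(ds), metadata = list())
    null_counts[b, ] <- runPipeline(ds_perm, config)$summary[stages]
  }
  null_mean <- colMeans(null_counts)
  fdr <- ifelse(observed[stages] > 0, null_mean / observed[stages], NA_real_)
  list(observed = observed[stages], nullMean = null_mean, fdr = fdr,
       nullCounts = null_counts)
}

#' Causality benchmark on a simulated triplet collection
#'
#' Computes the broad-sense causality p-value of every triplet and returns
#' AUC, the error matrix at \code{alpha}, balanced accuracy and balanced
#' FDR.
#'
#' @param collection output of \code{\link{simulateTriplets}}.
#' @param B permutations per triplet (default 100).
#' @param alpha call threshold (default 0.05).
#' @param seed RNG seed for the permutation nulls.
#' @return list(pvals, auc, errorMatrix, balancedAccuracy, balancedFdr).
#' @export
benchmarkCausality <- function(collection, B = 100, alpha = 0.05, seed = 1) {
  nt <- nrow(collection$v)
  pvals <- vapply(seq_len(nt), function(i)
    causalityPvalue(collection$v[i, ], collection$g[i, ], collection$p[i, ],
                    B = B, seed = .deriveSeed(seed, i))@causalityP,
    numeric(1))
  e <- causalityErrorMatrix(pvals, collection$causal, alpha)
  list(pvals = pvals, auc = aucBroadSense(pvals, collection$causal),
       errorMatrix = e, balancedAccuracy = balancedAccuracy(e),
       balancedFdr = balancedFdr(e))
}

#' Stage-III grouping benchmark on a sub-network collection
#'
#' Runs the stage-III refinement on every sub-network (its variant as the
#' representative, all transcripts as candidates, all traits as members) and
#' scores the retained trait groups against the ground truth, both naively
#' (against all sub-network traits) and by causality (against the causal
#' traits only).
#'
#' @param collection output of \code{\link{simulateSubnetworks}}.
#' @param transcriptCutoff Fisher-combined transcript cutoff (default 0.005).
#' @param traitCutoff per-pair trait-retention cutoff (default 0.05).
#' @param B permutations per causality test (default 1000).
#' @param seed RNG seed.
#' @return list(naive, causal, predicted): the two error matrices and the
#'   per-sub-network retained trait groups.
#' @export
benchmarkSubnetworkGrouping <- function(collection, transcriptCutoff = 0.005,
                                        traitCutoff = 0.05, B = 1000,
                                        seed = 1) {
  predicted <- list()
  truth <- list()
  universe <- character(0)
  for (s in seq_along(collection)) {
    sub <- collection[[s]]
    prefix <- paste0(sub$id, "_")
    trait_ids <- paste0(prefix, rownames(sub$traits))
    trans_ids <- rownames(sub$transcripts)
    universe <- c(universe, trait_ids)
    truth[[s]] <- list(
      traits = trait_ids,
      causalTraits = trait_ids[sub$trait_class == "causal"])
    pmat <- .causalityMatrix(sub$v, sub$transcripts, sub$traits, B = B,
                             seed = .deriveSeed(seed, s))
    colnames(pmat) <- trait_ids
    ref <- .refineOnMatrix(pmat, transcriptCutoff, traitCutoff)
    if (!is.null(ref)) predicted[[length(predicted) + 1]] <- ref$traits
  }
  res <- groupingErrorMatrices(predicted, truth, universe)
  c(res, list(predicted = predicted))
}
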