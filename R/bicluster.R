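# Stage-I biclustering: seed-and-improve search for heavy sub-blocks of the
# link-potential graph. A member (trait or variant) stays in a cluster iff
# its average link potential over the opposite side exceeds the improvement
# cutoff c_i; seeds are single edges above the seed cutoff c_s. The variant
# side is constrained to a consecutive run on one chromosome (a genomic
# interval): variant additions are restricted to run-adjacent positions and
# surviving variants are trimmed to the heaviest consecutive run.

#' Seed edges for bicluster search
#'
#' @param graph a \linkS4class{BipartiteGraph}.
#' @param cs seed threshold; all edges with weight strictly above it are
#'   seeds.
#' @return data.frame (variant, trait, weight) sorted by descending weight,
#'   ties broken by (variant, trait) lexicographic order; may be empty.
#' @export
seedClusters <- function(graph, cs = 180) {
  W <- graphWeights(graph)
  idx <- which(W > cs, arr.ind = TRUE)
  out <- data.frame(variant = rownames(W)[idx[, 1]],
                    trait = colnames(W)[idx[, 2]],
                    weight = W[idx],
                    stringsAsFactors = FALSE)
  out[order(-out$weight, out$variant, out$trait), , drop = FALSE]
}

# Heaviest maximal consecutive run (by run-block mean weight, ties -> the
# leftmost run) among surviving variant indices; indices refer to the global
# storage order of the variant table.
.heaviestRun <- function(vidx, chrom, W, traits) {
  if (length(vidx) == 0) return(integer(0))
  vidx <- sort(vidx)
  breaks <- which(diff(vidx) > 1 | chrom[vidx[-1]] != chrom[vidx[-length(vidx)]])
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(vidx))
  best <- NULL; best_w <- -Inf
  for (r in seq_along(starts)) {
    run <- vidx[starts[r]:ends[r]]
    w <- mean(W[run, traits, drop = FALSE])
    if (w > best_w + 1e-12) { best_w <- w; best <- run }
  }
  best
}

#' Refine one bicluster seed to a fixed point
#'
#' Alternates addition passes (traits whose mean weight over the current
#' variants exceeds \code{ci}; then variants adjacent to the current
#' consecutive run, same rule) with removal passes (members whose mean weight
#' over the opposite side is at or below \code{ci}), until nothing changes or
#' \code{maxIter} passes elapse.
#'
#' @param graph a \linkS4class{BipartiteGraph}.
#' @param seed one row of \code{\link{seedClusters}} output (or a list with
#'   \code{$variant} and \code{$trait}).
#' @param geno the \linkS4class{VariantTable} supplying variant order and
#'   coordinates.
#' @param cs,ci seed and improvement cutoffs (defaults 180 and 90).
#' @param maxIter iteration cap (default 100); hitting it returns the
#'   current cluster with a warning.
#' @return a \linkS4class{BipartiteModule}, or NULL if either side empties.
#' @export
refineBicluster <- function(graph, seed, geno, cs = 180, ci = 90,
                            maxIter = 100) {
  W <- graphWeights(graph)
  info <- variantInfo(geno)
  stopifnot(identical(rownames(W), rownames(info)))
  chrom <- info$chromosome
  vidx <- match(seed$variant, rownames(W))
  tids <- match(seed$trait, colnames(W))
  if (is.na(vidx) || is.na(tids)) stop("seed ids not found in graph")
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    old_v <- vidx; old_t <- tids
    # (a) additions: traits with mean weight over current variants > ci
    cand_t <- setdiff(seq_len(ncol(W)), tids)
    if (length(cand_t)) {
      mw <- colMeans(W[vidx, cand_t, drop = FALSE])
      tids <- c(tids, cand_t[mw > ci])
    }
    # variants: extend the consecutive run while an adjacent variant
    # (same chromosome) qualifies
    repeat {
      lo <- min(vidx) - 1L
      hi <- max(vidx) + 1L
      grew <- FALSE
      if (lo >= 1 && !(lo %in% vidx) && chrom[lo] == chrom[min(vidx)] &&
          mean(W[lo, tids]) > ci) { vidx <- c(lo, vidx); grew <- TRUE }
      if (hi <= nrow(W) && !(hi %in% vidx) && chrom[hi] == chrom[max(vidx)] &&
          mean(W[hi, tids]) > ci) { vidx <- c(vidx, hi); grew <- TRUE }
      if (!grew) break
    }
    # (b) removals: members whose mean over the opposite side is <= ci
    keep_t <- colMeans(W[vidx, tids, drop = FALSE]) > ci
    tids <- tids[keep_t]
    if (length(tids) == 0) return(NULL)
    keep_v <- rowMeans(W[vidx, tids, drop = FALSE]) > ci
    vidx <- vidx[keep_v]
    if (length(vidx) == 0) return(NULL)
    vidx <- .heaviestRun(vidx, chrom, W, tids)
    if (setequal(vidx, old_v) && setequal(tids, old_t)) { converged <- TRUE; break }
  }
  if (!converged) warning("refineBicluster: no fixed point after ", maxIter,
                          " iterations; returning current cluster")
  vidx <- sort(vidx)
  new("BipartiteModule",
      variantIds = rownames(W)[vidx],
      traitIds = sort(colnames(W)[tids]),
      chromosome = chrom[vidx[1]],
      startBp = min(info$position_bp[vidx]),
      endBp = max(info$position_bp[vidx]),
      meanWeight = mean(W[vidx, tids, drop = FALSE]))
}

#' Find all bipartite modules in a link-potential graph
#'
#' Refines every seed in order, collapses exact-duplicate modules (identical
#' variant and trait sets) and returns modules sorted by descending mean
#' weight.
#'
#' @inheritParams refineBicluster
#' @return list of \linkS4class{BipartiteModule} (possibly empty).
#' @export
findBipartiteModules <- function(graph, geno, cs = 180, ci = 90,
                                 maxIter = 100) {
  seeds <- seedClusters(graph, cs)
  mods <- list()
  keys <- character(0)
  for (i in seq_len(nrow(seeds))) {
    m <- refineBicluster(graph, seeds[i, ], geno, cs = cs, ci = ci,
                         maxIter = maxIter)
    if (is.null(m)) next
    key <- paste(c(m@variantIds, "|", m@traitIds), collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    mods[[length(mods) + 1]] <- m
  }
  if (length(mods))
    mods <- mods[order(-vapply(mods, function(m) m@meanWeight, numeric(1)))]
  mods
}
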