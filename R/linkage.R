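# Stage-I scoring primitives. The link potential of a (variant, trait) pair
# asks whether transcripts strongly associated with the variant are also
# unusually correlated with the trait -- evidence that some transcript could
# mediate between them. Scores are -log10 p-values throughout; degenerate
# statistics map to 0 so graph weights stay finite.

#' Variant-transcript association score
#'
#' For homozygous inbred individuals: -log10 of the two-sample t-test
#' p-value comparing a transcript's expression between the strains carrying
#' the two variant alleles (pooled-variance Student t by default, two-sided).
#'
#' @param g transcript values across strains.
#' @param v genotype values (0/1, NA allowed) across the same strains.
#' @param twoSided two-sided test (default) or upper-tailed.
#' @param welch use the Welch unequal-variance test instead of pooled.
#' @return non-negative score; 0 (with a warning) when either allele group
#'   has fewer than two observations or no variance, so genome scans never
#'   abort.
#' @export
associationScore <- function(g, v, twoSided = TRUE, welch = FALSE) {
  ok <- !is.na(g) & !is.na(v)
  res <- .pooledT(g[ok & v == 1], g[ok & v == 0],
                  one_sided = !twoSided, welch = welch)
  if (is.na(res$p)) {
    warning("degenerate allele groups; association score set to 0")
    return(0)
  }
  .neglog10(res$p)
}

#' Transcript-trait correlation score
#'
#' Absolute Pearson correlation across genetic backgrounds, on
#' pairwise-complete observations.
#'
#' @param g transcript values.
#' @param p trait values.
#' @return |r| in [0, 1]; 0 with a warning when fewer than 3 complete pairs
#'   or zero variance in either vector.
#' @export
correlationScore <- function(g, p) {
  ok <- !is.na(g) & !is.na(p)
  if (sum(ok) < 3 || sd(g[ok]) == 0 || sd(p[ok]) == 0) {
    warning("degenerate pair; correlation score set to 0")
    return(0)
  }
  abs(cor(g[ok], p[ok]))
}

#' All variant-transcript association scores
#'
#' @param expr transcripts x strains matrix.
#' @param geno variants x strains genotype matrix (0/1/NA) or a
#'   \linkS4class{VariantTable}.
#' @param ... passed to the per-row t-test (currently \code{one_sided}).
#' @return variants x transcripts matrix of -log10 t-test p-values;
#'   degenerate entries are 0.
#' @export
associationMatrix <- function(expr, geno, ...) {
  if (is(geno, "VariantTable")) geno <- genotypes(geno)
  stopifnot(identical(colnames(expr), colnames(geno)))
  out <- matrix(0, nrow(geno), nrow(expr),
                dimnames = list(rownames(geno), rownames(expr)))
  for (i in seq_len(nrow(geno))) {
    v <- geno[i, ]
    ok <- !is.na(v)
    if (sum(v[ok] == 1) < 2 || sum(v[ok] == 0) < 2) next
    p <- .rowPooledT(expr[, ok, drop = FALSE], v[ok] == 1, ...)
    score <- .neglog10(p)
    score[is.na(p)] <- 0
    out[i, ] <- score
  }
  out
}

#' All transcript-trait correlation scores
#'
#' @param expr transcripts x strains matrix.
#' @param traits traits x strains matrix (NAs allowed).
#' @return transcripts x traits matrix of absolute Pearson correlations on
#'   pairwise-complete observations; degenerate entries are 0.
#' @export
correlationMatrix <- function(expr, traits) {
  stopifnot(identical(colnames(expr), colnames(traits)))
  r <- suppressWarnings(cor(t(expr), t(traits), use = "pairwise.complete.obs"))
  r <- abs(r)
  r[!is.finite(r)] <- 0
  dimnames(r) <- list(rownames(expr), rownames(traits))
  r
}

# Core link-potential computation from per-transcript association and
# correlation vectors. Cutoffs sit at the 1/n .. (n-1)/n empirical quantiles
# of the association scores (equal-count groups); per cutoff, a pooled
# t-test compares correlation scores of transcripts above vs at/below the
# cutoff; the score is the best -log10 p over the cutoffs.
.linkPotentialFromScores <- function(assoc, corr, nGroups = 6, oneSided = TRUE) {
  stopifnot(length(assoc) == length(corr))
  if (length(assoc) < 2 * nGroups)
    stop("need at least ", 2 * nGroups, " transcripts")
  cutoffs <- quantile(assoc, probs = seq_len(nGroups - 1) / nGroups,
                      names = FALSE)
  best <- 0
  for (cut in cutoffs) {
    high <- assoc > cut
    res <- .pooledT(corr[high], corr[!high], one_sided = oneSided)
    if (!is.na(res$p)) best <- max(best, .neglog10(res$p))
  }
  best
}

#' Link potential of one variant-trait pair
#'
#' @param variant variant id.
#' @param trait trait id.
#' @param ds a \linkS4class{TriadDataset}.
#' @param nGroups number of equal-count association groups (default 6, i.e.
#'   5 cutoffs).
#' @param oneSided test whether high-association transcripts have the
#'   larger mean trait correlation (default); FALSE for two-sided.
#' @return non-negative link-potential score.
#' @export
linkPotential <- function(variant, trait, ds, nGroups = 6, oneSided = TRUE) {
  expr <- expressionValues(ds)
  v <- genotypes(variantTable(ds))[variant, ]
  p <- traitValues(ds)[trait, ]
  assoc <- suppressWarnings(
    vapply(seq_len(nrow(expr)), function(i) associationScore(expr[i, ], v),
           numeric(1)))
  corr <- suppressWarnings(
    vapply(seq_len(nrow(expr)), function(i) correlationScore(expr[i, ], p),
           numeric(1)))
  .linkPotentialFromScores(assoc, corr, nGroups = nGroups, oneSided = oneSided)
}

#' Build the variant x trait link-potential graph
#'
#' Computes every pairwise link potential, reusing one association matrix and
#' one correlation matrix; deterministic given the inputs.
#'
#' @inheritParams linkPotential
#' @return a \linkS4class{BipartiteGraph}.
#' @export
buildBipartiteGraph <- function(ds, nGroups = 6, oneSided = TRUE) {
  A <- associationMatrix(expressionValues(ds), variantTable(ds))
  C <- correlationMatrix(expressionValues(ds), traitValues(ds))
  W <- matrix(0, nrow(A), ncol(C), dimnames = list(rownames(A), colnames(C)))
  nT <- nrow(C)
  if (nT < 2 * nGroups)
    stop("need at least ", 2 * nGroups, " transcripts")
  Stot <- colSums(C)
  Qtot <- colSums(C^2)
  for (i in seq_len(nrow(A))) {
    assoc <- A[i, ]
    cutoffs <- quantile(assoc, probs = seq_len(nGroups - 1) / nGroups,
                        names = FALSE)
    best <- rep(0, ncol(C))
    for (cut in unique(cutoffs)) {
      high <- assoc > cut
      n1 <- sum(high); n0 <- nT - n1
      if (n1 < 2 || n0 < 2) next
      S1 <- colSums(C[high, , drop = FALSE])
      Q1 <- colSums(C[high, , drop = FALSE]^2)
      m1 <- S1 / n1; m0 <- (Stot - S1) / n0
      v1 <- (Q1 - S1^2 / n1) / (n1 - 1)
      v0 <- ((Qtot - Q1) - (Stot - S1)^2 / n0) / (n0 - 1)
      sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
      tstat <- (m1 - m0) / sqrt(sp2 * (1 / n1 + 1 / n0))
      pv <- if (oneSided) pt(tstat, n1 + n0 - 2, lower.tail = FALSE)
            else 2 * pt(-abs(tstat), n1 + n0 - 2)
      score <- .neglog10(pv)
      score[!is.finite(tstat) | sp2 <= 0] <- 0
      best <- pmax(best, score)
    }
    W[i, ] <- best
  }
  new("BipartiteGraph", weights = W)
}

#' Linkage disequilibrium with a focal variant
#'
#' Pearson correlation of every variant's genotype vector with the focal
#' variant's, on pairwise-complete strains.
#'
#' @param geno a \linkS4class{VariantTable}.
#' @param focal focal variant id.
#' @return named correlation vector over all variants; monomorphic variants
#'   get 0 with a warning.
#' @export
ldCorrelation <- function(geno, focal) {
  g <- genotypes(geno)
  if (!focal %in% rownames(g)) stop("unknown focal variant: ", focal)
  f <- g[focal, ]
  r <- suppressWarnings(as.numeric(cor(t(g), f, use = "pairwise.complete.obs")))
  if (any(!is.finite(r))) {
    warning("monomorphic variant(s); LD reported as 0")
    r[!is.finite(r)] <- 0
  }
  setNames(r, rownames(g))
}
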