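# Preprocessing for inbred-panel datasets: per-row Z-scores, the sliding-
# window variance filter for selecting variable genes, and strain alignment.

#' Row-wise Z-score normalization
#'
#' Centers and scales every row to mean 0, sd 1 (sample sd, n-1 denominator)
#' over its non-missing entries. Rows with fewer than two non-missing values
#' or zero variance are passed through unchanged; their ids are recorded in
#' the \code{"skippedRows"} attribute and reported via a message.
#'
#' @param m numeric matrix (features x individuals), NAs allowed.
#' @return the normalized matrix, same dimnames.
#' @export
zscoreNormalize <- function(m) {
  stopifnot(is.matrix(m))
  if (length(m) == 0) stop("empty matrix")
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, sd, na.rm = TRUE)
  nobs <- rowSums(!is.na(m))
  skip <- nobs < 2 | is.na(s) | s == 0
  out <- (m - mu) / s
  out[skip, ] <- m[skip, , drop = FALSE]
  skipped <- rownames(m)[skip]
  if (length(skipped))
    message("zscoreNormalize: ", length(skipped),
            " constant or too-sparse row(s) left unchanged: ",
            paste(head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  attr(out, "skippedRows") <- skipped
  out
}

#' Select genes more variable than their expression-level peers
#'
#' Microarray variance grows with mean intensity, so raw variance ranks
#' mostly reflect expression level. Genes are sorted by row mean; the
#' expected variance of each gene is the mean of row variances within a
#' centered sliding window (truncated at the ends) along that ordering.
#' Genes whose observed variance strictly exceeds their expected variance
#' are retained, in their original row order.
#'
#' @param expr pre-normalization (log-scale) expression matrix, genes x
#'   individuals.
#' @param window window size in genes (default 100).
#' @param center summary of the window variances: \code{"mean"} (default) or
#'   \code{"median"}.
#' @return submatrix of retained genes, original order.
#' @export
filterVariableGenes <- function(expr, window = 100, center = c("mean", "median")) {
  stopifnot(is.matrix(expr))
  center <- match.arg(center)
  n <- nrow(expr)
  if (window < 3 || window > n)
    stop("window must be between 3 and the number of genes (", n, ")")
  mu <- rowMeans(expr, na.rm = TRUE)
  v <- apply(expr, 1, var, na.rm = TRUE)
  ord <- order(mu)
  v_sorted <- v[ord]
  h <- floor(window / 2)
  expected_sorted <- vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    if (center == "mean") mean(v_sorted[idx]) else stats::median(v_sorted[idx])
  }, numeric(1))
  expected <- numeric(n)
  expected[ord] <- expected_sorted
  expr[v > expected, , drop = FALSE]
}

#' Align genotype, expression and trait matrices on common strains
#'
#' Restricts all three matrices to the (lexicographically sorted)
#' intersection of their strain ids and drops traits observed in fewer than
#' \code{minOverlap} of the common strains.
#'
#' @param geno a \linkS4class{VariantTable}.
#' @param expr transcripts x strains matrix.
#' @param traits traits x strains matrix (NAs allowed).
#' @param minOverlap minimum non-missing strain count per retained trait
#'   (default 15).
#' @return a \linkS4class{TriadDataset}; dropped trait ids are stored in
#'   \code{metadata$droppedTraits}.
#' @export
alignStrains <- function(geno, expr, traits, minOverlap = 15) {
  stopifnot(is(geno, "VariantTable"), is.matrix(expr), is.matrix(traits))
  common <- sort(Reduce(intersect, list(colnames(genotypes(geno)),
                                        colnames(expr), colnames(traits))))
  if (length(common) == 0)
    stop("no strains shared by genotype, expression and trait matrices")
  g <- genotypes(geno)[, common, drop = FALSE]
  e <- expr[, common, drop = FALSE]
  tr <- traits[, common, drop = FALSE]
  keep <- rowSums(!is.na(tr)) >= minOverlap
  dropped <- rownames(tr)[!keep]
  if (length(dropped))
    message("alignStrains: dropped ", length(dropped),
            " trait(s) with < ", minOverlap, " observed strains")
  tr <- tr[keep, , drop = FALSE]
  vt <- new("VariantTable", genotypes = g, info = variantInfo(geno))
  new("TriadDataset", genotypes = vt, expression = e, traits = tr,
      strains = common, metadata = list(droppedTraits = dropped,
                                        minOverlap = minOverlap))
}
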