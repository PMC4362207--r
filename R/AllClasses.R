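#' @import methods
#' @importFrom stats cor pchisq pt quantile rbinom rnorm sd setNames var
#' @importFrom utils head
NULL

#' Genotyped variants with genomic coordinates
#'
#' Container for a biallelic genotype matrix (variants x strains, coded 0/1
#' with \code{NA} for unknown or heterozygous calls) together with per-variant
#' chromosome and 1-based physical position. Variants are stored sorted by
#' (chromosome, position); within a chromosome positions must be strictly
#' increasing, so that a "genomic interval" is a consecutive run of rows.
#'
#' @slot genotypes numeric matrix, variants x strains, values in \{0, 1, NA\}.
#' @slot info data.frame with columns \code{chromosome} (character) and
#'   \code{position_bp} (positive integer), one row per variant, rownames
#'   matching the genotype rownames.
#' @exportClass VariantTable
setClass("VariantTable", representation(
  genotypes = "matrix",
  info = "data.frame"
))

setValidity("VariantTable", function(object) {
  g <- object@genotypes
  info <- object@info
  if (is.null(rownames(g)) || is.null(colnames(g)))
    return("genotype matrix must have row (variant) and column (strain) names")
  if (anyDuplicated(rownames(g))) return("duplicated variant ids")
  if (anyDuplicated(colnames(g))) return("duplicated strain ids")
  if (!all(g %in% c(0, 1, NA))) return("genotype values must be 0, 1 or NA")
  if (!identical(rownames(info), rownames(g)))
    return("info rownames must match genotype rownames")
  if (!all(c("chromosome", "position_bp") %in% colnames(info)))
    return("info must have columns chromosome and position_bp")
  if (any(info$position_bp < 1)) return("position_bp must be >= 1")
  # strictly increasing positions within each chromosome, in storage order
  for (chr in unique(info$chromosome)) {
    pos <- info$position_bp[info$chromosome == chr]
    if (any(diff(pos) <= 0))
      return(sprintf("positions on chromosome %s are not strictly increasing", chr))
  }
  TRUE
})

#' Construct a VariantTable
#'
#' Rows are sorted by (chromosome, position) on construction.
#'
#' @param genotypes variants x strains numeric matrix with values 0/1/NA and
#'   unique dimnames.
#' @param chromosome character vector, one entry per variant.
#' @param position_bp positive integer vector of 1-based physical positions.
#' @return A \linkS4class{VariantTable}.
#' @export
VariantTable <- function(genotypes, chromosome, position_bp) {
  stopifnot(is.matrix(genotypes),
            length(chromosome) == nrow(genotypes),
            length(position_bp) == nrow(genotypes))
  info <- data.frame(chromosome = as.character(chromosome),
                     position_bp = as.integer(position_bp),
                     row.names = rownames(genotypes),
                     stringsAsFactors = FALSE)
  ord <- order(info$chromosome, info$position_bp)
  new("VariantTable", genotypes = genotypes[ord, , drop = FALSE],
      info = info[ord, , drop = FALSE])
}

#' Accessors for VariantTable
#'
#' @param x a \linkS4class{VariantTable}.
#' @return \code{genotypes} returns the variants x strains matrix;
#'   \code{variantInfo} the coordinate data.frame; \code{variantIds} the ids.
#' @export
genotypes <- function(x) x@genotypes

#' @rdname genotypes
#' @export
variantInfo <- function(x) x@info

#' @rdname genotypes
#' @export
variantIds <- function(x) rownames(x@genotypes)

setMethod("show", "VariantTable", function(object) {
  cat(sprintf("VariantTable: %d variants x %d strains (%d chromosome(s))\n",
              nrow(object@genotypes), ncol(object@genotypes),
              length(unique(object@info$chromosome))))
})

#' Aligned genotype / expression / trait dataset
#'
#' The three input matrices restricted to a common, lexicographically ordered
#' strain list. Built by \code{\link{alignStrains}}.
#'
#' @slot genotypes a \linkS4class{VariantTable}.
#' @slot expression transcripts x strains numeric matrix.
#' @slot traits traits x strains numeric matrix (NAs allowed).
#' @slot strains character vector of common strain ids.
#' @slot metadata list of provenance notes (e.g. traits dropped at alignment).
#' @exportClass TriadDataset
setClass("TriadDataset", representation(
  genotypes = "VariantTable",
  expression = "matrix",
  traits = "matrix",
  strains = "character",
  metadata = "list"
))

setValidity("TriadDataset", function(object) {
  s <- object@strains
  if (anyDuplicated(s)) return("duplicated strain ids")
  if (!identical(colnames(object@genotypes@genotypes), s))
    return("genotype columns do not match strain list")
  if (!identical(colnames(object@expression), s))
    return("expression columns do not match strain list")
  if (!identical(colnames(object@traits), s))
    return("trait columns do not match strain list")
  if (anyDuplicated(rownames(object@expression))) return("duplicated transcript ids")
  if (anyDuplicated(rownames(object@traits))) return("duplicated trait ids")
  TRUE
})

#' Accessors for TriadDataset
#'
#' @param x a \linkS4class{TriadDataset}.
#' @return the corresponding component.
#' @export
expressionValues <- function(x) x@expression

#' @rdname expressionValues
#' @export
traitValues <- function(x) x@traits

#' @rdname expressionValues
#' @export
strains <- function(x) x@strains

#' @rdname expressionValues
#' @export
variantTable <- function(x) x@genotypes

setMethod("show", "TriadDataset", function(object) {
  cat(sprintf(paste0("TriadDataset: %d strains\n",
                     "  variants:    %d\n  transcripts: %d\n  traits:      %d\n"),
              length(object@strains), nrow(object@genotypes@genotypes),
              nrow(object@expression), nrow(object@traits)))
})

#' Variant-trait link-potential graph
#'
#' Weighted bipartite graph whose parts are genetic variants and traits; the
#' weight of an edge is the link-potential score, a non-negative -log10
#' p-value quantifying whether transcripts strongly associated with the
#' variant are also unusually correlated with the trait.
#'
#' @slot weights variants x traits non-negative matrix.
#' @exportClass BipartiteGraph
setClass("BipartiteGraph", representation(weights = "matrix"))

setValidity("BipartiteGraph", function(object) {
  w <- object@weights
  if (is.null(rownames(w)) || is.null(colnames(w)))
    return("weights must carry variant and trait ids as dimnames")
  if (any(!is.finite(w)) || any(w < 0))
    return("all weights must be finite and >= 0")
  TRUE
})

#' Edge weights of a bipartite link-potential graph
#'
#' @param x a \linkS4class{BipartiteGraph}.
#' @return the variants x traits weight matrix.
#' @export
setGeneric("graphWeights", function(x) standardGeneric("graphWeights"))

#' @rdname graphWeights
#' @export
setMethod("graphWeights", "BipartiteGraph", function(x) x@weights)

setMethod("show", "BipartiteGraph", function(object) {
  cat(sprintf("BipartiteGraph: %d variants x %d traits, max weight %.3g\n",
              nrow(object@weights), ncol(object@weights),
              if (length(object@weights)) max(object@weights) else NA_real_))
})

#' Bipartite module: one genomic interval plus a trait group
#'
#' A heavy bicluster of the link-potential graph: a consecutive run of
#' variants on one chromosome and a set of traits, such that every member's
#' average link potential over the opposite side exceeds the improvement
#' cutoff used during the search.
#'
#' @slot variantIds ordered ids of the interval's consecutive variants.
#' @slot traitIds member trait ids.
#' @slot chromosome,startBp,endBp the genomic interval.
#' @slot meanWeight mean link potential over the variant x trait block.
#' @exportClass BipartiteModule
setClass("BipartiteModule", representation(
  variantIds = "character",
  traitIds = "character",
  chromosome = "character",
  startBp = "numeric",
  endBp = "numeric",
  meanWeight = "numeric"
))

setValidity("BipartiteModule", function(object) {
  if (length(object@variantIds) < 1) return("module needs >= 1 variant")
  if (length(object@traitIds) < 1) return("module needs >= 1 trait")
  if (length(object@chromosome) != 1) return("interval must sit on one chromosome")
  TRUE
})

setMethod("show", "BipartiteModule", function(object) {
  cat(sprintf("BipartiteModule: %s:%d-%d (%d variants), %d traits, mean weight %.1f\n",
              object@chromosome, object@startBp, object@endBp,
              length(object@variantIds), length(object@traitIds),
              object@meanWeight))
})

#' Tripartite module: bipartite module plus candidate transcripts
#'
#' @slot base the underlying \linkS4class{BipartiteModule}.
#' @slot candidates transcript ids with significant link scores, sorted by
#'   ascending score.
#' @slot linkScores named numeric vector of Kolmogorov-Smirnov link-score
#'   p-values for the candidates.
#' @exportClass TripartiteModule
setClass("TripartiteModule", representation(
  base = "BipartiteModule",
  candidates = "character",
  linkScores = "numeric"
))

setValidity("TripartiteModule", function(object) {
  if (!identical(names(object@linkScores), object@candidates))
    return("linkScores must be named by (and ordered as) candidates")
  if (anyDuplicated(object@candidates)) return("duplicated candidate ids")
  TRUE
})

setMethod("show", "TripartiteModule", function(object) {
  show(object@base)
  cat(sprintf("  + %d candidate transcripts (best link score %.3g)\n",
              length(object@candidates),
              if (length(object@linkScores)) min(object@linkScores) else NA_real_))
})

#' Final module with validated driver transcripts
#'
#' Output of stage-III refinement: the genomic interval, its representative
#' variant, the surviving driver transcripts (Fisher-combined causality
#' p-value below the cutoff), the traits they affect, and the full causality
#' p-value matrix.
#'
#' @slot chromosome,startBp,endBp the genomic interval.
#' @slot representativeVariant id of the interval variant anchoring all
#'   causality tests.
#' @slot drivers driver transcript ids.
#' @slot traitIds affected trait ids.
#' @slot causalityMatrix drivers x traits matrix of causality p-values.
#' @slot fisherP named per-driver Fisher-combined p-value over the traits.
#' @exportClass DriverModule
setClass("DriverModule", representation(
  chromosome = "character",
  startBp = "numeric",
  endBp = "numeric",
  representativeVariant = "character",
  drivers = "character",
  traitIds = "character",
  causalityMatrix = "matrix",
  fisherP = "numeric"
))

setValidity("DriverModule", function(object) {
  if (length(object@drivers) < 1) return("module needs >= 1 driver")
  if (length(object@traitIds) < 1) return("module needs >= 1 trait")
  if (!identical(rownames(object@causalityMatrix), object@drivers) ||
      !identical(colnames(object@causalityMatrix), object@traitIds))
    return("causalityMatrix dimnames must match drivers and traits")
  if (!identical(names(object@fisherP), object@drivers))
    return("fisherP must be named by drivers")
  TRUE
})

setMethod("show", "DriverModule", function(object) {
  cat(sprintf(paste0("DriverModule: %s:%d-%d (representative %s)\n",
                     "  drivers: %s\n  traits:  %s\n"),
              object@chromosome, object@startBp, object@endBp,
              object@representativeVariant,
              paste(object@drivers, collapse = ", "),
              paste(object@traitIds, collapse = ", ")))
})

#' Result of one triplet causality test
#'
#' Likelihood-ratio scores of the causal model against the independence (M2)
#' and reactive (M3) alternatives, with empirical permutation p-values. The
#' broad-sense causality p-value is the maximum of the two.
#'
#' @slot lrVsM2,lrVsM3 observed log-likelihood-ratio scores.
#' @slot pVsM2,pVsM3 empirical p-values with add-one correction, each in
#'   [1/(B+1), 1].
#' @slot causalityP max(pVsM2, pVsM3).
#' @slot nPermutations number of transcript reshuffles B.
#' @slot seed RNG seed used.
#' @exportClass CausalityResult
setClass("CausalityResult", representation(
  lrVsM2 = "numeric", lrVsM3 = "numeric",
  pVsM2 = "numeric", pVsM3 = "numeric",
  causalityP = "numeric", nPermutations = "integer", seed = "integer"
))

setValidity("CausalityResult", function(object) {
  B <- object@nPermutations
  lo <- 1 / (B + 1)
  if (object@causalityP < max(object@pVsM2, object@pVsM3) - 1e-12 ||
      object@causalityP > max(object@pVsM2, object@pVsM3) + 1e-12)
    return("causalityP must equal max(pVsM2, pVsM3)")
  if (any(c(object@pVsM2, object@pVsM3) < lo - 1e-12) ||
      any(c(object@pVsM2, object@pVsM3) > 1 + 1e-12))
    return("p-values out of [1/(B+1), 1]")
  TRUE
})

setMethod("show", "CausalityResult", function(object) {
  cat(sprintf("CausalityResult: LR2 %.3f (p %.4g), LR3 %.3f (p %.4g) -> causality p %.4g [B=%d]\n",
              object@lrVsM2, object@pVsM2, object@lrVsM3, object@pVsM3,
              object@causalityP, object@nPermutations))
})

#' @rdname expressionValues
#' @export
causalityP <- function(x) x@causalityP
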