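# End-to-end pipeline: link-potential graph -> bipartite biclusters ->
# candidate transcripts -> validated driver modules, with provenance and
# file-based orchestration.

#' Pipeline configuration
#'
#' Collects the operating constants of the three stages. The seed cutoff
#' \code{cs} and improvement cutoff \code{ci} act on -log10 link-potential
#' scores; \code{linkCutoff} is the stage-II transcript link-score p-value
#' cutoff; \code{causalityCutoff} the stage-III transcript causality cutoff.
#' \code{bRefine} (permutations in refinement) must satisfy
#' bRefine >= 1/causalityCutoff - 1 so the cutoff is attainable.
#'
#' @param cs,ci bicluster seed / improvement thresholds (defaults 180 / 90).
#' @param nGroups link-potential association groups (default 6).
#' @param oneSided one-sided link-potential t-tests (default TRUE).
#' @param linkCutoff stage-II p-value cutoff (default 0.01; genome-scale
#'   backgrounds support far smaller operating points).
#' @param causalityCutoff stage-III Fisher-combined transcript cutoff
#'   (default 0.005).
#' @param traitCutoff stage-III per-pair trait-retention cutoff (default
#'   0.05).
#' @param bRefine permutations per causality test in refinement (default
#'   1000).
#' @param bBenchmark permutations in benchmarking contexts (default 100).
#' @param minOverlap minimum strains per trait at alignment (default 15).
#' @param maxIter bicluster iteration cap (default 100).
#' @param seed RNG seed for all stochastic steps.
#' @return a \code{"PipelineConfig"} list.
#' @export
pipelineConfig <- function(cs = 180, ci = 90, nGroups = 6, oneSided = TRUE,
                           linkCutoff = 0.01, causalityCutoff = 0.005,
                           traitCutoff = 0.05, bRefine = 1000,
                           bBenchmark = 100, minOverlap = 15, maxIter = 100,
                           seed = 1) {
  stopifnot(cs >= ci, ci > 0, nGroups >= 2,
            linkCutoff > 0, linkCutoff <= 1,
            causalityCutoff > 0, causalityCutoff < 1,
            traitCutoff > 0, traitCutoff < 1,
            bRefine >= 1 / min(causalityCutoff, traitCutoff) - 1)
  structure(list(cs = cs, ci = ci, nGroups = nGroups, oneSided = oneSided,
                 linkCutoff = linkCutoff, causalityCutoff = causalityCutoff,
                 traitCutoff = traitCutoff,
                 bRefine = bRefine, bBenchmark = bBenchmark,
                 minOverlap = minOverlap, maxIter = maxIter,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the three-stage module-discovery pipeline
#'
#' Stage I builds the link-potential graph and extracts bipartite modules;
#' stage II attaches candidate transcripts by their K-S link scores; stage
#' III validates drivers by permutation causality tests. A stage with zero
#' surviving modules short-circuits the rest.
#'
#' @param ds a \linkS4class{TriadDataset}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param verbose print per-stage progress.
#' @return a \code{"PipelineResult"} list: \code{graph}, \code{bipartite},
#'   \code{tripartite}, \code{modules} (driver modules), \code{summary}
#'   (named per-stage counts) and \code{config}.
#' @export
runPipeline <- function(ds, config = pipelineConfig(), verbose = FALSE) {
  assocMat <- associationMatrix(expressionValues(ds), variantTable(ds))
  corrMat <- correlationMatrix(expressionValues(ds), traitValues(ds))
  graph <- buildBipartiteGraph(ds, nGroups = config$nGroups,
                               oneSided = config$oneSided)
  bip <- findBipartiteModules(graph, variantTable(ds), cs = config$cs,
                              ci = config$ci, maxIter = config$maxIter)
  if (verbose) message("stage I: ", length(bip), " bipartite module(s)")
  trip <- list()
  for (m in bip) {
    tm <- extendToTripartite(m, ds, cutoff = config$linkCutoff,
                             assocMat = assocMat, corrMat = corrMat)
    if (!is.null(tm)) trip[[length(trip) + 1]] <- tm
  }
  if (verbose) message("stage II: ", length(trip), " tripartite module(s)")
  drivers <- list()
  for (i in seq_along(trip)) {
    dm <- refineModule(trip[[i]], ds,
                       transcriptCutoff = config$causalityCutoff,
                       traitCutoff = config$traitCutoff,
                       B = config$bRefine,
                       seed = .deriveSeed(config$seed, i),
                       assocMat = assocMat)
    if (!is.null(dm)) drivers[[length(drivers) + 1]] <- dm
  }
  if (verbose) message("stage III: ", length(drivers), " driver module(s)")
  structure(list(graph = graph, bipartite = bip, tripartite = trip,
                 modules = drivers,
                 summary = c(bipartite = length(bip),
                             tripartite = length(trip),
                             driver = length(drivers)),
                 config = config),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult: %d bipartite -> %d tripartite -> %d driver module(s)\n",
              x$summary["bipartite"], x$summary["tripartite"],
              x$summary["driver"]))
  invisible(x)
}

#' Run the pipeline from TSV inputs and write a report directory
#'
#' Reads the three matrices, aligns strains, Z-score-normalizes traits and
#' expression, runs \code{\link{runPipeline}} and writes: the module tables
#' (flat TSV: module_id, layer, member_id, score), the bipartite-graph edge
#' dump, and a JSON run summary carrying the full configuration and seed.
#'
#' @param genoPath variant table TSV (see \code{\link{readVariantTable}}).
#' @param exprPath,traitPath labeled-matrix TSVs, features on rows.
#' @param outDir output directory (created if absent).
#' @param config a \code{\link{pipelineConfig}}.
#' @param normalize Z-score-normalize expression and traits before the run
#'   (default TRUE).
#' @return the \code{"PipelineResult"}, invisibly.
#' @export
runPipelineFiles <- function(genoPath, exprPath, traitPath, outDir,
                             config = pipelineConfig(), normalize = TRUE) {
  geno <- readVariantTable(genoPath)
  expr <- readMatrixTSV(exprPath)
  traits <- readMatrixTSV(traitPath)
  ds <- alignStrains(geno, expr, traits, minOverlap = config$minOverlap)
  if (normalize) {
    ds@expression <- zscoreNormalize(ds@expression)
    attr(ds@expression, "skippedRows") <- NULL
    ds@traits <- zscoreNormalize(ds@traits)
    attr(ds@traits, "skippedRows") <- NULL
  }
  res <- runPipeline(ds, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeModuleReport(res, outDir)
  invisible(res)
}

# Flat member table for one module layer.
.memberRows <- function(module_id, layer, ids, scores = NA_real_) {
  if (length(ids) == 0) return(NULL)
  data.frame(module_id = module_id, layer = layer, member_id = ids,
             score = scores, stringsAsFactors = FALSE)
}

#' Write a pipeline result to disk
#'
#' Emits \code{modules.tsv} (flat member table over all stages),
#' \code{graph_edges.tsv} (variant, trait, link potential) and
#' \code{summary.json} (per-stage counts, configuration, seed).
#'
#' @param res a \code{"PipelineResult"}.
#' @param outDir output directory (must exist).
#' @return \code{outDir}, invisibly.
#' @export
writeModuleReport <- function(res, outDir) {
  rows <- list()
  for (i in seq_along(res$bipartite)) {
    m <- res$bipartite[[i]]
    id <- sprintf("bip%03d", i)
    rows[[length(rows) + 1]] <- .memberRows(id, "variant", m@variantIds)
    rows[[length(rows) + 1]] <- .memberRows(id, "trait", m@traitIds)
  }
  for (i in seq_along(res$tripartite)) {
    m <- res$tripartite[[i]]
    id <- sprintf("tri%03d", i)
    rows[[length(rows) + 1]] <- .memberRows(id, "variant", m@base@variantIds)
    rows[[length(rows) + 1]] <- .memberRows(id, "trait", m@base@traitIds)
    rows[[length(rows) + 1]] <- .memberRows(id, "candidate", m@candidates,
                                            m@linkScores)
  }
  for (i in seq_along(res$modules)) {
    m <- res$modules[[i]]
    id <- sprintf("mod%03d", i)
    rows[[length(rows) + 1]] <- .memberRows(id, "representative_variant",
                                            m@representativeVariant)
    rows[[length(rows) + 1]] <- .memberRows(id, "driver", m@drivers,
                                            m@fisherP)
    rows[[length(rows) + 1]] <- .memberRows(id, "trait", m@traitIds)
  }
  members <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = character(0), layer = character(0),
               member_id = character(0), score = numeric(0))
  utils::write.table(members, file.path(outDir, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  W <- graphWeights(res$graph)
  edges <- data.frame(variant_id = rep(rownames(W), ncol(W)),
                      trait_id = rep(colnames(W), each = nrow(W)),
                      link_potential = as.numeric(W))
  utils::write.table(edges, file.path(outDir, "graph_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = as.list(res$summary), config = unclass(res$config)),
    file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}
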