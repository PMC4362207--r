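# Tab-separated readers/writers for the labeled-matrix dialect:
# one header row of strain (column) ids, one leading column of row ids,
# "NA" (or empty) for missing. Strict: malformed input raises an error
# naming the offending id, line or cell instead of silently coercing.

.parseTsvTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) < 2)
    stop("file ", path, " must have a header row and at least one data row")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  ncol_expected <- length(header)
  for (i in seq_along(cells)[-1]) {
    if (length(cells[[i]]) != ncol_expected)
      stop(sprintf("ragged row at line %d: expected %d fields, found %d",
                   i, ncol_expected, length(cells[[i]])))
  }
  list(header = header, rows = cells[-1])
}

.numericCell <- function(token, row_id, col_id, missing_tokens) {
  if (token %in% missing_tokens) return(NA_real_)
  value <- suppressWarnings(as.numeric(token))
  if (is.na(value))
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s'",
                 token, row_id, col_id))
  value
}

#' Read a labeled matrix from tab-separated text
#'
#' Expects one header row of column (strain) ids and one leading column of
#' row ids; cells are decimal numbers or a missing token.
#'
#' @param path file path.
#' @param rowsAreFeatures if FALSE the matrix is transposed after reading, so
#'   features always end up on rows.
#' @param missingTokens tokens treated as missing (default \code{"NA"} and
#'   the empty string).
#' @return numeric matrix with unique row and column names.
#' @export
readMatrixTSV <- function(path, rowsAreFeatures = TRUE,
                          missingTokens = c("NA", "")) {
  tab <- .parseTsvTable(path)
  col_ids <- tab$header[-1]
  if (anyDuplicated(col_ids))
    stop("duplicated column id: ", col_ids[duplicated(col_ids)][1])
  row_ids <- vapply(tab$rows, `[[`, character(1), 1)
  if (anyDuplicated(row_ids))
    stop("duplicated row id: ", row_ids[duplicated(row_ids)][1])
  values <- matrix(NA_real_, length(row_ids), length(col_ids),
                   dimnames = list(row_ids, col_ids))
  for (i in seq_along(tab$rows)) {
    tokens <- tab$rows[[i]][-1]
    for (j in seq_along(tokens))
      values[i, j] <- .numericCell(tokens[j], row_ids[i], col_ids[j],
                                   missingTokens)
  }
  if (!rowsAreFeatures) values <- t(values)
  values
}

#' Write a labeled matrix as tab-separated text
#'
#' Emits the same dialect \code{\link{readMatrixTSV}} reads; numbers are
#' printed with 12 significant digits so a write-read round trip is lossless
#' at that precision. Missing values become \code{"NA"}.
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @param idHeader label for the leading id column.
#' @export
writeMatrixTSV <- function(m, path, idHeader = "id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.12g", x))
  lines <- c(paste(c(idHeader, colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a variant metadata + genotype table
#'
#' Expects columns \code{variant_id}, \code{chromosome}, \code{position_bp}
#' followed by one column per strain. Genotype tokens are mapped to 0/1 via
#' \code{alleleMap}; any other token (heterozygous or unknown call) becomes
#' missing.
#'
#' @param path file path.
#' @param alleleMap named numeric vector mapping genotype tokens to 0/1.
#' @return a \linkS4class{VariantTable}.
#' @export
readVariantTable <- function(path,
                             alleleMap = c("0" = 0, "1" = 1, "B" = 0, "D" = 1)) {
  tab <- .parseTsvTable(path)
  fixed <- c("variant_id", "chromosome", "position_bp")
  if (!identical(tab$header[1:3], fixed))
    stop("variant table must start with columns: ", paste(fixed, collapse = ", "))
  strain_ids <- tab$header[-(1:3)]
  if (anyDuplicated(strain_ids))
    stop("duplicated strain id: ", strain_ids[duplicated(strain_ids)][1])
  ids <- vapply(tab$rows, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicated variant id: ", ids[duplicated(ids)][1])
  chrom <- vapply(tab$rows, `[[`, character(1), 2)
  pos <- vapply(seq_along(tab$rows), function(i)
    .numericCell(tab$rows[[i]][3], ids[i], "position_bp", character(0)),
    numeric(1))
  if (any(pos < 1 | pos != round(pos)))
    stop("position_bp must be positive integers")
  geno <- matrix(NA_real_, length(ids), length(strain_ids),
                 dimnames = list(ids, strain_ids))
  for (i in seq_along(tab$rows)) {
    tokens <- tab$rows[[i]][-(1:3)]
    hit <- match(tokens, names(alleleMap))
    geno[i, ] <- unname(alleleMap)[hit]
  }
  VariantTable(geno, chrom, pos)
}

#' Write a variant table in the dialect of \code{\link{readVariantTable}}
#'
#' Genotypes are written as 0/1 with \code{"NA"} for missing.
#'
#' @param vt a \linkS4class{VariantTable}.
#' @param path output file path.
#' @export
writeVariantTable <- function(vt, path) {
  g <- genotypes(vt)
  info <- variantInfo(vt)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%d", as.integer(x)))
  lines <- c(paste(c("variant_id", "chromosome", "position_bp", colnames(g)),
                   collapse = "\t"),
             vapply(seq_len(nrow(g)), function(i)
               paste(c(rownames(g)[i], info$chromosome[i],
                       sprintf("%d", info$position_bp[i]), fmt(g[i, ])),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}
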