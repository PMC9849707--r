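#' Write a haplotype table as TSV with Total row and column
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
writeHaplotypeTable <- function(table, path) {
  cn <- counts(table)
  out <- rbind(cn, Total = colSums(cn))
  out <- cbind(out, Total = rowSums(out))
  df <- data.frame(haplotype = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a haplotype x period count table from TSV
#'
#' Accepts tables with or without Total row/column (they are stripped). The
#' first column holds haplotype labels; remaining columns are periods.
#'
#' @param path TSV path.
#' @return a \linkS4class{HaplotypeTable}.
#' @export
readHaplotypeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  labs <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- labs
  m <- m[rownames(m) != "Total", colnames(m) != "Total", drop = FALSE]
  HaplotypeTable(m)
}

#' The packaged Saimaa haplotype-by-period count table
#'
#' The published count table of 14 mtDNA control-region haplotypes across the
#' five temporal groups TG1 (1894-1939) to TG5 (2000-2011); per-period totals
#' 23, 33, 81, 56 and 128 (N = 321).
#'
#' @return a \linkS4class{HaplotypeTable}.
#' @export
saimaaTable <- function() {
  readHaplotypeTable(system.file("extdata", "saimaa_haplotype_counts.tsv",
                                 package = "haplodrift", mustWork = TRUE))
}

#' Export a haplotype catalog as JSON
#'
#' @param catalog a \linkS4class{HaplotypeCatalog}.
#' @param path output JSON path.
#' @return invisibly, the list serialized.
#' @export
writeCatalogJSON <- function(catalog, path) {
  x <- list(policy = catalog@policy,
            haplotypes = as.list(haploSequences(catalog)),
            membership = as.list(membership(catalog)),
            excluded = exclusions(catalog))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(x)
}
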