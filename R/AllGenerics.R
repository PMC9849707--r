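#' @importFrom BiocGenerics counts
NULL

#' Extract the haplotype x period count matrix
#'
#' @param object a \linkS4class{HaplotypeTable}.
#' @param ... ignored.
#' @return integer matrix (haplotypes x periods).
#' @export
setMethod("counts", "HaplotypeTable", function(object, ...) object@counts)

#' @rdname accessors
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname accessors
#' @export
setGeneric("exclusions", function(object) standardGeneric("exclusions"))

#' @rdname accessors
#' @export
setGeneric("haploSequences", function(object) standardGeneric("haploSequences"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("resultsTable", function(object) standardGeneric("resultsTable"))

#' @rdname accessors
#' @export
setGeneric("periodLabels", function(object) standardGeneric("periodLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleMeta", function(object) standardGeneric("sampleMeta"))

#' @rdname accessors
#' @export
setGeneric("alignmentLength", function(object) standardGeneric("alignmentLength"))

#' @rdname accessors
#' @export
setGeneric("replicationMask", function(object) standardGeneric("replicationMask"))

#' Accessors for haplodrift objects
#'
#' \code{membership} and \code{exclusions} read a catalog's sample-to-haplotype
#' map and its exclusion table; \code{haploSequences} its haplotype sequences.
#' \code{networkNodes}/\code{networkEdges} read a network's node and edge
#' tables. \code{resultsTable} reads the per-cell table of a test result.
#' \code{periodLabels} reads period labels; \code{sampleMeta},
#' \code{alignmentLength} and \code{replicationMask} read alignment pieces.
#'
#' @param object the object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("membership", "HaplotypeCatalog", function(object) object@membership)

#' @rdname accessors
#' @export
setMethod("exclusions", "HaplotypeCatalog", function(object) object@excluded)

#' @rdname accessors
#' @export
setMethod("haploSequences", "HaplotypeCatalog",
          function(object) object@sequences)

#' @rdname accessors
#' @export
setMethod("networkNodes", "HaplotypeNetwork", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("networkEdges", "HaplotypeNetwork", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("resultsTable", "ResamplingTestResult",
          function(object) object@results)

#' @rdname accessors
#' @export
setMethod("periodLabels", "TemporalGrouping", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("periodLabels", "HaplotypeTable",
          function(object) colnames(object@counts))

#' @rdname accessors
#' @export
setMethod("sampleMeta", "HaplotypeAlignment", function(object) object@meta)

#' @rdname accessors
#' @export
setMethod("alignmentLength", "HaplotypeAlignment",
          function(object) unique(Biostrings::width(object@seqs)))

#' @rdname accessors
#' @export
setMethod("replicationMask", "HaplotypeAlignment",
          function(object) object@replicated)

setMethod("show", "HaplotypeAlignment", function(object) {
  cat(sprintf("HaplotypeAlignment: %d sequences x %d columns\n",
              length(object@seqs), alignmentLength(object)))
  yr <- range(object@meta$year, na.rm = TRUE)
  cat(sprintf("  years %d-%d; %d unreplicated cells\n",
              yr[1], yr[2], sum(!object@replicated)))
})

setMethod("show", "TemporalGrouping", function(object) {
  cat("TemporalGrouping:\n")
  for (i in seq_along(object@label))
    cat(sprintf("  %s: %d-%d\n", object@label[i], object@start[i],
                object@end[i]))
})

setMethod("show", "HaplotypeCatalog", function(object) {
  cat(sprintf("HaplotypeCatalog: %d haplotypes, %d samples, %d excluded (policy %s)\n",
              length(object@sequences), length(object@membership),
              nrow(object@excluded), object@policy))
})

setMethod("show", "HaplotypeTable", function(object) {
  cat(sprintf("HaplotypeTable: %d haplotypes x %d periods (N = %d)\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts)))
  print(object@counts)
})

setMethod("show", "HaplotypeNetwork", function(object) {
  cat(sprintf("HaplotypeNetwork (%s): %d nodes, %d edges (%d tie edges)\n",
              object@gapMode, nrow(object@nodes), nrow(object@edges),
              sum(object@edges$tie_edge)))
})

setMethod("show", "ResamplingTestResult", function(object) {
  sig <- countSignificant(object)
  cat(sprintf(
    "ResamplingTestResult (%s, tail rule %s, reference %s, alpha %g):\n",
    object@method, object@tailRule, object@reference, object@alpha))
  cat(sprintf("  %d tests; %d significant cells in %d haplotypes\n",
              nrow(object@results), sig[["n_significant_tests"]],
              sig[["n_significant_haplotypes"]]))
})

setMethod("show", "RarefactionCurve", function(object) {
  cat(sprintf(
    "RarefactionCurve: n = %d, S_obs = %g, Chao1 asymptote = %g, %d grid points\n",
    object@n, object@sObs, object@asymptote, length(object@m)))
})

setMethod("show", "ChiSquareResult", function(object) {
  cat(sprintf("Chi-square homogeneity: X2 = %.4g, df = %d, p = %.4g%s\n",
              object@statistic, object@df, object@p,
              if (object@lowExpectedFlag)
                " [>20% of expected counts < 5]" else ""))
})

setMethod("show", "DiversityStats", function(object) {
  cat(sprintf("DiversityStats: h = %.4f, pi = %s (n = %d)\n",
              object@haplotypeDiversity,
              if (is.na(object@nucleotideDiversity)) "NA"
              else sprintf("%.6f", object@nucleotideDiversity), object@n))
})

setMethod("show", "TrajectorySpec", function(object) {
  cat(sprintf(
    "TrajectorySpec: %d anchors %d-%d, female fraction %.2f, generation %.1f y\n",
    length(object@years), min(object@years), max(object@years),
    object@femaleFraction, object@generationYears))
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d generations (%g-%g), %d haplotypes%s%s\n",
              nrow(object@freqPath), min(object@years), max(object@years),
              ncol(object@freqPath),
              if (!is.null(object@sampledTable)) ", sampled table" else "",
              if (!is.null(object@alignment)) ", alignment" else ""))
})
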