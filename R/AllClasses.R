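#' @import methods
#' @importFrom Biostrings DNAStringSet width
NULL

## Alphabet constants: the four bases, the IUPAC ambiguity codes and the
## alignment gap. Replication masks are per-sample, per-column logicals.
.BASES <- c("A", "C", "G", "T")
.AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
.GAP <- "-"
.ALPHABET <- c(.BASES, .AMBIG, .GAP)
.REGIONS <- c("northern", "southern", "unknown")

#' HaplotypeAlignment: aligned sequences with temporal metadata
#'
#' Container for an aligned set of mtDNA control-region sequences together
#' with per-sample collection metadata (year, site, basin region) and a
#' per-sample, per-column replication mask (\code{TRUE} = base confirmed by at
#' least two independent reads). Sequences are stored as a
#' \link[Biostrings]{DNAStringSet} over \{A,C,G,T, IUPAC ambiguity codes, -\}.
#'
#' @slot seqs a \code{DNAStringSet}, one entry per sample, all equal width.
#' @slot meta \code{data.frame} with columns \code{id}, \code{year},
#'   \code{site}, \code{region}; one row per sequence, same order.
#' @slot replicated logical matrix, samples x alignment columns.
#'
#' @exportClass HaplotypeAlignment
setClass("HaplotypeAlignment",
  representation(seqs = "DNAStringSet", meta = "data.frame",
                 replicated = "matrix"))

setValidity("HaplotypeAlignment", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (n == 0L) msg <- c(msg, "alignment must contain at least one sequence")
  w <- unique(Biostrings::width(object@seqs))
  if (length(w) > 1L)
    msg <- c(msg, "all sequences must have identical length")
  req <- c("id", "year", "site", "region")
  if (!all(req %in% names(object@meta)))
    msg <- c(msg, sprintf("meta must have columns %s",
                          paste(req, collapse = ", ")))
  else {
    if (nrow(object@meta) != n)
      msg <- c(msg, "meta must have one row per sequence")
    if (!identical(as.character(object@meta$id), names(object@seqs)))
      msg <- c(msg, "meta$id must match sequence names in order")
    yr <- object@meta$year
    cur <- as.integer(format(Sys.Date(), "%Y"))
    if (any(!is.na(yr) & (yr < 1800L | yr > cur)))
      msg <- c(msg, "years must lie in [1800, current year]")
    if (!all(object@meta$region %in% .REGIONS))
      msg <- c(msg, sprintf("region must be one of %s",
                            paste(.REGIONS, collapse = "/")))
  }
  if (n > 0L && length(w) == 1L) {
    if (!identical(dim(object@replicated), c(n, w)))
      msg <- c(msg, "replicated mask must be samples x columns")
    bad <- setdiff(unique(as.vector(.aln_matrix(object))), .ALPHABET)
    if (length(bad))
      msg <- c(msg, sprintf("illegal characters in alignment: %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

## character matrix view of the alignment (samples x columns)
.aln_matrix <- function(aln) {
  m <- as.matrix(aln@seqs)
  rownames(m) <- names(aln@seqs)
  m
}

#' TemporalGrouping: ordered, non-overlapping collection-year bins
#'
#' @slot label character vector of period labels.
#' @slot start,end integer vectors of inclusive year bounds.
#' @exportClass TemporalGrouping
setClass("TemporalGrouping",
  representation(label = "character", start = "integer", end = "integer"))

setValidity("TemporalGrouping", function(object) {
  msg <- character()
  k <- length(object@label)
  if (k == 0L) msg <- c(msg, "at least one period required")
  if (length(object@start) != k || length(object@end) != k)
    msg <- c(msg, "label/start/end lengths differ")
  else {
    if (any(object@end < object@start))
      msg <- c(msg, "period end before start")
    if (k > 1L && any(object@start[-1L] <= object@end[-k]))
      msg <- c(msg, "periods must be chronologically ordered and non-overlapping")
    if (anyDuplicated(object@label))
      msg <- c(msg, "period labels must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' HaplotypeCatalog: haplotypes and sample membership
#'
#' Result of collapsing an alignment: the distinct haplotype sequences, a
#' sample-to-haplotype membership map, and samples excluded by the collapsing
#' policy with the reason.
#'
#' @slot sequences named character vector, haplotype label -> sequence.
#' @slot membership named character vector, sample id -> haplotype label.
#' @slot excluded \code{data.frame} with columns \code{id}, \code{reason}.
#' @slot policy the collapsing policy used.
#' @exportClass HaplotypeCatalog
setClass("HaplotypeCatalog",
  representation(sequences = "character", membership = "character",
                 excluded = "data.frame", policy = "character"))

setValidity("HaplotypeCatalog", function(object) {
  msg <- character()
  if (anyDuplicated(object@sequences))
    msg <- c(msg, "haplotype sequences must be pairwise distinct")
  if (anyDuplicated(names(object@sequences)))
    msg <- c(msg, "haplotype labels must be unique")
  if (length(object@membership) &&
      !all(object@membership %in% names(object@sequences)))
    msg <- c(msg, "membership refers to unknown haplotype labels")
  if (length(msg)) msg else TRUE
})

#' HaplotypeTable: haplotype x temporal-period count matrix
#'
#' @slot counts integer matrix with haplotype row names and period column
#'   names; column sums are the per-period sample sizes.
#' @exportClass HaplotypeTable
setClass("HaplotypeTable", representation(counts = "matrix"))

setValidity("HaplotypeTable", function(object) {
  msg <- character()
  cn <- object@counts
  if (!is.numeric(cn)) msg <- c(msg, "counts must be numeric")
  else {
    if (any(cn < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cn != round(cn))) msg <- c(msg, "counts must be integers")
  }
  if (is.null(rownames(cn)) || is.null(colnames(cn)))
    msg <- c(msg, "counts must have haplotype row names and period column names")
  else {
    if (anyDuplicated(rownames(cn))) msg <- c(msg, "duplicate haplotype labels")
    if (anyDuplicated(colnames(cn))) msg <- c(msg, "duplicate period labels")
  }
  if (length(msg)) msg else TRUE
})

#' GapCharacterMatrix: simple indel coding of alignment gaps
#'
#' Each distinct maximal gap interval becomes one binary character; states are
#' \code{"present"}, \code{"absent"}, or \code{"missing"} (gap strictly nested
#' inside a longer gap). Intervals are stored half-open and 0-based; printing
#' and TSV export use 1-based inclusive coordinates.
#'
#' @slot intervals integer matrix with columns \code{start}, \code{end}
#'   (half-open, 0-based), one row per character.
#' @slot states character matrix, sequences x characters.
#' @exportClass GapCharacterMatrix
setClass("GapCharacterMatrix",
  representation(intervals = "matrix", states = "matrix"))

setValidity("GapCharacterMatrix", function(object) {
  msg <- character()
  if (nrow(object@intervals) != ncol(object@states))
    msg <- c(msg, "one states column per interval required")
  if (length(object@states) &&
      !all(object@states %in% c("present", "absent", "missing")))
    msg <- c(msg, "states must be present/absent/missing")
  if (anyDuplicated(object@intervals))
    msg <- c(msg, "intervals must be unique")
  if (length(msg)) msg else TRUE
})

#' HaplotypeNetwork: minimum-spanning network of haplotypes
#'
#' Nodes are haplotypes with observed frequencies; edges carry mutational-step
#' weights. The edge set is the union of all minimum spanning trees of the
#' complete pairwise-distance graph; \code{tie_edge} marks edges kept only
#' because they tie a minimum-spanning alternative.
#'
#' @slot nodes \code{data.frame} with columns \code{label}, \code{frequency}.
#' @slot edges \code{data.frame} with columns \code{from}, \code{to},
#'   \code{weight}, \code{tie_edge}.
#' @slot gapMode distance mode used (\code{"fifth_state"} or \code{"ignore"}).
#' @exportClass HaplotypeNetwork
setClass("HaplotypeNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 gapMode = "character"))

setValidity("HaplotypeNetwork", function(object) {
  msg <- character()
  if (!all(c("label", "frequency") %in% names(object@nodes)))
    msg <- c(msg, "nodes need label and frequency columns")
  if (!all(c("from", "to", "weight", "tie_edge") %in% names(object@edges)))
    msg <- c(msg, "edges need from/to/weight/tie_edge columns")
  else {
    if (nrow(object@edges) && any(object@edges$weight < 1))
      msg <- c(msg, "edge weights must be >= 1")
    lab <- object@nodes$label
    if (nrow(object@edges) &&
        !all(c(object@edges$from, object@edges$to) %in% lab))
      msg <- c(msg, "edge endpoints must be network nodes")
  }
  if (length(msg)) msg else TRUE
})

#' TemporalLayers: per-period decomposition of a haplotype network
#'
#' @slot layers named list, period label -> named integer vector of counts of
#'   the haplotypes present (count > 0) in that period.
#' @slot persistence named list, haplotype label -> character vector of the
#'   periods in which it occurs.
#' @exportClass TemporalLayers
setClass("TemporalLayers",
  representation(layers = "list", persistence = "list"))

#' ResamplingTestResult: per-cell temporal frequency-change test results
#'
#' One row per (haplotype, non-reference period): observed count, period
#' sample size, reference frequency (substitute frequency when the haplotype
#' is absent from the reference), lower/upper tail probabilities and the
#' significance flag. \code{method} records whether tails are Monte-Carlo
#' (resampling) or exact binomial.
#'
#' @slot results \code{data.frame} with columns \code{haplotype},
#'   \code{period}, \code{observed}, \code{n_period}, \code{ref_freq},
#'   \code{substitute}, \code{lower_tail}, \code{upper_tail},
#'   \code{significant}, \code{p_bonferroni}.
#' @slot reference,tailRule,method character scalars.
#' @slot alpha numeric significance level; \code{replicates} integer (NA for
#'   the exact method); \code{seed} integer.
#' @exportClass ResamplingTestResult
setClass("ResamplingTestResult",
  representation(results = "data.frame", reference = "character",
                 alpha = "numeric", replicates = "integer",
                 tailRule = "character", seed = "integer",
                 method = "character"))

setValidity("ResamplingTestResult", function(object) {
  req <- c("haplotype", "period", "observed", "n_period", "ref_freq",
           "substitute", "lower_tail", "upper_tail", "significant",
           "p_bonferroni")
  msg <- character()
  if (!all(req %in% names(object@results)))
    msg <- c(msg, "results is missing required columns")
  else {
    r <- object@results
    if (any(r$ref_freq <= 0))
      msg <- c(msg, "ref_freq must be positive (substitute rule)")
    if (any(r$lower_tail + r$upper_tail < 1 - 1e-9))
      msg <- c(msg, "tails must overlap at the observed value")
  }
  if (length(msg)) msg else TRUE
})

#' RarefactionCurve: interpolated/extrapolated haplotype richness
#'
#' @slot m integer grid of sample sizes; \code{richness} expected richness at
#'   each m; \code{ciLow}/\code{ciHigh} percentile bootstrap bounds;
#'   \code{asymptote} the Chao1 estimate; \code{sObs} observed richness;
#'   \code{n} the actual sample size; \code{nBoot} bootstrap replicates used.
#' @exportClass RarefactionCurve
setClass("RarefactionCurve",
  representation(m = "integer", richness = "numeric", ciLow = "numeric",
                 ciHigh = "numeric", asymptote = "numeric", sObs = "numeric",
                 n = "integer", nBoot = "integer"))

setValidity("RarefactionCurve", function(object) {
  msg <- character()
  if (any(diff(object@richness[order(object@m)]) < -1e-9))
    msg <- c(msg, "richness must be non-decreasing in m")
  if (any(object@richness > object@asymptote + 1e-9))
    msg <- c(msg, "richness cannot exceed the Chao1 asymptote")
  if (length(msg)) msg else TRUE
})

#' ChiSquareResult: Pearson chi-square homogeneity test
#'
#' @slot statistic,df,p test results; \code{lowExpectedFlag} is \code{TRUE}
#'   when more than 20\% of expected cell counts fall below 5;
#'   \code{expected} the expected-count matrix.
#' @exportClass ChiSquareResult
setClass("ChiSquareResult",
  representation(statistic = "numeric", df = "integer", p = "numeric",
                 lowExpectedFlag = "logical", expected = "matrix"))

#' DiversityStats: haplotype and nucleotide diversity
#'
#' @slot haplotypeDiversity unbiased haplotype diversity h in [0,1];
#'   \code{nucleotideDiversity} mean per-site pairwise difference (NA when no
#'   sequences were supplied); \code{n} sample size.
#' @exportClass DiversityStats
setClass("DiversityStats",
  representation(haplotypeDiversity = "numeric",
                 nucleotideDiversity = "numeric", n = "integer"))

#' TrajectorySpec: piecewise-linear census history
#'
#' @slot years,sizes anchor points (census size at calendar year), linearly
#'   interpolated between anchors.
#' @slot femaleFraction fraction of the census acting as effective breeding
#'   females (mtDNA tracks matrilines).
#' @slot generationYears generation time in years.
#' @exportClass TrajectorySpec
setClass("TrajectorySpec",
  representation(years = "numeric", sizes = "numeric",
                 femaleFraction = "numeric", generationYears = "numeric"))

setValidity("TrajectorySpec", function(object) {
  msg <- character()
  if (length(object@years) < 2L)
    msg <- c(msg, "at least two anchors required")
  if (any(diff(object@years) <= 0))
    msg <- c(msg, "anchor years must be strictly increasing")
  if (any(object@sizes < 2))
    msg <- c(msg, "census sizes must be >= 2")
  if (object@femaleFraction <= 0 || object@femaleFraction > 1)
    msg <- c(msg, "femaleFraction must be in (0, 1]")
  if (object@generationYears <= 0)
    msg <- c(msg, "generationYears must be positive")
  if (length(msg)) msg else TRUE
})

#' SimConfig: configuration for the Wright-Fisher generator
#'
#' @slot initFreqs named numeric vector of initial haplotype frequencies
#'   (sums to 1).
#' @slot trajectory a \linkS4class{TrajectorySpec}.
#' @slot sampling named integer vector, period label -> sample size.
#' @slot mutationRate per-sequence per-generation substitution rate used by
#'   the sequence-level generator.
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(initFreqs = "numeric", trajectory = "TrajectorySpec",
                 sampling = "numeric", mutationRate = "numeric",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (abs(sum(object@initFreqs) - 1) > 1e-8)
    msg <- c(msg, "initial frequencies must sum to 1")
  if (any(object@initFreqs < 0))
    msg <- c(msg, "initial frequencies must be non-negative")
  if (is.null(names(object@initFreqs)) || anyDuplicated(names(object@initFreqs)))
    msg <- c(msg, "initFreqs must have unique haplotype names")
  if (length(object@sampling) && any(object@sampling < 0))
    msg <- c(msg, "sample sizes must be >= 0")
  if (object@mutationRate < 0)
    msg <- c(msg, "mutationRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimResult: output of the Wright-Fisher generator
#'
#' @slot freqPath numeric matrix, generations x haplotypes; rows sum to 1.
#' @slot years numeric vector of calendar years, one per generation.
#' @slot sampledTable a \linkS4class{HaplotypeTable} or NULL.
#' @slot truth named character vector, sample id -> true haplotype label
#'   (sequence mode).
#' @slot alignment a \linkS4class{HaplotypeAlignment} or NULL (sequence mode).
#' @exportClass SimResult
setClass("SimResult",
  representation(freqPath = "matrix", years = "numeric",
                 sampledTable = "ANY", truth = "character",
                 alignment = "ANY"))

setValidity("SimResult", function(object) {
  msg <- character()
  if (nrow(object@freqPath) != length(object@years))
    msg <- c(msg, "one year per generation required")
  if (nrow(object@freqPath) &&
      any(abs(rowSums(object@freqPath) - 1) > 1e-8))
    msg <- c(msg, "frequencies must sum to 1 at every generation")
  if (length(msg)) msg else TRUE
})
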