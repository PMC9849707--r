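#' Collapse aligned sequences into haplotypes
#'
#' Two policies mirror the two ways ambiguity is handled downstream.
#' \code{"gap_fifth_state"} keeps every sequence and defines a haplotype by
#' exact string identity with '-' as a distinct fifth character (the network
#' dataset convention). \code{"strict_remove"} first excludes every sequence
#' carrying an IUPAC ambiguity code at a column that is polymorphic among the
#' ambiguity-free sequences (the phylogeny dataset convention), then collapses
#' by exact identity.
#'
#' Haplotype labels are assigned by decreasing total frequency, ties broken by
#' first occurrence in the alignment; \code{labelMap} (haplotype sequence ->
#' label) overrides, e.g. to reproduce a historical labelling.
#'
#' @param aln a \linkS4class{HaplotypeAlignment}.
#' @param policy \code{"gap_fifth_state"} (default) or \code{"strict_remove"}.
#' @param labelMap optional named character vector mapping haplotype sequences
#'   to labels.
#' @param prefix label prefix for automatic labels (default \code{"H"}).
#' @return a \linkS4class{HaplotypeCatalog}.
#' @export
collapseHaplotypes <- function(aln,
                               policy = c("gap_fifth_state", "strict_remove"),
                               labelMap = NULL, prefix = "H") {
  policy <- match.arg(policy)
  m <- .aln_matrix(aln)
  ids <- rownames(m)
  excluded <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)

  if (policy == "strict_remove") {
    has_ambig <- apply(m, 1L, function(x) any(x %in% .AMBIG))
    clean <- m[!has_ambig, , drop = FALSE]
    poly <- if (nrow(clean)) {
      apply(clean, 2L, function(col) length(unique(col)) > 1L)
    } else rep(FALSE, ncol(m))
    drop <- vapply(seq_len(nrow(m)), function(i)
      any(m[i, ] %in% .AMBIG & poly), logical(1L))
    if (any(drop))
      excluded <- data.frame(id = ids[drop],
                             reason = "ambiguity at polymorphic site",
                             stringsAsFactors = FALSE)
    m <- m[!drop, , drop = FALSE]
    ids <- ids[!drop]
  }
  if (nrow(m) == 0L)
    stop("empty catalog: all sequences excluded by the collapsing policy")

  seqs <- apply(m, 1L, paste, collapse = "")
  uniq <- unique(seqs)                       # first-occurrence order
  freq <- vapply(uniq, function(s) sum(seqs == s), integer(1L))
  ord <- order(-freq, match(uniq, uniq))     # frequency, then first occurrence
  uniq <- uniq[ord]

  if (!is.null(labelMap)) {
    miss <- setdiff(uniq, names(labelMap))
    if (length(miss))
      stop("labelMap does not cover ", length(miss), " haplotype sequence(s)")
    labels <- unname(labelMap[uniq])
  } else {
    labels <- paste0(prefix, seq_along(uniq))
  }
  sequences <- stats::setNames(uniq, labels)
  membership <- stats::setNames(labels[match(seqs, uniq)], ids)
  new("HaplotypeCatalog", sequences = sequences, membership = membership,
      excluded = excluded, policy = policy)
}

#' Tabulate haplotype counts by temporal period
#'
#' Counts, for every haplotype in the catalog and every period of the
#' grouping, the number of member samples collected in that period. Samples
#' whose year falls in no period are dropped with a warning (the grouping may
#' legitimately contain gaps).
#'
#' @param catalog a \linkS4class{HaplotypeCatalog}.
#' @param aln the \linkS4class{HaplotypeAlignment} the catalog was built from
#'   (source of collection years).
#' @param grouping a \linkS4class{TemporalGrouping}.
#' @return a \linkS4class{HaplotypeTable}; haplotype rows follow catalog label
#'   order, period columns follow the grouping.
#' @export
haplotypeTable <- function(catalog, aln, grouping) {
  meta <- sampleMeta(aln)
  ids <- names(membership(catalog))
  years <- meta$year[match(ids, meta$id)]
  if (anyNA(years)) stop("catalog member(s) missing from alignment metadata")
  period <- assignPeriod(years, grouping)
  if (anyNA(period)) {
    warning(sum(is.na(period)),
            " sample(s) fall outside all periods and were dropped")
  }
  keep <- !is.na(period)
  labs <- names(haploSequences(catalog))
  cn <- matrix(0L, length(labs), length(grouping@label),
               dimnames = list(labs, grouping@label))
  tab <- table(factor(membership(catalog)[keep], levels = labs),
               factor(period[keep], levels = grouping@label))
  cn[] <- as.integer(tab)
  HaplotypeTable(cn)
}

#' Construct a HaplotypeTable from a count matrix
#'
#' @param counts non-negative integer matrix with haplotype row names and
#'   period column names.
#' @return a validated \linkS4class{HaplotypeTable}.
#' @export
HaplotypeTable <- function(counts) {
  storage.mode(counts) <- "integer"
  new("HaplotypeTable", counts = counts)
}

#' Simple indel coding of alignment gaps
#'
#' Implements simple indel coding: every distinct maximal gap run (identical
#' start and end shared by one or more sequences) becomes one binary
#' character. A sequence scores \code{present} when it carries exactly that
#' gap, \code{absent} when it has residues across the interval, and
#' \code{missing} when its own gap strictly subsumes the interval (the state
#' is then unobservable). Characters are ordered by start, then end, column.
#'
#' @param aln a \linkS4class{HaplotypeAlignment}.
#' @return a \linkS4class{GapCharacterMatrix}; zero characters for a gap-free
#'   alignment.
#' @export
simpleIndelCoding <- function(aln) {
  m <- .aln_matrix(aln)
  runs <- lapply(seq_len(nrow(m)), function(i) {
    r <- rle(m[i, ] == .GAP)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values] - 1L, end = ends[r$values])  # half-open 0-based
  })
  all_runs <- unique(do.call(rbind, runs))
  if (is.null(all_runs) || nrow(all_runs) == 0L) {
    return(new("GapCharacterMatrix",
               intervals = matrix(integer(), 0L, 2L,
                                  dimnames = list(NULL, c("start", "end"))),
               states = matrix(character(), nrow(m), 0L,
                               dimnames = list(rownames(m), NULL))))
  }
  all_runs <- all_runs[order(all_runs[, 1L], all_runs[, 2L]), , drop = FALSE]
  states <- matrix("absent", nrow(m), nrow(all_runs),
                   dimnames = list(rownames(m), NULL))
  for (i in seq_len(nrow(m))) {
    own <- runs[[i]]
    for (k in seq_len(nrow(all_runs))) {
      s <- all_runs[k, 1L]; e <- all_runs[k, 2L]
      if (nrow(own) == 0L) next
      exact <- any(own[, 1L] == s & own[, 2L] == e)
      nested <- any(own[, 1L] <= s & own[, 2L] >= e &
                    (own[, 2L] - own[, 1L]) > (e - s))
      states[i, k] <- if (exact) "present" else if (nested) "missing"
                      else "absent"
    }
  }
  new("GapCharacterMatrix", intervals = all_runs, states = states)
}

#' Export gap characters as TSV (1-based inclusive coordinates)
#'
#' @param gcm a \linkS4class{GapCharacterMatrix}.
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
writeGapCharacters <- function(gcm, path) {
  iv <- gcm@intervals
  header <- sprintf("gap_%d_%d", iv[, "start"] + 1L, iv[, "end"])
  df <- as.data.frame(gcm@states, stringsAsFactors = FALSE)
  names(df) <- header
  df <- cbind(id = rownames(gcm@states), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
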