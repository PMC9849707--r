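#' Construct a HaplotypeAlignment
#'
#' @param seqs named character vector or \code{DNAStringSet} of equal-length
#'   aligned sequences ('-' for gaps).
#' @param meta \code{data.frame} with columns \code{id}, \code{year},
#'   \code{site}, \code{region}; rows are matched to sequences by \code{id}.
#' @param replicated optional logical matrix (samples x columns); defaults to
#'   all-\code{TRUE}, i.e. every base confirmed.
#' @return a \linkS4class{HaplotypeAlignment}.
#' @export
HaplotypeAlignment <- function(seqs, meta, replicated = NULL) {
  if (!is(seqs, "DNAStringSet")) {
    nms <- names(seqs)
    seqs <- Biostrings::DNAStringSet(toupper(unlist(seqs)))
    names(seqs) <- nms
  }
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("sequences must be named by sample id")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"id" %in% names(meta)) stop("metadata must contain an 'id' column")
  meta$id <- as.character(meta$id)
  missing_ids <- setdiff(names(seqs), meta$id)
  if (length(missing_ids))
    stop("no metadata for sequence id(s): ", paste(missing_ids, collapse = ", "))
  extra <- setdiff(meta$id, names(seqs))
  if (length(extra))
    stop("metadata id(s) absent from sequences: ", paste(extra, collapse = ", "))
  meta <- meta[match(names(seqs), meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  if (!"site" %in% names(meta)) meta$site <- "unknown"
  if (!"region" %in% names(meta)) meta$region <- "unknown"
  if (!"year" %in% names(meta)) stop("metadata must contain a 'year' column")
  if (any(is.na(suppressWarnings(as.integer(meta$year)))))
    stop("missing or non-integer year for id(s): ",
         paste(meta$id[is.na(suppressWarnings(as.integer(meta$year)))],
               collapse = ", "))
  meta$year <- as.integer(meta$year)
  w <- unique(Biostrings::width(seqs))
  if (length(w) > 1L) {
    ref <- Biostrings::width(seqs)[1L]
    bad <- names(seqs)[Biostrings::width(seqs) != ref]
    stop("alignment error: sequence length differs for id(s): ",
         paste(bad, collapse = ", "))
  }
  if (is.null(replicated))
    replicated <- matrix(TRUE, length(seqs), w)
  new("HaplotypeAlignment", seqs = seqs,
      meta = meta[, c("id", "year", "site", "region")],
      replicated = replicated)
}

## parse "24-30,101-101" (1-based inclusive) into a logical length-w vector
## marking the UNreplicated columns
.parse_ranges <- function(spec, w) {
  out <- rep(FALSE, w)
  if (is.na(spec) || !nzchar(trimws(spec))) return(out)
  for (part in strsplit(trimws(spec), ",", fixed = TRUE)[[1L]]) {
    bounds <- as.integer(strsplit(trimws(part), "-", fixed = TRUE)[[1L]])
    if (length(bounds) == 1L) bounds <- c(bounds, bounds)
    if (length(bounds) != 2L || any(is.na(bounds)) || bounds[1L] > bounds[2L] ||
        bounds[1L] < 1L || bounds[2L] > w)
      stop("malformed replicated_ranges entry: ", part)
    out[bounds[1L]:bounds[2L]] <- TRUE
  }
  out
}

#' Read an aligned FASTA and its sample metadata
#'
#' The FASTA must contain equal-length aligned sequences; the metadata TSV has
#' header columns \code{id}, \code{year}, \code{site}, \code{region} and an
#' optional \code{replicated_ranges} column listing the UNreplicated columns
#' of each sample as comma-separated 1-based inclusive ranges (empty = fully
#' replicated).
#'
#' @param fasta_path path to the aligned FASTA.
#' @param metadata_path path to the metadata TSV.
#' @return a validated \linkS4class{HaplotypeAlignment}.
#' @export
readAlignment <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  w <- Biostrings::width(seqs)[1L]
  repl <- NULL
  if ("replicated_ranges" %in% names(meta)) {
    rows <- match(names(seqs), meta$id)
    if (anyNA(rows))
      stop("no metadata for sequence id(s): ",
           paste(names(seqs)[is.na(rows)], collapse = ", "))
    repl <- t(vapply(meta$replicated_ranges[rows],
                     function(s) !.parse_ranges(s, w), logical(w)))
    rownames(repl) <- names(seqs)
  }
  HaplotypeAlignment(seqs, meta, replicated = repl)
}

#' Write an alignment back to FASTA + metadata TSV
#'
#' Inverse of \code{\link{readAlignment}}: unreplicated columns are encoded in
#' the \code{replicated_ranges} metadata column.
#'
#' @param aln a \linkS4class{HaplotypeAlignment}.
#' @param fasta_path,metadata_path output paths.
#' @return invisibly, the two paths.
#' @export
writeAlignmentFasta <- function(aln, fasta_path, metadata_path) {
  Biostrings::writeXStringSet(aln@seqs, fasta_path, width = 80L)
  meta <- aln@meta
  meta$replicated_ranges <- apply(!aln@replicated, 1L, function(unrep) {
    if (!any(unrep)) return("")
    r <- rle(unrep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    paste(sprintf("%d-%d", starts[r$values], ends[r$values]), collapse = ",")
  })
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, metadata_path))
}

## IUPAC code covering a set of bases, e.g. {C,T} -> Y. Ambiguity codes in the
## input are expanded to their base sets first, so masking is idempotent.
.IUPAC_SETS <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  stats::setNames(strsplit(m, ""), names(m))
})

.merge_bases <- function(chars) {
  bases <- sort(unique(unlist(.IUPAC_SETS[chars], use.names = FALSE)))
  key <- vapply(.IUPAC_SETS, function(s)
    identical(sort(s), bases), logical(1L))
  names(.IUPAC_SETS)[which(key)][1L]
}

#' Mask unique SNPs in unreplicated sequence parts
#'
#' At every column where a sample is unreplicated and its base differs from
#' the base shared by all other replicated samples, the base is replaced by
#' the IUPAC ambiguity code covering both (e.g. an unreplicated T where every
#' other sample has C becomes Y). Columns where the other samples disagree
#' among themselves, gap positions, and replicated cells are left unchanged.
#' The operation is idempotent.
#'
#' @param aln a \linkS4class{HaplotypeAlignment}.
#' @param ids optional character vector restricting masking to these samples.
#' @return the masked \linkS4class{HaplotypeAlignment}.
#' @export
maskUnreplicated <- function(aln, ids = NULL) {
  m <- .aln_matrix(aln)
  repl <- aln@replicated
  targets <- if (is.null(ids)) seq_len(nrow(m)) else match(ids, rownames(m))
  if (anyNA(targets)) stop("unknown sample id(s)")
  out <- m
  for (i in targets) {
    cols <- which(!repl[i, ])
    for (j in cols) {
      a <- m[i, j]
      if (a == .GAP) next
      others <- m[-i, j][repl[-i, j]]
      others <- others[others %in% .BASES]
      if (length(others) == 0L) next
      b <- unique(others)
      if (length(b) != 1L) next                   # others not unanimous
      if (b %in% .IUPAC_SETS[[a]] && length(.IUPAC_SETS[[a]]) == 1L) next
      merged <- .merge_bases(c(a, b))
      out[i, j] <- merged
    }
  }
  aln@seqs <- Biostrings::DNAStringSet(apply(out, 1L, paste, collapse = ""))
  names(aln@seqs) <- rownames(m)
  validObject(aln)
  aln
}

#' Trim alignment columns from both ends
#'
#' @param aln a \linkS4class{HaplotypeAlignment}.
#' @param head,tail number of columns removed from the start/end.
#' @return the trimmed alignment; replication masks are trimmed in step.
#' @export
trimAlignment <- function(aln, head = 0L, tail = 0L) {
  w <- alignmentLength(aln)
  head <- as.integer(head); tail <- as.integer(tail)
  if (head < 0L || tail < 0L) stop("head and tail must be >= 0")
  if (head + tail >= w)
    stop(sprintf("cannot trim %d + %d columns from a %d-column alignment",
                 head, tail, w))
  keep <- (head + 1L):(w - tail)
  aln@seqs <- Biostrings::subseq(aln@seqs, start = head + 1L, end = w - tail)
  aln@replicated <- aln@replicated[, keep, drop = FALSE]
  validObject(aln)
  aln
}
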