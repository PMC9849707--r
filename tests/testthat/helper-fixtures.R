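## small in-code fixtures shared across test files

## alignment from bare sequence strings; years default to one period
make_aln <- function(seqs, years = NULL, ids = NULL, replicated = NULL,
                     sites = "siteA", regions = "northern") {
  n <- length(seqs)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  if (is.null(years)) years <- rep(2005L, n)
  meta <- data.frame(id = ids, year = years,
                     site = rep_len(sites, n), region = rep_len(regions, n),
                     stringsAsFactors = FALSE)
  HaplotypeAlignment(stats::setNames(seqs, ids), meta, replicated = replicated)
}

## random gap-free sequences of length L (for distance/network properties)
random_seqs <- function(k, L) {
  vapply(seq_len(k), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1L))
}

## catalog built directly from labelled haplotype sequences, one member each
## unless freqs given
make_catalog <- function(seqs, freqs = NULL) {
  labs <- names(seqs)
  if (is.null(freqs)) freqs <- rep(1L, length(seqs))
  ids <- unlist(lapply(seq_along(labs), function(i)
    sprintf("%s_m%d", labs[i], seq_len(freqs[i]))))
  memb <- stats::setNames(rep(labs, freqs), ids)
  new("HaplotypeCatalog", sequences = seqs, membership = memb,
      excluded = data.frame(id = character(), reason = character()),
      policy = "gap_fifth_state")
}

## 14 pairwise-distinct dummy haplotype sequences labelled like the packaged
## count table, for network/layer tests that only need labels to line up
saimaa_like_catalog <- function(table = saimaaTable()) {
  cn <- counts(table)
  base <- strsplit(paste(rep("ACGT", 10), collapse = ""), "")[[1L]]
  seqs <- vapply(seq_len(nrow(cn)), function(i) {
    s <- base
    # substitute positions 1..i with a base always differing from the
    # original ACGT cycle, so different i give pairwise-distinct sequences
    s[seq_len(i)] <- rep(c("T", "A"), length.out = i)
    paste(s, collapse = "")
  }, character(1L))
  names(seqs) <- rownames(cn)
  make_catalog(seqs, freqs = rowSums(cn))
}

## brute-force minimum-spanning-network oracle: enumerate every spanning tree
## of the complete graph and take the union of all minimum-weight ones
brute_msn <- function(d) {
  k <- nrow(d)
  stopifnot(k >= 2L)
  idx <- which(upper.tri(d), arr.ind = TRUE)
  edges <- cbind(i = idx[, 1L], j = idx[, 2L], w = d[idx])
  ne <- nrow(edges)
  combs <- utils::combn(ne, k - 1L)
  weights <- rep(NA_real_, ncol(combs))
  for (c in seq_len(ncol(combs))) {
    sel <- combs[, c]
    parent <- seq_len(k)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (r in sel) {
      a <- find(edges[r, "i"]); b <- find(edges[r, "j"])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) weights[c] <- sum(edges[sel, "w"])
  }
  wmin <- min(weights, na.rm = TRUE)
  in_union <- rep(FALSE, ne)
  for (c in which(!is.na(weights) & abs(weights - wmin) < 1e-9))
    in_union[combs[, c]] <- TRUE
  list(mst_weight = wmin,
       edges = edges[in_union, , drop = FALSE])
}
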