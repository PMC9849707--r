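#' Mutational distance between two aligned haplotype sequences
#'
#' Counts columns at which the sequences differ. Under \code{"fifth_state"}
#' the gap character '-' is a fifth symbol, so every deleted position counts
#' as one mutational step (a 64-bp deletion contributes 64 steps). Under
#' \code{"ignore"} any column where either sequence has a gap is skipped.
#'
#' @param a,b equal-length haplotype sequences (character scalars) without
#'   ambiguity codes.
#' @param gap_mode \code{"fifth_state"} (default) or \code{"ignore"}.
#' @return integer number of mutational steps; 0 iff identical under the mode.
#' @export
pairwiseDistance <- function(a, b, gap_mode = c("fifth_state", "ignore")) {
  gap_mode <- match.arg(gap_mode)
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  if (length(av) != length(bv))
    stop(sprintf("sequence lengths differ (%d vs %d)", length(av), length(bv)))
  if (any(c(av, bv) %in% .AMBIG))
    stop("ambiguity codes are not allowed in haplotype distances; ",
         "collapse with an ambiguity-removing policy first")
  if (gap_mode == "ignore") {
    keep <- av != .GAP & bv != .GAP
    av <- av[keep]; bv <- bv[keep]
  }
  sum(av != bv)
}

## full pairwise distance matrix over catalog haplotypes
.distance_matrix <- function(sequences, gap_mode) {
  k <- length(sequences)
  d <- matrix(0L, k, k, dimnames = list(names(sequences), names(sequences)))
  if (k < 2L) return(d)
  chars <- lapply(sequences, function(s) strsplit(s, "")[[1L]])
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L) stop("haplotype sequences differ in length")
  if (any(unlist(chars) %in% .AMBIG))
    stop("ambiguity codes are not allowed in haplotype distances")
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    av <- chars[[i]]; bv <- chars[[j]]
    if (gap_mode == "ignore") {
      keep <- av != .GAP & bv != .GAP
      av <- av[keep]; bv <- bv[keep]
    }
    d[i, j] <- d[j, i] <- sum(av != bv)
  }
  d
}

## union-find with path compression
.uf_new <- function(n) seq_len(n)
.uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

#' Build the minimum-spanning network of a haplotype catalog
#'
#' The minimum-spanning network (MSN) is the union of all minimum spanning
#' trees of the complete pairwise-distance graph: an edge of weight w joins
#' the network exactly when its endpoints lie in different connected
#' components of the subgraph of strictly lighter edges (the cycle property).
#' The result is deterministic and independent of input order. Edges not in
#' the single lexicographic Kruskal tree are flagged \code{tie_edge}.
#'
#' Identical haplotype pairs (distance 0) cannot occur in a valid catalog;
#' edges heavier than \code{max_weight} can optionally be dropped, emulating a
#' parsimony connection limit (the network may then be disconnected).
#'
#' @param catalog a \linkS4class{HaplotypeCatalog}.
#' @param gap_mode gap handling for distances, see
#'   \code{\link{pairwiseDistance}}.
#' @param max_weight optional maximum retained edge weight (default
#'   \code{Inf}).
#' @return a \linkS4class{HaplotypeNetwork}.
#' @export
buildMSN <- function(catalog, gap_mode = c("fifth_state", "ignore"),
                     max_weight = Inf) {
  gap_mode <- match.arg(gap_mode)
  seqs <- haploSequences(catalog)
  if (length(seqs) < 1L) stop("catalog contains no haplotypes")
  labs <- sort(names(seqs))                 # deterministic node order
  seqs <- seqs[labs]
  freq <- vapply(labs, function(l) sum(membership(catalog) == l), integer(1L))
  nodes <- data.frame(label = labs, frequency = unname(freq),
                      stringsAsFactors = FALSE)
  k <- length(labs)
  edges <- data.frame(from = character(), to = character(),
                      weight = integer(), tie_edge = logical(),
                      stringsAsFactors = FALSE)
  if (k >= 2L) {
    d <- .distance_matrix(seqs, gap_mode)
    idx <- which(upper.tri(d), arr.ind = TRUE)
    cand <- data.frame(i = idx[, 1L], j = idx[, 2L],
                       weight = d[idx])
    cand <- cand[order(cand$weight, cand$i, cand$j), , drop = FALSE]

    in_msn <- logical(nrow(cand))
    in_mst <- logical(nrow(cand))
    parent <- .uf_new(k)             # components over strictly lighter edges
    row <- 1L
    while (row <= nrow(cand)) {
      w <- cand$weight[row]
      block <- which(cand$weight == w)
      # MSN membership: different components before adding any weight-w edge
      for (r in block) {
        ri <- .uf_find(parent, cand$i[r]); rj <- .uf_find(parent, cand$j[r])
        in_msn[r] <- ri != rj
      }
      # Kruskal tree: greedy within the block in deterministic order
      parent2 <- parent
      for (r in block) {
        ri <- .uf_find(parent2, cand$i[r]); rj <- .uf_find(parent2, cand$j[r])
        if (ri != rj) {
          in_mst[r] <- TRUE
          parent2[ri] <- rj
        }
      }
      parent <- parent2
      row <- max(block) + 1L
    }
    keep <- in_msn & cand$weight <= max_weight
    edges <- data.frame(from = labs[cand$i[keep]], to = labs[cand$j[keep]],
                        weight = as.integer(cand$weight[keep]),
                        tie_edge = !in_mst[keep],
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  new("HaplotypeNetwork", nodes = nodes, edges = edges, gapMode = gap_mode)
}

#' Decompose a network into temporal layers
#'
#' One layer per period of the count table, listing the haplotypes present
#' (count > 0) and their counts; the persistence map records, for every
#' haplotype, the set of periods in which it occurs.
#'
#' @param network a \linkS4class{HaplotypeNetwork}.
#' @param table a \linkS4class{HaplotypeTable}; its haplotypes must all be
#'   network nodes.
#' @return a \linkS4class{TemporalLayers}.
#' @export
temporalLayers <- function(network, table) {
  cn <- counts(table)
  unknown <- setdiff(rownames(cn), networkNodes(network)$label)
  if (length(unknown))
    stop("table haplotype(s) not in network: ", paste(unknown, collapse = ", "))
  layers <- lapply(colnames(cn), function(p) {
    col <- cn[, p]
    col[col > 0L]
  })
  names(layers) <- colnames(cn)
  persistence <- lapply(rownames(cn), function(h) {
    colnames(cn)[cn[h, ] > 0L]
  })
  names(persistence) <- rownames(cn)
  persistence <- persistence[vapply(persistence, length, integer(1L)) > 0L]
  new("TemporalLayers", layers = layers, persistence = persistence)
}

#' Export a haplotype network as GraphML
#'
#' Node attributes: frequency and (when a table is given) per-period counts;
#' edge attributes: weight and tie-edge flag.
#'
#' @param network a \linkS4class{HaplotypeNetwork}.
#' @param path output path.
#' @param table optional \linkS4class{HaplotypeTable} supplying per-period
#'   node counts.
#' @return invisibly, the igraph object written.
#' @export
writeNetworkGraphML <- function(network, path, table = NULL) {
  nodes <- networkNodes(network)
  edges <- networkEdges(network)
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = nodes)
  if (!is.null(table)) {
    cn <- counts(table)
    for (p in colnames(cn)) {
      v <- rep(0L, nrow(nodes))
      hit <- match(nodes$label, rownames(cn))
      v[!is.na(hit)] <- cn[hit[!is.na(hit)], p]
      g <- igraph::set_vertex_attr(g, paste0("count_", p), value = v)
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}

#' Export network edges as TSV
#'
#' @param network a \linkS4class{HaplotypeNetwork}.
#' @param path output path.
#' @return invisibly, the edge data.frame.
#' @export
writeEdgeList <- function(network, path) {
  utils::write.table(networkEdges(network), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(networkEdges(network))
}

#' Export temporal layers as TSV (period x haplotype counts)
#'
#' @param layers a \linkS4class{TemporalLayers}.
#' @param path output path.
#' @return invisibly, the exported data.frame.
#' @export
writeLayers <- function(layers, path) {
  rows <- do.call(rbind, lapply(names(layers@layers), function(p) {
    l <- layers@layers[[p]]
    if (!length(l)) return(NULL)
    data.frame(period = p, haplotype = names(l), count = as.integer(l),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(period = character(), haplotype = character(),
                       count = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
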