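#' Construct a piecewise-linear census trajectory
#'
#' @param years,sizes census anchors; census size is interpolated linearly
#'   between anchor years.
#' @param female_fraction fraction of the census that acts as effective
#'   breeding females (mtDNA drifts at the female effective size). Default
#'   0.25.
#' @param generation_years generation time in years (default 11).
#' @return a \linkS4class{TrajectorySpec}.
#' @export
TrajectorySpec <- function(years, sizes, female_fraction = 0.25,
                           generation_years = 11) {
  new("TrajectorySpec", years = as.numeric(years), sizes = as.numeric(sizes),
      femaleFraction = female_fraction, generationYears = generation_years)
}

#' Default census trajectory for a bottlenecked lake population
#'
#' Illustrative anchors for a landlocked seal population: roughly 1000 animals
#' in 1890, a 20th-century crash to about 140 in 1985, and partial recovery to
#' about 425 by 2011, with linear interpolation between anchors.
#'
#' @return a \linkS4class{TrajectorySpec}.
#' @export
defaultTrajectory <- function() {
  TrajectorySpec(years = c(1890, 1985, 2011), sizes = c(1000, 140, 425))
}

#' Census size at given years
#'
#' @param trajectory a \linkS4class{TrajectorySpec}.
#' @param years numeric vector of calendar years; years outside the anchor
#'   range take the nearest anchor's value.
#' @return numeric census sizes.
#' @export
censusAt <- function(trajectory, years) {
  stats::approx(trajectory@years, trajectory@sizes, xout = years,
                rule = 2)$y
}

#' Construct a simulation configuration
#'
#' @param init_freqs named numeric vector of initial haplotype frequencies
#'   (must sum to 1).
#' @param trajectory a \linkS4class{TrajectorySpec} (default
#'   \code{\link{defaultTrajectory}()}).
#' @param sampling named numeric vector, period label -> sample size (may be
#'   empty when only the frequency path is needed).
#' @param mutation_rate per-sequence per-generation substitution rate used by
#'   \code{\link{evolveSequences}} (default 0.3, i.e. on the order of a few
#'   substitutions per lineage over a century-scale history).
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimConfig}.
#' @export
SimConfig <- function(init_freqs, trajectory = defaultTrajectory(),
                      sampling = numeric(), mutation_rate = 0.3, seed = 1L) {
  new("SimConfig", initFreqs = init_freqs, trajectory = trajectory,
      sampling = sampling, mutationRate = mutation_rate,
      seed = as.integer(seed))
}

#' Haploid Wright-Fisher simulation along a census trajectory
#'
#' Starting from the configured initial haplotype frequencies at the first
#' anchor year, steps forward in whole generations of
#' \code{generation_years}. Each generation's haplotype counts are a single
#' multinomial draw of size \eqn{N_f(t) = round(census(t) \times
#' female\_fraction)} from the previous generation's frequencies; frequencies
#' are the drawn counts divided by \eqn{N_f(t)}. Fully reproducible from the
#' config seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SimResult} carrying the frequency path and the
#'   generation years (sampled table / alignment slots empty).
#' @export
wfSimulate <- function(config) {
  validObject(config)
  traj <- config@trajectory
  years <- seq(min(traj@years), max(traj@years), by = traj@generationYears)
  nf <- round(censusAt(traj, years) * traj@femaleFraction)
  if (any(nf < 1)) {
    bad <- years[which(nf < 1)[1L]]
    stop("female effective size below 1 at year ", bad)
  }
  k <- length(config@initFreqs)
  path <- matrix(NA_real_, length(years), k,
                 dimnames = list(NULL, names(config@initFreqs)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config@seed)
  path[1L, ] <- config@initFreqs
  for (t in seq_along(years)[-1L]) {
    draws <- stats::rmultinom(1L, nf[t], path[t - 1L, ])[, 1L]
    path[t, ] <- draws / nf[t]
  }
  new("SimResult", freqPath = path, years = years, sampledTable = NULL,
      truth = character(), alignment = NULL)
}

## generation index whose year is closest to `year`; error outside range
.generation_at <- function(result, year, what = "period") {
  if (year < min(result@years) - 1e-9 || year > max(result@years) + 1e-9)
    stop(what, " midpoint year ", year, " outside the simulated range ",
         min(result@years), "-", max(result@years))
  which.min(abs(result@years - year))
}

#' Sample a haplotype count table from a simulated frequency path
#'
#' For each period of the grouping with a configured sample size, draws that
#' many individuals multinomially from the haplotype frequencies at the
#' generation nearest the period midpoint, producing a haplotype x period
#' count table with known generating truth.
#'
#' @param result a \linkS4class{SimResult} from \code{\link{wfSimulate}}.
#' @param grouping a \linkS4class{TemporalGrouping}.
#' @param sampling named numeric vector, period label -> sample size; labels
#'   must be periods of the grouping.
#' @param seed integer RNG seed.
#' @return a \linkS4class{HaplotypeTable} (haplotypes x sampled periods).
#' @export
sampleTable <- function(result, grouping, sampling, seed = 1L) {
  if (is.null(names(sampling)) ||
      !all(names(sampling) %in% grouping@label))
    stop("sampling must be named by period labels of the grouping")
  mids <- periodMidpoints(grouping)[names(sampling)]
  gens <- vapply(seq_along(mids), function(i)
    .generation_at(result, mids[i], names(mids)[i]), integer(1L))
  k <- ncol(result@freqPath)
  cn <- matrix(0L, k, length(sampling),
               dimnames = list(colnames(result@freqPath), names(sampling)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  for (i in seq_along(sampling)) {
    if (sampling[i] > 0)
      cn[, i] <- stats::rmultinom(1L, sampling[i],
                                  result@freqPath[gens[i], ])[, 1L]
  }
  HaplotypeTable(cn)
}

## place k substitutions at distinct random positions of a base-vector
.mutate <- function(root, k, avoid = integer()) {
  free <- setdiff(seq_along(root), avoid)
  pos <- sample(free, min(k, length(free)))
  for (p in pos) root[p] <- sample(setdiff(.BASES, root[p]), 1L)
  root
}

#' Simulate sequences for the haplotypes of a Wright-Fisher run
#'
#' Generates a random root sequence and derives each haplotype by placing k
#' random substitutions on a star genealogy, k ~ Poisson(mutation_rate x
#' generations) (re-drawn until all haplotypes are pairwise distinct).
#' Optionally one haplotype (the last) additionally carries a contiguous
#' deletion rendered as '-' columns. The frequency path is then simulated
#' with \code{\link{wfSimulate}}, a count table is sampled per
#' \code{\link{sampleTable}}, and each sampled individual becomes an aligned
#' record with a collection year drawn uniformly within its period. The truth
#' map records every sample's generating haplotype; collapsing the emitted
#' alignment recovers it exactly on clean data.
#'
#' @param config a \linkS4class{SimConfig}; \code{sampling} must be non-empty.
#' @param grouping a \linkS4class{TemporalGrouping} covering the sampled
#'   periods.
#' @param root_length alignment length (default 663).
#' @param deletion optional \code{c(start, length)} (1-based start) giving a
#'   contiguous deletion carried by the last haplotype, e.g. \code{c(100,
#'   64)}.
#' @return a \linkS4class{SimResult} with \code{sampledTable},
#'   \code{alignment} and \code{truth} populated.
#' @export
evolveSequences <- function(config, grouping, root_length = 663L,
                            deletion = NULL) {
  validObject(config)
  if (!length(config@sampling)) stop("config@sampling must be non-empty")
  if (!is.null(deletion)) {
    if (length(deletion) != 2L || deletion[1L] < 1L || deletion[2L] < 1L ||
        deletion[1L] + deletion[2L] - 1L > root_length)
      stop("deletion must be c(start, length) within the root sequence")
  }
  labs <- names(config@initFreqs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config@seed + 1L)          # sequence stream, separate from WF/draws

  years_span <- diff(range(config@trajectory@years))
  n_gen <- max(1, floor(years_span / config@trajectory@generationYears))
  lambda <- config@mutationRate * n_gen
  del_cols <- if (!is.null(deletion))
    seq.int(deletion[1L], length.out = deletion[2L]) else integer()

  root <- sample(.BASES, root_length, replace = TRUE)
  haps <- vector("list", length(labs))
  haps[[1L]] <- root
  for (i in seq_along(labs)[-1L]) {
    is_del <- i == length(labs) && length(del_cols) > 0L
    if (lambda == 0) {
      ## degenerate case: no substitutions, every lineage equals the root
      cand <- root
      if (is_del) cand[del_cols] <- .GAP
      haps[[i]] <- cand
      next
    }
    for (try in 1:100) {
      k <- stats::rpois(1L, lambda)
      if (is_del) {
        cand <- .mutate(root, k, avoid = del_cols)
        cand[del_cols] <- .GAP
      } else {
        cand <- if (k == 0L && try < 100) NULL else .mutate(root, max(k, 1L))
      }
      if (is.null(cand)) next
      if (!any(vapply(haps[seq_len(i - 1L)],
                      function(h) !is.null(h) && identical(h, cand),
                      logical(1L)))) {
        haps[[i]] <- cand
        break
      }
    }
    if (is.null(haps[[i]]))
      stop("failed to generate distinct haplotype sequences; ",
           "increase mutation_rate or root_length")
  }
  hap_seqs <- vapply(haps, paste, character(1L), collapse = "")
  names(hap_seqs) <- labs

  wf <- wfSimulate(config)
  tab <- sampleTable(wf, grouping, config@sampling, seed = config@seed + 2L)

  set.seed(config@seed + 3L)          # metadata stream
  cn <- counts(tab)
  ids <- character(); hap_of <- character(); yr <- integer(); per <- character()
  for (p in colnames(cn)) for (h in rownames(cn)) {
    nph <- cn[h, p]
    if (nph == 0L) next
    ids <- c(ids, sprintf("S%04d", length(ids) + seq_len(nph)))
    hap_of <- c(hap_of, rep(h, nph))
    i <- match(p, grouping@label)
    yr <- c(yr, sample(grouping@start[i]:grouping@end[i], nph, replace = TRUE))
    per <- c(per, rep(p, nph))
  }
  meta <- data.frame(id = ids, year = yr,
                     site = "simulated",
                     region = sample(c("northern", "southern"), length(ids),
                                     replace = TRUE),
                     stringsAsFactors = FALSE)
  seqs <- stats::setNames(hap_seqs[hap_of], ids)
  aln <- HaplotypeAlignment(seqs, meta)
  new("SimResult", freqPath = wf@freqPath, years = wf@years,
      sampledTable = tab, truth = stats::setNames(hap_of, ids),
      alignment = aln)
}

#' Inject IUPAC ambiguity noise into an alignment
#'
#' Emulates damaged historical DNA: independently with probability
#' \code{rate}, each non-gap cell is replaced by the two-state IUPAC code
#' pairing its base with a random other base, and the cell is marked
#' unreplicated in the replication mask.
#'
#' @param aln a \linkS4class{HaplotypeAlignment}.
#' @param rate per-cell noise probability in [0, 1).
#' @param seed integer RNG seed.
#' @return the noised \linkS4class{HaplotypeAlignment}.
#' @export
injectAmbiguities <- function(aln, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(aln)
  m <- .aln_matrix(aln)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  hit <- matrix(stats::runif(length(m)) < rate, nrow(m), ncol(m)) &
    matrix(m %in% .BASES, nrow(m), ncol(m))
  idx <- which(hit)
  for (cell in idx) {
    base <- m[cell]
    other <- sample(setdiff(.BASES, base), 1L)
    m[cell] <- .merge_bases(c(base, other))
  }
  aln@replicated[idx] <- FALSE
  aln@seqs <- Biostrings::DNAStringSet(apply(m, 1L, paste, collapse = ""))
  names(aln@seqs) <- rownames(m)
  validObject(aln)
  aln
}
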