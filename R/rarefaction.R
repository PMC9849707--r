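#' Rarefaction and extrapolation of haplotype richness
#'
#' Sample-size-based interpolation and extrapolation of expected haplotype
#' richness for one period's abundance vector. For m <= n the classic
#' hypergeometric rarefaction formula is used,
#' \deqn{\hat S(m) = \sum_h [1 - C(n - n_h, m) / C(n, m)],}
#' computed on the log scale for numerical stability. For m > n the curve is
#' extrapolated toward the Chao1 asymptote
#' \eqn{S_{obs} + f_1^2 / (2 f_2)} (or \eqn{S_{obs} + f_1 (f_1 - 1) / 2} when
#' no doubletons are observed) via the standard Chao1-anchored exponential
#' form \eqn{\hat S(n + t) = S_{obs} + \hat f_0 [1 - (1 - f_1/(n \hat f_0 +
#' f_1))^t]}. Percentile bootstrap bounds come from resampling the n
#' individuals with replacement \code{n_boot} times.
#'
#' @param counts named or unnamed vector of per-haplotype counts for one
#'   period (zeros allowed and ignored).
#' @param m_grid integer sample sizes at which to evaluate the curve; default
#'   1..2n. All values must be >= 1.
#' @param n_boot bootstrap replicates for the confidence band (default 200).
#' @param seed integer RNG seed for the bootstrap.
#' @param conf confidence level of the percentile band (default 0.95).
#' @return a \linkS4class{RarefactionCurve}.
#' @export
rarefyRichness <- function(counts, m_grid = NULL, n_boot = 200L, seed = 1L,
                           conf = 0.95) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1L) stop("at least one individual required")
  if (is.null(m_grid)) m_grid <- seq_len(2L * n)
  m_grid <- as.integer(m_grid)
  if (any(m_grid < 1L)) stop("sample sizes in m_grid must be >= 1")

  s_obs <- length(counts)
  f1 <- sum(counts == 1L)
  f2 <- sum(counts == 2L)
  asym <- .chao1(s_obs, f1, f2)
  rich <- .rarefy_curve(counts, m_grid, asym)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  boot <- matrix(NA_real_, n_boot, length(m_grid))
  pool <- rep(seq_along(counts), counts)
  for (b in seq_len(n_boot)) {
    bc <- tabulate(sample(pool, n, replace = TRUE))
    bc <- bc[bc > 0]
    basym <- .chao1(length(bc), sum(bc == 1L), sum(bc == 2L))
    boot[b, ] <- .rarefy_curve(bc, m_grid, basym)
  }
  a <- (1 - conf) / 2
  new("RarefactionCurve", m = m_grid, richness = rich,
      ciLow = apply(boot, 2L, stats::quantile, probs = a),
      ciHigh = apply(boot, 2L, stats::quantile, probs = 1 - a),
      asymptote = asym, sObs = as.numeric(s_obs), n = as.integer(n),
      nBoot = as.integer(n_boot))
}

## Chao1 richness estimate from singleton/doubleton counts
.chao1 <- function(s_obs, f1, f2) {
  if (f2 > 0) s_obs + f1^2 / (2 * f2)
  else s_obs + f1 * (f1 - 1) / 2
}

.rarefy_curve <- function(counts, m_grid, asym) {
  n <- sum(counts)
  s_obs <- length(counts)
  f1 <- sum(counts == 1L)
  f0 <- asym - s_obs
  vapply(m_grid, function(m) {
    if (m <= n) {
      ## E[S(m)] = sum_h [1 - C(n - n_h, m) / C(n, m)]
      sum(1 - exp(lchoose(n - counts, m) - lchoose(n, m)))
    } else if (f1 == 0 || f0 <= 0) {
      as.numeric(s_obs)
    } else {
      s_obs + f0 * (1 - (1 - f1 / (n * f0 + f1))^(m - n))
    }
  }, numeric(1L))
}

#' Haplotype and nucleotide diversity
#'
#' Unbiased haplotype diversity \eqn{h = \frac{n}{n-1}(1 - \sum_i p_i^2)} from
#' the per-haplotype counts, and (when the haplotype sequences are supplied)
#' nucleotide diversity \eqn{\pi}: the mean per-site pairwise difference over
#' all sample pairs,
#' \eqn{\pi = \sum_{i<j} n_i n_j d_{ij} / [L_{ij} C(n,2)]}, with gap columns
#' handled per \code{gap_mode} (under \code{"fifth_state"} the full alignment
#' length is the denominator; under \code{"ignore"} only columns where neither
#' sequence is gapped are compared).
#'
#' @param counts named per-haplotype counts (names must match catalog labels
#'   when sequences are supplied).
#' @param sequences optional named character vector of haplotype sequences
#'   (e.g. \code{haploSequences(catalog)}).
#' @param gap_mode gap handling for pairwise differences.
#' @return a \linkS4class{DiversityStats}.
#' @export
diversityStats <- function(counts, sequences = NULL,
                           gap_mode = c("fifth_state", "ignore")) {
  gap_mode <- match.arg(gap_mode)
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2L) stop("at least two individuals required for unbiased diversity")
  p <- counts / n
  h <- n / (n - 1) * (1 - sum(p^2))
  pi_val <- NA_real_
  if (!is.null(sequences)) {
    miss <- setdiff(names(counts), names(sequences))
    if (length(miss))
      stop("no sequence for haplotype(s): ", paste(miss, collapse = ", "))
    seqs <- sequences[names(counts)]
    k <- length(seqs)
    total <- 0
    if (k >= 2L) {
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        av <- strsplit(seqs[[i]], "")[[1L]]
        bv <- strsplit(seqs[[j]], "")[[1L]]
        if (gap_mode == "ignore") {
          keep <- av != .GAP & bv != .GAP
          av <- av[keep]; bv <- bv[keep]
        }
        L <- length(av)
        d <- if (L) sum(av != bv) / L else 0
        total <- total + counts[[i]] * counts[[j]] * d
      }
    }
    pi_val <- total / choose(n, 2)
  }
  new("DiversityStats", haplotypeDiversity = unname(h),
      nucleotideDiversity = unname(pi_val), n = as.integer(n))
}

#' Export a rarefaction curve as TSV
#'
#' @param curve a \linkS4class{RarefactionCurve}.
#' @param path output TSV path.
#' @return invisibly, the exported data.frame.
#' @export
writeRarefaction <- function(curve, path) {
  df <- data.frame(m = curve@m, richness = curve@richness,
                   ci_low = curve@ciLow, ci_high = curve@ciHigh)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
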