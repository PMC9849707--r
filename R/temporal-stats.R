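#' Substitute frequency for haplotypes absent from the reference
#'
#' A haplotype unobserved in a reference sample of size \code{n_ref} cannot be
#' assigned frequency zero for resampling; instead it is assigned the
#' frequency f at which absence from a sample of that size has exactly
#' probability \code{alpha}: the solution of (1 - f)^n_ref = alpha, i.e.
#' f = 1 - alpha^(1/n_ref). For n_ref = 128 and alpha = 0.05 this is
#' 0.023132.
#'
#' @param n_ref reference sample size (>= 1).
#' @param alpha absence probability in (0, 1).
#' @return the substitute frequency, a proportion in (0, 1).
#' @export
substituteFrequency <- function(n_ref, alpha = 0.05) {
  if (length(n_ref) != 1L || is.na(n_ref) || n_ref < 1 || n_ref != round(n_ref))
    stop("n_ref must be a positive integer")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  1 - alpha^(1 / n_ref)
}

## reference frequencies with the substitute rule applied; attribute marks
## which haplotypes received the substitute
.reference_freqs <- function(cn, reference, alpha) {
  ref_counts <- stats::setNames(cn[, reference], rownames(cn))
  n_ref <- sum(ref_counts)
  if (n_ref == 0L) stop("reference period has no samples")
  f <- ref_counts / n_ref
  sub <- ref_counts == 0L
  f[sub] <- substituteFrequency(n_ref, alpha)
  attr(f, "substitute") <- sub
  f
}

## derived per-cell RNG seed so results are independent of iteration order
.cell_seed <- function(seed, h, p) {
  as.integer((as.numeric(seed) * 48271 + h * 1299709 + p * 104729) %%
               2147483647)
}

.tail_flags <- function(lower, upper, observed, n, f, alpha, tail_rule) {
  if (tail_rule == "two_tailed_2p5") {
    lower < alpha / 2 | upper < alpha / 2
  } else {  # outside_95_mass: outside the central [q(a/2), q(1-a/2)] interval
    qlo <- stats::qbinom(alpha / 2, n, f)
    qhi <- stats::qbinom(1 - alpha / 2, n, f)
    observed < qlo | observed > qhi
  }
}

.test_skeleton <- function(table, reference) {
  cn <- counts(table)
  if (ncol(cn) < 2L) stop("at least two periods required")
  if (is.null(reference)) reference <- colnames(cn)[ncol(cn)]
  if (!reference %in% colnames(cn))
    stop("reference period '", reference, "' not in table")
  n_per <- colSums(cn)
  if (any(n_per == 0L))
    stop("empty period column(s): ",
         paste(colnames(cn)[n_per == 0L], collapse = ", "))
  list(cn = cn, reference = reference,
       periods = setdiff(colnames(cn), reference))
}

#' Resampling test of temporal haplotype-frequency change
#'
#' For every haplotype h and non-reference period p, draws \code{replicates}
#' binomial counts Bin(n_p, f_h), where n_p is the period sample size and f_h
#' the haplotype's frequency in the reference period (or the substitute
#' frequency, \code{\link{substituteFrequency}}, when it is absent from the
#' reference). The observed count is compared with the empirical distribution:
#' \code{lower_tail} = P(X <= observed), \code{upper_tail} = P(X >= observed).
#' Under \code{tail_rule = "two_tailed_2p5"} a cell is significant when either
#' tail probability is below alpha/2; under \code{"outside_95_mass"} when the
#' observed count falls outside the central 1 - alpha quantile interval of the
#' null. No multiple-testing correction is applied (a Bonferroni-adjusted
#' two-sided p is emitted for information only); see
#' \code{\link{metaBinomial}} for the experiment-wise test.
#'
#' Per-cell random streams are derived deterministically from (seed,
#' haplotype index, period index), so results do not depend on iteration
#' order.
#'
#' @param table a \linkS4class{HaplotypeTable}.
#' @param reference reference period label (default: the last column).
#' @param alpha significance level (default 0.05).
#' @param replicates Monte-Carlo replicates per cell (default 100000).
#' @param tail_rule \code{"two_tailed_2p5"} (default) or
#'   \code{"outside_95_mass"}.
#' @param seed integer RNG seed.
#' @return a \linkS4class{ResamplingTestResult}.
#' @seealso \code{\link{exactTestOracle}} for the closed-form version.
#' @export
resamplingTest <- function(table, reference = NULL, alpha = 0.05,
                           replicates = 100000L,
                           tail_rule = c("two_tailed_2p5", "outside_95_mass"),
                           seed = 1L) {
  tail_rule <- match.arg(tail_rule)
  if (replicates < 1L) stop("replicates must be >= 1")
  sk <- .test_skeleton(table, reference)
  cn <- sk$cn
  f <- .reference_freqs(cn, sk$reference, alpha)
  subst <- attr(f, "substitute")
  rows <- list()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (p in sk$periods) {
    n_p <- sum(cn[, p])
    pi <- match(p, colnames(cn))
    for (h in rownames(cn)) {
      hi <- match(h, rownames(cn))
      set.seed(.cell_seed(seed, hi, pi))
      draws <- stats::rbinom(replicates, n_p, f[h])
      obs <- cn[h, p]
      lower <- mean(draws <= obs)
      upper <- mean(draws >= obs)
      rows[[length(rows) + 1L]] <- data.frame(
        haplotype = h, period = p, observed = obs, n_period = n_p,
        ref_freq = unname(f[h]), substitute = unname(subst[h]),
        lower_tail = lower, upper_tail = upper, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$significant <- .tail_flags(res$lower_tail, res$upper_tail, res$observed,
                                 res$n_period, res$ref_freq, alpha, tail_rule)
  p_two <- 2 * pmin(res$lower_tail, res$upper_tail)
  res$p_bonferroni <- pmin(1, p_two * nrow(res))
  new("ResamplingTestResult", results = res, reference = sk$reference,
      alpha = alpha, replicates = as.integer(replicates),
      tailRule = tail_rule, seed = as.integer(seed), method = "monte_carlo")
}

## save/restore global RNG state so seeded helpers do not clobber the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Exact-binomial oracle for the resampling test
#'
#' The resampling null for each cell is exactly Binomial(n_p, f_h), so the
#' tail probabilities have the closed forms P(X <= obs) = pbinom(obs, n, f)
#' and P(X >= obs) = 1 - pbinom(obs - 1, n, f). Identical structure and
#' significance rules to \code{\link{resamplingTest}}; used to validate the
#' Monte-Carlo version and as a fast exact alternative.
#'
#' @inheritParams resamplingTest
#' @return a \linkS4class{ResamplingTestResult} with \code{method = "exact"}.
#' @export
exactTestOracle <- function(table, reference = NULL, alpha = 0.05,
                            tail_rule = c("two_tailed_2p5",
                                          "outside_95_mass")) {
  tail_rule <- match.arg(tail_rule)
  sk <- .test_skeleton(table, reference)
  cn <- sk$cn
  f <- .reference_freqs(cn, sk$reference, alpha)
  subst <- attr(f, "substitute")
  grid <- expand.grid(haplotype = rownames(cn), period = sk$periods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ## match resamplingTest row order: period-major, haplotype-minor
  grid <- grid[order(match(grid$period, sk$periods),
                     match(grid$haplotype, rownames(cn))), , drop = FALSE]
  obs <- cn[cbind(grid$haplotype, grid$period)]
  n_p <- colSums(cn)[grid$period]
  fh <- f[grid$haplotype]
  res <- data.frame(
    haplotype = grid$haplotype, period = grid$period, observed = obs,
    n_period = as.integer(unname(n_p)), ref_freq = unname(fh),
    substitute = unname(subst[grid$haplotype]),
    lower_tail = stats::pbinom(obs, n_p, fh),
    upper_tail = 1 - stats::pbinom(obs - 1, n_p, fh),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res$significant <- .tail_flags(res$lower_tail, res$upper_tail, res$observed,
                                 res$n_period, res$ref_freq, alpha, tail_rule)
  p_two <- 2 * pmin(res$lower_tail, res$upper_tail)
  res$p_bonferroni <- pmin(1, p_two * nrow(res))
  new("ResamplingTestResult", results = res, reference = sk$reference,
      alpha = alpha, replicates = NA_integer_, tailRule = tail_rule,
      seed = NA_integer_, method = "exact")
}

#' Count significant cells and haplotypes
#'
#' @param result a \linkS4class{ResamplingTestResult}.
#' @return named integer vector: \code{n_significant_tests} (significant
#'   (haplotype, period) cells) and \code{n_significant_haplotypes}
#'   (haplotypes significant in at least one period).
#' @export
countSignificant <- function(result) {
  r <- resultsTable(result)
  c(n_significant_tests = sum(r$significant),
    n_significant_haplotypes = length(unique(r$haplotype[r$significant])))
}

#' Meta-binomial test on the number of significant results
#'
#' With \code{n_tests} independent tests at level alpha, the number of
#' nominally significant results is Binomial(n_tests, alpha); the expected
#' count is n_tests * alpha and the probability of observing at least the
#' attained number by chance is the binomial upper tail. For 56 tests at
#' alpha = 0.05 and 7 significant results: expectation 2.8, P = 0.021.
#'
#' @param n_tests number of tests performed.
#' @param n_significant number of nominally significant results.
#' @param alpha per-test significance level.
#' @return named numeric vector \code{expected} and \code{p_at_least}.
#' @export
metaBinomial <- function(n_tests, n_significant, alpha = 0.05) {
  if (n_significant < 0 || n_significant > n_tests)
    stop("n_significant must lie in [0, n_tests]")
  c(expected = n_tests * alpha,
    p_at_least = 1 - stats::pbinom(n_significant - 1, n_tests, alpha))
}

#' Pearson chi-square test of sampling homogeneity
#'
#' Standard Pearson chi-square on a rows x columns contingency table of
#' counts (no continuity correction), flagging the classic small-expected-
#' count caveat: \code{lowExpectedFlag} is \code{TRUE} when strictly more than
#' 20\% of expected cell counts are below 5.
#'
#' @param cont_table non-negative count matrix with at least 2 rows and 2
#'   columns and no all-zero row or column.
#' @return a \linkS4class{ChiSquareResult}.
#' @export
chiSquareHomogeneity <- function(cont_table) {
  cont_table <- as.matrix(cont_table)
  if (nrow(cont_table) < 2L || ncol(cont_table) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(cont_table < 0)) stop("counts must be non-negative")
  if (any(rowSums(cont_table) == 0) || any(colSums(cont_table) == 0))
    stop("zero marginal row/column")
  ct <- suppressWarnings(stats::chisq.test(cont_table, correct = FALSE))
  new("ChiSquareResult",
      statistic = unname(ct$statistic), df = as.integer(unname(ct$parameter)),
      p = unname(ct$p.value),
      lowExpectedFlag = mean(ct$expected < 5) > 0.2,
      expected = ct$expected)
}

#' Write per-cell test results as TSV
#'
#' @param result a \linkS4class{ResamplingTestResult}.
#' @param path output TSV path.
#' @return invisibly, the results data.frame.
#' @export
writeTestResults <- function(result, path) {
  utils::write.table(resultsTable(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(resultsTable(result))
}
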