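test_that("substitute frequency solves the absence equation", {
  expect_equal(round(substituteFrequency(128, 0.05), 6), 0.023132)
  expect_equal(substituteFrequency(1, 0.05), 0.95)
  expect_lt(substituteFrequency(50, 1 - 1e-12), 1e-10)  # alpha -> 1 limit
  # round-trip (1 - f)^n = alpha to machine precision
  for (n in c(1, 10, 128, 1000)) for (a in c(0.01, 0.05, 0.5)) {
    f <- substituteFrequency(n, a)
    expect_equal((1 - f)^n, a, tolerance = 1e-12)
  }
  expect_error(substituteFrequency(0, 0.05), "n_ref")
  expect_error(substituteFrequency(128, 1), "alpha")
})

test_that("Monte-Carlo tails agree with the exact binomial oracle", {
  tab <- saimaaTable()
  mc <- resamplingTest(tab, replicates = 20000L, seed = 99L)
  ex <- exactTestOracle(tab)
  rmc <- resultsTable(mc); rex <- resultsTable(ex)
  expect_identical(rmc[c("haplotype", "period", "observed", "n_period")],
                   rex[c("haplotype", "period", "observed", "n_period")])
  expect_equal(rmc$ref_freq, rex$ref_freq)
  # every empirical tail within 3 Monte-Carlo standard errors of the exact tail
  se <- sqrt(rex$lower_tail * (1 - rex$lower_tail) / 20000)
  expect_true(all(abs(rmc$lower_tail - rex$lower_tail) <= 3 * se + 1e-12))
  se_u <- sqrt(rex$upper_tail * (1 - rex$upper_tail) / 20000)
  expect_true(all(abs(rmc$upper_tail - rex$upper_tail) <= 3 * se_u + 1e-12))
  # same flags at the study scale
  expect_identical(rmc$significant, rex$significant)
  # reproducible from seed
  mc2 <- resamplingTest(tab, replicates = 20000L, seed = 99L)
  expect_identical(resultsTable(mc2), rmc)
})

test_that("substitute frequencies apply only to reference-absent haplotypes", {
  tab <- saimaaTable()
  r <- resultsTable(exactTestOracle(tab))
  sub_haps <- unique(r$haplotype[r$substitute])
  expect_setequal(sub_haps, c("H5", "H9", "H10", "H11", "H12", "H14"))
  expect_equal(unique(r$ref_freq[r$substitute]), substituteFrequency(128))
  expect_true(all(r$ref_freq > 0))
  # tails overlap at the observed value
  expect_true(all(r$lower_tail + r$upper_tail >= 1))
})

test_that("cells at the null expectation are not significant", {
  cn <- rbind(H1 = c(5L, 50L), H2 = c(5L, 50L))
  colnames(cn) <- c("P1", "REF")
  r <- resultsTable(exactTestOracle(HaplotypeTable(cn), reference = "REF"))
  expect_false(any(r$significant))  # observed == n_p * f exactly

  # extreme departure: ref_freq 0.5, n = 10, observed 10
  cn2 <- rbind(H1 = c(10L, 5L), H2 = c(0L, 5L))
  colnames(cn2) <- c("P1", "REF")
  ex2 <- resultsTable(exactTestOracle(HaplotypeTable(cn2), reference = "REF"))
  h1 <- ex2[ex2$haplotype == "H1", ]
  expect_equal(h1$upper_tail, 0.5^10, tolerance = 1e-9)
  expect_equal(h1$upper_tail, 0.0009766, tolerance = 1e-4)
  expect_true(h1$significant)
})

test_that("significance counting summarizes cells and haplotypes", {
  tab <- saimaaTable()
  sig <- countSignificant(exactTestOracle(tab))
  expect_equal(unname(sig), c(7L, 5L))

  # frequencies identical to the reference -> nothing significant
  cn <- cbind(P1 = c(10L, 10L), P2 = c(20L, 20L), REF = c(50L, 50L))
  rownames(cn) <- c("H1", "H2")
  expect_equal(unname(countSignificant(
    exactTestOracle(HaplotypeTable(cn), reference = "REF"))), c(0L, 0L))

  # single haplotype: frequency pinned at 1, never significant
  cn1 <- cbind(P1 = 12L, REF = 40L); rownames(cn1) <- "H1"
  expect_equal(unname(countSignificant(
    exactTestOracle(HaplotypeTable(cn1), reference = "REF"))), c(0L, 0L))
})

test_that("both tail rules reproduce the study's significant set", {
  tab <- saimaaTable()
  for (rule in c("two_tailed_2p5", "outside_95_mass")) {
    r <- resultsTable(exactTestOracle(tab, tail_rule = rule))
    sig <- r[r$significant, ]
    expect_equal(nrow(sig), 7L)
    got <- paste(sig$haplotype, sig$period)
    expect_setequal(got, c("H9 TG1", "H12 TG1", "H1 TG3", "H3 TG3",
                           "H7 TG3", "H1 TG4", "H3 TG4"))
  }
})

test_that("the meta-binomial test matches closed forms and is monotone", {
  m <- metaBinomial(56, 7, 0.05)
  expect_equal(unname(m["expected"]), 2.8)
  expect_equal(round(unname(m["p_at_least"]), 3), 0.021)
  expect_equal(unname(metaBinomial(30, 0, 0.05)["p_at_least"]), 1.0)
  expect_equal(unname(metaBinomial(10, 10, 0.5)["p_at_least"]), 0.5^10,
               tolerance = 1e-9)
  p <- vapply(0:10, function(k)
    unname(metaBinomial(10, k, 0.1)["p_at_least"]), numeric(1))
  expect_true(all(diff(p) < 0))
  expect_error(metaBinomial(5, 6), "n_significant")
})

test_that("chi-square homogeneity matches hand computations and flags low counts", {
  r0 <- chiSquareHomogeneity(rbind(c(10, 10), c(10, 10)))
  expect_equal(r0@statistic, 0)
  expect_equal(r0@df, 1L)
  expect_false(r0@lowExpectedFlag)

  r1 <- chiSquareHomogeneity(rbind(c(20, 0), c(0, 20)))
  expect_equal(r1@statistic, 40)   # all expected counts are 10
  expect_equal(r1@df, 1L)

  # 2 of 8 expected cells below 5 -> 25% > 20% -> flagged
  m <- rbind(c(2, 30, 30, 30), c(2, 30, 30, 30))
  r2 <- chiSquareHomogeneity(m)
  expect_equal(sum(r2@expected < 5), 2L)
  expect_true(r2@lowExpectedFlag)

  # df = (r-1)(c-1) and agreement with stats::chisq.test
  m3 <- rbind(c(12, 5, 9), c(4, 16, 8), c(7, 9, 20), c(10, 3, 5))
  r3 <- chiSquareHomogeneity(m3)
  ref <- suppressWarnings(chisq.test(m3, correct = FALSE))
  expect_equal(r3@statistic, unname(ref$statistic))
  expect_equal(r3@df, 6L)
  expect_equal(r3@p, ref$p.value)

  expect_error(chiSquareHomogeneity(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("rarefaction interpolates exactly and anchors at Chao1", {
  tg1 <- counts(saimaaTable())[, "TG1"]
  curve <- rarefyRichness(tg1, m_grid = c(1, 5, 10, 23, 40, 60), n_boot = 50,
                          seed = 3)
  expect_equal(curve@richness[curve@m == 1], 1.0)
  expect_equal(curve@richness[curve@m == 23], 8)     # observed richness at n
  # TG1 has 4 singletons and no doubletons: Chao1 = 8 + 4*3/2 = 14
  expect_equal(curve@asymptote, 14)
  expect_true(all(diff(curve@richness) >= -1e-9))     # monotone
  expect_true(all(curve@richness <= curve@asymptote + 1e-9))
  expect_error(rarefyRichness(tg1, m_grid = 0), "m_grid")

  # independent interpolation oracle
  skip_if_not_installed("vegan")
  v <- as.numeric(vegan::rarefy(matrix(tg1[tg1 > 0], nrow = 1), 10))
  expect_equal(curve@richness[curve@m == 10], v, tolerance = 1e-9)
})

test_that("rarefaction bootstrap bands bracket the point estimate", {
  tg5 <- counts(saimaaTable())[, "TG5"]
  curve <- rarefyRichness(tg5, m_grid = c(10, 50, 128), n_boot = 200, seed = 7)
  expect_true(all(curve@ciLow <= curve@ciHigh))
  # reproducibility
  curve2 <- rarefyRichness(tg5, m_grid = c(10, 50, 128), n_boot = 200, seed = 7)
  expect_identical(curve@ciLow, curve2@ciLow)
})

test_that("diversity indices match direct formulas", {
  expect_equal(diversityStats(c(A = 5))@haplotypeDiversity,
               0)                                       # monomorphic
  expect_equal(diversityStats(c(A = 1, B = 1))@haplotypeDiversity, 1.0)
  tg5 <- counts(saimaaTable())[, "TG5"]
  h <- diversityStats(tg5)@haplotypeDiversity
  expect_equal(h, 128 / 127 * (1 - sum((tg5 / 128)^2)))  # direct arithmetic
  expect_error(diversityStats(c(A = 1)), "two individuals")

  # nucleotide diversity: 2 haplotypes differing at 1 of 4 sites, counts (1,1)
  d <- diversityStats(c(X = 1, Y = 1),
                      sequences = c(X = "ACGT", Y = "ACGA"))
  expect_equal(d@nucleotideDiversity, 0.25)
  # identical sequences -> pi = 0
  d0 <- diversityStats(c(X = 2, Y = 1),
                       sequences = c(X = "ACGT", Y = "ACGT"))
  expect_equal(d0@nucleotideDiversity, 0)
  # gap handling: deletion counts under fifth_state, skipped under ignore
  dgap <- diversityStats(c(X = 1, Y = 1),
                         sequences = c(X = "ACGT", Y = "AC--"))
  expect_equal(dgap@nucleotideDiversity, 0.5)
  dign <- diversityStats(c(X = 1, Y = 1),
                         sequences = c(X = "ACGT", Y = "AC--"),
                         gap_mode = "ignore")
  expect_equal(dign@nucleotideDiversity, 0)
})

test_that("test inputs are validated", {
  tab <- saimaaTable()
  expect_error(resamplingTest(tab, reference = "TG9"), "reference")
  cn <- counts(tab); cn[, "TG2"] <- 0L
  expect_error(exactTestOracle(HaplotypeTable(cn)), "empty period")
  one <- HaplotypeTable(counts(tab)[, "TG5", drop = FALSE])
  expect_error(exactTestOracle(one), "two periods")
})
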