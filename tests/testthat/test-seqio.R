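test_that("readAlignment round-trips valid FASTA + metadata and validates input", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "aln.fasta")
  md <- file.path(dir, "meta.tsv")
  writeLines(c(">s1", "ACGT-", ">s2", "ACGTA", ">s3", "ACTTA"), fa)
  write.table(
    data.frame(id = c("s1", "s2", "s3"), year = c(1900L, 1985L, 2005L),
               site = "x", region = "northern",
               replicated_ranges = c("2-3", "", "")),
    md, sep = "\t", quote = FALSE, row.names = FALSE)
  aln <- readAlignment(fa, md)
  expect_s4_class(aln, "HaplotypeAlignment")
  expect_equal(length(sampleMeta(aln)$id), 3L)
  expect_equal(alignmentLength(aln), 5L)
  # replicated_ranges lists UNreplicated columns
  expect_equal(unname(replicationMask(aln)[1, ]),
               c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(replicationMask(aln)[2:3, ]))

  # FASTA id missing from metadata
  writeLines(c(">s1", "ACGTA", ">s9", "ACGTA"), fa)
  write.table(data.frame(id = "s1", year = 1900L), md, sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(readAlignment(fa, md), "s9")

  # deviant sequence length
  writeLines(c(">s1", "ACGTA", ">s2", "ACG"), fa)
  write.table(data.frame(id = c("s1", "s2"), year = c(1900L, 1950L)),
              md, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readAlignment(fa, md), "length")
})

test_that("alignment FASTA export round-trips the replication mask", {
  repl <- matrix(TRUE, 2, 6)
  repl[1, 2:4] <- FALSE
  aln <- make_aln(c("ACGTAC", "ACGTAA"), replicated = repl)
  dir <- withr::local_tempdir()
  writeAlignmentFasta(aln, file.path(dir, "a.fasta"), file.path(dir, "m.tsv"))
  back <- readAlignment(file.path(dir, "a.fasta"), file.path(dir, "m.tsv"))
  expect_equal(replicationMask(back), replicationMask(aln),
               ignore_attr = TRUE)
  expect_equal(as.character(back@seqs), as.character(aln@seqs),
               ignore_attr = TRUE)
})

test_that("masking replaces unique unreplicated SNPs with IUPAC codes", {
  # unreplicated T where all others have C -> Y
  repl <- matrix(TRUE, 3, 4)
  repl[1, 2] <- FALSE
  aln <- make_aln(c("ATGA", "ACGA", "ACGA"), replicated = repl)
  masked <- maskUnreplicated(aln)
  expect_equal(as.character(masked@seqs[[1]]), "AYGA")
  expect_equal(as.character(masked@seqs[[2]]), "ACGA")

  # fully replicated record returned unchanged
  aln2 <- make_aln(c("ATGA", "ACGA", "ACGA"))
  expect_equal(as.character(maskUnreplicated(aln2)@seqs),
               as.character(aln2@seqs), ignore_attr = TRUE)

  # unreplicated base equal to the shared base -> unchanged
  repl3 <- matrix(TRUE, 3, 4)
  repl3[1, 2] <- FALSE
  aln3 <- make_aln(c("ACGA", "ACGA", "ACGA"), replicated = repl3)
  expect_equal(as.character(maskUnreplicated(aln3)@seqs[[1]]), "ACGA")

  # no masking when the other samples disagree among themselves
  repl4 <- matrix(TRUE, 3, 4)
  repl4[1, 2] <- FALSE
  aln4 <- make_aln(c("ATGA", "ACGA", "AGGA"), replicated = repl4)
  expect_equal(as.character(maskUnreplicated(aln4)@seqs[[1]]), "ATGA")
})

test_that("masking is idempotent on randomly noised alignments", {
  set.seed(11)
  for (rep in 1:5) {
    base <- random_seqs(1, 40)
    aln <- make_aln(rep(base, 6))
    noisy <- injectAmbiguities(aln, rate = 0.05, seed = rep)
    once <- maskUnreplicated(noisy)
    twice <- maskUnreplicated(once)
    expect_identical(as.character(twice@seqs), as.character(once@seqs))
  }
})

test_that("trimming removes the requested columns and validates bounds", {
  aln <- make_aln(random_seqs(3, 100))
  expect_equal(alignmentLength(trimAlignment(aln, 24, 20)), 56L)
  expect_identical(as.character(trimAlignment(aln, 0, 0)@seqs),
                   as.character(aln@seqs))
  # the published frame: 707 columns minus 24 head and 20 tail leaves 663
  aln707 <- make_aln(random_seqs(2, 707))
  expect_equal(alignmentLength(trimAlignment(aln707, 24, 20)), 663L)
  expect_error(trimAlignment(aln, 60, 40), "trim")

  # replication mask trimmed in step
  repl <- matrix(TRUE, 3, 100); repl[2, 30] <- FALSE
  alnr <- make_aln(random_seqs(3, 100), replicated = repl)
  tr <- trimAlignment(alnr, 24, 20)
  expect_false(replicationMask(tr)[2, 6])
  expect_equal(ncol(replicationMask(tr)), 56L)
})

test_that("years map to their period, with gap years mapping to none", {
  g <- saimaaGrouping()
  expect_equal(assignPeriod(1894, g), "TG1")
  expect_equal(assignPeriod(2011, g), "TG5")
  expect_true(is.na(assignPeriod(1950, g)))  # between TG1 and TG2
  expect_equal(assignPeriod(c(1939, 1960, 1980), g), c("TG1", "TG2", "TG3"))
})

test_that("collapsing groups identical sequences and orders labels by frequency", {
  aln <- make_aln(c("ACGT", "ACGT"))
  cat1 <- collapseHaplotypes(aln)
  expect_equal(length(haploSequences(cat1)), 1L)
  expect_equal(unname(table(membership(cat1))[["H1"]]), 2L)

  cat2 <- collapseHaplotypes(make_aln(c("ACGT", "ACGA", "ACGT")))
  expect_equal(unname(haploSequences(cat2)), c("ACGT", "ACGA"))
  expect_equal(as.vector(table(factor(membership(cat2), c("H1", "H2")))),
               c(2L, 1L))

  # frequency ties broken by first occurrence
  cat3 <- collapseHaplotypes(make_aln(c("TTTT", "ACGT", "ACGT", "TTTT")))
  expect_equal(names(which(haploSequences(cat3) == "TTTT")), "H1")

  # user-supplied label map overrides automatic labels
  cat4 <- collapseHaplotypes(make_aln(c("ACGT", "ACGA")),
                             labelMap = c(ACGT = "Hx", ACGA = "Hy"))
  expect_setequal(names(haploSequences(cat4)), c("Hx", "Hy"))
})

test_that("strict_remove excludes ambiguity at polymorphic sites only", {
  # column 3 is polymorphic among unambiguous sequences (A vs G); ACYT is
  # ambiguous at... column 3 of ACYT: Y at a polymorphic column -> excluded
  aln <- make_aln(c("ACYT", "ACAT", "ACGT"))
  cat <- collapseHaplotypes(aln, policy = "strict_remove")
  expect_equal(exclusions(cat)$id, "s01")
  expect_equal(length(haploSequences(cat)), 2L)

  # ambiguity at a monomorphic column is retained
  aln2 <- make_aln(c("AYGT", "ACGT", "ACGA"))
  cat2 <- collapseHaplotypes(aln2, policy = "strict_remove")
  expect_equal(nrow(exclusions(cat2)), 0L)

  # with no unambiguous sequences there are no polymorphic columns,
  # so nothing is excluded and each string stays its own haplotype
  aln3 <- make_aln(c("AYGT", "ARGT"))
  cat3 <- collapseHaplotypes(aln3, policy = "strict_remove")
  expect_equal(nrow(exclusions(cat3)), 0L)
  expect_equal(length(haploSequences(cat3)), 2L)
})

test_that("collapsing then expanding membership is a partition of the input", {
  set.seed(21)
  for (rep in 1:5) {
    pool <- random_seqs(3, 25)
    seqs <- sample(pool, 12, replace = TRUE)
    aln <- make_aln(seqs)
    cat <- collapseHaplotypes(aln)
    covered <- c(names(membership(cat)), exclusions(cat)$id)
    expect_setequal(covered, sampleMeta(aln)$id)
    expect_equal(anyDuplicated(covered), 0L)
    # members carry exactly their haplotype's sequence
    for (id in names(membership(cat))) {
      i <- match(id, sampleMeta(aln)$id)
      expect_equal(seqs[i],
                   unname(haploSequences(cat)[membership(cat)[id]]))
    }
  }
})

test_that("simple indel coding produces one character per distinct gap interval", {
  gcm <- simpleIndelCoding(make_aln(c("AC--T", "AC--T", "ACGGT")))
  expect_equal(nrow(gcm@intervals), 1L)
  expect_equal(unname(gcm@intervals[1, ]), c(2L, 4L))  # half-open 0-based
  expect_equal(unname(gcm@states[, 1]), c("present", "present", "absent"))

  expect_equal(ncol(simpleIndelCoding(make_aln(c("ACGT", "ACGA")))@states), 0L)

  # nested gaps: the subsumed interval is missing for the longer-gap sequence
  gcm2 <- simpleIndelCoding(make_aln(c("A----T", "AC--GT", "ACGGGT")))
  expect_equal(nrow(gcm2@intervals), 2L)
  expect_equal(unname(gcm2@intervals), rbind(c(1L, 5L), c(2L, 4L)),
               ignore_attr = TRUE)
  expect_equal(unname(gcm2@states[1, ]), c("present", "missing"))
  expect_equal(unname(gcm2@states[2, ]), c("absent", "present"))
  expect_equal(unname(gcm2@states[3, ]), c("absent", "absent"))
})

test_that("indel coding yields exactly k characters for k distinct maximal gaps", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 6; L <- 30
    m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
    # plant random gap runs
    intervals <- list()
    for (i in 1:n) {
      if (runif(1) < 0.7) {
        s <- sample(2:(L - 8), 1); len <- sample(2:5, 1)
        m[i, s:(s + len - 1)] <- "-"
        intervals[[length(intervals) + 1]] <- c(s - 1L, s + len - 1L)
      }
    }
    aln <- make_aln(apply(m, 1, paste, collapse = ""))
    gcm <- simpleIndelCoding(aln)
    expect_equal(nrow(gcm@intervals), nrow(unique(do.call(rbind, intervals))))
    # 'missing' only with a strictly containing gap
    if (any(gcm@states == "missing")) {
      for (w in which(gcm@states == "missing")) {
        i <- (w - 1) %% nrow(gcm@states) + 1
        k <- (w - 1) %/% nrow(gcm@states) + 1
        iv <- gcm@intervals[k, ]
        row <- strsplit(as.character(aln@seqs[[i]]), "")[[1]]
        expect_true(all(row[(iv[1] + 1):iv[2]] == "-"))
      }
    }
  }
})

test_that("haplotype tables count members per period and conserve samples", {
  # one haplotype, one period
  aln <- make_aln(c("ACGT", "ACGT", "ACGT"), years = c(2001L, 2005L, 2010L))
  cat <- collapseHaplotypes(aln)
  tab <- haplotypeTable(cat, aln, saimaaGrouping())
  expect_equal(counts(tab)["H1", "TG5"], 3L)
  expect_equal(sum(counts(tab)), 3L)

  # sample in the grouping's gap is dropped with a warning
  aln2 <- make_aln(c("ACGT", "ACGA", "ACGT"), years = c(2001L, 1950L, 1894L))
  cat2 <- collapseHaplotypes(aln2)
  expect_warning(tab2 <- haplotypeTable(cat2, aln2, saimaaGrouping()),
                 "outside all periods")
  expect_equal(sum(counts(tab2)), 2L)
  expect_equal(unname(colSums(counts(tab2))[c("TG1", "TG5")]), c(1L, 1L))
})

test_that("haplotype table TSV round-trips through Total row/column", {
  tab <- saimaaTable()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.tsv")
  df <- writeHaplotypeTable(tab, p)
  expect_equal(df$Total[df$haplotype == "Total"], 321)
  back <- readHaplotypeTable(p)
  expect_identical(counts(back), counts(tab))
})
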