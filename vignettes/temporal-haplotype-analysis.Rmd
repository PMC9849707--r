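---
title: "Temporal haplotype-frequency analysis with haplodrift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal haplotype-frequency analysis with haplodrift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplodrift)
```

## The problem

Small, isolated populations lose genetic variation to drift, and for many
endangered populations the loss happened before systematic sampling began.
Museum specimens extend the record backwards: sequencing the mitochondrial
control region of dated historical samples and binning them into temporal
groups turns a static picture of diversity into a time series of haplotype
frequencies. The statistical difficulty is that historical sample sizes are
small and uneven, so an apparent frequency change may be nothing but sampling
noise. haplodrift implements the full chain from aligned control-region
sequences (or a ready haplotype-by-period count table) to a defensible answer:
haplotype collapsing, minimum-spanning networks with temporal layers, a
binomial resampling test of per-period frequency change, rarefaction of
haplotype richness, homogeneity tests, and a Wright–Fisher generator that
produces synthetic datasets with known truth for end-to-end validation.

The packaged example is the mtDNA record of the Saimaa ringed seal, a
landlocked subspecies that crashed from roughly a thousand animals in the
late 1800s to fewer than 150 in the 1980s. Its 321 dated samples span
1894–2011 in five temporal groups (TG1–TG5, sizes 23, 33, 81, 56, 128), with
TG5 (2000–2011) as the modern reference; `saimaaTable()` ships the 14 × 5
count table and `saimaaGrouping()` the year bins. The grouping deliberately
leaves 1940–1959 uncovered; samples from gap years map to no period and are
dropped with a warning, since no assignment rule would be defensible.

## Sequence handling

**Replicate-aware masking.** Historical DNA is damaged, and base calls
supported by a single read are suspect exactly where they look interesting.
`maskUnreplicated()` implements the conservative convention: wherever a
sample is unreplicated (its `replicated_ranges` metadata column lists those
alignment columns) *and* its base differs from the base shared by all other
replicated samples, the call is replaced by the two-state IUPAC code covering
both (an unreplicated T against a unanimous C becomes Y). Columns where the
other samples disagree are left alone — the variant is then not a "unique
SNP" — as are gap positions. The operation is idempotent: merged codes
already contain the consensus base, so a second pass changes nothing.

**Collapsing policies.** Two policies mirror the two downstream uses.
`gap_fifth_state` keeps every sequence and defines a haplotype by exact
string identity with `-` as a fifth character — the right choice for network
construction, where a long deletion is real signal. `strict_remove` first
excludes sequences carrying an ambiguity code at any column that is
polymorphic among the ambiguity-free sequences; this is the phylogeny-dataset
convention, where an ambiguous base at an informative site would smear
signal. Ambiguity at monomorphic columns is retained under both policies —
removal there would discard samples over noise that cannot affect any
inference. Labels are assigned by decreasing total frequency with
first-occurrence tie-break; a user label map can reproduce a historical
labelling (H1–H14), which is bookkeeping, not biology.

**Indel coding.** `simpleIndelCoding()` converts shared gap runs into binary
presence/absence characters: each distinct maximal gap interval is one
character; a sequence is `present` when it has exactly that gap, `absent`
when it has residues across the interval, and `missing` when its own gap
strictly subsumes the interval (the state is then unobservable). Partially
overlapping gaps that are neither identical nor nested score `absent`, the
simple-coding convention. Intervals are half-open and 0-based internally —
unambiguous arithmetic — and 1-based inclusive in every user-facing report.

## The haplotype network

`buildMSN()` computes a minimum-spanning network: the union of all minimum
spanning trees of the complete pairwise-distance graph. An edge of weight w
is retained exactly when its endpoints are in different connected components
of the subgraph of strictly lighter edges, so the result is deterministic and
independent of input order — unlike a single MST, which breaks ties
arbitrarily, and unlike statistical-parsimony networks, whose connection
limit adds a model choice the downstream analysis never uses. Distances are
Hamming counts with gaps as a fifth state by default, so a 64-bp deletion
plus two substitutions sits 66 steps from its relative; unobserved
intermediate haplotypes are reported as edge weights greater than 1 rather
than materialised as phantom nodes. An optional maximum connection weight
emulates parsimony-style disconnection. `temporalLayers()` splits the network
by period for temporal visualisation, and the persistence map records each
haplotype's span of occurrence.

## The resampling test

For haplotype h in a non-reference period p with sample size $n_p$, the null
hypothesis is that the period is a random sample from the reference
population, so the observed count is
$X \sim \mathrm{Binomial}(n_p, f_h)$ with $f_h$ the haplotype's reference
frequency. `resamplingTest()` draws 100,000 such counts per cell (the study
default) and reports empirical tails $P(X \le \mathrm{obs})$ and
$P(X \ge \mathrm{obs})$; `exactTestOracle()` computes the same tails in
closed form, which is both the validation oracle for the Monte-Carlo version
and a fast exact alternative. Per-cell random streams are derived
deterministically from (seed, haplotype index, period index), so results do
not depend on iteration order.

**Substitute frequency.** A haplotype absent from the reference cannot be
given frequency zero — the null would then be degenerate. It is assigned the
frequency at which absence from a reference sample of size $n$ has exactly
probability $\alpha$: $f = 1 - \alpha^{1/n}$, i.e. 0.023132 for $n = 128$,
$\alpha = 0.05$. The substitute applies only to reference-absent haplotypes;
observed zeros in non-reference periods need no special handling.

**Tail rules.** "Observed outside 95% of the simulated probability mass" is
ambiguous for a discrete statistic, so both readings are implemented:
`two_tailed_2p5` flags a cell when either tail probability is below
$\alpha/2$, and `outside_95_mass` flags when the observed count falls outside
the central $[q_{\alpha/2}, q_{1-\alpha/2}]$ quantile interval of the null.
On the packaged table the two rules flag the identical set — 7 cells in 5
haplotypes (H9 and H12 in TG1; H1 and H3 in both TG3 and TG4; H7 in TG3) —
and `two_tailed_2p5` is the default.

**Calibration and discreteness.** Because the statistic is a discrete count,
the attainable size of the test is strictly below the nominal $\alpha$: with
the study's sample sizes and reference frequencies the exact per-cell type-I
rate is about 0.016, not 0.05. The test suite therefore checks calibration
against the analytically exact discrete level (and the $\le \alpha$ bound)
rather than against nominal 5%, which no discrete test could attain. This
conservatism means flagged cells are, if anything, under-claimed.

**Multiple testing.** No per-cell correction is applied; a Bonferroni column
is emitted for information only. The experiment-wise statement is
`metaBinomial()`: among $n$ independent tests at level $\alpha$, the number
of nominally significant results is $\mathrm{Binomial}(n, \alpha)$, so 56
tests expect 2.8 by chance and the probability of seeing 7 or more is 0.021.

`chiSquareHomogeneity()` is plain Pearson $\chi^2$ on a count table (no
continuity correction, via `stats::chisq.test`), flagging the standard
caveat when more than 20% of expected counts fall below 5 — in the study's
spatial-sampling application the user pools rows/columns until the flag
clears.

## Rarefaction and diversity

`rarefyRichness()` interpolates expected richness at subsample size $m \le n$
with the hypergeometric formula
$\hat S(m) = \sum_h [1 - \binom{n - n_h}{m}/\binom{n}{m}]$, computed on the
log-choose scale to avoid overflow. Beyond $n$ it extrapolates toward the
Chao1 asymptote $S_{\mathrm{obs}} + f_1^2/(2 f_2)$ (or
$S_{\mathrm{obs}} + f_1(f_1-1)/2$ when no doubletons exist) along the
standard Chao1-anchored exponential form. The confidence band is a
percentile bootstrap over individuals (200 replicates by default, the study
setting). For TG1 (n = 23, 8 haplotypes, 4 singletons, no doubletons) the
asymptote is $8 + 4 \cdot 3/2 = 14$ — matching the total count of haplotypes
ever observed, a reminder that the earliest, smallest sample alone predicts
substantial unsampled variation. Extrapolation more than roughly a doubling
of $n$ beyond the data leans entirely on the Chao1 anchor and should be read
qualitatively.

`diversityStats()` reports unbiased haplotype diversity
$h = \frac{n}{n-1}(1 - \sum p_i^2)$ and, when sequences are supplied,
nucleotide diversity $\pi$ as the mean per-site pairwise difference with gap
columns handled per the distance mode.

## The synthetic-data generator

`wfSimulate()` is a haploid Wright–Fisher simulator on a piecewise-linear
census trajectory: generations step by 11 years (a seal-like generation
time), and each generation's haplotype counts are one multinomial draw of
size $N_f(t) = \mathrm{round}(\mathrm{census}(t) \times 0.25)$ from the
previous frequencies. The default anchors — (1890, 1000), (1985, 140),
(2011, 425) — reproduce the documented census history: about a thousand
animals before persecution, a crash to below 150, partial recovery to the
low 400s. The female effective fraction 0.25 is a single transparent knob:
mtDNA drifts at the effective number of breeding females, for which no
direct estimate exists, and a quarter of the census is a conventional
middle-ground for a polygynous mammal with overlapping generations. Under
constant size the simulator reproduces the closed-form heterozygosity decay
$E[H_t] = H_0 (1 - 1/N_f)^t$, which the test suite verifies at
$N_f \in \{25, 100\}$.

`sampleTable()` draws period samples multinomially from the frequencies at
the generation nearest each period midpoint. `evolveSequences()` adds a
sequence level: haplotypes are placed on a star genealogy, each a
Poisson-distributed number of substitutions from a random root (rate 0.3 per
lineage per generation by default, giving control-region-like divergences of
a few steps), optionally with one lineage carrying a contiguous 64-bp
deletion; every simulated sample's true haplotype is recorded, and
collapsing the emitted alignment recovers the truth exactly on clean data.
`injectAmbiguities()` overlays museum-style damage: random cells become
two-state IUPAC codes and are marked unreplicated, exercising the masking
path.

What the generator does **not** emulate: genealogical structure (a star
phylogeny, not a coalescent — adequate for testing collapsing, networks and
the count-based test, inadequate for anything tree-shaped), spatial
structure within the lake, selection, recombination (absent in mtDNA
anyway), and heterogeneous per-site mutation. Passing tests therefore
validate the machinery, not the demographic realism of any particular run.
With `mutation_rate = 0` all lineages collapse to the root sequence by
construction, so truth recovery is only guaranteed at positive rates.

## Numerical and design choices

- Binomial coefficients in rarefaction via `lchoose` differences; tails via
  `pbinom`, never by summing densities.
- All randomness flows from a single integer seed; per-cell test streams are
  derived from (seed, haplotype index, period index); simulation stages use
  fixed offsets of the config seed. Identical config and seed give
  byte-identical pipeline outputs.
- Network node order is alphabetical by label; edge lists are sorted by
  (weight, endpoints); no layout coordinates are computed or stored.
- Gap intervals: half-open 0-based internally, 1-based inclusive in output.
- Degenerate inputs fail loudly and early: empty periods, a reference column
  of zeros, trims that exhaust the alignment, female effective sizes below 1
  (the error names the year), deletions exceeding the root length.
- Exact ties in haplotype frequency at labelling are broken by first
  occurrence in the alignment, making labels reproducible.

The test suite runs the full resampling test at the study's 100,000
replicates, validates Monte-Carlo tails within three standard errors of the
exact binomial tails on every cell, checks calibration on 500 null tables,
verifies heterozygosity decay over 1000 replicates per effective size, and
compares the network builder against exhaustive spanning-tree enumeration on
catalogs of up to six haplotypes — sizes chosen so each property is tested
at meaningful resolution while the whole suite stays interactive.

## Limitations

- The resampling test treats periods as independent samples from a fixed
  reference; serial correlation between adjacent periods (the same matriline
  persisting) is not modelled, so the meta-binomial p-value assumes
  independence it cannot fully have.
- The MSN is a descriptive summary; it does not estimate genealogy, and
  reticulations reflect tie structure in Hamming distances, not recombination.
- Chao1 is a lower-bound-style estimator; with four singletons and no
  doubletons its variance is substantial, and the bootstrap band reflects
  resampling error only, not estimator bias.
- The pipeline assumes a pre-aligned input; alignment errors upstream
  propagate silently into haplotype definitions.
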