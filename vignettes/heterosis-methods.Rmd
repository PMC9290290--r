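---
title: "Methods: expression-pattern and allele-specific expression analysis of parent-hybrid triads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-pattern and allele-specific expression analysis of parent-hybrid triads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetexpr)
```

# Scope

`hetexpr` analyses RNA-seq read counts from a parent-hybrid triad (two
inbred parents and their F1) to ask the classic heterosis questions at
the transcriptome level: which genes deviate from the additive
mid-parent expectation, in which direction, and whether the two parental
alleles are expressed unequally inside the hybrid. It also covers the
supporting steps such a study needs: FPKM normalisation, Fisher-exact
differential expression on pooled counts, DEG set partitioning between
near-isogenic hybrids, hypergeometric term enrichment, and trait-level
heterosis indices. A seeded synthetic-data generator with ground truth
backs every statistical claim with a recovery test.

# Statistical model

## Exact count tests

All expression comparisons use exact tests on pooled counts rather than
a fitted count model. For a gene compared between two conditions, the
2x2 table pits the gene's pooled count against the remainder of the
pooled library in each condition, and `fisher_exact_counts()` returns
the two-sided conditional (hypergeometric) p-value under probability
ordering: all tables with the observed margins whose point probability
does not exceed the observed table's are summed. This matches
`stats::fisher.test()`; a relative tolerance of `1e-7` guards the
`<=` comparison against floating-point ties, the same guard
`stats::binom.test()` uses.

The choice is deliberate: pooling replicates treats within-genotype
variation as purely technical (Poisson-like). That is the sampling model
under which the test is calibrated, and the packaged simulator's default
`dispersion = 0` mirrors it. Real biological replicates are
overdispersed; under overdispersion the pooled Fisher test is
anticonservative. `call_degs(test = "welch_logfpkm")` provides a
replicate-aware Welch t-test on log2(FPKM + 1) as a cross-check, and the
limitation is stated rather than hidden.

## The mid-parent value as a pseudo-sample

The additive expectation for hybrid expression is the mid-parent value
(MPV), the arithmetic mean of the parents. To test the hybrid against it
with the *same* exact machinery used for hybrid-parent comparisons,
`build_mpv()` materialises the MPV as a pseudo-sample: per-gene count
`round_half_up((pooled_P1 + pooled_P2) / 2)` with pseudo library size
`round_half_up((lib_P1 + lib_P2) / 2)`. Half-up rounding keeps counts
integral (a requirement of the exact test) and is symmetric in the
parents. The rounding perturbs each gene by at most 0.5 reads, which is
negligible at realistic depths.

## Expression-pattern taxonomy

`classify_patterns()` assigns each gene one class from the standard
heterosis taxonomy, using three Fisher families (F1 vs MPV, F1 vs P1,
F1 vs P2), each Benjamini-Hochberg adjusted separately across genes —
one family per comparison, since each comparison asks its own question
and should control its own FDR. With `q_mpv`, `q_p1`, `q_p2` at level
`alpha` (default 0.05), in order:

1. `q_mpv >= alpha` — **additive**: the hybrid sits at the additive
   expectation.
2. Significant vs both parents and above both — **over-dominant**;
   below both — **under-dominant**.
3. Not significant vs exactly one parent — **parent1-** /
   **parent2-dominant**.
4. Significant vs both parents with the hybrid strictly inside the
   parental range — **conserved**.
5. Otherwise — **ambiguous**.

Direction comparisons (above / below / within) use depth-normalised
pooled counts, so unequal library sizes cannot masquerade as
expression differences. The explicit **ambiguous** class exists because
the first four rules do not partition the outcome space: a gene can
differ from the MPV yet be statistically indistinguishable from both
parents (underpowered between close parents), or sit exactly on a
parental value. Forcing such genes into a named class would overstate
certainty; counting them separately keeps the additive / non-additive
split honest. `pattern_summary()` counts ambiguous genes as
non-additive (they do differ from the MPV) but never as over- or
under-dominant.

The **conserved** range test is strict (`p_lo < f1 < p_hi`): a hybrid
exactly at a parental boundary is better described by a dominance class
or left ambiguous, and with continuous normalised proportions exact
boundary hits are measure-zero anyway.

## Allele-specific expression

Within a hybrid, SNPs that distinguish the parental alleles give
per-SNP allelic read counts. Each testable SNP (total reads >= 1) is
tested against the balanced null `p = 0.5` with an exact two-sided
binomial test (probability ordering again; a `midp` flag offers the
less conservative mid-p variant). The BH family is *all testable SNPs
of one hybrid* — SNP tests within a hybrid are the natural family, and
mixing hybrids would let one hybrid's signal distort the other's
threshold.

A gene is called ASE when both of the following hold:

- at least `min_snps` (default 2) SNPs are individually significant
  with their ratios all on the same side of 0.5 — demanding
  direction-consistent support guards against spurious single-SNP
  artefacts and against genes whose SNPs disagree (which more likely
  reflect mapping bias than true allelic imbalance);
- the gene-level ratio `P` lies outside `[0.4, 0.6]`.

The gene-level `P` is the read-weighted mean of SNP ratios, which
equals the pooled-read ratio: robust to shallow SNPs and identical to
the single-SNP ratio when only one SNP exists. The unweighted mean is
available (`aggregate = "unweighted"`) because the aggregation rule is
a genuine open choice; both modes are exposed rather than silently
picking one. Likewise `rule = "relaxed"` implements the looser reading
of the multi-SNP requirement (>= 2 testable SNPs plus a significant
pooled gene-level test); the strict reading is the default.

SNP discovery (unique mapping, parental consensus) is upstream of this
package: the input table is assumed pre-filtered, and the validator
rejects structurally inconsistent rows (duplicate positions, genes
spanning chromosomes) rather than attempting repair.

## Normalisation and thresholds

FPKM is `1e9 * count / (length * library_size)`. Library sizes default
to column sums but can (and for simulated data should) be supplied
explicitly. A gene is *expressed* in a genotype at mean FPKM >= 1
across replicates; expressed genes are binned high (>= 50), medium
([20, 50)) and low (< 20) with left-closed boundaries, so a value at a
cut belongs to the upper bin. These thresholds are conventional
RNA-seq practice and are parameters everywhere they appear.

## Enrichment, FDR, and traits

Term enrichment is the one-sided hypergeometric upper tail
(`phyper(k - 1, K, N - K, n, lower.tail = FALSE)`) per term against an
expressed-gene background, with the rich factor `k / K` as effect size.
Benjamini-Yekutieli is offered alongside BH because term families
overlap heavily and BY is valid under arbitrary dependence; BY's
significant set is provably a subset of BH's. Both adjustments delegate
to `stats::p.adjust()` — a step-up rule is not worth reimplementing,
and the tests pin the wrapper to it.

Trait-level heterosis uses summary statistics only: over-standard
heterosis `100 * (hybrid - check) / check` at two decimals, environment
averages as means of per-environment values (for percentages this is
the mean of percentages, not the percentage of means), Welch's t from
summary statistics when replicate sizes are known, and the dominance
decomposition `d = F1 - MPV`, `a = |P1 - P2| / 2` with `|d/a| >= 1`
flagging over-dominance.

# The synthetic-data generator

`simulate_triad()` draws parental baseline means from a log-normal
(default `meanlog = log(100)`, `sdlog = 1`), separates the parents by a
fold factor (default 2, random direction) for non-equal genes, and
places the hybrid mean according to the gene's sampled class: additive
at the mid-parent, over-/under-dominant beyond the parental range by
the configured fold change, parent-dominant exactly at that parent,
conserved strictly between the parents at 25% or 75% of the interval
(off the midpoint, so the class is detectable). Counts are Poisson by
default or negative-binomial for `dispersion > 0`.

One design decision deserves emphasis. Class semantics are *absolute*:
an all-over-dominant genome really does express more total RNA in the
hybrid. Standard depth normalisation (proportions of the column sum)
would therefore shift every gene's hybrid proportion downward and
systematically violate the very truths the generator wrote — a
composition bias, not a bug in the classifier. The generator instead
uses a single common exposure (counts per unit expression, calibrated
so parent 1's expected depth hits the configured value) for every
sample and exports the matching per-sample normalisers as `lib_sizes`.
Passing those normalisers downstream is the simulated analogue of
normalising real data by total mapped fragments from a spike-in or
whole-library count rather than by the analysed subset. The recovery
tests pass `lib_sizes` for exactly this reason.

What the generator does **not** emulate: biological replicate
overdispersion (unless configured), gene-length bias in counting,
mapping error, positional or allele-specific mapping bias in the SNP
counts, and correlation between genes. It is a calibration instrument
for the statistical pipeline, not a transcriptome emulator.

`simulate_ase()` assigns each gene a true tester-allele fraction `f`
(0.5 for balanced genes; 0.2 or 0.8 for the imbalanced fraction) and
draws each SNP's tester reads `Binomial(50, f)` at 4 SNPs per gene.
A useful exact consequence: the pooled gene ratio is `Binomial(200, f)
/ 200`, so the probability that it lands within ±0.05 of `f` is exactly
`P(|X - 200 f| <= 10)` — about 0.863 at `f = 0.5` and 0.937 at
`f = 0.2`. The test suite checks the simulated coverage against these
exact values; note that no such band reaches 95% coverage at this
depth, a fact worth remembering when interpreting gene-level ratios
from a handful of SNPs.

# Problem sizes and reproducibility

The default problem sizes (2 000 genes, 3 replicates, depth 1e6;
1 000 ASE genes at 4 SNPs x 50 reads) are this package's own choice:
large enough that recovery rates are stable, small enough that the full
test suite runs in minutes on one CPU. Every simulation is a pure
function of its configuration, including the seed; identical
configurations give byte-identical outputs, and `run_pipeline()`
threads one seed through all stages. `scripts/acceptance.R` (in the
source tree) recomputes the headline numbers end to end from a single
`--seed`.

# Limitations

- Pooled Fisher DEG calls ignore biological overdispersion and will be
  anticonservative on real replicates; use `welch_logfpkm` as a
  cross-check or an external NB-based caller for production DEG lists.
- Pattern classes inherit the power of their component tests: with few
  reads or close parents, genes drift into `additive` (not enough
  evidence against the MPV) or `ambiguous` — the classifier reports
  uncertainty rather than resolving it.
- ASE calling assumes unbiased allelic read counts; reference-mapping
  bias must be handled upstream.
- The trait module works from summary statistics; with raw replicate
  measurements, a mixed model across environments would be stronger
  than per-environment Welch tests.
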