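---
title: "Motif enrichment, mutation spectra and assay statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif enrichment, mutation spectra and assay statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutmotif)
```

This vignette is the package's account of its statistical machinery: the
models and procedures, the parameters that matter and their defaults, the
numerical and design choices that were genuinely open, and what the
synthetic-data generators do and do not demonstrate about real data.

## The experimental setting

The package targets forward-mutation experiments of the kind run with the
yeast *CAN1* reporter: cultures of a haploid strain are exposed to a
mutagen (or water), resistant and viable colony counts measure the mutation
frequency per culture, and resistant isolates are whole-genome sequenced to
ask *which* mutations the treatment produced. Two statistical questions
follow:

* does the treatment increase the forward-mutation frequency
  (a two-group, small-n, nonparametric comparison), and
* do the induced mutations carry a specific trinucleotide signature —
  for acetaldehyde, C→A changes at gCn (equivalently nGc→T on the other
  strand) — beyond what the sequence composition explains?

## Variant filtering

Sequenced resistant isolates carry a mixture of treatment-induced
mutations, mutations pre-existing in the shared culture, parent-strain
variants, and sequencing artifacts. `apply_filters()` applies, in a fixed
order, with each call removed for exactly the first applicable reason:

1. **SNV-only**: indels and multi-nucleotide variants are set aside; the
   downstream statistics are defined on single-base substitutions.
2. **VAF floor** (default 0.90, inclusive): in clonal haploid isolates a
   genuine mutation is expected near 100% allele frequency; sub-clonal
   calls are treated as artifacts. The inclusive boundary (`vaf >= 0.90`)
   reads the threshold as a retention level; the boundary case is pinned by
   a test, and the threshold is a parameter.
3. **Parent subtraction**: any call matching a parent/untreated-culture
   call on the full key (contig, position, ref, alt) is pre-existing.
   Matching is deliberately on the full key: two different substitutions at
   one site are independent events.
4. **Recurrence removal** (default: a key in ≥ 2 distinct samples):
   isolates from a common culture share pre-existing mutations; a variant
   recurring across isolates is overwhelmingly more likely shared ancestry
   than independent recurrence at the same base. Recurrence is assessed
   within the cohort passed to the function.

The fixed order makes the per-sample `filter_report()` counters
deterministic and exactly balancing. The cascade is idempotent, and
removal can only shrink sets, so no later stage resurrects a removed call.

## Spectra

`classify_substitution()` folds every SNV onto the strand where the
reference base is a pyrimidine, giving the conventional six classes; a
spectrum is the per-isolate count vector, summarised across a cohort as
the arithmetic mean per isolate (the number of isolates is taken from the
data, never hard-coded). Trinucleotide contexts at contig ends are
N-padded and excluded from the 96-class table, since their context is
undefined.

## The enrichment statistic

For a motif with mutated base class C (counting C on the forward strand
and G on the reverse), in one sample:

* `m_motif` — class mutations whose reference context matches the motif,
  strand-aware: a mutated C with a 5′ G, or a mutated G with a 3′ C;
* `m_class` — all class mutations (C→A plus G→T for the default motif);
* `x_motif`, `x_class` — occurrences of the motif and of the class base,
  both strands, in windows of ±20 bp around each class mutation
  (`flank = 20`), windows counted with multiplicity and the mutated base
  included;

and the fold-enrichment is

$$E = \frac{m_\text{motif}/m_\text{class}}{x_\text{motif}/x_\text{class}}.$$

Significance uses a one-sided Fisher's exact test on
`[[m_motif, m_class − m_motif], [x_motif, x_class − x_motif]]` with the
alternative of motif over-representation among mutations; conditional on
the margins this is the upper hypergeometric tail, computed with
`phyper()` and verified in the tests against brute-force enumeration of
the point probabilities and against `fisher.test()`. Degenerate tables
(a zero margin) return p = 1 with a flag. A sample with no class mutations
reports `NA` enrichment, p and load — absence of class mutations is not
evidence in either direction — and `x_motif = 0` with motif mutations
present reports an infinite enrichment with the p-value still computed.

The **mutation load** `m_motif · (E − 1)/E` estimates how many of the
motif-matching mutations the signature explains: under no enrichment each
motif mutation is fully explained by opportunity (load 0, and the formula
is floored at 0 for E ≤ 1); as E → ∞ every motif mutation is attributed
(load → `m_motif`).

### Windowed vs genome-wide opportunity

The opportunity counts can come from the ±20 bp windows (default) or from
the whole genome (`opportunity = "genome"`). The windowed denominator is
the right default for real genomes because it measures opportunity where
the mutations actually are, absorbing local composition bias. It has,
however, a structural coupling: each window is *centered on a class
mutation*, so when motif mutations dominate, the windows are enriched for
motif contexts through their own centers — a gC dinucleotide is
simultaneously a forward gCn and a reverse-strand nGc occurrence, so a
motif-centered window necessarily contributes two motif occurrences before
any flanking sequence is counted. The windowed estimator is therefore
conservative (biased toward 1) under strong enrichment and saturates near
the ratio of class to motif occurrences inside a motif-centered window
(about 3.5 at yeast-like GC on composition-homogeneous sequence),
regardless of how strong the planted signal is. On an i.i.d. genome there
is no local composition to correct for, the genome-wide denominator is
exactly the null motif fraction, and the estimator is unbiased for the
planted enrichment; the parameter-recovery validation therefore uses
`opportunity = "genome"`, while the null-calibration and strand-symmetry
checks exercise the windowed default. Both modes agree under the null.

### Other choices

* Windows are drawn around **class** mutations only: the statistic
  compares motif mutations to class mutations, so the opportunity set
  belongs to the mutated class.
* Per-sample analysis is the default (`pooled = TRUE` concatenates a
  group, and equals the per-sample computation on the concatenated calls).
* Benjamini–Hochberg adjustment across samples is available
  (`adjust = TRUE`) and off by default; per-group experiments typically
  report per-sample significance.
* N bases match nothing, including the `n` context code: an unread base is
  not evidence of opportunity.
* The exact 2×2 orientation is isolated in `fisher_one_sided()` so it can
  be revised in one place.

## Assay statistics

* `mutation_frequency()` and `viability_percent()` are the plain ratios
  (viability deliberately not clamped at 100%).
* `median_with_ci()` uses the distribution-free order-statistic interval
  from the binomial(n, ½) construction — the interval
  `(x_(d), x_(n−d+1))` with the largest d whose two-sided tail stays
  within 1 − level — which is conservative (coverage ≥ 95% by
  construction, e.g. 97.9% at n = 10) and assumption-free, matching
  median-centric reporting. Below n = 6 no such 95% interval exists and
  the sample range is returned, flagged.
* `mann_whitney_one_sided()` tests "treated stochastically greater".
  Ties get midranks. When `choose(n1 + n2, n2) ≤ 1e6` the p-value is exact
  by enumerating all rank assignments (group sizes up to ~10 vs 10, which
  covers typical culture counts); beyond that, the normal approximation
  with tie-corrected variance and continuity correction takes over. At
  8 vs 8 the worst-case disagreement between the branches is 0.0055.
* `compare_groups()` reports the fold-change as the **ratio of group
  medians**, consistent with median bars in plots; the per-culture-ratio
  alternative was rejected because cultures are not paired across
  treatment arms. A zero untreated median flags the fold-change as
  undefined rather than returning infinity.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with a truth
record, under a single seed (all randomness is scoped with `withr`, so
generation never perturbs the caller's RNG).

* `simulate_genome()` draws i.i.d. bases at a given GC content (default
  0.38, yeast-like). Default cohort shape is 36 isolates, mirroring common
  per-group sequencing designs.
* `simulate_cohort()` plants class mutations such that the **expected
  enrichment against genome-wide opportunity equals the requested E***:
  each mutation is a motif-site mutation with probability `E* · f`
  (f = the genome's motif fraction among class sites, ~0.19 at GC 0.38),
  sites drawn uniformly without replacement within the chosen stratum.
  This binomial-split construction makes the planted expectation exact and
  closed-form; requests beyond `1/f` are impossible for point mutations
  and raise an error. Genuine calls get VAFs uniform on [0.90, 1];
  planted confounders sit at sites disjoint from genuine calls: shared
  keys copied into 2–3 samples, parent keys placed in the parent set and a
  random subset of samples, low-VAF artifacts uniform on [0.10, 0.80].
  With `distinct_sites = TRUE` genuine sites are unique cohort-wide, so
  filter-accuracy checks are exact set comparisons; by default genuine
  sites may collide across samples (as real shared-culture data can).
* `simulate_assay()` draws viable titers log-normally (dispersion 0.3 on
  the log scale — a moderate culture-to-culture spread) and resistant
  counts as Poisson(frequency × cells plated). Culture variability is
  log-normal rather than a Luria–Delbrück jackpot model on purpose: the
  pipeline analyses frequencies, not rates, and the dispersion parameter
  can approximate heavier tails.

Passing the recovery and calibration tests on these generators shows the
statistics are correct *given their assumptions*. It does not show
robustness to what real genomes add: regional composition and replication-
timing structure (the windowed denominator exists precisely for this),
mutation clustering, sub-clonal lineages in a culture, or systematic
caller biases in VAF. The Luria–Delbrück fluctuation structure of real
cultures is likewise only approximated through the dispersion knob.

## Validation problem sizes

The shipped checks use: all 2×2 tables with margins ≤ 30 for the Fisher
oracle (≈ 246,000 tables); all group sizes ≤ 7, tied and tie-free, for the
Mann-Whitney oracle; 100-kb genomes with 100 isolates × 200 class
mutations for recovery at E* ∈ {1, 2, 5}; 100 random fixtures for strand
symmetry; and 1000 regenerations for assay fold recovery and null
calibration — sizes at which the Monte-Carlo error of each check is far
below its tolerance.

## Known limitations

* Genomes are held in memory as character vectors; indexed FASTA access
  for very large genomes is out of scope.
* The VCF reader targets minimal single-sample somatic-caller output
  (FREQ/AF fields); it is not a general-purpose VCF parser.
* Motif patterns describe a single mutated base with IUPAC context;
  multi-base signatures (e.g. dinucleotide substitutions) are not
  representable.
* Mutation-rate estimation (fluctuation analysis) is intentionally
  absent: the assay statistics operate on frequencies.
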