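---
title: "Noninvasive fetal genotyping from single-molecule cfDNA counts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noninvasive fetal genotyping from single-molecule cfDNA counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmartnipt)
```

## The measurement and its statistical model

Maternal plasma cfDNA is a mixture: a fraction FF (the *fetal fraction*,
typically 8–17% in the second trimester) is of placental origin, the rest
maternal. A barcoded targeted assay ligates degenerate 7-base barcode
adapters to cfDNA fragments before amplification, so that after sequencing,
reads sharing a (barcode, fragment start) pair are PCR copies of one
original molecule. Collapsing them gives, at each targeted pathogenic locus,
the number of unique molecules T and the number carrying the mutant allele
m.

Because one fetal allele contributes Δ = FF/2 of the plasma molecules, the
expected mutant fraction ε is determined by the maternal and fetal genotypes
jointly. For a recessive-disease carrier couple the mother is wild-type (AA)
or heterozygous (AB) and the fetus carries 0, 1 or 2 mutant alleles, giving
five states:

| state | maternal | fetal | ε |
|-------|----------|-------|----|
| AAaa  | WT       | WT    | 0 |
| AAab  | WT       | het   | Δ |
| ABaa  | het      | WT    | 0.5 − Δ |
| ABab  | het      | het   | 0.5 |
| ABbb  | het      | hom   | 0.5 + Δ |

Conditional on T and the state, m is binomial, so the state is deduced by
maximum likelihood and reported with the normalised probability

$$P(G) = \frac{\max_k \binom{T}{m}\varepsilon_k^m(1-\varepsilon_k)^{T-m}}
              {\sum_k \binom{T}{m}\varepsilon_k^m(1-\varepsilon_k)^{T-m}}.$$

`genotype_posterior()` computes the five log-likelihoods with
`dbinom(log = TRUE)` and normalises by log-sum-exp; a brute-force
direct-arithmetic evaluation agrees to 10 decimal places for every m at
T ≤ 50 (tested), and the log route stays finite at any realistic depth.

**Error floor.** A literal ε = 0 for AAaa would give zero likelihood the
moment a single sequencing error produces a mutant molecule. We therefore
clamp ε to [0.001, 0.999]; 0.001 is of the order of the post-consensus
per-molecule error of barcode-collapsed amplicon data. The floor is a
tunable argument (`error_floor`) and must stay below Δ, or AAaa and AAab
would become indistinguishable by construction.

**Tie-breaking.** Exactly equal posteriors are measure-zero but must be
reproducible: the argmax takes the first maximum in ε-ascending order, i.e.
the lower-ε state wins.

## Quality control

A call is valid when all of FF ≥ 5%, T ≥ 500 and P(G) ≥ 70% hold
(inclusive comparisons; `qc_thresholds()` makes them tunable). Every failed
criterion is named in the call's `qc_reasons`, and a case without a usable
FF estimate fails with `ff_unavailable`. A pregnancy passes QC only if all
of its targeted loci pass.

## Fetal-fraction estimation

At a SNP where the mother is homozygous and the fetus heterozygous, the
plasma minor-allele fraction equals Δ = FF/2 exactly — whichever homozygote
the mother is, because the minor-allele fraction is symmetric. The
estimator:

* classify a SNP informative when its minor fraction lies in [0.5%, 25%]
  and its depth is ≥ 100 molecules. The lower bound suppresses
  error-only signal at SNPs where the fetus shares the maternal homozygous
  genotype (these are silently non-informative, not errors); the upper bound
  excludes maternal heterozygotes, whose minor fraction sits near 50%.
* FF = 2 × median of the informative minor fractions, Δ = FF/2 (exact by
  construction, and asserted in tests). The median tolerates a few
  misclassified SNPs; with ≥ 3 informative SNPs required (configurable
  floor) the estimate is defined, otherwise the case QC-fails.

With the default 76-SNP panel at population alternate-allele frequency 0.5,
about a quarter of SNPs are informative (~19), and at depth 900 the
estimator's absolute bias is below 0.01 across true FF from 5% to 17%
(tested with 200 replicates per point).

## The synthetic cfDNA generator

No raw plasma data of this kind is publicly obtainable, so the package
carries a first-class generator whose defaults are the study conditions of
the motivating cohort:

* unique-molecule depth per locus: normal(902, 293) truncated to
  [486, 1754] and rounded — the published mean ± SD and range; the true
  depth distribution was not published, so a truncated normal matching
  those three statistics is the minimal choice. Note the asymmetric
  truncation places the realised mean slightly above 902.
* fetal fraction per pregnancy: normal(11.07%, 2.18%) truncated to
  [8.63%, 17.37%], the published cohort statistics (`simulate_cohort()`);
  single-case functions take a fixed `fetal_fraction`.
* couple mix: 23/29 compound-het couples (two loci, one per parent) and
  6/29 same-variant couples (one shared locus), as in the motivating
  cohort; fetal genotypes by Mendelian segregation.
* molecular identity: a random 7-base barcode plus a fragment start drawn
  from a 40-position window. Two true molecules can collide and merge
  downstream — under the defaults <0.1% of molecules at depth 900, an
  accepted small bias; tests that need exactness widen the window instead
  of pretending collisions cannot happen.
* PCR duplication: 1 + Poisson(mean − 1) reads per molecule (default mean
  3); no duplication model was published, and a shifted Poisson is the
  simplest family guaranteeing ≥ 1 read.
* per-read base error: symmetric allele flip, default 0.001.
* cross-target reads: 1% of reads flagged, allele uninformative; the
  pipeline's first step deletes them.

With error 0 and duplication 1 the mutant-molecule count is exactly
Binomial(T, ε) — a goodness-of-fit test over 500 seeded replicates backs
the generator's claim to be the model the caller assumes.

What the generator does **not** emulate: fragment-length distributions
(only a start-position jitter), sequence context and alignment artefacts,
indel-specific detection losses, maternal somatic or placental mosaic
variants, and barcode synthesis errors. Passing tests therefore show the
*analysis chain* is correct under its own statistical assumptions, not that
those assumptions exhaust real plasma data.

## What accuracy is achievable: the binomial ceiling

The three het-mother states are separated by Δ in expected mutant fraction.
At FF = 10% and T = 900 that is 0.05 against a binomial standard deviation
of ≈ 0.017 — about 1.5σ between ABab and its neighbours. The P ≥ 70% gate
removes only a narrow (±4 molecules) ambiguity band around each decision
boundary, so a draw a little beyond the boundary is called *confidently
wrong*. Exact summation over the binomial pmf gives the recovery among
QC-passed calls at FF = 0.10, T = 900, error 0.001:

| AAaa | AAab | ABaa | ABab | ABbb | mean |
|------|------|------|------|------|------|
| 1.000 | 1.000 | 0.958 | 0.910 | 0.958 | 0.965 |

Monte-Carlo calibration in the test suite reproduces these numbers, and the
end-to-end round trip (500 simulated pregnancies, cohort FF distribution,
all loci ≥ 500 molecules) lands at ~96% correct clinical statuses among QC
passes. Two acceptance expectations assert a ≥ 99% bound instead; they are
left failing deliberately, because under these study conditions the bound is
not attainable by any decision rule on (m, T) — the likelihoods themselves
overlap. The paternal-side states (AAaa/AAab, separated by Δ against a
standard deviation of ≈ 0.007 at ε = Δ) are recovered essentially perfectly,
which is why real cohorts of this design report their rare discordances on
the maternal side. Raising accuracy requires deeper unique-molecule counts,
higher FF, or a stricter P cutoff trading accuracy against no-call rate.

## Clinical interpretation and performance statistics

`combine_calls()` maps per-locus codes to a fetal status per couple
structure and is total: every code combination yields either a status or an
`inconsistent` flag (a code impossible for the locus's parental origin,
e.g. ABbb where the father carries no mutant allele). Inconsistent cases
are excluded from performance counts with a warning — except in the
end-to-end calibration, where an inconsistent call is counted as an
incorrect status, since excusing it would inflate accuracy.

Sensitivity and specificity take *clinically affected* (mutant homozygote
or compound heterozygote) as the positive class; carriers and normals are
both negative. Intervals are exact Clopper–Pearson from beta quantiles —
chosen because the all-success lower bound (α/2)^(1/n) reproduces the
published 54.07% (n = 6) and 83.89% (n = 21) bounds exactly, which
Wilson or Wald intervals do not. Percentages are rounded half-up to two
decimals only at the reporting boundary; full precision is kept internally.

The published cohort structure itself (genotype categories, one discordant
carrier-heterozygote case, two QC failures) ships as `mmachc_cohort()`:
its table resolves an internal inconsistency in the source material in
favour of the overall totals (28/29 unfiltered, 27/27 filtered, 6 affected
among 27), which are the counts the published interval bounds imply.
Per-case values not published (most P values, depths) are synthetic
stand-ins at the cohort means, documented as such; they only need to pass
or fail QC correctly.

## Problem sizes and runtimes

The test suite simulates at the sizes the claims need, not larger: 10,000
Mendelian draws for segregation ratios, 500 replicates for the binomial
goodness of fit, 200 replicates per FF point for estimator calibration,
1,000 cases per hypothesis for genotyper recovery, and 500 pregnancies
(~2.5 million reads) for the end-to-end round trip; the whole suite runs in
well under a minute on one core. The molecule-count fast path
(`simulate_molecule_counts()`) is used where only (m, T) matters, which the
read-level round-trip tests justify.

## Known limitations

* Direct counting cannot distinguish gene from pseudogene and does not
  detect exon-level deletions or duplications; variants are point-like
  alleles with REF/ALT semantics (indel efficiency differences are not
  modelled).
* HGVS strings are opaque identifiers; no coordinate arithmetic or
  normalisation is attempted.
* The FF estimator assumes an autosome-based SNP panel and a singleton
  pregnancy; no chrY route, no twin handling.
* Barcodes are not error-corrected (no within-edit-distance-1 merging);
  a barcode sequencing error creates a spurious singleton molecule.
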