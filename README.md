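# csmartnipt

Noninvasive prenatal genotyping of autosomal-recessive single-gene disorders
from single-molecule cell-free DNA counts.

## The problem

A couple in which both partners carry a pathogenic allele of a recessive
disease gene (here the motivating case: *MMACHC*, whose biallelic mutations
cause cblC-type methylmalonic acidemia) has a 1-in-4 risk of an affected
fetus in every pregnancy. The fetal genotype can be determined invasively
(amniocentesis), or noninvasively from the ~10% of cell-free DNA (cfDNA) in
maternal plasma that is of placental origin. Barcoded, targeted
single-molecule assays (cSMART-style) count original plasma DNA molecules at
each pathogenic locus; the mutant-molecule fraction then carries the
maternal *and* fetal genotype signal.

This package implements the full analysis chain for such an assay, plus a
seeded synthetic cfDNA generator so the chain is testable end-to-end without
access-restricted patient data:

1. **Molecule consolidation** — delete cross-target reads, group reads by
   (molecular barcode, fragment start), keep each group's majority allele as
   one unique molecule: per-locus counts (T total, m mutant).
2. **Fetal fraction** — FF = 2 × median minor-allele fraction over
   informative SNPs of a 76-SNP panel (maternal-homozygous /
   fetal-heterozygous sites, minor fraction within [0.5%, 25%]); the fetal
   allelic fraction is Δ = FF/2.
3. **Genotype deduction** — binomial maximum likelihood over the five
   maternal/fetal states with expected mutant fractions

   | AAaa | AAab | ABaa  | ABab | ABbb  |
   |------|------|-------|------|-------|
   | 0    | Δ    | 0.5−Δ | 0.5  | 0.5+Δ |

   (capital = maternal allele, small = fetal; A/a wild-type, B/b mutant),
   reporting P(G) = max_k Binom(m; T, ε_k) / Σ_j Binom(m; T, ε_j) and the QC
   rule FF ≥ 5%, T ≥ 500, P ≥ 70%.
4. **Clinical interpretation** — per-locus codes combine into a fetal status
   (normal / carrier / affected) per couple structure, and cohorts are
   summarised as concordance, sensitivity and specificity against invasive
   diagnosis with exact Clopper–Pearson 95% intervals.

## Worked example

```r
library(csmartnipt)

sim <- simulate_cohort(29, sim_params(), seed = 20220107)
out <- run_nipt_pipeline(sim$reads, sim$snps, sim$cases, sim$panel)
out$results <- merge(out$results,
                     data.frame(case_id = sim$cases$case_id,
                                ipd_status = sim$cases$true_status))
concordance(out$results, apply_qc = TRUE)
```

```
Concordance: 96.43% (27/28) [1 QC-failed case(s) removed]
Sensitivity: 100.00% (63.06-100.00%)  [8/8 affected]
Specificity: 95.00% (75.13-99.87%)  [19/20 unaffected]
```

One simulated pregnancy failed QC on a low genotype probability (P = 60.68%)
and one maternal-locus call was discordant — the same behaviour the QC rule
exists to catch in real cohorts. The numbered scripts under `analysis/` run
these stages one at a time, narrating what each found and writing its tables
under `results/`.

The published validation statistics are reproduced from their printed
inputs:

```r
pooled_summary(csmart_published_studies())$concordance_pct  # 95.88 (279/291)
clopper_pearson(6, 6)[["lower_pct"]]                        # 54.074...
allele_frequency_table()[1:2, ]
#    variant          count denominator   pct
#    c.609G>A            29          58 50.00
#    c.658_660delAAG     12          58 20.69
```

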