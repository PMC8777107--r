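#!/usr/bin/env Rscript
# Stage 4: deduce the maternal-fetal genotype at every targeted locus by
# binomial maximum likelihood over the five hypotheses (expected mutant
# fractions 0, Delta, 0.5-Delta, 0.5, 0.5+Delta), report the normalised
# genotype probability, and apply the QC rule FF >= 5%, T >= 500, P >= 70%.

library(csmartnipt)

counts <- read_table_tsv("results/counts.tsv")
ff <- read_table_tsv("results/ff.tsv")
calls <- call_genotypes(counts, ff)
write_table_tsv(calls, "results/calls.tsv")

panel <- read_panel_tsv("results/panel.tsv")
write_calls_vcf(calls, panel, "results/calls.vcf")

message(sprintf("called %d loci; %d (%.1f%%) with P > 90%%", nrow(calls),
                sum(calls$p_value > 0.9),
                100 * mean(calls$p_value > 0.9)))
fails <- calls[!calls$qc_pass, c("case_id", "locus_id", "p_value",
                                 "total_T", "qc_reasons")]
if (nrow(fails) > 0) {
  message("QC-failed loci:")
  for (i in seq_len(nrow(fails)))
    message(sprintf("  %s %s: P=%.2f%%, T=%d (%s)", fails$case_id[i],
                    fails$locus_id[i], 100 * fails$p_value[i],
                    fails$total_T[i], fails$qc_reasons[i]))
} else message("all loci passed QC")
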