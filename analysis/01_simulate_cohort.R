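#!/usr/bin/env Rscript
# Stage 1: generate a synthetic 29-pregnancy carrier-couple cohort at the
# published scale (unique-molecule depth ~902, fetal fraction ~11%), writing
# the barcoded read records, the 76-SNP fetal-fraction panel and the truth
# manifest as TSV under results/.

library(csmartnipt)

seed <- 20220107L
dir.create("results", showWarnings = FALSE)

sim <- simulate_cohort(29, sim_params(), seed = seed)

write_table_tsv(sim$reads, "results/reads.tsv")
write_table_tsv(sim$snps, "results/snps.tsv")
write_table_tsv(sim$truth, "results/truth.tsv")
write_table_tsv(sim$cases, "results/cases.tsv")
write_table_tsv(sim$panel, "results/panel.tsv")

message(sprintf("simulated %d pregnancies (%d compound-het, %d same-variant)",
                nrow(sim$cases),
                sum(sim$cases$couple_type == "compound_het"),
                sum(sim$cases$couple_type == "same_variant")))
message(sprintf("%d reads over %d loci; true FF %.2f-%.2f%%",
                nrow(sim$reads), nrow(sim$truth),
                100 * min(sim$cases$true_ff), 100 * max(sim$cases$true_ff)))
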