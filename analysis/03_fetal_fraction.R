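#!/usr/bin/env Rscript
# Stage 3: estimate each pregnancy's fetal DNA fraction as twice the median
# minor-allele fraction over the informative SNPs (maternal-homozygous /
# fetal-heterozygous sites), and derive the fetal allelic fraction
# Delta = FF/2 used by the genotype likelihoods.

library(csmartnipt)

snps <- read_table_tsv("results/snps.tsv")
ff <- estimate_ff_by_case(snps)
write_table_tsv(ff, "results/ff.tsv")

truth <- read_table_tsv("results/cases.tsv")
err <- ff$ff - truth$true_ff[match(ff$case_id, truth$case_id)]
message(sprintf("estimated FF for %d/%d cases; %d-%d informative SNPs each",
                sum(!is.na(ff$ff)), nrow(ff),
                min(ff$n_informative_snps), max(ff$n_informative_snps)))
message(sprintf("FF recovery: mean estimate %.2f%%, max |error| %.2f points",
                100 * mean(ff$ff, na.rm = TRUE),
                100 * max(abs(err), na.rm = TRUE)))
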