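#!/usr/bin/env Rscript
# Stage 2: delete cross-target reads and collapse PCR duplicates sharing a
# (barcode, fragment start) molecular identity into unique-molecule counts
# per targeted locus.

library(csmartnipt)

reads <- read_table_tsv("results/reads.tsv")
n_cross <- sum(reads$is_cross_target)
counts <- consolidate(delete_cross_target_reads(reads))
write_table_tsv(counts, "results/counts.tsv")

message(sprintf("deleted %d cross-target reads (%.2f%%)", n_cross,
                100 * n_cross / nrow(reads)))
message(sprintf("consolidated %d reads -> %d unique molecules over %d loci",
                nrow(reads) - n_cross, sum(counts$total_T), nrow(counts)))
message(sprintf("unique-molecule depth: mean %.0f, range %d-%d",
                mean(counts$total_T), min(counts$total_T),
                max(counts$total_T)))
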