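#!/usr/bin/env Rscript
# Stage 5: combine per-locus calls into a clinical fetal status per
# pregnancy, compare with the simulation truth (standing in for invasive
# prenatal diagnosis), and summarise concordance, sensitivity and
# specificity with exact Clopper-Pearson intervals, before and after QC.

library(csmartnipt)

calls <- read_table_tsv("results/calls.tsv")
panel <- read_panel_tsv("results/panel.tsv")
cases <- read_table_tsv("results/cases.tsv")
calls$parental_origin <-
  panel$parental_origin[match(calls$locus_id, panel$locus_id)]

results <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
  cc <- calls[calls$case_id == cases$case_id[i], , drop = FALSE]
  combine_calls(cc, cases$couple_type[i])
}))
results$ipd_status <- cases$true_status[match(results$case_id,
                                              cases$case_id)]
write_table_tsv(results, "results/case_results.tsv")

message("unfiltered:")
print(raw <- concordance(results, apply_qc = FALSE))
message("QC-filtered:")
print(qcf <- concordance(results, apply_qc = TRUE))
write_summary_json(qcf, "results/performance.json")
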