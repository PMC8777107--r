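#' Run the full noninvasive genotyping pipeline on a cohort
#'
#' Composes the analysis stages on in-memory tables: delete cross-target
#' reads, consolidate barcoded reads into unique-molecule counts, estimate
#' the fetal fraction per case from the SNP panel, call the maternal-fetal
#' genotype at every targeted locus with QC, and combine per-locus calls into
#' a clinical fetal status per pregnancy.
#'
#' @param reads read-record data.frame (see [simulate_reads()] for the
#'   schema).
#' @param snps SNP-panel data.frame (`case_id`, `snp_id`, `total_reads`,
#'   `alt_reads`).
#' @param cases data.frame with `case_id` and `couple_type`.
#' @param panel variant panel (`locus_id`, `parental_origin`, ...).
#' @param qc thresholds from [qc_thresholds()].
#' @param error_floor residual error rate for the genotype likelihoods.
#' @param ff_args list of arguments passed on to [estimate_ff_by_case()].
#' @param verbose emit per-case log messages.
#' @return list: `counts`, `ff`, `calls` (per-locus, with
#'   `parental_origin`), `results` (per-case `fetal_status`, `qc_pass`,
#'   `inconsistent`).
#' @export
run_nipt_pipeline <- function(reads, snps, cases, panel,
                              qc = qc_thresholds(), error_floor = 0.001,
                              ff_args = list(), verbose = FALSE) {
  counts <- consolidate(delete_cross_target_reads(reads))
  ff <- do.call(estimate_ff_by_case, c(list(snps = snps), ff_args))
  calls <- call_genotypes(counts, ff, qc = qc, error_floor = error_floor)
  calls$parental_origin <-
    panel$parental_origin[match(calls$locus_id, panel$locus_id)]
  results <- lapply(seq_len(nrow(cases)), function(i) {
    cid <- cases$case_id[i]
    cc <- calls[calls$case_id == cid, , drop = FALSE]
    res <- combine_calls(cc, cases$couple_type[i])
    if (verbose) {
      msg <- sprintf("[%s] status=%s qc=%s", cid, res$fetal_status,
                     ifelse(res$qc_pass, "pass", "FAIL"))
      if (res$qc_pass) message(msg) else warning(msg, call. = FALSE)
    }
    res
  })
  list(counts = counts, ff = ff, calls = calls,
       results = do.call(rbind, results))
}
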