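#' Read and write pipeline tables as TSV
#'
#' All interchange tables (variant panel, read records, unique-molecule
#' counts, SNP panel, truth manifest, per-locus calls, per-case results) are
#' plain TSV with a header line. `write_table_tsv()`/`read_table_tsv()`
#' round-trip exactly for these column types (character, integer, double,
#' logical).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_table_tsv()` returns a data.frame; `write_table_tsv()`
#'   returns `path` invisibly.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA")
}

#' Read a variant panel table
#'
#' A panel row is one targeted pathogenic allele: `locus_id`, `gene`,
#' `hgvs_c`, `parental_origin` (`maternal`/`paternal`/`shared`). HGVS cDNA
#' strings are treated as opaque identifiers; validation only requires
#' non-emptiness and unique locus ids.
#'
#' @param path TSV path.
#' @return validated panel data.frame.
#' @export
read_panel_tsv <- function(path) {
  panel <- read_table_tsv(path)
  need <- c("locus_id", "gene", "hgvs_c", "parental_origin")
  if (!all(need %in% names(panel)))
    stop_with("csmart_validation_error",
              paste("panel must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(panel$locus_id))
    stop_with("csmart_validation_error", "locus_id must be unique in a panel")
  if (any(!nzchar(panel$hgvs_c)))
    stop_with("csmart_validation_error", "hgvs_c must be non-empty")
  if (!all(panel$parental_origin %in% c("maternal", "paternal", "shared")))
    stop_with("csmart_validation_error",
              "parental_origin must be maternal/paternal/shared")
  panel
}

#' Write a performance summary as JSON
#'
#' @param summary a `performance_summary` (or any list of scalars/vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write called fetal variants as a minimal VCF
#'
#' One record per called fetal variant (loci whose fetal genotype carries at
#' least one mutant allele), with the fetal genotype in the sample `GT` field
#' (`ab` -> 0/1, `bb` -> 1/1). Positions come from the panel's `chrom`/`pos`
#' columns when present; otherwise the gene is used as the contig name and
#' the panel row index as a placeholder position, since the pipeline operates
#' on allele-count abstractions and never needs genomic coordinates.
#'
#' @param calls per-locus calls ([call_genotypes()]).
#' @param panel variant panel data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, panel, path) {
  chrom <- if ("chrom" %in% names(panel)) panel$chrom else panel$gene
  pos <- if ("pos" %in% names(panel)) panel$pos else seq_len(nrow(panel))
  idx <- match(calls$locus_id, panel$locus_id)
  fetal_gt <- c(AAaa = "0/0", AAab = "0/1", ABaa = "0/0", ABab = "0/1",
                ABbb = "1/1")[calls$genotype_code]
  keep <- fetal_gt %in% c("0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=csmartnipt",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Fetal genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "FETUS", sep = "\t"))
  if (any(keep)) {
    recs <- paste(chrom[idx][keep], pos[idx][keep],
                  panel$hgvs_c[idx][keep], "N", "M", ".",
                  ifelse(calls$qc_pass[keep], "PASS", "qc_fail"),
                  paste0("P=", formatC(calls$p_value[keep], digits = 4,
                                       format = "f")),
                  "GT", fetal_gt[keep], sep = "\t")
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Check sample-tracking spike-in tokens
#'
#' Each case's plasma can be spiked with a recorded artificial barcoded DNA
#' fragment; after sequencing, the recovered token must match the recorded
#' one, otherwise cross-sample contamination is suspected.
#'
#' @param manifest data.frame with `case_id`, `expected_spike_token`,
#'   `observed_spike_token`.
#' @return logical vector (TRUE = tokens match); mismatches raise a warning
#'   naming the cases.
#' @export
check_spike_tokens <- function(manifest) {
  stopifnot(all(c("case_id", "expected_spike_token",
                  "observed_spike_token") %in% names(manifest)))
  ok <- manifest$expected_spike_token == manifest$observed_spike_token
  if (any(!ok))
    warning("possible cross-sample contamination for case(s): ",
            paste(manifest$case_id[!ok], collapse = ", "))
  ok
}
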