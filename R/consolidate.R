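#' Delete reads amplified across targeted alleles
#'
#' Reads produced by primer pairs spanning two targeted alleles cannot be
#' assigned to a single molecule of one locus and are removed before
#' consolidation. Input order of the surviving reads is preserved.
#'
#' @param reads read-record data.frame with an `is_cross_target` column.
#' @return the subset with `is_cross_target == FALSE`.
#' @export
delete_cross_target_reads <- function(reads) {
  stopifnot(is.data.frame(reads), "is_cross_target" %in% names(reads))
  out <- reads[!reads$is_cross_target, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse duplicated barcoded reads into unique-molecule counts
#'
#' Reads are grouped by (case_id, locus_id, barcode, fragment_start) -- the
#' molecular identity of one original cfDNA fragment -- and each group is
#' reduced to a single unique molecule carrying the group's majority allele
#' (the highest-frequency sequence). Groups with an exact allele tie carry no
#' majority and are discarded from both the mutant and the total count.
#' Counts are then aggregated per (case, locus).
#'
#' The result is permutation-invariant in the input reads, and lossless when
#' the per-read error rate is zero (barring barcode collisions, where two
#' true molecules merge into one group).
#'
#' @param reads read-record data.frame (`case_id`, `locus_id`, `barcode`,
#'   `fragment_start`, `observed_allele`); cross-target reads must already be
#'   deleted.
#' @return data.frame: `case_id`, `locus_id`, `total_T`, `mutant_m`, sorted
#'   by case then locus.
#' @export
consolidate <- function(reads) {
  stopifnot(is.data.frame(reads),
            all(c("case_id", "locus_id", "barcode", "fragment_start",
                  "observed_allele") %in% names(reads)))
  if (!is.null(reads$is_cross_target) && any(reads$is_cross_target))
    stop_with("csmart_validation_error",
              "cross-target reads must be deleted before consolidation")
  bad <- nchar(reads$barcode) != 7L
  if (any(bad))
    stop_with("csmart_validation_error",
              paste0(sum(bad), " read(s) with malformed (non-7-base) barcode"))
  if (!all(reads$observed_allele %in% c("REF", "ALT")))
    stop_with("csmart_validation_error", "observed_allele must be REF or ALT")
  if (nrow(reads) == 0L)
    return(data.frame(case_id = character(0), locus_id = character(0),
                      total_T = integer(0), mutant_m = integer(0),
                      stringsAsFactors = FALSE))
  key <- paste(reads$case_id, reads$locus_id, reads$barcode,
               reads$fragment_start, sep = "\r")
  is_alt <- reads$observed_allele == "ALT"
  grp <- rowsum(cbind(alt = as.integer(is_alt), n = 1L), key, reorder = FALSE)
  majority_alt <- grp[, "alt"] * 2L > grp[, "n"]
  tie <- grp[, "alt"] * 2L == grp[, "n"]
  # one (case, locus) label per group
  first <- !duplicated(key)
  lab <- paste(reads$case_id[first], reads$locus_id[first], sep = "\r")
  keep <- !tie
  per_locus <- rowsum(cbind(total_T = as.integer(keep),
                            mutant_m = as.integer(keep & majority_alt)),
                      lab, reorder = FALSE)
  parts <- strsplit(rownames(per_locus), "\r", fixed = TRUE)
  out <- data.frame(case_id = vapply(parts, `[`, "", 1L),
                    locus_id = vapply(parts, `[`, "", 2L),
                    total_T = as.integer(per_locus[, "total_T"]),
                    mutant_m = as.integer(per_locus[, "mutant_m"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$case_id, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
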