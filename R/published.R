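#' Published 29-pregnancy MMACHC cohort structure
#'
#' Reconstructs, at the genotype-code level, the published 29-case cblC-type
#' MMA validation cohort: 23 compound-het carrier couples (2 normal, 7
#' maternal-carrier, 9 paternal-carrier, 5 affected compound-het fetuses by
#' invasive diagnosis) and 6 same-variant couples (2 normal, 3 carrier, 1
#' affected homozygote). One carrier-heterozygote case was discordant
#' (noninvasive call: normal) and two carrier-heterozygote cases failed QC --
#' the discordant case among them -- so the cohort is 28/29 concordant
#' unfiltered and 27/27 after QC filtering.
#'
#' Per-case read counts and P values were not published except for the two
#' QC-failed cases (P = 58.12%; P = 66.96% with 486 unique molecules), so the
#' remaining rows carry synthetic stand-in values at the cohort means (P =
#' 0.95, T = 902, FF = 0.1107) that pass every QC criterion; only the QC
#' verdicts, genotype codes and truth statuses affect the statistics.
#'
#' @return list with `calls` (one row per case-locus: `case_id`,
#'   `couple_type`, `locus_id`, `parental_origin`, `genotype_code`,
#'   `p_value`, `total_T`, `ff`, `qc_pass`, `qc_reasons`) and `truth`
#'   (`case_id`, `couple_type`, `ipd_status`).
#' @export
mmachc_cohort <- function() {
  qc <- qc_thresholds()
  mk_ch <- function(case_id, gm, gp) {
    data.frame(case_id = case_id, couple_type = "compound_het",
               locus_id = c("L_mat", "L_pat"),
               parental_origin = c("maternal", "paternal"),
               genotype_code = c(gm, gp),
               p_value = 0.95, total_T = 902, ff = 0.1107,
               stringsAsFactors = FALSE)
  }
  mk_sv <- function(case_id, g, p_value = 0.95, total_T = 902, ff = 0.1107) {
    data.frame(case_id = case_id, couple_type = "same_variant",
               locus_id = "L_shared", parental_origin = "shared",
               genotype_code = g, p_value = p_value, total_T = total_T,
               ff = ff, stringsAsFactors = FALSE)
  }
  ch_truth <- c(rep("normal", 2), rep("maternal_carrier", 7),
                rep("paternal_carrier", 9), rep("affected_compound_het", 5))
  ch_codes <- list(normal = c("ABaa", "AAaa"),
                   maternal_carrier = c("ABab", "AAaa"),
                   paternal_carrier = c("ABaa", "AAab"),
                   affected_compound_het = c("ABab", "AAab"))
  calls <- list(); truth <- list()
  for (i in seq_along(ch_truth)) {
    cid <- sprintf("PD%04d", i)
    g <- ch_codes[[ch_truth[i]]]
    calls[[cid]] <- mk_ch(cid, g[1], g[2])
    truth[[cid]] <- data.frame(case_id = cid, couple_type = "compound_het",
                               ipd_status = ch_truth[i],
                               stringsAsFactors = FALSE)
  }
  # same-variant couples: 2 normal, 3 carrier (1 discordant + both QC
  # failures), 1 affected homozygote
  sv <- list(
    list(id = "PD0024", truth = "normal",  code = "ABaa"),
    list(id = "PD0025", truth = "normal",  code = "ABaa"),
    list(id = "PD0026", truth = "carrier", code = "ABab"),
    # PD0614: discordant (called normal) and QC-failed on low P value
    list(id = "PD0614", truth = "carrier", code = "ABaa", p = 0.5812),
    # PD0579: concordant but QC-failed on low P value and read count
    list(id = "PD0579", truth = "carrier", code = "ABab", p = 0.6696,
         T = 486L),
    list(id = "PD0029", truth = "affected_homozygote", code = "ABbb")
  )
  for (s in sv) {
    calls[[s$id]] <- mk_sv(s$id, s$code,
                           p_value = if (is.null(s$p)) 0.95 else s$p,
                           total_T = if (is.null(s$T)) 902L else s$T)
    truth[[s$id]] <- data.frame(case_id = s$id, couple_type = "same_variant",
                                ipd_status = s$truth,
                                stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  rownames(calls) <- NULL
  verdicts <- lapply(seq_len(nrow(calls)), function(i)
    qc_evaluate(calls$ff[i], calls$total_T[i], calls$p_value[i], qc))
  calls$qc_pass <- vapply(verdicts, `[[`, logical(1), "pass")
  calls$qc_reasons <- vapply(verdicts, function(v)
    paste(v$reasons, collapse = ";"), character(1))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(calls = calls, truth = truth)
}

#' Pathogenic MMACHC alleles of the 29 published probands
#'
#' The published proband mutation spectrum: 11 MMACHC variants over 58
#' alleles, with 6 homozygotes (5 for c.609G>A, 1 for c.567dupT) and 23
#' compound heterozygotes. Per-variant allele counts match the published
#' table exactly; the pairing of alleles within compound-het probands was not
#' published, so this table uses one synthetic pairing consistent with those
#' counts (the allele-frequency table is invariant to the pairing).
#'
#' @return data.frame in long form: `proband_id`, `hgvs_c` (two rows per
#'   proband).
#' @export
mmachc_proband_alleles <- function() {
  pair <- function(a, b) c(a, b)
  pairs <- c(
    replicate(5, pair("c.609G>A", "c.609G>A"), simplify = FALSE),   # hom
    list(pair("c.567dupT", "c.567dupT")),                           # hom
    replicate(12, pair("c.609G>A", "c.658_660delAAG"), simplify = FALSE),
    replicate(3, pair("c.609G>A", "c.217C>T"), simplify = FALSE),
    replicate(3, pair("c.609G>A", "c.482G>A"), simplify = FALSE),
    list(pair("c.609G>A", "c.567dupT")),
    list(pair("c.80A>G", "c.394C>T")),
    list(pair("c.80A>G", "c.394C>T")),
    list(pair("c.271dupA", "c.276+1G>A")),
    list(pair("c.427C>T", "c.606_641delinsCTT"))
  )
  stopifnot(length(pairs) == 29L)
  data.frame(
    proband_id = rep(sprintf("P%02d", seq_along(pairs)), each = 2L),
    hgvs_c = unlist(pairs),
    stringsAsFactors = FALSE
  )
}

#' Per-variant allele frequencies among probands
#'
#' Counts pathogenic alleles over 2 x n probands and reports percentages
#' rounded half-up to 2 decimals, sorted by descending count.
#'
#' @param alleles long-form data.frame with `proband_id` and `hgvs_c`
#'   columns; every proband must contribute exactly 2 alleles.
#' @return data.frame: `variant`, `count`, `denominator`, `pct`.
#' @export
allele_frequency_table <- function(alleles = mmachc_proband_alleles()) {
  stopifnot(is.data.frame(alleles),
            all(c("proband_id", "hgvs_c") %in% names(alleles)))
  per <- table(alleles$proband_id)
  if (any(per != 2L))
    stop_with("csmart_validation_error",
              "every proband must contribute exactly 2 pathogenic alleles")
  counts <- sort(table(alleles$hgvs_c), decreasing = TRUE)
  denom <- nrow(alleles)
  data.frame(variant = names(counts), count = as.integer(counts),
             denominator = denom,
             pct = round_half_up(100 * as.integer(counts) / denom),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Published single-molecule NIPT validation studies
#'
#' Case and concordant counts of the seven published validation cohorts of
#' this assay family across ten genes (Wilson disease, hearing loss,
#' phenylketonuria, beta-thalassemia and cblC-type MMA), as printed, with no
#' QC filtering; pooling them reproduces the published 279/291 = 95.88%
#' overall concordance.
#'
#' @return data.frame: `disease`, `gene`, `case_n`, `concordant_n`.
#' @export
csmart_published_studies <- function() {
  data.frame(
    disease = c("Wilson disease", "Inherited non-syndromic hearing loss",
                "Autosomal recessive non-syndromic hearing loss",
                "PKU", "PKU", "beta-thalassemia", "cblC type MMA"),
    gene = c("ATP7B", "GJB2/GJB3/SLC26A4/RNR1/TRNL1/COX1", "GJB2/SLC26A4",
             "PAH", "PAH", "HBB", "MMACHC"),
    case_n = c(4L, 25L, 80L, 18L, 33L, 102L, 29L),
    concordant_n = c(4L, 25L, 73L, 18L, 32L, 99L, 28L),
    stringsAsFactors = FALSE
  )
}
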