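#' Combine per-locus genotype calls into a fetal clinical status
#'
#' A carrier couple is either *compound-het* (mother and father each carry a
#' different pathogenic allele; two targeted loci, one of maternal and one of
#' paternal origin) or *same-variant* (both parents carry the same allele; one
#' shared locus). The per-locus maternal-fetal genotype codes map to the
#' clinical fetal status:
#'
#' * compound-het couple: (ABaa, AAaa) -> `normal`; (ABab, AAaa) ->
#'   `maternal_carrier`; (ABaa, AAab) -> `paternal_carrier`; (ABab, AAab) ->
#'   `affected_compound_het` (maternal-origin locus listed first).
#' * same-variant couple: ABaa -> `normal`; ABab -> `carrier`; ABbb ->
#'   `affected_homozygote`.
#'
#' A code impossible for a locus's parental origin (e.g. ABbb at a
#' maternal-only variant, where the father carries no mutant allele to
#' transmit) marks the case `inconsistent`; such cases are excluded from
#' performance counts by [concordance()] with a warning. The case passes QC
#' iff every constituent locus passes.
#'
#' @param calls data.frame of per-locus calls for ONE case, with columns
#'   `case_id`, `locus_id`, `parental_origin` (`maternal`/`paternal`/`shared`),
#'   `genotype_code`, `qc_pass`.
#' @param couple_type `"compound_het"` or `"same_variant"`.
#' @return one-row data.frame: `case_id`, `couple_type`, `fetal_status`,
#'   `qc_pass`, `inconsistent`.
#' @export
combine_calls <- function(calls, couple_type = c("compound_het",
                                                 "same_variant")) {
  couple_type <- match.arg(couple_type)
  stopifnot(is.data.frame(calls), nrow(calls) >= 1L,
            length(unique(calls$case_id)) == 1L)
  res <- data.frame(case_id = calls$case_id[1], couple_type = couple_type,
                    fetal_status = NA_character_,
                    qc_pass = all(calls$qc_pass), inconsistent = FALSE,
                    stringsAsFactors = FALSE)
  if (couple_type == "compound_het") {
    if (nrow(calls) != 2L ||
        !setequal(calls$parental_origin, c("maternal", "paternal")))
      stop_with("csmart_validation_error",
                "a compound-het couple needs exactly one maternal and one paternal locus")
    gm <- calls$genotype_code[calls$parental_origin == "maternal"]
    gp <- calls$genotype_code[calls$parental_origin == "paternal"]
    # the mother is het at her own variant and WT at the father's; the fetus
    # can carry at most one mutant allele per locus
    if (!(gm %in% c("ABaa", "ABab")) || !(gp %in% c("AAaa", "AAab"))) {
      res$inconsistent <- TRUE
      return(res)
    }
    key <- paste(gm, gp)
    res$fetal_status <- switch(key,
      "ABaa AAaa" = "normal",
      "ABab AAaa" = "maternal_carrier",
      "ABaa AAab" = "paternal_carrier",
      "ABab AAab" = "affected_compound_het")
  } else {
    if (nrow(calls) != 1L)
      stop_with("csmart_validation_error",
                "a same-variant couple has exactly one shared locus")
    g <- calls$genotype_code[1]
    if (!(g %in% c("ABaa", "ABab", "ABbb"))) {
      res$inconsistent <- TRUE
      return(res)
    }
    res$fetal_status <- switch(g, ABaa = "normal", ABab = "carrier",
                               ABbb = "affected_homozygote")
  }
  res
}

#' Is a fetal status clinically affected?
#'
#' The positive class for sensitivity/specificity: an affected fetus
#' (compound heterozygote or mutant homozygote). Carriers and normals are
#' both negative.
#'
#' @param status character vector of fetal statuses.
#' @return logical vector.
#' @export
is_affected <- function(status) {
  status %in% c("affected_compound_het", "affected_homozygote")
}

#' Exact Clopper-Pearson binomial confidence interval (percent)
#'
#' Two-sided exact interval from beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)`, upper =
#' `qbeta(1 - alpha/2, x + 1, n - x)`, with the closed-form boundary cases
#' lower = `(alpha/2)^(1/n)` when x = n and upper = `1 - (alpha/2)^(1/n)`
#' when x = 0.
#'
#' @param successes number of successes, `0 <= successes <= n`.
#' @param n number of trials, `>= 1`.
#' @param confidence confidence level (default 0.95).
#' @return numeric vector `c(lower_pct, upper_pct)` in percent.
#' @examples
#' clopper_pearson(6, 6)    # lower 54.07
#' clopper_pearson(21, 21)  # lower 83.89
#' @export
clopper_pearson <- function(successes, n, confidence = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_with("csmart_validation_error",
              "Clopper-Pearson interval undefined for n < 1")
  if (successes < 0 || successes > n)
    stop_with("csmart_validation_error", "need 0 <= successes <= n")
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower_pct = 100 * lower, upper_pct = 100 * upper)
}

#' Concordance, sensitivity and specificity versus invasive diagnosis
#'
#' Compares noninvasively deduced fetal statuses with the invasive prenatal
#' diagnosis (IPD) truth. Concordance is the fraction of cases whose statuses
#' match. The positive class is a clinically affected fetus ([is_affected()]);
#' sensitivity and specificity carry exact Clopper-Pearson 95% intervals.
#' Percentages are rounded half-up to 2 decimals at this reporting boundary;
#' counts are exact.
#'
#' @param results data.frame with `case_id`, `fetal_status` (NIPT),
#'   `ipd_status`, `qc_pass`, and optionally `inconsistent` (such cases are
#'   dropped with a warning before any counting).
#' @param apply_qc if `TRUE` (default), QC-failed cases are removed before
#'   counting.
#' @param confidence confidence level for the intervals (default 0.95).
#' @return list of class `performance_summary`: `n_total`, `n_concordant`,
#'   `concordance_pct`, `concordance_ci_pct`, `tp`, `fn`, `tn`, `fp`,
#'   `sensitivity_pct`, `sensitivity_ci_pct`, `specificity_pct`,
#'   `specificity_ci_pct`, `n_qc_failed_removed`.
#' @export
concordance <- function(results, apply_qc = TRUE, confidence = 0.95) {
  stopifnot(is.data.frame(results))
  if (!is.null(results$inconsistent) && any(results$inconsistent)) {
    warning(sum(results$inconsistent),
            " case(s) with parental-origin-inconsistent genotype codes",
            " excluded from performance counts")
    results <- results[!results$inconsistent, , drop = FALSE]
  }
  n_removed <- 0L
  if (apply_qc) {
    n_removed <- sum(!results$qc_pass)
    results <- results[results$qc_pass, , drop = FALSE]
  }
  n <- nrow(results)
  if (n == 0L)
    stop_with("csmart_empty_cohort_error", "no cases left to evaluate")
  conc <- results$fetal_status == results$ipd_status
  pos <- is_affected(results$ipd_status)       # truth = IPD
  called_pos <- is_affected(results$fetal_status)
  tp <- sum(pos & called_pos);  fn <- sum(pos & !called_pos)
  tn <- sum(!pos & !called_pos); fp <- sum(!pos & called_pos)
  sens_ci <- if (tp + fn > 0) clopper_pearson(tp, tp + fn, confidence)
             else c(NA_real_, NA_real_)
  spec_ci <- if (tn + fp > 0) clopper_pearson(tn, tn + fp, confidence)
             else c(NA_real_, NA_real_)
  structure(list(
    n_total = n, n_concordant = sum(conc),
    concordance_pct = round_half_up(100 * sum(conc) / n),
    concordance_ci_pct = round_half_up(clopper_pearson(sum(conc), n,
                                                       confidence)),
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity_pct = if (tp + fn > 0) round_half_up(100 * tp / (tp + fn))
                      else NA_real_,
    sensitivity_ci_pct = round_half_up(sens_ci),
    specificity_pct = if (tn + fp > 0) round_half_up(100 * tn / (tn + fp))
                      else NA_real_,
    specificity_ci_pct = round_half_up(spec_ci),
    n_qc_failed_removed = n_removed
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Concordance: %.2f%% (%d/%d)", x$concordance_pct,
              x$n_concordant, x$n_total))
  if (x$n_qc_failed_removed > 0)
    cat(sprintf(" [%d QC-failed case(s) removed]", x$n_qc_failed_removed))
  cat("\n")
  if (!is.na(x$sensitivity_pct))
    cat(sprintf("Sensitivity: %.2f%% (%.2f-%.2f%%)  [%d/%d affected]\n",
                x$sensitivity_pct, x$sensitivity_ci_pct[1],
                x$sensitivity_ci_pct[2], x$tp, x$tp + x$fn))
  if (!is.na(x$specificity_pct))
    cat(sprintf("Specificity: %.2f%% (%.2f-%.2f%%)  [%d/%d unaffected]\n",
                x$specificity_pct, x$specificity_ci_pct[1],
                x$specificity_ci_pct[2], x$tn, x$tn + x$fp))
  invisible(x)
}

#' Pooled concordance across published studies
#'
#' Sums case and concordant counts across study rows and reports the pooled
#' concordance with its exact Clopper-Pearson interval.
#'
#' @param studies data.frame with `case_n` and `concordant_n` columns
#'   (`concordant_n <= case_n` per row).
#' @param confidence confidence level (default 0.95).
#' @return list: `n_total`, `n_concordant`, `concordance_pct`,
#'   `concordance_ci_pct`.
#' @export
pooled_summary <- function(studies, confidence = 0.95) {
  stopifnot(is.data.frame(studies))
  if (nrow(studies) == 0L)
    stop_with("csmart_empty_cohort_error", "empty study table")
  if (any(studies$concordant_n > studies$case_n) ||
      any(studies$concordant_n < 0) || any(studies$case_n < 1))
    stop_with("csmart_validation_error",
              "need 0 <= concordant_n <= case_n and case_n >= 1 in every row")
  n <- sum(studies$case_n); k <- sum(studies$concordant_n)
  list(n_total = n, n_concordant = k,
       concordance_pct = round_half_up(100 * k / n),
       concordance_ci_pct = round_half_up(clopper_pearson(k, n, confidence)))
}
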