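#' Flag fetal-fraction-informative SNPs
#'
#' A SNP informs the fetal fraction when the mother is homozygous and the
#' fetus heterozygous: the plasma minor-allele fraction then equals FF/2. The
#' classifier keeps SNPs whose minor-allele fraction lies inside
#' `[low, high]`: the lower bound suppresses error-only signal at SNPs where
#' the fetus shares the maternal homozygous genotype, the upper bound
#' excludes maternal heterozygotes (minor fraction near 0.5). SNPs below the
#' minimum depth are never informative; zero-depth SNPs are excluded with a
#' warning.
#'
#' @param snps data.frame with `total_reads` and `alt_reads` columns.
#' @param low,high minor-allele-fraction window (defaults 0.005 and 0.25).
#' @param min_depth minimum unique-molecule depth (default 100).
#' @return logical vector, one flag per row of `snps`.
#' @export
classify_snp <- function(snps, low = 0.005, high = 0.25, min_depth = 100) {
  stopifnot(is.data.frame(snps),
            all(c("total_reads", "alt_reads") %in% names(snps)))
  if (any(snps$alt_reads > snps$total_reads))
    stop_with("csmart_validation_error", "alt_reads exceeds total_reads")
  if (any(snps$total_reads == 0))
    warning(sum(snps$total_reads == 0), " SNP(s) with zero depth excluded")
  frac <- ifelse(snps$total_reads > 0, snps$alt_reads / snps$total_reads, NA)
  minor <- pmin(frac, 1 - frac)
  !is.na(minor) & snps$total_reads >= min_depth & minor >= low & minor <= high
}

#' Estimate the fetal DNA fraction from the SNP panel
#'
#' FF is estimated as twice the median minor-allele fraction over the
#' informative SNPs ([classify_snp()]), and the fetal allelic fraction is
#' Delta = FF/2 -- the plasma contribution of a single fetal allele. The
#' median is robust to a few misclassified SNPs and is deterministic for
#' fixed input.
#'
#' @param snps data.frame with `snp_id`, `total_reads`, `alt_reads` for one
#'   case.
#' @param low,high,min_depth informative-SNP window, see [classify_snp()].
#' @param min_informative minimum number of informative SNPs required
#'   (default 3); below it the case has no usable FF and QC-fails.
#' @return list of class `ff_estimate`: `ff`, `delta` (= ff/2 exactly),
#'   `n_informative_snps`.
#' @examples
#' snps <- data.frame(snp_id = c("a", "b", "c"), total_reads = 1000,
#'                    alt_reads = c(50, 50, 950))
#' estimate_ff(snps)  # ff = 0.10, delta = 0.05
#' @export
estimate_ff <- function(snps, low = 0.005, high = 0.25, min_depth = 100,
                        min_informative = 3L) {
  informative <- classify_snp(snps, low, high, min_depth)
  if (sum(informative) < min_informative)
    stop_with("csmart_ff_unavailable",
              sprintf("only %d informative SNP(s); need >= %d",
                      sum(informative), min_informative))
  frac <- snps$alt_reads[informative] / snps$total_reads[informative]
  minor <- pmin(frac, 1 - frac)
  ff <- 2 * stats::median(minor)
  structure(list(ff = ff, delta = ff / 2,
                 n_informative_snps = sum(informative)),
            class = "ff_estimate")
}

#' Estimate fetal fractions for a whole cohort SNP table
#'
#' Applies [estimate_ff()] per case; cases where FF is unavailable get `NA`
#' (they will QC-fail downstream with reason `ff_unavailable`).
#'
#' @param snps data.frame with `case_id`, `snp_id`, `total_reads`,
#'   `alt_reads`.
#' @param ... passed to [estimate_ff()].
#' @return data.frame: `case_id`, `ff`, `delta`, `n_informative_snps`.
#' @export
estimate_ff_by_case <- function(snps, ...) {
  stopifnot("case_id" %in% names(snps))
  ids <- unique(snps$case_id)
  rows <- lapply(ids, function(cid) {
    e <- tryCatch(estimate_ff(snps[snps$case_id == cid, , drop = FALSE], ...),
                  csmart_ff_unavailable = function(cnd) NULL)
    data.frame(case_id = cid,
               ff = if (is.null(e)) NA_real_ else e$ff,
               delta = if (is.null(e)) NA_real_ else e$delta,
               n_informative_snps = if (is.null(e)) 0L
                                    else e$n_informative_snps,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
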