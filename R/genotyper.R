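#' The five maternal-fetal genotype hypotheses
#'
#' In a pregnancy at risk for an autosomal-recessive disorder the mother is
#' either wild-type homozygous or a carrier at a targeted locus, and the fetus
#' carries zero, one or two mutant alleles consistent with that. The plasma
#' mutant-allele fraction expected under each state is a function of the fetal
#' allelic fraction Delta = FF/2 (one fetal allele contributes half the fetal
#' fraction FF of cfDNA):
#'
#' | code | maternal | fetal   | expected mutant fraction |
#' |------|----------|---------|--------------------------|
#' | AAaa | WT-hom   | WT-hom  | 0                        |
#' | AAab | WT-hom   | het     | Delta                    |
#' | ABaa | het      | WT-hom  | 0.5 - Delta              |
#' | ABab | het      | het     | 0.5                      |
#' | ABbb | het      | mut-hom | 0.5 + Delta              |
#'
#' Capital letters denote maternal alleles (A wild-type, B mutant), small
#' letters fetal alleles (a wild-type, b mutant). The rows are ordered by
#' expected fraction; every function in the package that returns per-hypothesis
#' values uses this order.
#'
#' @return data.frame with columns `code`, `maternal`, `fetal`.
#' @export
genotype_hypotheses <- function() {
  data.frame(
    code     = c("AAaa", "AAab", "ABaa", "ABab", "ABbb"),
    maternal = c("WT", "WT", "het", "het", "het"),
    fetal    = c("WT", "het", "WT", "het", "hom"),
    stringsAsFactors = FALSE
  )
}

# raw (unclamped) expected mutant fractions, in hypothesis order
epsilon_raw <- function(delta) {
  c(AAaa = 0, AAab = delta, ABaa = 0.5 - delta, ABab = 0.5, ABbb = 0.5 + delta)
}

#' Expected plasma mutant fraction under a genotype hypothesis
#'
#' Returns the expected mutant-molecule fraction epsilon_k(Delta) for one of
#' the five hypotheses, clamped to `[error_floor, 1 - error_floor]`. The floor
#' replaces the theoretical epsilon = 0 of the AAaa state: with a literal zero
#' any single sequencing-error-derived mutant molecule would give that state
#' zero likelihood, so a residual per-molecule error rate is modelled instead.
#'
#' @param hypothesis hypothesis code (one of `genotype_hypotheses()$code`).
#' @param delta fetal allelic fraction, FF/2; must lie in (0, 0.5).
#' @param error_floor residual error rate in (0, delta); default 0.001.
#' @return expected mutant fraction in `[error_floor, 1 - error_floor]`.
#' @examples
#' expected_epsilon("ABbb", delta = 0.05)   # 0.55
#' expected_epsilon("AAaa", delta = 0.05)   # clamped to 0.001
#' @export
expected_epsilon <- function(hypothesis, delta, error_floor = 0.001) {
  check_delta(delta, error_floor)
  eps <- epsilon_raw(delta)
  if (!all(hypothesis %in% names(eps)))
    stop_with("csmart_parameter_error", "unknown genotype hypothesis code")
  unname(pmin(pmax(eps[hypothesis], error_floor), 1 - error_floor))
}

check_delta <- function(delta, error_floor) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0 || delta >= 0.5)
    stop_with("csmart_parameter_error",
              "delta (= FF/2) must lie strictly between 0 and 0.5")
  if (!is.numeric(error_floor) || error_floor <= 0 || error_floor >= delta)
    stop_with("csmart_parameter_error",
              "error_floor must lie strictly between 0 and delta")
  invisible(TRUE)
}

#' Posterior probabilities of the five maternal-fetal genotypes
#'
#' Scores the observed mutant unique-molecule count m out of T against the
#' five genotype hypotheses by binomial likelihood at their expected mutant
#' fractions epsilon_k(Delta), and normalises:
#' `P(G_k) = Binom(m; T, eps_k) / sum_j Binom(m; T, eps_j)`.
#' The maximum of this vector is the genotype probability (P value) reported
#' for the argmax call. Likelihoods are computed in log space and combined by
#' log-sum-exp, so T in the thousands is numerically safe.
#'
#' @param m observed mutant unique molecules, `0 <= m <= T`.
#' @param T total unique molecules, `>= 1`.
#' @param delta fetal allelic fraction FF/2.
#' @param error_floor residual error rate clamping epsilon (default 0.001).
#' @return named numeric vector of five probabilities summing to 1, in
#'   `genotype_hypotheses()` order.
#' @examples
#' genotype_posterior(m = 550, T = 1000, delta = 0.05)
#' @export
genotype_posterior <- function(m, T, delta, error_floor = 0.001) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 1)
    stop_with("csmart_no_data_error", "T must be >= 1 (no unique molecules)")
  if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 0 || m > T)
    stop_with("csmart_parameter_error", "m must satisfy 0 <= m <= T")
  eps <- expected_epsilon(genotype_hypotheses()$code, delta, error_floor)
  ll <- stats::dbinom(m, T, eps, log = TRUE)
  post <- exp(ll - logsumexp(ll))
  names(post) <- genotype_hypotheses()$code
  post
}

#' Quality-control thresholds for a valid maternal-fetal genotype call
#'
#' The call-validity rule: fetal fraction `>= min_ff`, total unique molecules
#' `>= min_reads`, and genotype probability `>= min_p`. All comparisons are
#' inclusive.
#'
#' @param min_ff minimum fetal fraction (default 0.05).
#' @param min_reads minimum total unique molecules (default 500).
#' @param min_p minimum genotype probability (default 0.70).
#' @return list of thresholds.
#' @export
qc_thresholds <- function(min_ff = 0.05, min_reads = 500, min_p = 0.70) {
  stopifnot(min_ff > 0, min_ff < 1, min_reads >= 1, min_p > 0, min_p <= 1)
  list(min_ff = min_ff, min_reads = min_reads, min_p = min_p)
}

#' Evaluate the QC rule for one call
#'
#' @param ff fetal fraction (NA if unavailable).
#' @param total_T total unique molecules.
#' @param p_value genotype probability of the argmax hypothesis.
#' @param qc thresholds from [qc_thresholds()].
#' @return list with `pass` (logical) and `reasons` (character vector naming
#'   every failed criterion: `ff_unavailable`, `ff_below_min`,
#'   `reads_below_min`, `p_below_min`).
#' @export
qc_evaluate <- function(ff, total_T, p_value, qc = qc_thresholds()) {
  reasons <- character(0)
  if (is.na(ff)) reasons <- c(reasons, "ff_unavailable")
  else if (ff < qc$min_ff) reasons <- c(reasons, "ff_below_min")
  if (total_T < qc$min_reads) reasons <- c(reasons, "reads_below_min")
  if (is.na(p_value) || p_value < qc$min_p) reasons <- c(reasons, "p_below_min")
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Call the maternal-fetal genotype at one locus
#'
#' Combines a per-locus unique-molecule count with the case's fetal-fraction
#' estimate: the genotype code is the argmax of [genotype_posterior()], the
#' P value its posterior probability, and QC applies the inclusive rule
#' FF >= 5%, T >= 500, P >= 70% (defaults). Exact posterior ties are broken
#' deterministically in favour of the lower expected mutant fraction.
#'
#' All five hypotheses are always scored, even when parental genotypes exclude
#' some; compatibility with a known parental origin is checked downstream
#' (see [combine_calls()]) rather than by constraining the maximisation.
#'
#' @param count one-row data.frame with `case_id`, `locus_id`, `total_T`,
#'   `mutant_m` (see [consolidate()]).
#' @param ffe fetal-fraction estimate from [estimate_ff()], or `NULL` if FF
#'   could not be estimated (the call then QC-fails with `ff_unavailable`;
#'   the posterior is evaluated at `fallback_delta`).
#' @param qc thresholds from [qc_thresholds()].
#' @param error_floor residual error rate (default 0.001).
#' @param fallback_delta delta used only when `ffe` is `NULL` (default 0.05).
#' @return one-row data.frame: `case_id`, `locus_id`, `genotype_code`,
#'   `p_value`, `mutant_m`, `total_T`, `ff`, `qc_pass`, `qc_reasons`
#'   (semicolon-separated).
#' @export
call_genotype <- function(count, ffe, qc = qc_thresholds(),
                          error_floor = 0.001, fallback_delta = 0.05) {
  stopifnot(is.data.frame(count), nrow(count) == 1L)
  if (count$total_T < 1)
    stop_with("csmart_no_data_error",
              paste0("no unique molecules at ", count$locus_id))
  ff <- if (is.null(ffe)) NA_real_ else ffe$ff
  delta <- if (is.null(ffe)) fallback_delta else ffe$delta
  post <- genotype_posterior(count$mutant_m, count$total_T, delta, error_floor)
  k <- which.max(post)  # first max = lowest-epsilon tie-break
  verdict <- qc_evaluate(ff, count$total_T, post[[k]], qc)
  data.frame(
    case_id = count$case_id, locus_id = count$locus_id,
    genotype_code = names(post)[k], p_value = unname(post[[k]]),
    mutant_m = count$mutant_m, total_T = count$total_T, ff = ff,
    qc_pass = verdict$pass, qc_reasons = paste(verdict$reasons, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Call genotypes for a whole counts table
#'
#' Vector version of [call_genotype()]: joins a consolidated counts table with
#' a per-case fetal-fraction table and calls every (case, locus) row.
#'
#' @param counts data.frame from [consolidate()].
#' @param ff_table data.frame with `case_id`, `ff`, `delta` (NA ff allowed).
#' @param qc,error_floor,fallback_delta passed to [call_genotype()].
#' @return data.frame of per-locus calls.
#' @export
call_genotypes <- function(counts, ff_table, qc = qc_thresholds(),
                           error_floor = 0.001, fallback_delta = 0.05) {
  stopifnot(is.data.frame(counts), is.data.frame(ff_table))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    cid <- counts$case_id[i]
    j <- match(cid, ff_table$case_id)
    ffe <- if (is.na(j) || is.na(ff_table$ff[j])) NULL
           else list(ff = ff_table$ff[j], delta = ff_table$delta[j])
    call_genotype(counts[i, , drop = FALSE], ffe, qc, error_floor,
                  fallback_delta)
  })
  do.call(rbind, rows)
}
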