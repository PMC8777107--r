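# Independent oracles and tiny fixtures shared across test files.

# Brute-force five-hypothesis posterior: direct arithmetic, no logs. Kept
# independent of genotype_posterior() so the two routes cross-check.
brute_posterior <- function(m, T, delta, error_floor = 0.001) {
  eps <- c(0, delta, 0.5 - delta, 0.5, 0.5 + delta)
  eps <- pmin(pmax(eps, error_floor), 1 - error_floor)
  lik <- choose(T, m) * eps^m * (1 - eps)^(T - m)
  stats::setNames(lik / sum(lik), c("AAaa", "AAab", "ABaa", "ABab", "ABbb"))
}

# Exact expected argmax-recovery rate among QC passes for one true state:
# sums the binomial pmf of the observed mutant count over all m, with the
# posterior computed by the brute-force oracle.
exact_recovery <- function(code, T, ff, error_rate, min_p = 0.70,
                           error_floor = 0.001) {
  delta <- ff / 2
  eps_true <- c(AAaa = 0, AAab = delta, ABaa = 0.5 - delta, ABab = 0.5,
                ABbb = 0.5 + delta)[[code]]
  p_obs <- eps_true * (1 - error_rate) + (1 - eps_true) * error_rate
  pm <- stats::dbinom(0:T, T, p_obs)
  hit <- pass <- logical(T + 1)
  for (m in 0:T) {
    post <- brute_posterior(m, T, delta, error_floor)
    pass[m + 1] <- max(post) >= min_p
    hit[m + 1] <- pass[m + 1] && names(which.max(post)) == code
  }
  c(recovery = sum(pm[hit]) / sum(pm[pass]), pass_rate = sum(pm[pass]))
}

# two-locus compound-het panel and one-locus shared panel
panel_ch <- data.frame(locus_id = c("L1", "L2"), gene = "MMACHC",
                       hgvs_c = c("c.609G>A", "c.658_660delAAG"),
                       parental_origin = c("maternal", "paternal"),
                       stringsAsFactors = FALSE)
panel_sv <- data.frame(locus_id = "L1", gene = "MMACHC",
                       hgvs_c = "c.609G>A", parental_origin = "shared",
                       stringsAsFactors = FALSE)

# hand-built read records: one row per read
mk_reads <- function(barcode, allele, fragment_start = 0L, locus = "L1",
                     case = "c1", cross = FALSE) {
  data.frame(case_id = case, locus_id = locus, barcode = barcode,
             fragment_start = fragment_start, observed_allele = allele,
             primer_id = "prm", is_cross_target = cross,
             stringsAsFactors = FALSE)
}
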