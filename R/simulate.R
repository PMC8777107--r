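#' Simulation parameters for the synthetic cfDNA generator
#'
#' Defaults reproduce the scale of the validation cohort: unique-molecule
#' depth per locus drawn from a normal(902, 293) truncated to [486, 1754]
#' (the published mean, SD and range; the depth distribution itself was not
#' published), fetal fraction 11.07% (cohort mean), a 76-SNP fetal-fraction
#' panel with population alternate-allele frequency 0.5, shifted-Poisson PCR
#' duplication (1 + Poisson(mean - 1) reads per molecule), per-read base
#' error 0.001, and 1% cross-target reads.
#'
#' @param fetal_fraction fetal fraction FF in (0, 1); default 0.1107.
#' @param n_unique_molecules_mean,n_unique_molecules_sd,n_unique_molecules_range
#'   truncated-normal depth model for unique molecules per locus.
#' @param pcr_duplication_mean mean reads per unique molecule, `>= 1`.
#' @param base_error_rate per-read, per-site allele flip probability in
#'   `[0, 0.1]`.
#' @param n_snps number of fetal-fraction SNPs (default 76).
#' @param snp_pop_alt_freq population alternate-allele frequency of the SNP
#'   panel (default 0.5, maximising informative-SNP yield).
#' @param cross_target_fraction fraction of extra reads amplified across
#'   targeted alleles (deleted upstream of counting); default 0.01.
#' @param jitter_window number of distinct fragment start positions per locus
#'   (default 40); together with the 7-base barcode this sets the molecular
#'   identity space.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(fetal_fraction = 0.1107,
                       n_unique_molecules_mean = 902,
                       n_unique_molecules_sd = 293,
                       n_unique_molecules_range = c(486L, 1754L),
                       pcr_duplication_mean = 3,
                       base_error_rate = 0.001,
                       n_snps = 76L,
                       snp_pop_alt_freq = 0.5,
                       cross_target_fraction = 0.01,
                       jitter_window = 40L,
                       seed = NULL) {
  if (fetal_fraction <= 0 || fetal_fraction >= 1)
    stop_with("csmart_parameter_error", "fetal_fraction must lie in (0, 1)")
  if (length(n_unique_molecules_range) != 2L ||
      n_unique_molecules_range[1] < 1)
    stop_with("csmart_parameter_error",
              "n_unique_molecules_range must be [min >= 1, max]")
  if (base_error_rate < 0 || base_error_rate > 0.1)
    stop_with("csmart_parameter_error", "base_error_rate must lie in [0, 0.1]")
  if (pcr_duplication_mean < 1)
    stop_with("csmart_parameter_error", "pcr_duplication_mean must be >= 1")
  if (n_snps < 1)
    stop_with("csmart_parameter_error", "n_snps must be >= 1")
  if (cross_target_fraction < 0 || cross_target_fraction >= 1)
    stop_with("csmart_parameter_error",
              "cross_target_fraction must lie in [0, 1)")
  structure(list(
    fetal_fraction = fetal_fraction,
    n_unique_molecules_mean = n_unique_molecules_mean,
    n_unique_molecules_sd = n_unique_molecules_sd,
    n_unique_molecules_range = as.integer(n_unique_molecules_range),
    pcr_duplication_mean = pcr_duplication_mean,
    base_error_rate = base_error_rate,
    n_snps = as.integer(n_snps),
    snp_pop_alt_freq = snp_pop_alt_freq,
    cross_target_fraction = cross_target_fraction,
    jitter_window = as.integer(jitter_window),
    seed = seed
  ), class = "sim_params")
}

maybe_seed <- function(params) {
  if (!is.null(params$seed)) set.seed(params$seed)
  invisible(NULL)
}

zyg_levels <- c("WT", "het", "hom")

# zygosity -> number of mutant alleles
zyg_dose <- function(z) c(WT = 0L, het = 1L, hom = 2L)[z]

#' Draw Mendelian fetal genotypes for a carrier couple
#'
#' Builds a trio over the panel's 1 or 2 pathogenic loci. With two loci
#' (compound-het couple) the mother is heterozygous at the maternal-origin
#' locus and wild-type at the paternal one, and vice versa for the father;
#' with one shared locus (same-variant couple) both parents are heterozygous.
#' Parental zygosities can be overridden. The fetal genotype at each locus is
#' one allele drawn from each parent, independently across loci.
#'
#' @param panel data.frame of targeted loci with `locus_id` and
#'   `parental_origin` (`maternal`/`paternal`/`shared`); 1 or 2 rows.
#' @param params a [sim_params()] (seed honoured if set).
#' @param maternal_zygosity,paternal_zygosity optional named vectors
#'   (locus_id -> `"WT"`/`"het"`/`"hom"`) overriding the carrier-couple
#'   defaults.
#' @return list of class `trio_genotypes`: `panel`, `maternal`, `paternal`,
#'   `fetal` (named zygosity vectors).
#' @export
simulate_trio <- function(panel, params = sim_params(),
                          maternal_zygosity = NULL,
                          paternal_zygosity = NULL) {
  stopifnot(is.data.frame(panel), "locus_id" %in% names(panel),
            "parental_origin" %in% names(panel))
  if (nrow(panel) < 1L || nrow(panel) > 2L)
    stop_with("csmart_unsupported_configuration",
              "a couple carries pathogenic alleles at 1 or 2 loci")
  maybe_seed(params)
  loci <- panel$locus_id
  mat <- stats::setNames(ifelse(panel$parental_origin %in%
                                  c("maternal", "shared"), "het", "WT"), loci)
  pat <- stats::setNames(ifelse(panel$parental_origin %in%
                                  c("paternal", "shared"), "het", "WT"), loci)
  if (!is.null(maternal_zygosity)) mat[names(maternal_zygosity)] <- maternal_zygosity
  if (!is.null(paternal_zygosity)) pat[names(paternal_zygosity)] <- paternal_zygosity
  if (!all(c(mat, pat) %in% zyg_levels))
    stop_with("csmart_parameter_error", "zygosities must be WT/het/hom")
  transmit <- function(z) stats::rbinom(length(z), 1L, zyg_dose(z) / 2)
  fetal_dose <- transmit(mat) + transmit(pat)
  fet <- stats::setNames(zyg_levels[fetal_dose + 1L], loci)
  structure(list(panel = panel, maternal = mat, paternal = pat, fetal = fet),
            class = "trio_genotypes")
}

# maternal/fetal zygosity pair -> genotype code of the true state
state_code <- function(maternal, fetal) {
  if (maternal == "hom")
    stop_with("csmart_unsupported_configuration",
              "mutant-homozygous mothers are outside the hypothesis space")
  key <- paste(maternal, fetal)
  code <- c("WT WT" = "AAaa", "WT het" = "AAab",
            "het WT" = "ABaa", "het het" = "ABab", "het hom" = "ABbb")[key]
  if (is.na(code))
    stop_with("csmart_parameter_error",
              paste("impossible maternal/fetal state:", key))
  unname(code)
}

#' Draw true mutant-molecule counts for genotype states
#'
#' The molecule-level kernel of the read simulator: for a true maternal-fetal
#' state with expected plasma mutant fraction eps = epsilon_k(Delta), each of
#' T unique molecules is mutant with probability eps; a per-molecule error
#' rate flips alleles symmetrically, so the observed mutant count is exactly
#' `Binomial(T, eps(1 - e) + (1 - eps)e)`. This is the distribution the full
#' read-level simulator reduces to when PCR duplication is 1, and is the fast
#' path for large calibration studies.
#'
#' @param code genotype code(s) of the true state (recycled against `T`).
#' @param T total unique molecules (vector).
#' @param delta fetal allelic fraction FF/2.
#' @param error_rate per-molecule allele flip probability.
#' @return integer vector of mutant-molecule counts.
#' @export
simulate_molecule_counts <- function(code, T, delta, error_rate = 0) {
  n <- max(length(code), length(T))
  code <- rep_len(code, n)
  T <- rep_len(T, n)
  eps <- epsilon_raw(delta)[code]
  if (any(is.na(eps)))
    stop_with("csmart_parameter_error", "unknown genotype code")
  if (any(eps < 0) || any(eps > 1))
    stop_with("csmart_parameter_error", "epsilon outside [0, 1]")
  p <- eps * (1 - error_rate) + (1 - eps) * error_rate
  stats::rbinom(n, T, unname(p))
}

#' Simulate barcoded targeted reads for one pregnancy
#'
#' For each targeted locus: draws the unique-molecule depth from the
#' truncated-normal model, assigns each molecule a mutant/wild-type allele
#' with probability epsilon_k(Delta) of the trio's true state, a random
#' 7-base molecular barcode and a fragment start within the jitter window,
#' emits `1 + Poisson(mean - 1)` duplicate reads per molecule sharing
#' (barcode, fragment_start), flips each read's allele with the base error
#' rate, and appends a configurable fraction of cross-target reads (flagged,
#' allele uninformative, removed by [delete_cross_target_reads()]).
#'
#' Two true molecules may draw the same (barcode, fragment_start) and merge
#' downstream; with the default 40-position window and 4^7 barcodes this is
#' rare (<0.1% of molecules at depth 900) and is an accepted small bias.
#'
#' @param trio a [simulate_trio()] result.
#' @param params a [sim_params()] (seed honoured if set).
#' @param case_id case label for the output records.
#' @return data.frame of read records (`case_id`, `locus_id`, `barcode`,
#'   `fragment_start`, `observed_allele`, `primer_id`, `is_cross_target`)
#'   with attribute `truth`: per-locus true molecule table (`locus_id`,
#'   `state_code`, `total_T`, `mutant_m`).
#' @export
simulate_reads <- function(trio, params = sim_params(), case_id = "case01") {
  stopifnot(inherits(trio, "trio_genotypes"))
  maybe_seed(params)
  delta <- params$fetal_fraction / 2
  per_locus <- lapply(trio$panel$locus_id, function(loc) {
    code <- state_code(trio$maternal[[loc]], trio$fetal[[loc]])
    T_i <- rtruncnorm_int(1L, params$n_unique_molecules_mean,
                          params$n_unique_molecules_sd,
                          params$n_unique_molecules_range[1],
                          params$n_unique_molecules_range[2])
    eps <- epsilon_raw(delta)[[code]]
    if (eps < 0 || eps > 1)
      stop_with("csmart_parameter_error", "epsilon outside [0, 1]")
    alt <- stats::runif(T_i) < eps
    bc <- random_barcodes(T_i)
    fs <- sample.int(params$jitter_window, T_i, replace = TRUE) - 1L
    dups <- 1L + stats::rpois(T_i, params$pcr_duplication_mean - 1)
    idx <- rep.int(seq_len(T_i), dups)
    allele <- ifelse(alt[idx], "ALT", "REF")
    flip <- stats::runif(length(idx)) < params$base_error_rate
    allele[flip] <- ifelse(allele[flip] == "ALT", "REF", "ALT")
    reads <- data.frame(
      case_id = case_id, locus_id = loc, barcode = bc[idx],
      fragment_start = fs[idx], observed_allele = allele,
      primer_id = paste0("prm_", loc), is_cross_target = FALSE,
      stringsAsFactors = FALSE)
    n_cross <- round(params$cross_target_fraction * nrow(reads))
    if (n_cross > 0) {
      cross <- data.frame(
        case_id = case_id, locus_id = loc,
        barcode = random_barcodes(n_cross),
        fragment_start = sample.int(params$jitter_window, n_cross,
                                    replace = TRUE) - 1L,
        observed_allele = "REF", primer_id = "prm_cross",
        is_cross_target = TRUE, stringsAsFactors = FALSE)
      reads <- rbind(reads, cross)
    }
    list(reads = reads,
         truth = data.frame(locus_id = loc, state_code = code,
                            total_T = T_i, mutant_m = sum(alt),
                            stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(per_locus, `[[`, "reads"))
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, lapply(per_locus, `[[`, "truth"))
  out
}

#' Simulate the fetal-fraction SNP panel for one pregnancy
#'
#' Maternal and paternal SNP genotypes are drawn from Hardy-Weinberg
#' proportions at the population alternate-allele frequency; the fetus
#' inherits one allele from each parent. The plasma alternate-allele fraction
#' at each SNP is the mixture expectation `(1 - FF) * mat/2 + FF * fet/2`
#' (allele dosages over 2), perturbed by the base error rate, and the
#' observed alternate count is binomial at the locus depth drawn from the
#' unique-molecule model.
#'
#' @param trio a [simulate_trio()] result (only used for labelling; SNP
#'   genotypes are independent of the pathogenic loci).
#' @param params a [sim_params()] (seed honoured if set).
#' @param case_id case label.
#' @return data.frame: `case_id`, `snp_id`, `total_reads`, `alt_reads` with
#'   attribute `truth` (maternal/fetal allele dosages per SNP).
#' @export
simulate_snp_panel <- function(trio, params = sim_params(),
                               case_id = "case01") {
  maybe_seed(params)
  n <- params$n_snps
  q <- params$snp_pop_alt_freq
  ff <- params$fetal_fraction
  mat <- stats::rbinom(n, 2L, q)
  pat <- stats::rbinom(n, 2L, q)
  fet <- stats::rbinom(n, 1L, mat / 2) + stats::rbinom(n, 1L, pat / 2)
  p <- (1 - ff) * mat / 2 + ff * fet / 2
  p <- p * (1 - params$base_error_rate) + (1 - p) * params$base_error_rate
  depth <- rtruncnorm_int(n, params$n_unique_molecules_mean,
                          params$n_unique_molecules_sd,
                          params$n_unique_molecules_range[1],
                          params$n_unique_molecules_range[2])
  out <- data.frame(case_id = case_id, snp_id = sprintf("snp%03d", seq_len(n)),
                    total_reads = depth,
                    alt_reads = stats::rbinom(n, depth, p),
                    stringsAsFactors = FALSE)
  attr(out, "truth") <- data.frame(snp_id = out$snp_id, maternal_dose = mat,
                                   paternal_dose = pat, fetal_dose = fet,
                                   stringsAsFactors = FALSE)
  out
}

#' Simulate a cohort of carrier-couple pregnancies
#'
#' Draws `n_cases` pregnancies: each couple is compound-het (two loci) or
#' same-variant (one shared locus) with probability `prop_same_variant` for
#' the latter (default 6/29, the published cohort mix); each case's fetal
#' fraction is drawn from the published normal(0.1107, 0.0218) truncated to
#' [0.0863, 0.1737] unless `ff_values` fixes it. Returns the reads, SNP
#' panel, and a truth manifest with the Mendelian fetal genotypes and the
#' implied clinical status.
#'
#' @param n_cases number of pregnancies.
#' @param params a [sim_params()]; its `fetal_fraction` is overridden per
#'   case unless `ff_values` is given.
#' @param prop_same_variant probability a couple shares one variant
#'   (default 6/29).
#' @param ff_values optional numeric vector (recycled) of true fetal
#'   fractions, bypassing the cohort FF distribution.
#' @param seed integer seed for the whole cohort.
#' @return list: `reads`, `snps`, `truth` (per-locus:`case_id`, `locus_id`,
#'   `parental_origin`, maternal/paternal/fetal zygosity, `state_code`,
#'   `true_ff`), `cases` (`case_id`, `couple_type`, `true_ff`,
#'   `true_status`), `panel`.
#' @export
simulate_cohort <- function(n_cases, params = sim_params(),
                            prop_same_variant = 6 / 29, ff_values = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params$seed <- NULL  # one seeded stream for the whole cohort
  reads <- list(); snps <- list(); truth <- list(); cases <- list()
  panel_ch <- data.frame(locus_id = c("L_mat", "L_pat"),
                         gene = "MMACHC",
                         hgvs_c = c("c.609G>A", "c.658_660delAAG"),
                         parental_origin = c("maternal", "paternal"),
                         stringsAsFactors = FALSE)
  panel_sv <- data.frame(locus_id = "L_shared", gene = "MMACHC",
                         hgvs_c = "c.609G>A", parental_origin = "shared",
                         stringsAsFactors = FALSE)
  for (i in seq_len(n_cases)) {
    cid <- sprintf("SIM%04d", i)
    same <- stats::runif(1) < prop_same_variant
    panel <- if (same) panel_sv else panel_ch
    ff <- if (!is.null(ff_values)) ff_values[(i - 1) %% length(ff_values) + 1]
          else cohort_ff(1)
    p <- params; p$fetal_fraction <- ff
    trio <- simulate_trio(panel, p)
    rd <- simulate_reads(trio, p, case_id = cid)
    sp <- simulate_snp_panel(trio, p, case_id = cid)
    tr <- attr(rd, "truth")
    truth[[cid]] <- data.frame(
      case_id = cid, locus_id = panel$locus_id,
      parental_origin = panel$parental_origin,
      maternal_zygosity = unname(trio$maternal[panel$locus_id]),
      paternal_zygosity = unname(trio$paternal[panel$locus_id]),
      fetal_zygosity = unname(trio$fetal[panel$locus_id]),
      state_code = tr$state_code[match(panel$locus_id, tr$locus_id)],
      true_ff = ff, stringsAsFactors = FALSE)
    cases[[cid]] <- data.frame(
      case_id = cid,
      couple_type = if (same) "same_variant" else "compound_het",
      true_ff = ff,
      true_status = true_status(truth[[cid]]),
      stringsAsFactors = FALSE)
    reads[[cid]] <- rd; snps[[cid]] <- sp
  }
  list(reads = do.call(rbind, c(reads, list(make.row.names = FALSE))),
       snps = do.call(rbind, c(snps, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       cases = do.call(rbind, c(cases, list(make.row.names = FALSE))),
       panel = unique(rbind(panel_ch, panel_sv)))
}

# fetal fraction draws at the published cohort scale
cohort_ff <- function(n) {
  rtruncnorm_int(n, 1107, 218, 863, 1737) / 10000
}

# clinical status implied by the true per-locus states of one case
true_status <- function(case_truth) {
  codes <- stats::setNames(case_truth$state_code, case_truth$parental_origin)
  if ("shared" %in% names(codes)) {
    switch(codes[["shared"]], AAaa = , AAab = "inconsistent",
           ABaa = "normal", ABab = "carrier", ABbb = "affected_homozygote")
  } else {
    key <- paste(codes[["maternal"]], codes[["paternal"]])
    switch(key,
           "ABaa AAaa" = "normal", "ABab AAaa" = "maternal_carrier",
           "ABaa AAab" = "paternal_carrier",
           "ABab AAab" = "affected_compound_het", "inconsistent")
  }
}
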