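test_that("Mendelian segregation gives the expected fetal genotype ratios", {
  set.seed(101)
  p <- sim_params()
  # both parents het at one shared locus: 1/4 WT, 1/2 het, 1/4 hom-mut
  fetal <- replicate(10000, simulate_trio(panel_sv, p)$fetal[["L1"]])
  expect_equal(mean(fetal == "hom"), 0.25, tolerance = 0.02 / 0.25)
  expect_equal(mean(fetal == "het"), 0.50, tolerance = 0.02 / 0.50)
  # compound-het couple: loci segregate independently; joint compound het 1/4
  both <- replicate(10000, {
    f <- simulate_trio(panel_ch, p)$fetal
    f[["L1"]] == "het" && f[["L2"]] == "het"
  })
  expect_equal(mean(both), 0.25, tolerance = 0.02 / 0.25)
})

test_that("a wild-type father never transmits the paternal-branch allele", {
  set.seed(102)
  for (i in 1:200) {
    trio <- simulate_trio(panel_ch, sim_params(),
                          paternal_zygosity = c(L1 = "WT", L2 = "WT"))
    expect_true(trio$fetal[["L2"]] %in% c("WT"))  # paternal locus: no source
    expect_true(trio$fetal[["L1"]] %in% c("WT", "het"))  # maternal branch only
  }
})

test_that("panels with more than two loci are rejected", {
  bad <- rbind(panel_ch, data.frame(locus_id = "L3", gene = "MMACHC",
                                    hgvs_c = "c.80A>G",
                                    parental_origin = "maternal"))
  expect_error(simulate_trio(bad, sim_params()),
               class = "csmart_unsupported_configuration")
})

test_that("identical parameters and seed reproduce byte-identical tables", {
  p <- sim_params(seed = 7)
  trio1 <- simulate_trio(panel_ch, p)
  trio2 <- simulate_trio(panel_ch, p)
  expect_identical(trio1, trio2)
  r1 <- simulate_reads(trio1, p); r2 <- simulate_reads(trio2, p)
  expect_identical(r1, r2)
  s1 <- simulate_snp_panel(trio1, p); s2 <- simulate_snp_panel(trio2, p)
  expect_identical(s1, s2)
  c1 <- simulate_cohort(3, sim_params(), seed = 11)
  c2 <- simulate_cohort(3, sim_params(), seed = 11)
  expect_identical(c1, c2)
})

test_that("read records have the assay structure", {
  set.seed(103)
  p <- sim_params(n_unique_molecules_range = c(200L, 400L),
                  n_unique_molecules_mean = 300, n_unique_molecules_sd = 50)
  reads <- simulate_reads(simulate_trio(panel_ch, p), p)
  expect_true(all(nchar(reads$barcode) == 7L))
  expect_true(all(grepl("^[ACGT]{7}$", reads$barcode)))
  expect_true(all(reads$observed_allele %in% c("REF", "ALT")))
  expect_true(all(reads$fragment_start >= 0 &
                    reads$fragment_start < p$jitter_window))
  expect_gt(sum(reads$is_cross_target), 0)
  truth <- attr(reads, "truth")
  expect_true(all(truth$total_T >= 200 & truth$total_T <= 400))
})

test_that("distinct molecular identities equal the drawn unique count", {
  # wide jitter window makes barcode collisions vanishingly unlikely
  set.seed(104)
  p <- sim_params(jitter_window = 100000L, pcr_duplication_mean = 3)
  reads <- simulate_reads(simulate_trio(panel_ch, p), p)
  reads <- delete_cross_target_reads(reads)
  truth <- attr(reads, "truth")
  for (loc in truth$locus_id) {
    sub <- reads[reads$locus_id == loc, ]
    groups <- unique(paste(sub$barcode, sub$fragment_start))
    expect_identical(length(groups), as.integer(truth$total_T[truth$locus_id == loc]))
  }
})

test_that("with no error and no duplication the mutant count is binomial", {
  # het mother / mut-hom fetus at FF = 0.10: epsilon = 0.5 + 0.05
  set.seed(105)
  p <- sim_params(fetal_fraction = 0.10, base_error_rate = 0,
                  pcr_duplication_mean = 1, cross_target_fraction = 0,
                  n_unique_molecules_mean = 300, n_unique_molecules_sd = 0,
                  n_unique_molecules_range = c(300L, 300L))
  trio <- simulate_trio(panel_sv, p, maternal_zygosity = c(L1 = "het"))
  trio$fetal[["L1"]] <- "hom"
  m <- replicate(500, {
    counts <- consolidate(delete_cross_target_reads(simulate_reads(trio, p)))
    counts$mutant_m
  })
  expect_equal(mean(m) / 300, 0.55, tolerance = 0.01 / 0.55)
  # chi-squared goodness of fit against Binomial(300, 0.55) at alpha = 0.01
  breaks <- c(-Inf, stats::qbinom(seq(0.1, 0.9, 0.1), 300, 0.55), Inf)
  obs <- table(cut(m, breaks))
  p_bins <- diff(stats::pbinom(c(-Inf, stats::qbinom(seq(0.1, 0.9, 0.1),
                                                     300, 0.55), Inf),
                               300, 0.55))
  gof <- stats::chisq.test(as.vector(obs), p = p_bins, rescale.p = TRUE)
  expect_gt(gof$p.value, 0.01)
})

test_that("a wild-type/wild-type case with zero error yields zero mutants", {
  set.seed(106)
  p <- sim_params(base_error_rate = 0, cross_target_fraction = 0)
  trio <- simulate_trio(panel_sv, p, maternal_zygosity = c(L1 = "WT"),
                        paternal_zygosity = c(L1 = "WT"))
  reads <- simulate_reads(trio, p)
  expect_identical(sum(reads$observed_allele == "ALT"), 0L)
})

test_that("molecule-count fast path matches the epsilon model in the mean", {
  # het mother / WT fetus, FF = 0.12: epsilon = 0.5 - 0.06 = 0.44
  set.seed(107)
  m <- simulate_molecule_counts(rep("ABaa", 200), 1000, delta = 0.06)
  expect_equal(mean(m) / 1000, 0.44, tolerance = 0.01 / 0.44)
})

test_that("SNP panel mixture fractions follow the plasma expectation", {
  set.seed(108)
  p <- sim_params(fetal_fraction = 0.10, base_error_rate = 0,
                  n_snps = 2000L, n_unique_molecules_mean = 1000,
                  n_unique_molecules_sd = 0,
                  n_unique_molecules_range = c(1000L, 1000L))
  snp <- simulate_snp_panel(simulate_trio(panel_sv, p), p)
  truth <- attr(snp, "truth")
  frac <- snp$alt_reads / snp$total_reads
  # maternal hom-REF / fetal het: alt fraction ~ FF/2
  sel <- truth$maternal_dose == 0 & truth$fetal_dose == 1
  expect_gt(sum(sel), 50)
  expect_equal(mean(frac[sel]), 0.05, tolerance = 0.05)
  # maternal het / fetal het: balanced
  sel2 <- truth$maternal_dose == 1 & truth$fetal_dose == 1
  expect_equal(mean(frac[sel2]), 0.50, tolerance = 0.01)
})

test_that("simulation parameters are validated", {
  expect_error(sim_params(fetal_fraction = 1.2),
               class = "csmart_parameter_error")
  expect_error(sim_params(base_error_rate = 0.5),
               class = "csmart_parameter_error")
  expect_error(sim_params(n_unique_molecules_range = c(0L, 10L)),
               class = "csmart_parameter_error")
  expect_error(sim_params(pcr_duplication_mean = 0.5),
               class = "csmart_parameter_error")
})
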