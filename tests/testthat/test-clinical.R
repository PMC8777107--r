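mk_call <- function(case, origin, code, qc = TRUE) {
  data.frame(case_id = case, locus_id = paste0("L_", origin),
             parental_origin = origin, genotype_code = code, qc_pass = qc,
             stringsAsFactors = FALSE)
}

test_that("per-locus codes combine into the clinical fetal status", {
  ch <- function(gm, gp, qc = c(TRUE, TRUE))
    combine_calls(rbind(mk_call("c1", "maternal", gm, qc[1]),
                        mk_call("c1", "paternal", gp, qc[2])), "compound_het")
  expect_identical(ch("ABaa", "AAaa")$fetal_status, "normal")
  expect_identical(ch("ABab", "AAaa")$fetal_status, "maternal_carrier")
  expect_identical(ch("ABaa", "AAab")$fetal_status, "paternal_carrier")
  expect_identical(ch("ABab", "AAab")$fetal_status, "affected_compound_het")
  expect_false(ch("ABab", "AAab", qc = c(TRUE, FALSE))$qc_pass)
  sv <- function(g) combine_calls(mk_call("c1", "shared", g), "same_variant")
  expect_identical(sv("ABaa")$fetal_status, "normal")
  expect_identical(sv("ABab")$fetal_status, "carrier")
  expect_identical(sv("ABbb")$fetal_status, "affected_homozygote")
  expect_true(is_affected("affected_homozygote"))
  expect_false(any(is_affected(c("normal", "carrier", "maternal_carrier"))))
})

test_that("codes impossible for the parental origin flag inconsistency", {
  # ABbb at a maternal-only variant: the father carries no mutant allele
  res <- combine_calls(rbind(mk_call("c1", "maternal", "ABbb"),
                             mk_call("c1", "paternal", "AAaa")),
                       "compound_het")
  expect_true(res$inconsistent)
  expect_true(is.na(res$fetal_status))
  # wild-type-mother code at a shared locus of a carrier couple
  res2 <- combine_calls(mk_call("c1", "shared", "AAab"), "same_variant")
  expect_true(res2$inconsistent)
})

test_that("combine_calls is total over the genotype-code space", {
  codes <- genotype_hypotheses()$code
  for (gm in codes) for (gp in codes) {
    res <- combine_calls(rbind(mk_call("c1", "maternal", gm),
                               mk_call("c1", "paternal", gp)),
                         "compound_het")
    expect_true(xor(res$inconsistent, !is.na(res$fetal_status)))
  }
  for (g in codes) {
    res <- combine_calls(mk_call("c1", "shared", g), "same_variant")
    expect_true(xor(res$inconsistent, !is.na(res$fetal_status)))
  }
  expect_error(combine_calls(mk_call("c1", "shared", "ABaa"), "compound_het"),
               class = "csmart_validation_error")
  expect_error(combine_calls(rbind(mk_call("c1", "maternal", "ABaa"),
                                   mk_call("c1", "paternal", "AAaa")),
                             "same_variant"),
               class = "csmart_validation_error")
})

test_that("exact intervals match the closed form and binom.test", {
  # all-success lower bound: 100 * (alpha/2)^(1/n), n = 1..100
  for (n in 1:100) {
    ci <- clopper_pearson(n, n)
    expect_equal(ci[["lower_pct"]], 100 * 0.025^(1 / n), tolerance = 1e-6)
    expect_identical(ci[["upper_pct"]], 100)
  }
  expect_equal(unname(clopper_pearson(0, 10)), c(0, 100 * (1 - 0.025^0.1)),
               tolerance = 1e-6)
  # independent route: stats::binom.test
  set.seed(501)
  for (i in 1:25) {
    n <- sample(1:200, 1); x <- sample(0:n, 1)
    want <- 100 * stats::binom.test(x, n)$conf.int
    expect_equal(unname(clopper_pearson(x, n)), as.numeric(want),
                 tolerance = 1e-8)
  }
  expect_error(clopper_pearson(1, 0), class = "csmart_validation_error")
})

test_that("the interval lower bound is monotone in the success count", {
  for (n in c(5, 29, 100)) {
    lows <- vapply(0:n, function(x) clopper_pearson(x, n)[["lower_pct"]],
                   numeric(1))
    expect_true(all(diff(lows) >= 0))
  }
})

test_that("cohort concordance counts QC removal and the affected split", {
  co <- mmachc_cohort()
  res <- do.call(rbind, lapply(split(co$calls, co$calls$case_id), function(cc)
    combine_calls(cc, cc$couple_type[1])))
  res <- merge(res, co$truth[, c("case_id", "ipd_status")], by = "case_id")
  raw <- concordance(res, apply_qc = FALSE)
  expect_identical(c(raw$n_concordant, raw$n_total), c(28L, 29L))
  expect_equal(raw$concordance_pct, 96.55)
  qc <- concordance(res, apply_qc = TRUE)
  expect_identical(c(qc$n_concordant, qc$n_total), c(27L, 27L))
  expect_equal(qc$concordance_pct, 100)
  expect_identical(qc$n_total, raw$n_total - qc$n_qc_failed_removed)
  expect_identical(c(qc$tp, qc$fn, qc$tn, qc$fp), c(6L, 0L, 21L, 0L))
  # fully discordant cohort
  bad <- data.frame(case_id = letters[1:5], fetal_status = "normal",
                    ipd_status = "carrier", qc_pass = TRUE)
  expect_equal(concordance(bad, apply_qc = FALSE)$concordance_pct, 0)
  expect_error(concordance(bad[0, ]), class = "csmart_empty_cohort_error")
  # inconsistent cases are excluded with a warning
  bad$inconsistent <- c(TRUE, rep(FALSE, 4))
  expect_warning(out <- concordance(bad), "inconsistent")
  expect_identical(out$n_total, 4L)
})

test_that("pooling the published study counts reproduces the meta-summary", {
  pooled <- pooled_summary(csmart_published_studies())
  expect_identical(c(pooled$n_concordant, pooled$n_total), c(279L, 291L))
  expect_equal(pooled$concordance_pct, 95.88)
  one <- pooled_summary(data.frame(case_n = 4L, concordant_n = 4L))
  expect_equal(one$concordance_pct, 100)
  two <- pooled_summary(data.frame(case_n = c(10L, 10L),
                                   concordant_n = c(5L, 5L)))
  expect_equal(two$concordance_pct, 50)
  expect_error(pooled_summary(data.frame(case_n = 2L, concordant_n = 3L)),
               class = "csmart_validation_error")
  expect_error(pooled_summary(data.frame(case_n = integer(0),
                                         concordant_n = integer(0))),
               class = "csmart_empty_cohort_error")
})

test_that("reported percentages round half away from zero", {
  expect_equal(round_half_up(20.685), 20.69)
  expect_equal(round_half_up(96.551724), 96.55)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
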