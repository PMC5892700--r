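test_that("group assignment reproduces the published worked examples", {
  th <- default_thresholds()
  # pathway-2 rows of the published table (OpFc / ObFc / FpFc)
  expect_equal(assign_group(6.89e-15, 1.21e-05, 2.83e-07, th), "HP")
  expect_equal(assign_group(1.09e-10, 7.13e-12, 9.13e-10, th), "HB")
  expect_equal(assign_group(1.34e-08, 3.03e-06, 3.77e-08, th), "M")
  # both omnibus tests genome-wide with a large Fisher gap
  expect_equal(assign_group(1.58e-12, 1.60e-08, 4.71e-05, th), "HP/HB")
  # no genome-wide test at all
  expect_equal(assign_group(1e-4, 1e-3, 1e-2, th), "none")
  expect_error(assign_group(NA, 0.1, 0.1, th), "missing")
})

test_that("group assignment reproduces the full published classification", {
  t2 <- load_table2_fixture()
  grp <- assign_group(p_op = t2$p_op, p_ob = t2$p_ob,
                      p_fisher = t2$p_fisher_comparator)
  expect_identical(grp, t2$group)
})

test_that("published group totals are reproduced", {
  t2 <- load_table2_fixture()
  grp <- assign_group(p_op = t2$p_op, p_ob = t2$p_ob,
                      p_fisher = t2$p_fisher_comparator)
  expect_equal(sum(grp %in% c("HP", "HB", "HP/HB")), 108L)
  expect_equal(as.integer(table(grp)[c("HP", "HB", "HP/HB", "M")]),
               c(81L, 5L, 22L, 7L))
  expect_equal(sum(t2$pathway == 1L), 29L)
  # the pathway-wise split of the antagonistic groups
  expect_equal(sum(grp == "HP" & t2$pathway == 1L), 27L)
  expect_equal(sum(grp == "HP" & t2$pathway == 2L), 54L)
})

test_that("validation rules follow the cross-cohort arithmetic", {
  th <- default_thresholds()
  # pathway 2: one genome-wide cohort plus one at the Bonferroni level
  expect_true(validate_snp(2, c(3e-9, 0.009, 0.5, 0.3, 0.7), 5, th))
  # one genome-wide cohort, nothing else below 0.05/4
  expect_false(validate_snp(2, c(3e-9, 0.013, 0.5, 0.3, 0.7), 5, th))
  # no genome-wide cohort: automatically validated
  expect_true(validate_snp(2, c(1e-4, 0.02, 0.5, 0.3, 0.7), 5, th))
  expect_error(validate_snp(2, c(3e-9), 1, th), "2 cohorts")
  # pathway 1: all univariate parts above the genome-wide level
  expect_true(validate_snp(1, c(1e-6, 1e-4, 0.3), thresholds = th))
  expect_false(validate_snp(1, c(1e-9, 1e-4, 0.3), thresholds = th))
})

test_that("antagonism replication counts cohorts by the 0.2-order rule", {
  th <- default_thresholds()
  pc <- data.frame(cohort = c("A", "B", "C"),
                   p_OpC = c(0.01, 0.04, 0.5),
                   p_ObC = c(0.5, 0.5, 0.5),
                   p_FpC = c(0.05, 0.05, 0.6))
  r <- replicate_antagonism(pc, th)
  # A: gap log10(0.05)-log10(0.01) = 0.699 >= 0.2, suggestive -> counts
  # B: gap 0.097 < 0.2 -> no; C: not suggestive -> no
  expect_equal(r$count, 1L)
  expect_false(r$replicated)
  expect_equal(r$cohorts, "A")
  pc2 <- rbind(pc, data.frame(cohort = "D", p_OpC = 0.002, p_ObC = 0.5,
                              p_FpC = 0.02))
  expect_true(replicate_antagonism(pc2, th)$replicated)
})

test_that("prior-evidence Fisher penalizes unreported phenotypes at 0.4", {
  pe <- prior_evidence_fisher(numeric(0), 20)
  expect_equal(pe$statistic, -2 * 20 * log(0.4), tolerance = 1e-12)
  expect_equal(pe$df, 40L)
  expect_equal(pe$p, 0.62, tolerance = 0.01)
  expect_true(pe$novel)
  # a single overwhelming prior association kills novelty via combination
  pe2 <- prior_evidence_fisher(1e-20, 20)
  expect_lt(pe2$p, 5e-8)
  expect_false(pe2$novel)
  # a reported univariate prior at genome-wide level kills novelty directly
  pe3 <- prior_evidence_fisher(4e-8, 20)
  expect_false(pe3$novel)
  expect_error(prior_evidence_fisher(c(0.5, 2), 20), "\\(0, 1\\]")
  expect_error(prior_evidence_fisher(runif(21), 20))
})

test_that("efficiency ratio recovers the published 4-fold figure", {
  expect_equal(efficiency_ratio(9.4e-14, 33431, 1.6e-14, 140059),
               3.956, tolerance = 1e-3)
  expect_equal(efficiency_ratio(0.01, 500, 0.01, 500), 1.0)
  expect_equal(efficiency_ratio(0.01, 500, 0.01, 1000), 2.0)
  expect_error(efficiency_ratio(1, 10, 0.5, 10), "inside")
})

test_that("classification of a simulated antagonistic SNP is antagonistic", {
  eff <- list(effect_config("rs_ant", 0.25, c(P1 = 0.4, P2 = -0.4),
                            "antagonistic"),
              effect_config("rs_ali", 0.25, c(P1 = 0.4, P2 = 0.4),
                            "aligned"))
  st <- quick_study(n_cohorts = 3, n = 1200, K = 2, rho = 0.6,
                    effects = eff, seed = 71, icc = 1)
  pl <- run_pleiotropy(st, domains = list(both = c("P1", "P2")),
                       R = 150, seed = 4)
  cl <- classify_snps(pl)
  ant <- cl[cl$snp_id == "rs_ant", ]
  expect_true(ant$antagonistic)
  # equal-magnitude aligned effects never qualify through the ratio rule
  ali <- cl[cl$snp_id == "rs_ali", ]
  expect_false(ali$group %in% c("HP", "HB", "HP/HB"))
  # novelty wiring: flat prior table marks the SNP novel
  cl2 <- classify_snps(pl, prior_evidence = data.frame(
    snp_id = "rs_ant", phenotype = "P1", p = 0.2))
  expect_true(cl2$novel[cl2$snp_id == "rs_ant"])
})
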