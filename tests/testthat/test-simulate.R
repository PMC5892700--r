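test_that("phenotype correlation matrices are valid and honour the dialects", {
  expect_equal(make_phenotype_correlation(2, 0, method = "fixed"), diag(2))
  S <- make_phenotype_correlation(2, 0.6, method = "fixed")
  expect_equal(S[1, 2], 0.6)
  for (seed in 1:5) {
    S <- make_phenotype_correlation(20, 0.5, seed = seed, method = "random")
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_equal(diag(S), rep(1, 20))
    expect_lte(max(abs(S[upper.tri(S)])), 0.5 + 1e-12)
    expect_equal(S, t(S))
  }
})

test_that("genotype dosages follow Hardy-Weinberg proportions", {
  expect_error(simulate_genotypes(10, 0), "maf")
  expect_error(simulate_genotypes(10, 0.7), "maf")
  g <- simulate_genotypes(10000, 0.5, seed = 1)
  expect_true(abs(mean(g) / 2 - 0.5) < 0.02)
  expect_identical(simulate_genotypes(4, 0.25, seed = 7),
                   simulate_genotypes(4, 0.25, seed = 7))
  g <- simulate_genotypes(100000, 0.25, seed = 3)
  props <- tabulate(g + 1L, 3L) / length(g)
  expect_equal(props, c(0.5625, 0.375, 0.0625), tolerance = 0.02)
})

test_that("simulated cohorts reproduce the target phenotype correlation", {
  # icc = 1 removes measurement noise, so subject values carry the latent
  # correlation directly
  st <- quick_study(n_cohorts = 1, n = 10000, K = 4, rho = 0.4, icc = 1,
                    seed = 5)
  M <- phenotype_matrix(st$cohorts[[1]])
  C <- cor(M)
  expect_lt(max(abs(C[upper.tri(C)] - 0.4)), 0.03)
})

test_that("visit-level noise attenuates measured correlation as rho * icc", {
  st <- quick_study(n_cohorts = 1, n = 20000, K = 2, rho = 0.6, icc = 0.5,
                    seed = 6)
  M <- phenotype_matrix(st$cohorts[[1]])
  # covariate effects shared across phenotypes add a small common component
  X <- cbind(1, as.matrix(st$cohorts[[1]]$covariates))
  R <- qr.resid(qr(X), M)
  expect_lt(abs(cor(R)[1, 2] - 0.6 * 0.5), 0.03)
})

test_that("null SNPs give uniform stage-1 p-values and no phantom effects", {
  st <- quick_study(n_cohorts = 1, n = 2000, K = 1, seed = 9)
  cd <- st$cohorts[[1]]
  g <- cd$dosage[, "rs_null"]
  y <- phenotype_matrix(cd)[, 1]
  expect_lt(abs(cor(g, y)), 3 / sqrt(length(y)))
  # p-value uniformity over a battery of independent null SNPs
  effs <- lapply(seq_len(1000), function(i)
    effect_config(sprintf("s%04d", i), 0.3, pattern = "null"))
  st <- quick_study(n_cohorts = 1, n = 500, K = 1, effects = effs, seed = 21)
  cd <- st$cohorts[[1]]
  fit <- batch_quant_assoc(cd$dosage, phenotype_matrix(cd), cd$covariates)
  ks <- ks.test(10^fit$log10_p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("injected antagonistic effects surface as opposite-sign z-scores", {
  eff <- list(effect_config("rs_a", 0.3, c(P1 = 0.3, P2 = -0.3),
                            "antagonistic"))
  st <- quick_study(n_cohorts = 1, n = 5000, K = 2, rho = 0.6,
                    effects = eff, seed = 31)
  cd <- st$cohorts[[1]]
  fit <- batch_quant_assoc(cd$dosage, phenotype_matrix(cd), cd$covariates)
  expect_gt(fit$z["rs_a", "P1"], 2)
  expect_lt(fit$z["rs_a", "P2"], -2)
})

test_that("study simulation is deterministic and respects cohort structure", {
  a <- quick_study(seed = 17)
  b <- quick_study(seed = 17)
  expect_identical(a$cohorts[[1]]$dosage, b$cohorts[[1]]$dosage)
  expect_identical(a$cohorts[[2]]$quant, b$cohorts[[2]]$quant)
  # duplicate cohort names rejected
  ph <- study_phenotypes()
  cs <- list(cohort_spec("X", 60, names(ph)), cohort_spec("X", 60, names(ph)))
  expect_error(simulate_study(cs, effects = list(
    effect_config("rs1", 0.3, pattern = "null"))), "duplicate")
})

test_that("default study design matches the published cohort structure", {
  cs <- study_cohorts()
  expect_equal(sum(vapply(cs, `[[`, 0L, "n_subjects")), 33431L)
  expect_length(study_phenotypes(), 20L)
  # per-cohort phenotype gaps carried into the simulated data
  small <- study_cohorts(scale = 0.02)
  st <- simulate_study(small["HRS"], effects = list(
    effect_config("rs1", 0.3, pattern = "null")), seed = 3)
  expect_length(st$cohorts$HRS$phenotypes,
                length(small$HRS$phenotype_subset))
  expect_equal(ncol(phenotype_matrix(st$cohorts$HRS)),
               length(small$HRS$phenotype_subset))
})

test_that("phenotype and effect specifications enforce their invariants", {
  expect_error(phenotype_spec("x", "binary", "marker"), "marker")
  expect_error(phenotype_spec("x", "binary", "outcome", n_visits = 3),
               "n_visits")
  expect_error(effect_config("s", 0.3, c(P1 = 0.1), pattern = "null"),
               "null")
  expect_error(effect_config("s", 0.3, c(P1 = 0.1, P2 = 0.2),
                             pattern = "antagonistic"), "both signs")
  expect_warning(effect_config("s", 0.01, pattern = "null"), "MAF")
  expect_error(cohort_spec("c", 10, "P1"))
})
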