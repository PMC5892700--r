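test_that("fixed-effects pooling matches hand arithmetic", {
  m <- fixed_effects_meta(0.5, 0.1)
  expect_equal(m$beta_meta, 0.5)
  expect_equal(m$se_meta, 0.1)

  m <- fixed_effects_meta(c(0.2, 0.4), c(0.1, 0.2))
  expect_equal(unname(m$weights), c(100, 25))
  expect_equal(m$beta_meta, 0.24, tolerance = 1e-12)
  expect_equal(m$se_meta, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(m$z, 0.24 * sqrt(125), tolerance = 1e-12)
  expect_equal(m$p_meta, 2 * pnorm(-0.24 * sqrt(125)), tolerance = 1e-12)

  m <- fixed_effects_meta(c(0.3, -0.3), c(0.07, 0.07))
  expect_equal(m$beta_meta, 0)
  expect_equal(m$p_meta, 1)

  expect_error(fixed_effects_meta(c(0.1, 0.2), c(0.1, 0), c("A", "B")), "B")
})

test_that("fixed-effects pooling is order invariant and bounded by inputs", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    b <- rnorm(k)
    s <- runif(k, 0.05, 0.5)
    m1 <- fixed_effects_meta(b, s)
    o <- sample(k)
    m2 <- fixed_effects_meta(b[o], s[o])
    expect_equal(m1$beta_meta, m2$beta_meta, tolerance = 1e-12)
    expect_gte(m1$beta_meta, min(b) - 1e-12)
    expect_lte(m1$beta_meta, max(b) + 1e-12)
  }
  # equal standard errors reduce to the arithmetic mean
  m <- fixed_effects_meta(c(0.1, 0.2, 0.6), rep(0.2, 3))
  expect_equal(m$beta_meta, mean(c(0.1, 0.2, 0.6)), tolerance = 1e-12)
})

test_that("Fisher combination matches the chi-square oracle and identities", {
  expect_equal(fisher_combine(c(1, 1, 1))$p, 1)
  expect_equal(fisher_combine(0.05)$p, 0.05, tolerance = 1e-12)  # df=2
  fc <- fisher_combine(c(0.01, 0.04))
  expect_equal(fc$statistic, 15.64812, tolerance = 1e-4)
  expect_equal(fc$df, 4L)
  expect_equal(fc$p, pchisq(-2 * log(0.01 * 0.04), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 1.2)), "above 1")
  expect_warning(fc0 <- fisher_combine(c(0, 0.5)), "clipped")
  expect_true(is.finite(fc0$statistic))
})

test_that("Fisher combination is order invariant and monotone", {
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    expect_equal(fisher_combine(p)$p, fisher_combine(rev(p))$p,
                 tolerance = 1e-14)
    p2 <- p
    p2[1] <- p2[1] / 2
    expect_lte(fisher_combine(p2)$p, fisher_combine(p)$p)
  }
})

test_that("heterogeneity Q and I2 match hand arithmetic and bounds", {
  expect_error(heterogeneity_I2(0.2, 0.1), "single")
  h <- heterogeneity_I2(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.05))
  expect_equal(h$Q, 0)
  expect_equal(h$I2, 0)
  h <- heterogeneity_I2(c(0.2, 0.4), c(0.1, 0.2))
  expect_equal(h$Q, 0.8, tolerance = 1e-12)
  expect_equal(h$I2, 0)                       # Q below df truncates to zero
  h <- heterogeneity_I2(c(0.0, 0.5), c(0.1, 0.1))
  expect_equal(h$Q, 12.5, tolerance = 1e-12)
  expect_equal(h$I2, 92, tolerance = 1e-12)
  # I2 grows as one effect moves away (fixed ses) and stays in [0, 100]
  prev <- -1
  for (d in seq(0, 1, by = 0.2)) {
    i2 <- heterogeneity_I2(c(0.2, 0.2 + d), c(0.1, 0.1))$I2
    expect_gte(i2, prev)
    expect_gte(i2, 0)
    expect_lte(i2, 100)
    prev <- i2
  }
})

test_that("allele harmonization flips, flags ambiguity, excludes mismatches", {
  base <- data.frame(
    snp_id = "rs1", phenotype = "P", cohort = c("C1", "C2", "C3"),
    effect_allele = c("A", "G", "A"), other_allele = c("G", "A", "C"),
    eaf = c(0.3, 0.7, 0.3), beta = c(0.2, 0.3, 0.1),
    se = 0.1, z = c(2, 3, 1), p = 0.05, n = 100)
  h <- harmonize_alleles(base)
  expect_equal(nrow(h), 2L)                      # A/C record irreconcilable
  expect_equal(h$beta[h$cohort == "C2"], -0.3)   # flipped to A/G
  expect_equal(h$eaf[h$cohort == "C2"], 0.3)
  expect_false(any(h$ambiguous))
  expect_match(attr(h, "harmonization_log"), "C3")
  # concordant records pass through unchanged
  conc <- base[c(1, 1), ]
  conc$cohort <- c("C1", "C2")
  expect_equal(harmonize_alleles(conc)$beta, c(0.2, 0.2))
  # strand-ambiguous A/T pair flagged
  amb <- base[1, ]
  amb$other_allele <- "T"
  expect_true(all(harmonize_alleles(amb)$ambiguous))
})

test_that("univariate meta table combines cohorts per SNP and phenotype", {
  s1 <- data.frame(
    snp_id = "rs1", phenotype = c("P1", "P1", "P2"),
    cohort = c("C1", "C2", "C1"),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = c(0.2, 0.4, 0.1), se = c(0.1, 0.2, 0.1), n = 100)
  s1$z <- s1$beta / s1$se
  s1$p <- 2 * pnorm(-abs(s1$z))
  mt <- meta_analyse(s1)
  r1 <- mt[mt$phenotype == "P1", ]
  expect_equal(r1$beta_meta, 0.24, tolerance = 1e-12)
  expect_equal(r1$n_cohorts, 2L)
  r2 <- mt[mt$phenotype == "P2", ]
  expect_equal(r2$beta_meta, 0.1)           # single cohort is the identity
  expect_true(is.na(r2$I2))                 # heterogeneity undefined, not 0
  expect_equal(r2$p_fisher_cohorts, r2$p_meta, tolerance = 1e-12)  # df=2
})
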