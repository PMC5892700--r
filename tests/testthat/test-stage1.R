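test_that("single-visit quantitative fit equals ordinary least squares", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- c(0, 0, 1, 1, 2, 2)
  st <- fit_quantitative(g, y, min_n = 3)
  # closed-form OLS: slope = Sxy / Sxx = 8 / 4
  expect_equal(st$beta, 2.0, tolerance = 1e-12)
  ref <- summary(lm(y ~ g))$coefficients
  expect_equal(st$beta, ref["g", 1], tolerance = 1e-12)
  expect_equal(st$se, ref["g", 2], tolerance = 1e-12)
  # with covariates, still OLS to machine precision
  set.seed(2)
  n <- 120
  g <- rbinom(n, 2, 0.3)
  age <- rnorm(n, 60, 8)
  yy <- 0.2 * g + 0.05 * age + rnorm(n)
  st <- fit_quantitative(g, yy, data.frame(age = age))
  ref <- summary(lm(yy ~ g + age))$coefficients
  expect_equal(st$beta, ref["g", 1], tolerance = 1e-10)
  expect_equal(st$se, ref["g", 2], tolerance = 1e-10)
})

test_that("random-intercept fit agrees with REML on repeated measures", {
  skip_if_not_installed("lme4")
  set.seed(4)
  n <- 400
  g <- rbinom(n, 2, 0.3)
  b_i <- rnorm(n)
  Y <- b_i + 0.25 * g + matrix(rnorm(n * 3), n, 3)
  st <- fit_quantitative(g, Y)
  long <- data.frame(y = as.vector(Y), g = rep(g, 3),
                     id = rep(seq_len(n), 3))
  ref <- lme4::lmer(y ~ g + (1 | id), data = long, REML = TRUE)
  cf <- summary(ref)$coefficients
  expect_equal(st$beta, cf["g", 1], tolerance = 0.02)
  expect_equal(st$se, cf["g", 2], tolerance = 0.05)
  # balanced design, no covariates: subject-mean OLS is also fully efficient
  sm <- fit_quantitative(g, Y, method = "subject_mean")
  expect_equal(st$beta, sm$beta, tolerance = 1e-6)
})

test_that("log-transform scales by 100*log and rejects non-positive values", {
  set.seed(5)
  n <- 200
  g <- rbinom(n, 2, 0.4)
  x <- 0.3 * g + rnorm(n)
  st_direct <- fit_quantitative(g, x)
  st_log <- fit_quantitative(g, exp(x / 100), log_transform = TRUE)
  expect_equal(st_log$beta, st_direct$beta, tolerance = 1e-8)
  bad <- exp(x / 100)
  bad[7] <- -1
  expect_error(fit_quantitative(g, bad, log_transform = TRUE), "7")
})

test_that("every emitted record satisfies z * se = beta and p matches z", {
  st <- quick_study(n_cohorts = 2, n = 300, K = 3,
                    effects = list(effect_config("rs1", 0.3,
                                                 c(P1 = 0.2), "custom")),
                    seed = 41)
  s1 <- do.call(rbind, lapply(st$cohorts, cohort_stage1))
  expect_true(all(abs(s1$z * s1$se - s1$beta) < 1e-9))
  expect_true(all(abs(s1$p - 2 * pnorm(-abs(s1$z))) < 1e-9))
  expect_true(all(s1$se > 0))
})

test_that("logistic fit reproduces the contingency-table odds ratio", {
  g <- rep(c(1, 0), c(100, 100))
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  st <- fit_binary(g, y)
  expect_equal(st$beta, log(30 * 90 / (70 * 10)), tolerance = 1e-6)
  # monomorphic dosage flagged, degenerate outcome rejected
  expect_equal(fit_binary(rep(1, 200), y)$status, "monomorphic")
  expect_error(fit_binary(g, rep(1, 200)), "classes")
  expect_error(fit_binary(g, c(rep(1, 5), rep(0, 195))), "events")
})

test_that("logistic null calibration keeps extreme z-scores rare", {
  set.seed(6)
  zs <- replicate(40, {
    g <- rbinom(2000, 2, 0.3)
    y <- rbinom(2000, 1, 0.2)
    fit_binary(g, y)$z
  })
  expect_true(all(abs(zs) < 4))
})

test_that("Cox fit matches the brute-force partial likelihood on toys", {
  set.seed(7)
  for (rep in 1:3) {
    n <- 18
    g <- rbinom(n, 2, 0.4)
    if (var(g) == 0) next
    tm <- rexp(n, 0.1 * exp(0.4 * g))
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) < 2) next
    st <- fit_survival(g, tm, ev, min_events = 1)
    expect_equal(st$beta, breslow_mle(tm, ev, g), tolerance = 1e-4)
  }
})

test_that("Cox fit recovers a known hazard ratio and rejects no-event data", {
  set.seed(8)
  hits <- replicate(30, {
    g <- rbinom(2000, 1, 0.5)
    tm <- rexp(2000, 0.05 * 2^g)
    cens <- quantile(tm, 0.5)
    ev <- as.integer(tm <= cens)
    st <- fit_survival(g, pmin(tm, cens) + 1e-9, ev)
    abs(st$beta - log(2)) < 2 * st$se
  })
  expect_gte(mean(hits), 0.8)
  expect_error(fit_survival(rbinom(50, 2, 0.3), rexp(50, 1) + 1,
                            rep(0, 50)), "events")
  expect_error(fit_survival(rbinom(50, 2, 0.3), rexp(50, 1) + 1,
                            c(1, rep(0, 49))), "events")
})

test_that("prioritization combines nominal hits and ranks as specified", {
  s1 <- data.frame(
    snp_id = c("a", "a", "a", "b", "b", "c"),
    phenotype = "P", cohort = c("C1", "C2", "C3", "C1", "C2", "C1"),
    p = c(0.01, 0.04, 0.5, 0.2, 0.6, 0.03))
  pr <- prioritize(s1, top_n = 2)
  ra <- pr[pr$snp_id == "a", ]
  expect_equal(ra$fisher_statistic, -2 * (log(0.01) + log(0.04)),
               tolerance = 1e-9)
  expect_equal(ra$df, 4L)
  rb <- pr[pr$snp_id == "b", ]
  expect_equal(rb$p_prioritize, 1)
  expect_equal(rb$rank, 3L)           # no nominal hit ranks last
  expect_equal(sum(pr$selected), 2L)
  # selection size is honoured exactly on a larger panel
  s2 <- data.frame(snp_id = sprintf("s%03d", 1:150), phenotype = "P",
                   cohort = "C1", p = runif(150))
  expect_equal(sum(prioritize(s2, top_n = 100)$selected), 100L)
})
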