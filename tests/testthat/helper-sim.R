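# Shared fixtures built in code.

# small K-phenotype quantitative study: `n_cohorts` equal cohorts, fixed
# exchangeable phenotype correlation, one SNP per effect configuration
quick_study <- function(n_cohorts = 2, n = 400, K = 3, rho = 0.3,
                        effects = list(effect_config("rs_null", 0.3,
                                                     pattern = "null")),
                        seed = 11, n_visits = 1, icc = 0.5, ...) {
  ph <- lapply(paste0("P", seq_len(K)), phenotype_spec,
               kind = "quantitative", domain_tag = "marker",
               n_visits = n_visits)
  names(ph) <- paste0("P", seq_len(K))
  S <- if (K == 1) matrix(1, 1, 1)
       else make_phenotype_correlation(K, rho, method = "fixed")
  dimnames(S) <- list(names(ph), names(ph))
  cs <- lapply(seq_len(n_cohorts), function(i)
    cohort_spec(paste0("C", i), n, names(ph)))
  simulate_study(cs, ph, S, effects, seed = seed, icc = icc, ...)
}

# independent brute-force Breslow partial likelihood (used as the Cox
# oracle on tiny datasets): returns the log partial likelihood at beta
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force maximizer of the Breslow partial likelihood
breslow_mle <- function(time, event, x, lower = -5, upper = 5) {
  optimize(function(b) breslow_loglik(b, time, event, x),
           c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}
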