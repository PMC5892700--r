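#' Random weak-to-modest phenotype correlation matrix
#'
#' Builds a K x K positive-definite correlation matrix whose off-diagonal
#' magnitudes do not exceed `strength`. Two dialects: `"fixed"` sets every
#' off-diagonal entry to `strength` (exchangeable structure), `"random"`
#' draws entries uniformly in `[-strength, strength]` and repairs any
#' non-positive-definite draw by shrinking towards the identity.
#'
#' @param K number of phenotypes (>= 2).
#' @param strength maximum off-diagonal magnitude, in `[0, 1)`.
#' @param seed integer seed (used by the `"random"` dialect).
#' @param method `"fixed"` or `"random"`.
#' @return K x K correlation matrix (symmetric, unit diagonal, PD).
#' @export
make_phenotype_correlation <- function(K, strength = 0.3, seed = 1L,
                                       method = c("fixed", "random")) {
  method <- match.arg(method)
  stopifnot(K >= 2, strength >= 0, strength < 1)
  if (method == "fixed") {
    S <- matrix(strength, K, K)
    diag(S) <- 1
    return(S)
  }
  set.seed(seed)
  S <- matrix(0, K, K)
  S[upper.tri(S)] <- runif(K * (K - 1) / 2, -strength, strength)
  S <- S + t(S)
  diag(S) <- 1
  # shrink towards identity until positive definite with a safe margin
  lam <- 0
  while (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
    lam <- lam + 0.05
    S <- (1 - lam) * S + lam * diag(K)
    diag(S) <- 1
  }
  S
}

#' Hardy-Weinberg genotype dosages
#'
#' Draws additive-model allele dosages as Binomial(2, maf) per subject.
#'
#' @param n number of subjects.
#' @param maf effect-allele frequency in `(0, 0.5]`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return integer vector of dosages in `{0, 1, 2}`.
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || maf <= 0 || maf > 0.5)
    stop("maf must lie in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  rbinom(n, 2L, maf)
}

# covariate effects on the latent trait index, in SD units
.cov_effects <- function(age, sex, age_mean) {
  0.02 * (age - age_mean) + 0.1 * sex
}

#' Simulate one cohort's individual-level data
#'
#' Subjects get a latent multivariate-normal trait vector with the study
#' phenotype correlation (Gaussian copula over mixed phenotype types), plus
#' additive genetic effects in SD units, age and sex effects. Quantitative
#' phenotypes add independent visit-level noise with intraclass correlation
#' `icc`; log-transformed markers are stored as `exp(x / 100)` so that the
#' analysis transform `100 * log(y)` recovers the linear-scale signal.
#' Time-to-event outcomes use an exponential hazard from age 30 scaled by
#' `exp(latent_loading * latent + beta * dosage)`, administratively censored
#' at `censor_age`; the stored binary indicator is the event indicator.
#'
#' @param cohort a [cohort_spec()].
#' @param phenos named list of [phenotype_spec()] covering the full study
#'   phenotype list.
#' @param pheno_corr correlation matrix over the full phenotype list (row
#'   and column order = `names(phenos)`).
#' @param effects list of [effect_config()] (one per SNP).
#' @param seed integer seed (defaults to the cohort's own seed).
#' @param icc intraclass correlation of repeated quantitative measurements.
#' @param censor_age administrative censoring age in years.
#' @param base_hazard baseline event hazard per year from age 30.
#' @param latent_loading loading of the latent trait on binary/event risk.
#' @return a `cohort_data` list: `name`, `phenotypes` (specs measured here),
#'   `covariates` (data.frame: age, sex), `dosage` (n x SNP matrix),
#'   `snp_info` (snp_id, effect_allele, other_allele, maf), `quant` (named
#'   list of n x visits matrices), `events` (named list of data.frames with
#'   `event`, `age`).
#' @export
simulate_cohort <- function(cohort, phenos, pheno_corr, effects,
                            seed = cohort$seed, icc = 0.5, censor_age = 85,
                            base_hazard = 0.012, latent_loading = 0.3) {
  stopifnot(inherits(cohort, "cohort_spec"))
  K <- length(phenos)
  if (!all(cohort$phenotype_subset %in% names(phenos)))
    stop("cohort '", cohort$name, "' lists unknown phenotype(s): ",
         paste(setdiff(cohort$phenotype_subset, names(phenos)), collapse = ", "))
  if (!is.matrix(pheno_corr) || nrow(pheno_corr) != K || ncol(pheno_corr) != K)
    stop("pheno_corr must be ", K, " x ", K, " to match the phenotype list (",
         paste(names(phenos)[seq_len(min(3, K))], collapse = ", "), ", ...)")
  if (is.null(seed)) stop("no seed for cohort '", cohort$name, "'")
  set.seed(seed)

  n <- cohort$n_subjects
  age <- rnorm(n, cohort$age_mean, cohort$age_sd)
  sex <- rbinom(n, 1L, 0.5)
  L <- matrix(rnorm(n * K), n, K) %*% chol(pheno_corr)
  colnames(L) <- names(phenos)

  dosage <- sapply(effects, function(e) rbinom(n, 2L, e$maf))
  if (length(effects) == 1L) dosage <- matrix(dosage, ncol = 1L)
  snp_ids <- vapply(effects, `[[`, "", "snp_id")
  colnames(dosage) <- snp_ids
  snp_info <- data.frame(snp_id = snp_ids, effect_allele = "A",
                         other_allele = "G",
                         maf = vapply(effects, `[[`, 0, "maf"),
                         row.names = NULL)

  # total genetic contribution to each phenotype, cohort multiplier applied
  gshift <- matrix(0, n, K, dimnames = list(NULL, names(phenos)))
  for (e in effects) {
    m <- e$cohort_multipliers
    mult <- if (cohort$name %in% names(m)) m[[cohort$name]] else 1
    b <- e$beta[e$beta != 0]
    for (ph in names(b))
      gshift[, ph] <- gshift[, ph] + b[[ph]] * mult * dosage[, e$snp_id]
  }
  covef <- .cov_effects(age, sex, cohort$age_mean)

  quant <- list()
  events <- list()
  sd_e <- sqrt(1 / icc - 1)
  for (ph in cohort$phenotype_subset) {
    sp <- phenos[[ph]]
    idx <- L[, ph] + gshift[, ph] + covef
    if (sp$kind == "quantitative") {
      V <- sp$n_visits
      y <- idx + matrix(rnorm(n * V, sd = sd_e), n, V)
      if (sp$log_transform) y <- exp(y / 100)
      quant[[ph]] <- y
    } else if (sp$kind == "binary") {
      # logistic liability: injected beta is the log-odds ratio
      eta <- qlogis(0.15) + latent_loading * L[, ph] + gshift[, ph] + covef
      events[[ph]] <- data.frame(
        event = rbinom(n, 1L, plogis(eta)), age = age)
    } else {
      rate <- base_hazard *
        exp(latent_loading * L[, ph] + gshift[, ph] + covef)
      onset <- 30 + rexp(n, rate)
      events[[ph]] <- data.frame(event = as.integer(onset <= censor_age),
                                 age = pmin(onset, censor_age))
    }
  }

  structure(list(name = cohort$name,
                 phenotypes = phenos[cohort$phenotype_subset],
                 covariates = data.frame(age = age, sex = sex),
                 dosage = dosage, snp_info = snp_info,
                 quant = quant, events = events),
            class = "cohort_data")
}

#' Simulate a multi-cohort study
#'
#' One independent dataset per cohort, sharing the SNP panel and phenotype
#' definitions; each cohort only carries the phenotypes in its subset. All
#' randomness flows deterministically from `seed` (cohorts without their own
#' seed get one derived from it).
#'
#' @param cohorts named list of [cohort_spec()]; duplicate names rejected.
#' @param phenos named list of [phenotype_spec()].
#' @param pheno_corr full-phenotype correlation matrix.
#' @param effects list of [effect_config()].
#' @param seed study-level integer seed.
#' @param ... passed to [simulate_cohort()].
#' @return a `pleio_study` list: `cohorts` (named list of `cohort_data`),
#'   `phenotypes`, `pheno_corr`, `effects`, `snp_info`.
#' @export
simulate_study <- function(cohorts, phenos = study_phenotypes(),
                           pheno_corr = make_phenotype_correlation(length(phenos)),
                           effects, seed = 1L, ...) {
  stopifnot(length(cohorts) >= 1L)
  nm <- vapply(cohorts, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate cohort names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  datasets <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    sp <- cohorts[[i]]
    if (is.null(sp$seed)) sp$seed <- .derive_seed(seed, i)
    datasets[[i]] <- simulate_cohort(sp, phenos, pheno_corr, effects, ...)
  }
  names(datasets) <- nm
  structure(list(cohorts = datasets, phenotypes = phenos,
                 pheno_corr = pheno_corr, effects = effects,
                 snp_info = datasets[[1L]]$snp_info),
            class = "pleio_study")
}

#' Per-subject analysis-scale phenotype matrix
#'
#' Quantitative phenotypes averaged over visits on the analysis scale
#' (`100 * log` for log-scale markers); binary / time-to-event outcomes as
#' 0/1 event indicators. This is the matrix behind the phenotype-based
#' correlation matrix and the fast association routines.
#'
#' @param cohort_data a `cohort_data` object.
#' @param phenotypes optional character vector restricting/ordering columns.
#' @return n x K numeric matrix (NA where a phenotype is missing).
#' @export
phenotype_matrix <- function(cohort_data, phenotypes = NULL) {
  if (is.null(phenotypes)) phenotypes <- names(cohort_data$phenotypes)
  n <- nrow(cohort_data$covariates)
  out <- matrix(NA_real_, n, length(phenotypes),
                dimnames = list(NULL, phenotypes))
  for (ph in phenotypes) {
    sp <- cohort_data$phenotypes[[ph]]
    if (is.null(sp)) next
    if (sp$kind == "quantitative") {
      y <- cohort_data$quant[[ph]]
      if (sp$log_transform) y <- 100 * log(y)
      out[, ph] <- rowMeans(y, na.rm = TRUE)
    } else {
      out[, ph] <- cohort_data$events[[ph]]$event
    }
  }
  out
}
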