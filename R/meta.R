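# Stage-2 primitive meta-tests: fixed-effects inverse-variance pooling,
# Fisher p-value combination, Cochran's Q / I-squared heterogeneity.

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort effect sizes with weights `w_j = 1 / se_j^2`:
#' pooled effect `sum(w * beta) / sum(w)` with variance `1 / sum(w)`,
#' two-sided Wald p-value. Also reports Cochran's Q and I-squared when at
#' least two cohorts contribute.
#'
#' @param beta per-cohort effect sizes (alleles already harmonized).
#' @param se per-cohort standard errors (all > 0).
#' @param labels optional cohort names (used in error messages).
#' @return list: `beta_meta`, `se_meta`, `z`, `p_meta`, `log10_p`, `weights`,
#'   `Q`, `I2` (percent, `NA` for a single cohort), `n_cohorts`.
#' @export
fixed_effects_meta <- function(beta, se, labels = NULL) {
  stopifnot(length(beta) == length(se), length(beta) >= 1L)
  if (any(!is.finite(se)) || any(se <= 0)) {
    bad <- which(!is.finite(se) | se <= 0)
    lab <- if (is.null(labels)) paste0("#", bad) else labels[bad]
    stop("non-positive standard error for cohort(s): ",
         paste(lab, collapse = ", "))
  }
  w <- 1 / se^2
  beta_meta <- sum(w * beta) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  z <- beta_meta / se_meta
  het <- if (length(beta) >= 2L) heterogeneity_I2(beta, se)
         else list(Q = NA_real_, I2 = NA_real_)
  l10 <- .log10p_z(z)
  list(beta_meta = beta_meta, se_meta = se_meta, z = z,
       p_meta = .p_from_log10(l10), log10_p = l10, weights = w,
       Q = het$Q, I2 = het$I2, n_cohorts = length(beta))
}

#' Fisher's p-value combination
#'
#' Statistic `-2 * sum(log(p))` referred to a chi-square with `2 m` degrees
#' of freedom. Assumes independent tests; under positive dependence the
#' combined p-value is anticonservative, which is exactly the contrast the
#' omnibus tests exploit. Exact zero p-values are clipped to 1e-300 with a
#' warning; p-values above 1 are rejected. For p-values beyond double
#' underflow, supply `log10_p` and leave `p = NULL`.
#'
#' @param p numeric p-values in `(0, 1]` (or `NULL` when `log10_p` given).
#' @param log10_p optional exact log10 p-values (overrides `p`).
#' @return list: `statistic`, `df` (= 2 m), `p`, `log10_p`.
#' @export
fisher_combine <- function(p = NULL, log10_p = NULL) {
  if (is.null(log10_p)) {
    stopifnot(length(p) >= 1L)
    if (any(p > 1)) stop("p-values above 1")
    if (any(p < 0)) stop("negative p-values")
    log10_p <- log10(.clip_p(p))
  }
  stopifnot(length(log10_p) >= 1L, all(is.finite(log10_p)), all(log10_p <= 0))
  m <- length(log10_p)
  stat <- -2 * log(10) * sum(log10_p)
  l10 <- .log10p_chisq(stat, 2L * m)
  list(statistic = stat, df = 2L * m, p = .p_from_log10(l10), log10_p = l10)
}

#' Cochran's Q and the I-squared heterogeneity coefficient
#'
#' `Q = sum(w_j * (beta_j - beta_meta)^2)` with inverse-variance weights;
#' `I2 = max(0, (Q - (k - 1)) / Q) * 100`, the percentage of total effect-
#' size variability due to between-cohort variability (truncated at 0).
#'
#' @param beta,se per-cohort effects and standard errors (k >= 2).
#' @return list: `Q`, `df` (= k - 1), `I2` (percent).
#' @export
heterogeneity_I2 <- function(beta, se) {
  if (length(beta) < 2L)
    stop("heterogeneity is undefined for a single cohort")
  stopifnot(length(beta) == length(se), all(se > 0))
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bm)^2)
  k <- length(beta)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  list(Q = Q, df = k - 1L, I2 = I2)
}

#' Harmonize effect alleles across cohorts
#'
#' Within each SNP, records are flipped (`beta -> -beta`, `z -> -z`,
#' `eaf -> 1 - eaf`, alleles swapped) so that every cohort reports the
#' effect for the first record's effect allele. Strand-ambiguous A/T and
#' C/G SNPs are flagged in an `ambiguous` column; records whose allele pair
#' cannot be reconciled with the reference pair are excluded, with the
#' exclusions recorded in the `"harmonization_log"` attribute.
#'
#' @param stage1 stage-1 summary-statistics data.frame.
#' @return harmonized data.frame (possibly fewer rows) with an added
#'   `ambiguous` column and a `"harmonization_log"` attribute.
#' @export
harmonize_alleles <- function(stage1) {
  amb_pairs <- c("A/T", "T/A", "C/G", "G/C")
  log_entries <- character(0)
  parts <- split(stage1, stage1$snp_id)
  out <- lapply(parts, function(d) {
    ref_ea <- d$effect_allele[1L]
    ref_oa <- d$other_allele[1L]
    keep <- rep(TRUE, nrow(d))
    for (i in seq_len(nrow(d))) {
      if (d$effect_allele[i] == ref_ea && d$other_allele[i] == ref_oa) next
      if (d$effect_allele[i] == ref_oa && d$other_allele[i] == ref_ea) {
        d$beta[i] <- -d$beta[i]
        d$z[i] <- -d$z[i]
        d$eaf[i] <- 1 - d$eaf[i]
        d$effect_allele[i] <- ref_ea
        d$other_allele[i] <- ref_oa
      } else {
        keep[i] <- FALSE
        log_entries <<- c(log_entries, paste0(
          d$snp_id[i], " [", d$cohort[i], "]: alleles ", d$effect_allele[i],
          "/", d$other_allele[i], " irreconcilable with ", ref_ea, "/", ref_oa))
      }
    }
    d$ambiguous <- paste0(ref_ea, "/", ref_oa) %in% amb_pairs
    d[keep, , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "harmonization_log") <- log_entries
  res
}

#' Univariate meta-analysis table
#'
#' For every SNP x phenotype: the fixed-effects pooled estimate across
#' cohorts, the Fisher combination of per-cohort p-values, and the
#' heterogeneity statistics.
#'
#' @param stage1 harmonized stage-1 summary-statistics data.frame (with a
#'   `log10_p` column; recomputed from `z` if absent).
#' @return data.frame: snp_id, phenotype, beta_meta, se_meta, z, p_meta,
#'   log10_p_meta, p_fisher_cohorts, log10_p_fisher_cohorts, Q, I2,
#'   n_cohorts, n_total.
#' @export
meta_analyse <- function(stage1) {
  if (is.null(stage1$log10_p)) stage1$log10_p <- .log10p_z(stage1$z)
  key <- interaction(stage1$snp_id, stage1$phenotype, drop = TRUE)
  rows <- lapply(split(stage1, key), function(d) {
    fm <- fixed_effects_meta(d$beta, d$se, d$cohort)
    fc <- fisher_combine(log10_p = d$log10_p)
    data.frame(snp_id = d$snp_id[1L], phenotype = d$phenotype[1L],
               beta_meta = fm$beta_meta, se_meta = fm$se_meta, z = fm$z,
               p_meta = fm$p_meta, log10_p_meta = fm$log10_p,
               p_fisher_cohorts = fc$p, log10_p_fisher_cohorts = fc$log10_p,
               Q = fm$Q, I2 = fm$I2, n_cohorts = fm$n_cohorts,
               n_total = sum(d$n), row.names = NULL)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
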