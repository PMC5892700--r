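# The stage-2 test battery along the two combination pathways:
#   pathway 1: across cohorts first (fixed-effects meta / Fisher), then
#              across phenotypes (omnibus with Sigma_mP or Sigma_mB, Fisher);
#   pathway 2: across phenotypes first within each cohort (omnibus with
#              Sigma_jP or Sigma_jB, Fisher), then across cohorts (Fisher).

.test_order <- c("MOp", "MOb", "MFp", "FcFp", "OpFc", "ObFc", "FpFc")

#' Pathway-1 tests for one SNP and domain
#'
#' Builds the meta z-score vector (`beta_meta / se_meta` per phenotype) over
#' the domain phenotypes with univariate meta results, then evaluates:
#' `MOp` omnibus with the phenotype-based meta-scope matrix, `MOb` omnibus
#' with the effect-statistic matrix, `MFp` Fisher over the meta p-values,
#' and `FcFp` Fisher over the per-phenotype Fisher-across-cohorts p-values.
#'
#' @param snp_id SNP identifier.
#' @param meta_tbl univariate meta table from [meta_analyse()].
#' @param sigma_mP,sigma_mB meta-scope correlation matrices.
#' @param domain character vector of domain phenotype names.
#' @return list: `tests` (named list MOp/MOb/MFp/FcFp, each with
#'   `p` and `log10_p`), `phenotypes`, `z`.
#' @export
run_pathway1 <- function(snp_id, meta_tbl, sigma_mP, sigma_mB, domain) {
  d <- meta_tbl[meta_tbl$snp_id == snp_id & meta_tbl$phenotype %in% domain, ]
  if (nrow(d) == 0L)
    stop("no univariate meta results for ", snp_id, " in this domain")
  z <- setNames(d$z, d$phenotype)
  mop <- omnibus_test(z, sigma_mP)
  mob <- omnibus_test(z, sigma_mB)
  mfp <- fisher_combine(log10_p = d$log10_p_meta)
  fcfp <- fisher_combine(log10_p = d$log10_p_fisher_cohorts)
  pl <- function(x) list(p = x$p, log10_p = x$log10_p)
  list(tests = list(MOp = pl(mop), MOb = pl(mob), MFp = pl(mfp),
                    FcFp = pl(fcfp)),
       phenotypes = d$phenotype, z = z)
}

#' Pathway-2 tests for one SNP and domain
#'
#' Per cohort j: `OpC_j` omnibus of the cohort's stage-1 z-vector with its
#' phenotype-based matrix, `ObC_j` with its effect-statistic matrix, and
#' `FpC_j` Fisher over the cohort's p-values; phenotypes missing in a cohort
#' are dropped from that cohort's tests (K_j reduced). The per-cohort
#' p-values are then combined across cohorts with Fisher's method, giving
#' `OpFc`, `ObFc`, `FpFc`.
#'
#' @param snp_id SNP identifier.
#' @param stage1 stage-1 summary-statistics data.frame.
#' @param sigma_jP,sigma_jB named lists (by cohort) of cohort-scope
#'   correlation matrices.
#' @param domain character vector of domain phenotype names.
#' @return list: `tests` (OpFc/ObFc/FpFc), `per_cohort` (data.frame with
#'   cohort, K, and the three per-cohort p-values with log10 columns).
#' @export
run_pathway2 <- function(snp_id, stage1, sigma_jP, sigma_jB, domain) {
  d <- stage1[stage1$snp_id == snp_id & stage1$phenotype %in% domain, ]
  if (nrow(d) == 0L)
    stop("no stage-1 results for ", snp_id, " in this domain")
  if (is.null(d$log10_p)) d$log10_p <- .log10p_z(d$z)
  per <- lapply(split(d, d$cohort), function(dc) {
    co <- dc$cohort[1L]
    if (is.null(sigma_jP[[co]]) || is.null(sigma_jB[[co]]))
      stop("missing cohort-scope correlation matrix for ", co)
    z <- setNames(dc$z, dc$phenotype)
    op <- omnibus_test(z, sigma_jP[[co]])
    ob <- omnibus_test(z, sigma_jB[[co]])
    fp <- fisher_combine(log10_p = dc$log10_p)
    data.frame(cohort = co, K = length(z),
               p_OpC = op$p, log10_OpC = op$log10_p,
               p_ObC = ob$p, log10_ObC = ob$log10_p,
               p_FpC = fp$p, log10_FpC = fp$log10_p, row.names = NULL)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  pl <- function(x) list(p = x$p, log10_p = x$log10_p)
  list(tests = list(OpFc = pl(fisher_combine(log10_p = per$log10_OpC)),
                    ObFc = pl(fisher_combine(log10_p = per$log10_ObC)),
                    FpFc = pl(fisher_combine(log10_p = per$log10_FpC))),
       per_cohort = per)
}

#' Full stage-2 battery for one SNP
#'
#' Evaluates both pathways on every requested domain; flags genome-wide
#' significance (any test p below `p_gw`) and records the best (smallest-p)
#' test, with ties broken in the fixed order MOp, MOb, MFp, FcFp, OpFc,
#' ObFc, FpFc.
#'
#' @param snp_id SNP identifier.
#' @param stage1 stage-1 summary statistics.
#' @param meta_tbl univariate meta table.
#' @param sigma_mP,sigma_mB meta-scope matrices.
#' @param sigma_jP,sigma_jB named lists of cohort-scope matrices.
#' @param domains named list of phenotype-name vectors.
#' @param p_gw genome-wide significance cut-off.
#' @return list of class `pleio_result`: `snp_id`, `domains` (per domain:
#'   `tests` across both pathways, `per_cohort`, `min_p`, `best_test`,
#'   `best_pathway`), `gw`, `best_domain`, `min_log10_p`.
#' @export
run_snp_battery <- function(snp_id, stage1, meta_tbl, sigma_mP, sigma_mB,
                            sigma_jP, sigma_jB,
                            domains = default_domains(), p_gw = 5e-8) {
  res <- list()
  for (dn in names(domains)) {
    dom <- domains[[dn]]
    have_meta <- any(meta_tbl$snp_id == snp_id & meta_tbl$phenotype %in% dom)
    have_s1 <- any(stage1$snp_id == snp_id & stage1$phenotype %in% dom)
    if (!have_meta || !have_s1) next
    # domain matrices: subset to the domain phenotypes present in each scope
    sub <- function(S, ph) {
      ph <- intersect(ph, rownames(S))
      S[ph, ph, drop = FALSE]
    }
    p1 <- run_pathway1(snp_id, meta_tbl, sub(sigma_mP, dom),
                       sub(sigma_mB, dom), dom)
    p2 <- run_pathway2(snp_id, stage1,
                       lapply(sigma_jP, sub, ph = dom),
                       lapply(sigma_jB, sub, ph = dom), dom)
    tests <- c(p1$tests, p2$tests)
    l10 <- vapply(tests[.test_order], `[[`, 0, "log10_p")
    best <- which.min(l10)[1L]
    res[[dn]] <- list(tests = tests, per_cohort = p2$per_cohort,
                      phenotypes = p1$phenotypes,
                      min_p = .p_from_log10(min(l10)),
                      min_log10_p = min(l10),
                      best_test = .test_order[best],
                      best_pathway = if (best <= 4L) 1L else 2L)
  }
  if (length(res) == 0L) stop("no testable domain for ", snp_id)
  mins <- vapply(res, `[[`, 0, "min_log10_p")
  structure(list(snp_id = snp_id, domains = res,
                 gw = any(mins < log10(p_gw)),
                 best_domain = names(res)[which.min(mins)[1L]],
                 min_log10_p = min(mins)),
            class = "pleio_result")
}

#' Run the pleiotropy pipeline over a simulated study
#'
#' Convenience driver: stage-1 fits in every cohort, allele harmonization,
#' univariate meta-analysis, all correlation matrices (phenotype-based once
#' per scope; effect-statistic matrices per SNP from `R` dosage
#' permutations), then the full battery per SNP and domain.
#'
#' @param study a `pleio_study`.
#' @param domains named list of domains (default [default_domains()] of the
#'   study's phenotypes).
#' @param R permutations for the effect-statistic matrices.
#' @param seed integer seed for the permutations.
#' @param snps optional SNP subset.
#' @param p_gw genome-wide cut-off.
#' @return list: `stage1`, `meta`, `results` (named list of `pleio_result`),
#'   `table` (long data.frame: snp_id, domain, pathway, test, p, log10_p),
#'   `wide` (per SNP x domain, Table-2-style columns), `sigma` (all
#'   matrices).
#' @export
run_pleiotropy <- function(study, domains = NULL, R = 250L, seed = 1L,
                           snps = NULL, p_gw = 5e-8) {
  if (is.null(domains)) domains <- default_domains(study$phenotypes)
  stage1 <- do.call(rbind, lapply(study$cohorts, cohort_stage1, snps = snps))
  rownames(stage1) <- NULL
  stage1 <- harmonize_alleles(stage1)
  meta_tbl <- meta_analyse(stage1)
  sigma_mP <- estimate_sigma_P(study, "meta")
  sigma_jP <- lapply(study$cohorts, estimate_sigma_P, scope = "cohort")
  if (is.null(snps)) snps <- unique(stage1$snp_id)
  results <- list()
  for (i in seq_along(snps)) {
    snp <- snps[i]
    sseed <- .derive_seed(seed, i)
    sigma_mB <- estimate_sigma_B(study, snp, "meta", R = R, seed = sseed)
    sigma_jB <- lapply(study$cohorts, function(cd)
      estimate_sigma_B(cd, snp, R = R, seed = sseed))
    results[[snp]] <- run_snp_battery(snp, stage1, meta_tbl, sigma_mP,
                                      sigma_mB, sigma_jP, sigma_jB,
                                      domains, p_gw)
  }
  long <- do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(names(r$domains), function(dn) {
      tl <- r$domains[[dn]]$tests
      data.frame(snp_id = r$snp_id, domain = dn,
                 pathway = ifelse(names(tl) %in% c("MOp", "MOb", "MFp", "FcFp"),
                                  1L, 2L),
                 test = names(tl),
                 p = vapply(tl, `[[`, 0, "p"),
                 log10_p = vapply(tl, `[[`, 0, "log10_p"), row.names = NULL)
    }))
  }))
  rownames(long) <- NULL
  wide <- do.call(rbind, lapply(results, function(r) {
    dn <- r$best_domain
    dd <- r$domains[[dn]]
    tl <- dd$tests
    pw <- dd$best_pathway
    pick <- function(t1, t2) if (pw == 1L) tl[[t1]]$p else tl[[t2]]$p
    data.frame(snp_id = r$snp_id, domain = dn, pathway = pw,
               p_op = pick("MOp", "OpFc"), p_ob = pick("MOb", "ObFc"),
               p_mfp = if (pw == 1L) tl$MFp$p else NA_real_,
               p_fpfc = pick("FcFp", "FpFc"),
               min_p = dd$min_p, best_test = dd$best_test, gw = r$gw,
               row.names = NULL)
  }))
  rownames(wide) <- NULL
  list(stage1 = stage1, meta = meta_tbl, results = results, table = long,
       wide = wide,
       sigma = list(mP = sigma_mP, jP = sigma_jP))
}

#' Per-phenotype -log10(p) heat-map table
#'
#' SNP x phenotype matrix of `-log10(p_meta)` trimmed at the genome-wide
#' level `-log10(5e-8) = 7.3` for display resolution.
#'
#' @param meta_tbl univariate meta table.
#' @param snps optional SNP subset.
#' @param trim trimming value (default `-log10(5e-8)`).
#' @return numeric matrix, SNPs in rows.
#' @export
heatmap_table <- function(meta_tbl, snps = NULL, trim = -log10(5e-8)) {
  if (!is.null(snps)) meta_tbl <- meta_tbl[meta_tbl$snp_id %in% snps, ]
  ph <- unique(meta_tbl$phenotype)
  sn <- unique(meta_tbl$snp_id)
  M <- matrix(NA_real_, length(sn), length(ph), dimnames = list(sn, ph))
  M[cbind(match(meta_tbl$snp_id, sn), match(meta_tbl$phenotype, ph))] <-
    pmin(-meta_tbl$log10_p_meta, trim)
  M
}
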