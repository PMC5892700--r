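# Vectorized batch routines for calibration studies over many SNPs. These
# are algebraically identical to the per-SNP pipeline (single-visit linear
# fits, fixed-effects pooling, Fisher and omnibus combinations) but operate
# on whole dosage matrices at once; a consistency test pins them to the
# per-SNP path.

#' Batch linear association of many SNPs with many phenotypes
#'
#' Ordinary least-squares slope, standard error and Wald z of every
#' phenotype on every dosage column, covariates partialled out of both
#' sides (Frisch-Waugh), matching `fit_quantitative` on single-visit data.
#'
#' @param G n x S dosage matrix.
#' @param Y n x K phenotype matrix (per-subject analysis-scale values).
#' @param covariates optional data.frame/matrix of covariates.
#' @return list of S x K matrices: `beta`, `se`, `z`, `log10_p`; plus `n`.
#' @export
batch_quant_assoc <- function(G, Y, covariates = NULL) {
  G <- as.matrix(G)
  Y <- as.matrix(Y)
  n <- nrow(G)
  stopifnot(nrow(Y) == n)
  X <- cbind(rep(1, n))
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  q <- qr(X)
  Gr <- qr.resid(q, G)
  Yr <- qr.resid(q, Y)
  df <- n - ncol(X) - 1L
  Sxx <- colSums(Gr^2)                       # S
  Syy <- colSums(Yr^2)                       # K
  Sxy <- crossprod(Gr, Yr)                   # S x K
  beta <- Sxy / Sxx
  rss <- outer(rep(1, length(Sxx)), Syy) - Sxy^2 / Sxx
  se <- sqrt(pmax(rss, 0) / df / Sxx)
  z <- beta / se
  dimnames(beta) <- dimnames(se) <- dimnames(z) <-
    list(colnames(G), colnames(Y))
  list(beta = beta, se = se, z = z, log10_p = .log10p_z(z), n = n)
}

#' Batch fixed-effects meta-analysis across cohorts
#'
#' Element-wise inverse-variance pooling of per-cohort `beta`/`se` matrices
#' (same SNP x phenotype layout in every cohort).
#'
#' @param stats_list list of results from [batch_quant_assoc()].
#' @return list of matrices: `beta`, `se`, `z`, `log10_p`.
#' @export
batch_meta <- function(stats_list) {
  stopifnot(length(stats_list) >= 1L)
  wsum <- 0
  bwsum <- 0
  for (st in stats_list) {
    w <- 1 / st$se^2
    wsum <- wsum + w
    bwsum <- bwsum + w * st$beta
  }
  beta <- bwsum / wsum
  se <- 1 / sqrt(wsum)
  z <- beta / se
  list(beta = beta, se = se, z = z, log10_p = .log10p_z(z))
}

#' Batch omnibus test
#'
#' Quadratic form `z' Sigma^-1 z` for every row of a z-score matrix.
#'
#' @param Z S x K z-score matrix (columns matching `sigma`).
#' @param sigma K x K correlation matrix.
#' @return list: `statistic` (length S), `df`, `log10_p`.
#' @export
batch_omnibus <- function(Z, sigma) {
  Z <- as.matrix(Z)
  sigma <- repair_sigma(as.matrix(sigma))
  if (!is.null(colnames(Z)) && !is.null(rownames(sigma)))
    sigma <- sigma[colnames(Z), colnames(Z), drop = FALSE]
  stat <- rowSums((Z %*% solve(sigma)) * Z)
  K <- ncol(Z)
  list(statistic = stat, df = K, log10_p = .log10p_chisq(stat, K))
}

#' Batch Fisher combination across columns
#'
#' @param L10 S x m matrix of log10 p-values (one combination per row).
#' @return list: `statistic`, `df`, `log10_p`.
#' @export
batch_fisher <- function(L10) {
  L10 <- as.matrix(L10)
  m <- ncol(L10)
  stat <- -2 * log(10) * rowSums(L10)
  list(statistic = stat, df = 2L * m, log10_p = .log10p_chisq(stat, 2L * m))
}

#' Batch stage-2 battery over many SNPs
#'
#' All seven pathway tests for every SNP at once, from per-cohort batch
#' association statistics. Assumes every cohort measured the same phenotype
#' set (the calibration-study layout).
#'
#' @param stats_list named list (by cohort) of [batch_quant_assoc()] results.
#' @param sigma_jP,sigma_jB named lists of cohort-scope matrices.
#' @param sigma_mP,sigma_mB meta-scope matrices.
#' @return data.frame of log10 p-values, one row per SNP, columns MOp, MOb,
#'   MFp, FcFp, OpFc, ObFc, FpFc.
#' @export
batch_pleio_tests <- function(stats_list, sigma_jP, sigma_jB,
                              sigma_mP, sigma_mB) {
  meta <- batch_meta(stats_list)
  mop <- batch_omnibus(meta$z, sigma_mP)$log10_p
  mob <- batch_omnibus(meta$z, sigma_mB)$log10_p
  mfp <- batch_fisher(meta$log10_p)$log10_p
  # per-phenotype Fisher across cohorts, then Fisher across phenotypes
  l10_fc <- 0
  for (st in stats_list) l10_fc <- l10_fc + st$log10_p
  m <- length(stats_list)
  stat_fc <- -2 * log(10) * l10_fc
  l10_percol <- .log10p_chisq(stat_fc, 2L * m)
  fcfp <- batch_fisher(l10_percol)$log10_p
  # pathway 2
  op_l10 <- ob_l10 <- fp_l10 <- NULL
  for (co in names(stats_list)) {
    st <- stats_list[[co]]
    op_l10 <- cbind(op_l10, batch_omnibus(st$z, sigma_jP[[co]])$log10_p)
    ob_l10 <- cbind(ob_l10, batch_omnibus(st$z, sigma_jB[[co]])$log10_p)
    fp_l10 <- cbind(fp_l10, batch_fisher(st$log10_p)$log10_p)
  }
  data.frame(MOp = mop, MOb = mob, MFp = mfp, FcFp = fcfp,
             OpFc = batch_fisher(op_l10)$log10_p,
             ObFc = batch_fisher(ob_l10)$log10_p,
             FpFc = batch_fisher(fp_l10)$log10_p)
}
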