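# Omnibus chi-square tests across phenotypes, with the z-score correlation
# matrix estimated either from the phenotypes themselves (Sigma_P) or from
# association statistics of permuted dosages (Sigma_B).

.new_sigma <- function(S, kind, scope, n_permutations = NA_integer_,
                       repaired = FALSE, lambda = 0) {
  structure(S, kind = kind, scope = scope,
            n_permutations = n_permutations, repaired = repaired,
            lambda = lambda, class = c("sigma_matrix", "matrix"))
}

#' Repair a near-singular correlation matrix
#'
#' Shrinks `S <- (1 - lambda) * S + lambda * I` with the smallest
#' `lambda` in `{0.01, 0.02, ...}` giving condition number below `max_cond`.
#' Degrees of freedom of the downstream omnibus test are unaffected.
#'
#' @param S symmetric correlation matrix.
#' @param max_cond maximum admissible condition number (default 1e8).
#' @return repaired matrix with attributes `repaired` and `lambda`.
#' @export
repair_sigma <- function(S, max_cond = 1e8) {
  cond_ok <- function(M) {
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    min(ev) > 0 && max(ev) / min(ev) < max_cond
  }
  if (cond_ok(S)) {
    attr(S, "repaired") <- FALSE
    attr(S, "lambda") <- 0
    return(S)
  }
  K <- nrow(S)
  for (lambda in seq(0.01, 0.99, by = 0.01)) {
    S2 <- (1 - lambda) * S + lambda * diag(K)
    if (cond_ok(S2)) {
      message("correlation matrix repaired by shrinkage, lambda = ", lambda)
      attr(S2, "repaired") <- TRUE
      attr(S2, "lambda") <- lambda
      dimnames(S2) <- dimnames(S)
      return(S2)
    }
  }
  stop("correlation matrix could not be repaired")
}

#' Phenotype-based correlation matrix (Sigma_P)
#'
#' Pairwise Pearson correlations of per-subject phenotype values:
#' quantitative traits averaged over visits on the analysis scale, binary /
#' time-to-event outcomes as 0/1 event indicators (point-biserial). Cohort
#' scope uses one cohort's subjects; meta scope pools the subjects of all
#' cohorts (pairwise-complete, so cohort-specific phenotype gaps are
#' handled). A phenotype constant in scope gets an identity row/column with
#' a warning.
#'
#' @param study a `pleio_study` (or a single `cohort_data` for cohort scope).
#' @param scope `"meta"` or `"cohort"`.
#' @param cohort cohort name (required for cohort scope on a study).
#' @param phenotypes optional phenotype subset/order.
#' @return `sigma_matrix` with kind `"P"`.
#' @export
estimate_sigma_P <- function(study, scope = c("meta", "cohort"),
                             cohort = NULL, phenotypes = NULL) {
  scope <- match.arg(scope)
  if (inherits(study, "cohort_data")) {
    M <- phenotype_matrix(study, phenotypes)
    scope_lab <- paste0("cohort-", study$name)
  } else if (scope == "cohort") {
    if (is.null(cohort) || !cohort %in% names(study$cohorts))
      stop("cohort scope requires a cohort name present in the study")
    cd <- study$cohorts[[cohort]]
    if (is.null(phenotypes)) phenotypes <- names(cd$phenotypes)
    M <- phenotype_matrix(cd, phenotypes)
    scope_lab <- paste0("cohort-", cohort)
  } else {
    if (is.null(phenotypes)) phenotypes <- names(study$phenotypes)
    M <- do.call(rbind, lapply(study$cohorts, phenotype_matrix,
                               phenotypes = phenotypes))
    scope_lab <- "meta"
  }
  keep <- colnames(M)[apply(M, 2L, function(x) sum(!is.na(x)) > 0L)]
  M <- M[, keep, drop = FALSE]
  S <- suppressWarnings(cor(M, use = "pairwise.complete.obs"))
  const <- apply(M, 2L, function(x) var(x, na.rm = TRUE) == 0 ||
                   !is.finite(var(x, na.rm = TRUE)))
  if (any(const) || anyNA(S)) {
    bad <- unique(c(colnames(M)[const], colnames(S)[apply(is.na(S), 1L, any)]))
    warning("constant phenotype(s) in scope, set to identity: ",
            paste(bad, collapse = ", "), call. = FALSE)
    S[bad, ] <- 0
    S[, bad] <- 0
    diag(S) <- 1
  }
  S <- repair_sigma(S)
  .new_sigma(unclass(S), "P", scope_lab,
             repaired = attr(S, "repaired"), lambda = attr(S, "lambda"))
}

# Null-model (covariate-only) residuals on the analysis scale, one column per
# phenotype: OLS residuals of visit-averaged quantitative traits, response
# residuals of a covariate-only logistic fit for binary indicators,
# martingale residuals of a covariate-only Cox fit for time-to-event.
.null_residuals <- function(cohort_data, phenotypes = NULL) {
  if (is.null(phenotypes)) phenotypes <- names(cohort_data$phenotypes)
  phenotypes <- intersect(phenotypes, names(cohort_data$phenotypes))
  cv <- cohort_data$covariates
  n <- nrow(cv)
  X <- cbind(1, as.matrix(cv))
  out <- matrix(NA_real_, n, length(phenotypes),
                dimnames = list(NULL, phenotypes))
  for (ph in phenotypes) {
    sp <- cohort_data$phenotypes[[ph]]
    if (sp$kind == "quantitative") {
      y <- phenotype_matrix(cohort_data, ph)[, 1L]
      out[, ph] <- stats::lm.fit(X, y)$residuals
    } else if (sp$kind == "binary") {
      y <- cohort_data$events[[ph]]$event
      fit <- suppressWarnings(glm(y ~ ., data = cv, family = binomial()))
      out[, ph] <- y - fitted(fit)
    } else {
      ev <- cohort_data$events[[ph]]
      fit <- survival::coxph(survival::Surv(ev$age, ev$event) ~ sex,
                             data = cv, ties = "breslow")
      out[, ph] <- residuals(fit, type = "martingale")
    }
  }
  out
}

# R permuted copies of one SNP's dosage vector (columns), the same
# permutation reused across all phenotypes of the cohort so cross-phenotype
# dependence of the z-scores is preserved.
.perm_dosage <- function(g, R) {
  n <- length(g)
  vapply(seq_len(R), function(r) g[sample.int(n)], numeric(n))
}

# score-type z-scores of (permuted) dosage columns against null residuals:
# z = sqrt(n) * cor(g, resid), the standard score statistic up to O(1/n)
.score_z <- function(G, resid_mat) {
  suppressWarnings(cor(G, resid_mat)) * sqrt(nrow(G))
}

#' Effect-statistic correlation matrix from dosage permutations (Sigma_B)
#'
#' Randomly permutes the dosage vector of one SNP `R` times within each
#' cohort (one permutation per replicate, reused against all of that
#' cohort's phenotypes), computes score-type association z-scores of each
#' permuted dosage with every phenotype under the covariate-only null model,
#' and returns the Pearson correlation of the z-score vectors over the `R`
#' replicates. Meta scope first combines the per-cohort z-scores of each
#' replicate by inverse-variance (sample-size) weighting. Replicates with
#' undefined statistics are dropped; more than `drop_tol` dropped is an
#' error.
#'
#' @param study a `pleio_study` (or single `cohort_data` for cohort scope).
#' @param snp_id SNP identifier (must be present in all scope cohorts).
#' @param scope `"meta"` or `"cohort"`.
#' @param cohort cohort name for cohort scope on a study.
#' @param R number of permutations (>= 50; study default 250).
#' @param seed integer seed.
#' @param phenotypes optional phenotype subset.
#' @param drop_tol maximum tolerated fraction of dropped replicates.
#' @return `sigma_matrix` with kind `"B"` and attribute `n_permutations`.
#' @export
estimate_sigma_B <- function(study, snp_id, scope = c("meta", "cohort"),
                             cohort = NULL, R = 250L, seed = 1L,
                             phenotypes = NULL, drop_tol = 0.1) {
  scope <- match.arg(scope)
  if (R < 50L) stop("R must be at least 50")
  if (inherits(study, "cohort_data")) {
    cohorts <- list(study)
  } else if (scope == "cohort") {
    if (is.null(cohort) || !cohort %in% names(study$cohorts))
      stop("cohort scope requires a cohort name present in the study")
    cohorts <- study$cohorts[cohort]
  } else {
    cohorts <- study$cohorts
  }
  for (cd in cohorts)
    if (!snp_id %in% colnames(cd$dosage))
      stop("SNP ", snp_id, " absent from cohort ", cd$name)
  if (is.null(phenotypes))
    phenotypes <- unique(unlist(lapply(cohorts, function(cd)
      names(cd$phenotypes))))

  set.seed(seed)
  Zs <- list()   # per cohort: R x K_j z matrices
  ws <- numeric(length(cohorts))
  for (i in seq_along(cohorts)) {
    cd <- cohorts[[i]]
    resid_mat <- .null_residuals(cd, phenotypes)
    G <- .perm_dosage(cd$dosage[, snp_id], R)
    Zs[[i]] <- .score_z(G, resid_mat)
    ws[i] <- nrow(cd$covariates)
  }
  # combine across cohorts per replicate: inverse-variance weighting of
  # z-scores is sqrt(n)-weighting under equal per-subject information
  Zm <- matrix(0, R, length(phenotypes), dimnames = list(NULL, phenotypes))
  Wm <- matrix(0, 1L, length(phenotypes), dimnames = list(NULL, phenotypes))
  for (i in seq_along(Zs)) {
    ph <- colnames(Zs[[i]])
    Zm[, ph] <- Zm[, ph] + sweep(Zs[[i]], 2L, sqrt(ws[i]), `*`)
    Wm[, ph] <- Wm[, ph] + ws[i]
  }
  Zm <- sweep(Zm, 2L, sqrt(drop(Wm)), `/`)
  ok <- apply(is.finite(Zm), 1L, all)
  if (mean(!ok) > drop_tol)
    stop("more than ", drop_tol * 100, "% of permutations dropped")
  S <- suppressWarnings(cor(Zm[ok, , drop = FALSE]))
  if (anyNA(S)) {
    bad <- colnames(S)[apply(is.na(S), 1L, any)]
    warning("degenerate permutation statistics, identity used for: ",
            paste(bad, collapse = ", "), call. = FALSE)
    S[bad, ] <- 0; S[, bad] <- 0; diag(S) <- 1
  }
  S <- repair_sigma(S)
  scope_lab <- if (length(cohorts) > 1L) "meta"
               else paste0("cohort-", cohorts[[1L]]$name)
  .new_sigma(unclass(S), "B", scope_lab, n_permutations = sum(ok),
             repaired = attr(S, "repaired"), lambda = attr(S, "lambda"))
}

#' Omnibus chi-square test
#'
#' Evaluates the quadratic form `t(z) %*% solve(Sigma) %*% z`, referred to a
#' chi-square distribution with `K = length(z)` degrees of freedom (K is
#' kept even for strongly correlated phenotypes). A singular `Sigma` is
#' repaired by shrinkage before inversion.
#'
#' @param z numeric z-score vector (names, if present, must match `sigma`).
#' @param sigma K x K correlation matrix.
#' @return list: `statistic`, `df`, `p`, `log10_p`.
#' @export
omnibus_test <- function(z, sigma) {
  K <- length(z)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != K || ncol(sigma) != K)
    stop("dimension mismatch: z has length ", K, ", sigma is ",
         nrow(sigma), " x ", ncol(sigma))
  if (!is.null(names(z)) && !is.null(rownames(sigma))) {
    if (!all(names(z) %in% rownames(sigma)))
      stop("z names missing from sigma: ",
           paste(setdiff(names(z), rownames(sigma)), collapse = ", "))
    sigma <- sigma[names(z), names(z), drop = FALSE]
  }
  if (any(!is.finite(z))) stop("non-finite z-score(s)")
  sigma <- repair_sigma(sigma)
  stat <- drop(crossprod(z, solve(sigma, z)))
  l10 <- .log10p_chisq(stat, K)
  list(statistic = stat, df = K, p = .p_from_log10(l10), log10_p = l10)
}

#' Two-phenotype omnibus statistic in closed form
#'
#' Direct evaluation of the 2 x 2 quadratic form
#' `(z1^2 * S22 - z1 * z2 * S21 + z2^2 * S11 - z1 * z2 * S12) / det(S)`.
#' Equals the general quadratic form to machine precision; shows explicitly
#' that effects antagonistic relative to the phenotype correlation
#' (`z1 * z2 * r < 0`) inflate the statistic above `z1^2 + z2^2` while
#' aligned effects deflate it.
#'
#' @param z1,z2 the two z-scores.
#' @param sigma 2 x 2 correlation matrix with `|r| < 1`.
#' @return the scalar statistic.
#' @export
two_phenotype_statistic <- function(z1, z2, sigma) {
  sigma <- as.matrix(sigma)
  stopifnot(nrow(sigma) == 2L, ncol(sigma) == 2L)
  if (abs(sigma[1L, 2L]) >= 1) stop("|r| must be below 1")
  (z1^2 * sigma[2L, 2L] - z1 * z2 * sigma[2L, 1L] +
   z2^2 * sigma[1L, 1L] - z1 * z2 * sigma[1L, 2L]) /
    (sigma[1L, 1L] * sigma[2L, 2L] - sigma[1L, 2L] * sigma[2L, 1L])
}
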