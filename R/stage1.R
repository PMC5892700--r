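# Stage-1 univariate association fits: one SNP x one phenotype x one cohort,
# additive genetic model, age/sex adjustment.

.new_assoc <- function(beta = NA_real_, se = NA_real_, n = NA_integer_,
                       status = "ok") {
  z <- if (is.na(se) || se <= 0) NA_real_ else beta / se
  l10 <- if (is.na(z)) NA_real_ else .log10p_z(z)
  structure(list(beta = beta, se = se, z = z,
                 p = if (is.na(l10)) NA_real_ else .p_from_log10(l10),
                 log10_p = l10, n = n, status = status),
            class = "assoc_stat")
}

.design_matrix <- function(n, dosage, covariates) {
  X <- cbind(`(Intercept)` = 1, dosage = dosage)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- as.data.frame(covariates)
    X <- cbind(X, as.matrix(covariates))
  }
  X
}

#' Quantitative association with repeated measurements
#'
#' Additive-model effect per effect-allele copy on a quantitative phenotype,
#' adjusted for covariates. Repeated visits are handled by a compound-
#' symmetry random-intercept model fitted by a two-stage moment/GLS scheme:
#' the within-subject variance comes from the pooled within-subject mean
#' square, the between-subject variance from a moment equation on the
#' weighted residuals of the subject-mean regression, and the two are
#' iterated to a fixed point (tolerance 1e-8 on the variance ratio). With a
#' single visit the fit reduces exactly to ordinary least squares. A
#' `subject_mean` fallback skips the weighting.
#'
#' @param dosage numeric dosage vector (one value per subject, in `[0, 2]`).
#' @param values numeric vector (one visit) or subject x visit matrix with
#'   `NA` for missed visits.
#' @param covariates optional data.frame of subject-level covariates
#'   (e.g. age, sex).
#' @param log_transform analyse `100 * log(values)`; non-positive values are
#'   rejected with the offending subject index.
#' @param method `"random_intercept"` (default) or `"subject_mean"`.
#' @param min_n minimum number of subjects with at least one visit.
#' @return an `assoc_stat` list: `beta`, `se`, `z`, `p`, `log10_p`, `n`,
#'   `status` (`"ok"` or `"monomorphic"`).
#' @export
fit_quantitative <- function(dosage, values, covariates = NULL,
                             log_transform = FALSE,
                             method = c("random_intercept", "subject_mean"),
                             min_n = 30L) {
  method <- match.arg(method)
  if (is.vector(values)) values <- matrix(values, ncol = 1L)
  stopifnot(length(dosage) == nrow(values))
  if (log_transform) {
    bad <- which(apply(values <= 0, 1L, any, na.rm = TRUE))
    if (length(bad))
      stop("non-positive value(s) under log-transform for subject(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    values <- 100 * log(values)
  }
  nvis <- rowSums(!is.na(values))
  keep <- nvis > 0L & !is.na(dosage)
  values <- values[keep, , drop = FALSE]
  dosage <- dosage[keep]
  nvis <- nvis[keep]
  if (!is.null(covariates)) covariates <- as.data.frame(covariates)[keep, , drop = FALSE]
  n <- length(dosage)
  if (n < min_n) stop("fewer than ", min_n, " subjects with a visit")
  if (var(dosage) == 0) return(.new_assoc(n = n, status = "monomorphic"))

  ybar <- rowMeans(values, na.rm = TRUE)
  X <- .design_matrix(n, dosage, covariates)

  # pooled within-subject variance (subjects with >= 2 visits)
  multi <- nvis >= 2L
  sw2 <- 0
  if (any(multi)) {
    dev <- values[multi, , drop = FALSE] - ybar[multi]
    sw2 <- sum(dev^2, na.rm = TRUE) / sum(nvis[multi] - 1L)
  }

  wls <- function(w) {
    xw <- X * w
    XtX <- crossprod(xw, X)
    coefv <- solve(XtX, crossprod(xw, ybar))
    list(coef = coefv, resid = ybar - drop(X %*% coefv), XtXinv = solve(XtX))
  }

  if (method == "subject_mean" || sw2 == 0 || all(nvis == 1L)) {
    f <- wls(rep(1, n))
    s2 <- sum(f$resid^2) / (n - ncol(X))
    se <- sqrt(s2 * f$XtXinv["dosage", "dosage"])
  } else {
    sb2 <- max(mean((wls(rep(1, n))$resid)^2) - sw2 / mean(nvis), 1e-8)
    ratio_old <- Inf
    for (it in 1:200) {
      w <- 1 / (sb2 + sw2 / nvis)
      f <- wls(w)
      # moment update: E[w_i r_i^2] ~ 1 (up to the p fitted parameters)
      scale <- sum(w * f$resid^2) / (n - ncol(X))
      sb2 <- max(scale * sb2 + (scale - 1) * sw2 / mean(nvis), 0)
      ratio <- sb2 / sw2
      if (abs(ratio - ratio_old) < 1e-8) break
      ratio_old <- ratio
    }
    w <- 1 / (sb2 + sw2 / nvis)
    f <- wls(w)
    se <- sqrt(f$XtXinv["dosage", "dosage"])
  }
  .new_assoc(beta = unname(f$coef["dosage", 1L]), se = unname(se), n = n)
}

#' Binary-outcome association (logistic model)
#'
#' Log-odds ratio per effect-allele copy from a logistic regression with
#' covariate adjustment; Wald z and two-sided p. Quasi-complete separation
#' is flagged (`status = "separation"`) rather than silently returned.
#'
#' @param dosage numeric dosage vector.
#' @param event_indicator 0/1 outcome vector.
#' @param covariates optional data.frame of covariates.
#' @param min_events minimum number of events (and of non-events).
#' @return an `assoc_stat` list.
#' @export
fit_binary <- function(dosage, event_indicator, covariates = NULL,
                       min_events = 10L) {
  stopifnot(length(dosage) == length(event_indicator))
  y <- event_indicator
  if (length(unique(y[!is.na(y)])) < 2L || sum(y, na.rm = TRUE) < min_events)
    stop("need both outcome classes and at least ", min_events, " events")
  if (var(dosage, na.rm = TRUE) == 0)
    return(.new_assoc(n = length(y), status = "monomorphic"))
  df <- data.frame(y = y, dosage = dosage)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  cf <- summary(fit)$coefficients
  out <- .new_assoc(beta = cf["dosage", 1L], se = cf["dosage", 2L],
                    n = nobs(fit))
  if (!fit$converged || abs(cf["dosage", 1L]) > 15 || cf["dosage", 2L] > 100)
    out$status <- "separation"
  out
}

#' Time-to-event association (Cox proportional hazards)
#'
#' Log hazard ratio per effect-allele copy from a Cox model on age at onset
#' (right-censored), Breslow tie handling, covariate adjustment, no frailty
#' term.
#'
#' @param dosage numeric dosage vector.
#' @param age_at_event positive event/censoring ages.
#' @param event_indicator 0/1 event indicator.
#' @param covariates optional data.frame of covariates (baseline age is not
#'   included by default since age is the time axis).
#' @param min_events minimum number of events.
#' @return an `assoc_stat` list.
#' @export
fit_survival <- function(dosage, age_at_event, event_indicator,
                         covariates = NULL, min_events = 10L) {
  stopifnot(length(dosage) == length(age_at_event),
            length(dosage) == length(event_indicator))
  if (any(age_at_event <= 0, na.rm = TRUE)) stop("event ages must be positive")
  if (sum(event_indicator, na.rm = TRUE) < min_events)
    stop("fewer than ", min_events, " events")
  if (var(dosage, na.rm = TRUE) == 0)
    return(.new_assoc(n = length(dosage), status = "monomorphic"))
  df <- data.frame(time = age_at_event, event = event_indicator,
                   dosage = dosage)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                         ties = "breslow")
  cf <- summary(fit)$coefficients
  .new_assoc(beta = cf["dosage", 1L], se = cf["dosage", 3L], n = fit$n)
}

#' All stage-1 fits for one cohort
#'
#' Runs the appropriate fit for every SNP x phenotype pair of a simulated
#' cohort and assembles the stage-1 summary-statistics table (the pipeline's
#' interchange format). Time-to-event phenotypes use the Cox fit; the Cox
#' model is adjusted for sex only (age is the time axis), other kinds for
#' age and sex. Flagged fits (monomorphic, separation) are dropped with a
#' message.
#'
#' @param cohort_data a `cohort_data` object.
#' @param snps optional subset of SNP ids.
#' @param phenotypes optional subset of phenotype names.
#' @return data.frame with columns snp_id, phenotype, cohort, effect_allele,
#'   other_allele, eaf, beta, se, z, p, log10_p, n.
#' @export
cohort_stage1 <- function(cohort_data, snps = NULL, phenotypes = NULL) {
  if (is.null(snps)) snps <- colnames(cohort_data$dosage)
  if (is.null(phenotypes)) phenotypes <- names(cohort_data$phenotypes)
  cov_full <- cohort_data$covariates
  rows <- list()
  for (snp in snps) {
    g <- cohort_data$dosage[, snp]
    info <- cohort_data$snp_info[cohort_data$snp_info$snp_id == snp, ]
    for (ph in phenotypes) {
      sp <- cohort_data$phenotypes[[ph]]
      if (is.null(sp)) next
      st <- tryCatch({
        if (sp$kind == "quantitative") {
          fit_quantitative(g, cohort_data$quant[[ph]], cov_full,
                           log_transform = sp$log_transform)
        } else if (sp$kind == "binary") {
          fit_binary(g, cohort_data$events[[ph]]$event, cov_full)
        } else {
          ev <- cohort_data$events[[ph]]
          fit_survival(g, ev$age, ev$event, cov_full["sex"])
        }
      }, error = function(e) .new_assoc(status = conditionMessage(e)))
      if (st$status != "ok") {
        message("skipping ", snp, " x ", ph, " in ", cohort_data$name,
                ": ", st$status)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snp, phenotype = ph, cohort = cohort_data$name,
        effect_allele = info$effect_allele, other_allele = info$other_allele,
        eaf = mean(g) / 2, beta = st$beta, se = st$se, z = st$z, p = st$p,
        log10_p = st$log10_p, n = st$n, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

#' Stage-1 SNP prioritization
#'
#' Per SNP, Fisher's statistic over only those phenotype p-values below
#' `alpha` (pooled over cohorts and phenotypes); SNPs without a nominal hit
#' get prioritization p-value 1. SNPs are ranked ascending; ties are broken
#' by the smallest single univariate p-value, then lexicographically by
#' snp_id. The top `top_n` SNPs are flagged for stage 2.
#'
#' @param stage1 stage-1 summary-statistics data.frame.
#' @param top_n number of SNPs to select (default 1000).
#' @param alpha nominal-significance cut-off (default 0.05).
#' @return data.frame: snp_id, fisher_statistic, df, p_prioritize, rank,
#'   selected.
#' @export
prioritize <- function(stage1, top_n = 1000L, alpha = 0.05) {
  stopifnot(nrow(stage1) >= 1L)
  by_snp <- split(stage1, stage1$snp_id)
  rec <- lapply(by_snp, function(d) {
    sel <- d$p < alpha
    m <- sum(sel)
    if (m == 0L)
      return(data.frame(snp_id = d$snp_id[1L], fisher_statistic = 0,
                        df = 0L, p_prioritize = 1, min_p = min(d$p)))
    stat <- -2 * sum(log(.clip_p(d$p[sel])))
    data.frame(snp_id = d$snp_id[1L], fisher_statistic = stat, df = 2L * m,
               p_prioritize = pchisq(stat, 2L * m, lower.tail = FALSE),
               min_p = min(d$p))
  })
  out <- do.call(rbind, rec)
  ord <- order(out$p_prioritize, out$min_p, out$snp_id)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= top_n
  out$min_p <- NULL
  rownames(out) <- NULL
  out
}
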