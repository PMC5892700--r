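# Decision rules on the stage-2 battery: genome-wide significance,
# antagonistic-heterogeneity group assignment, cross-cohort validation,
# per-cohort antagonism replication, prior-evidence novelty, efficiency.

# orders-of-magnitude gap between two p-values, judged at the stated
# decimal resolution (p-values are compared as printed, to three
# significant figures, so a gap is assessed at 0.1-order resolution)
.orders_gap_ok <- function(log10_num, log10_den, orders, resolution) {
  (log10_num - log10_den) >= (orders - resolution / 2)
}

#' Antagonistic-heterogeneity group assignment
#'
#' With `(p_op, p_ob, p_fisher)` the phenotype-based omnibus, effect-
#' statistic omnibus and Fisher pleiotropic p-values of the SNP's pathway
#' (`MOp`/`MOb`/`MFp` for pathway 1, `OpFc`/`ObFc`/`FpFc` for pathway 2):
#' \itemize{
#'   \item HP: `p_op` genome-wide significant and the Fisher p-value at
#'     least `ratio_orders` orders of magnitude larger than `p_op`;
#'   \item HB: the same with `p_ob` in place of `p_op`;
#'   \item HP/HB: both qualify;
#'   \item M: neither qualifies but at least one test is genome-wide
#'     significant;
#'   \item none: no test reaches genome-wide significance.
#' }
#' All inputs may be given as p-values or exact log10 p-values; the gap is
#' judged at `orders_resolution` decimal resolution (the resolution at
#' which p-values printed to three significant figures can be compared).
#'
#' @param p_op,p_ob,p_fisher p-values (vectorized).
#' @param thresholds list from [default_thresholds()].
#' @param log10_op,log10_ob,log10_fisher optional exact log10 p-values
#'   (override the `p_*` arguments).
#' @return character vector of group labels.
#' @export
assign_group <- function(p_op = NULL, p_ob = NULL, p_fisher = NULL,
                         thresholds = default_thresholds(),
                         log10_op = NULL, log10_ob = NULL,
                         log10_fisher = NULL) {
  if (is.null(log10_op)) log10_op <- log10(.clip_p(.assert_prob(p_op, "p_op")))
  if (is.null(log10_ob)) log10_ob <- log10(.clip_p(.assert_prob(p_ob, "p_ob")))
  if (is.null(log10_fisher))
    log10_fisher <- log10(.clip_p(.assert_prob(p_fisher, "p_fisher")))
  if (anyNA(log10_op) || anyNA(log10_ob) || anyNA(log10_fisher))
    stop("missing test values")
  lgw <- log10(thresholds$p_gw)
  hp <- log10_op < lgw &
    .orders_gap_ok(log10_fisher, log10_op, thresholds$ratio_orders,
                   thresholds$orders_resolution)
  hb <- log10_ob < lgw &
    .orders_gap_ok(log10_fisher, log10_ob, thresholds$ratio_orders,
                   thresholds$orders_resolution)
  any_gw <- pmin(log10_op, log10_ob, log10_fisher) < lgw
  ifelse(hp & hb, "HP/HB",
         ifelse(hp, "HP",
                ifelse(hb, "HB", ifelse(any_gw, "M", "none"))))
}

#' Cross-cohort / cross-phenotype validation of a pleiotropic association
#'
#' Pathway 1: a genome-wide pleiotropic association is automatically
#' validated when every contributing univariate meta p-value is itself
#' above the genome-wide level (the signal was assembled from sub-threshold
#' parts). Pathway 2: automatically validated when no individual cohort is
#' genome-wide significant; otherwise at least one additional cohort
#' (beyond the genome-wide ones) must reach the Bonferroni level
#' `alpha / (n_cohorts - 1)`.
#'
#' @param pathway 1 or 2.
#' @param p_values for pathway 1 the univariate meta p-values over the
#'   domain phenotypes; for pathway 2 the per-cohort pleiotropic p-values
#'   of the SNP's best test.
#' @param n_cohorts number of cohorts (pathway 2, >= 2).
#' @param thresholds list from [default_thresholds()].
#' @return logical.
#' @export
validate_snp <- function(pathway, p_values, n_cohorts = length(p_values),
                         thresholds = default_thresholds()) {
  stopifnot(pathway %in% c(1L, 2L), length(p_values) >= 1L)
  if (pathway == 1L) return(all(p_values > thresholds$p_gw))
  gw <- p_values < thresholds$p_gw
  if (!any(gw)) return(TRUE)
  if (n_cohorts < 2L)
    stop("Bonferroni validation requires at least 2 cohorts")
  bonf <- thresholds$validation_alpha / (n_cohorts - 1)
  any(!gw & p_values < bonf)
}

#' Per-cohort replication of antagonistic heterogeneity
#'
#' A cohort replicates the antagonism when its pleiotropic tests reach
#' suggestive significance (`min(OpC, ObC) < suggestive` or
#' `FpC < suggestive`) and the Fisher p-value exceeds the smaller omnibus
#' p-value by at least `replication_orders` orders of magnitude (judged at
#' the same decimal resolution as the group assignment). Replication is
#' declared with two or more such cohorts.
#'
#' @param per_cohort data.frame with per-cohort columns `p_OpC`, `p_ObC`,
#'   `p_FpC` (or `log10_*` equivalents) as produced by [run_pathway2()].
#' @param thresholds list from [default_thresholds()].
#' @return list: `count` (cohorts replicating), `replicated` (count >= 2),
#'   `cohorts` (names when available).
#' @export
replicate_antagonism <- function(per_cohort, thresholds = default_thresholds()) {
  l_op <- if (!is.null(per_cohort$log10_OpC)) per_cohort$log10_OpC
          else log10(.clip_p(per_cohort$p_OpC))
  l_ob <- if (!is.null(per_cohort$log10_ObC)) per_cohort$log10_ObC
          else log10(.clip_p(per_cohort$p_ObC))
  l_fp <- if (!is.null(per_cohort$log10_FpC)) per_cohort$log10_FpC
          else log10(.clip_p(per_cohort$p_FpC))
  l_omni <- pmin(l_op, l_ob)
  lsug <- log10(thresholds$suggestive)
  hits <- (l_omni < lsug | l_fp < lsug) &
    .orders_gap_ok(l_fp, l_omni, thresholds$replication_orders,
                   thresholds$orders_resolution)
  list(count = sum(hits), replicated = sum(hits) >= 2L,
       cohorts = if (!is.null(per_cohort$cohort)) per_cohort$cohort[hits])
}

#' Prior-evidence Fisher combination and novelty
#'
#' Combines previously reported per-phenotype p-values for a SNP with
#' Fisher's method over all `K_total` study phenotypes, substituting a flat
#' penalizing p-value (default 0.4) for every phenotype without a reported
#' result. The SNP is novel when the combined prior evidence does not reach
#' genome-wide significance and no reported univariate prior p-value does
#' either.
#'
#' @param prior_p numeric vector of reported prior p-values (possibly empty).
#' @param K_total total number of study phenotypes to penalize over.
#' @param flat_p flat substitute p-value for unreported phenotypes.
#' @param p_gw genome-wide cut-off.
#' @return list: `statistic`, `df`, `p`, `log10_p`, `novel`.
#' @export
prior_evidence_fisher <- function(prior_p, K_total, flat_p = 0.4,
                                  p_gw = 5e-8) {
  stopifnot(length(prior_p) <= K_total)
  if (length(prior_p) && (any(prior_p <= 0) || any(prior_p > 1)))
    stop("reported prior p-values must lie in (0, 1]")
  pp <- c(prior_p, rep(flat_p, K_total - length(prior_p)))
  fc <- fisher_combine(pp)
  fc$novel <- fc$p >= p_gw &&
    (length(prior_p) == 0L || min(prior_p) >= p_gw)
  fc
}

#' Relative efficiency of two association studies
#'
#' Ratio of `log10(p) / n` between studies a and b:
#' `(log10(p_a) * n_b) / (log10(p_b) * n_a)`, quantifying how much
#' significance study a extracts per subject relative to study b.
#'
#' @param p_a,p_b the two p-values, in `(0, 1)`.
#' @param n_a,n_b the two sample sizes.
#' @return the efficiency ratio (> 1 means study a is more efficient).
#' @export
efficiency_ratio <- function(p_a, n_a, p_b, n_b) {
  stopifnot(n_a > 0, n_b > 0)
  if (any(c(p_a, p_b) <= 0) || any(c(p_a, p_b) >= 1))
    stop("p-values must lie strictly inside (0, 1)")
  (log10(p_a) * n_b) / (log10(p_b) * n_a)
}

#' Classify the SNPs of a pipeline run
#'
#' Applies [assign_group()] to every SNP's best-pathway battery, the
#' validation rule, the per-cohort antagonism replication, and (when a
#' prior-evidence table is supplied) the novelty rule.
#'
#' @param pleio result of [run_pleiotropy()].
#' @param thresholds list from [default_thresholds()].
#' @param prior_evidence optional data.frame (snp_id, phenotype, p) of
#'   previously reported associations.
#' @param K_total phenotypes to penalize over in the novelty Fisher
#'   combination (default: the study's phenotype count).
#' @return data.frame: snp_id, domain, pathway, group, antagonistic,
#'   validated, replicated_cohort_count, replicated, novel.
#' @export
classify_snps <- function(pleio, thresholds = default_thresholds(),
                          prior_evidence = NULL, K_total = NULL) {
  rows <- lapply(pleio$results, function(r) {
    dd <- r$domains[[r$best_domain]]
    tl <- dd$tests
    pw <- dd$best_pathway
    g <- if (pw == 1L) {
      assign_group(log10_op = tl$MOp$log10_p, log10_ob = tl$MOb$log10_p,
                   log10_fisher = tl$MFp$log10_p, thresholds = thresholds)
    } else {
      assign_group(log10_op = tl$OpFc$log10_p, log10_ob = tl$ObFc$log10_p,
                   log10_fisher = tl$FpFc$log10_p, thresholds = thresholds)
    }
    val <- if (pw == 1L) {
      pm <- pleio$meta[pleio$meta$snp_id == r$snp_id &
                         pleio$meta$phenotype %in% dd$phenotypes, ]
      validate_snp(1L, pm$p_meta, thresholds = thresholds)
    } else {
      pc <- switch(dd$best_test, OpFc = dd$per_cohort$p_OpC,
                   ObFc = dd$per_cohort$p_ObC, dd$per_cohort$p_FpC)
      validate_snp(2L, pc, n_cohorts = nrow(dd$per_cohort),
                   thresholds = thresholds)
    }
    rep <- replicate_antagonism(dd$per_cohort, thresholds)
    novel <- NA
    if (!is.null(prior_evidence)) {
      pe <- prior_evidence[prior_evidence$snp_id == r$snp_id, ]
      kt <- if (is.null(K_total)) length(unique(pleio$meta$phenotype))
            else K_total
      novel <- prior_evidence_fisher(pe$p, kt,
                                     flat_p = thresholds$flat_prior_p,
                                     p_gw = thresholds$p_gw)$novel
    }
    data.frame(snp_id = r$snp_id, domain = r$best_domain, pathway = pw,
               group = g, antagonistic = g %in% c("HP", "HB", "HP/HB"),
               validated = val, replicated_cohort_count = rep$count,
               replicated = rep$replicated, novel = novel, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
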