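#' Phenotype specification
#'
#' Describes one study phenotype: a quantitative marker measured at repeated
#' visits, a binary disease indicator, or an age-at-onset (time-to-event)
#' outcome. Markers may be natural-log-transformed (and scaled by 100) before
#' association analysis, the convention used for skewed biomarkers.
#'
#' @param name phenotype identifier.
#' @param kind one of `"quantitative"`, `"binary"`, `"time-to-event"`.
#' @param domain_tag `"marker"` (quantitative markers) or `"outcome"`
#'   (diseases and death). Markers must be quantitative.
#' @param log_transform logical; analyse `100 * log(y)` instead of `y`.
#' @param n_visits number of repeated measurements per subject
#'   (quantitative kinds only; binary and time-to-event have one record).
#' @return an object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, kind = c("quantitative", "binary", "time-to-event"),
                           domain_tag = c("marker", "outcome"),
                           log_transform = FALSE, n_visits = 1L) {
  kind <- match.arg(kind)
  domain_tag <- match.arg(domain_tag)
  n_visits <- as.integer(n_visits)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name), n_visits >= 1L)
  if (domain_tag == "marker" && kind != "quantitative")
    stop("domain_tag = 'marker' requires kind = 'quantitative'")
  if (kind != "quantitative" && n_visits != 1L)
    stop("binary and time-to-event phenotypes have n_visits = 1")
  structure(list(name = name, kind = kind, domain_tag = domain_tag,
                 log_transform = log_transform, n_visits = n_visits),
            class = "phenotype_spec")
}

#' Cohort specification
#'
#' @param name cohort identifier (unique within a study).
#' @param n_subjects number of subjects (>= 50).
#' @param phenotype_subset character vector of phenotype names measured in
#'   this cohort (non-empty subset of the study phenotype list).
#' @param age_mean,age_sd baseline age distribution in years.
#' @param seed optional cohort-level seed; when `NULL` one is derived from the
#'   study seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n_subjects, phenotype_subset,
                        age_mean = 60, age_sd = 8, seed = NULL) {
  n_subjects <- as.integer(n_subjects)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            n_subjects >= 50L, length(phenotype_subset) >= 1L)
  structure(list(name = name, n_subjects = n_subjects,
                 phenotype_subset = as.character(phenotype_subset),
                 age_mean = age_mean, age_sd = age_sd, seed = seed),
            class = "cohort_spec")
}

#' Per-SNP effect configuration
#'
#' True genetic effects injected by the simulator, in phenotype-standard-
#' deviation units per effect-allele copy (log-odds / log-hazard units for
#' binary / time-to-event phenotypes). An `antagonistic` pattern carries
#' effects of opposite sign on directly (positively) correlated phenotypes;
#' an `aligned` pattern carries same-sign effects.
#'
#' @param snp_id SNP identifier.
#' @param maf minor (= effect) allele frequency; the default study filter
#'   keeps MAF >= 0.02.
#' @param beta named numeric vector of per-phenotype effects (phenotypes not
#'   named get effect 0). All zero for `pattern = "null"`.
#' @param pattern one of `"null"`, `"aligned"`, `"antagonistic"`, `"custom"`;
#'   checked against the signs of `beta`.
#' @param cohort_multipliers named numeric vector of per-cohort effect-size
#'   multipliers (inter-cohort heterogeneity); unnamed cohorts get 1.
#' @return an object of class `effect_config`.
#' @export
effect_config <- function(snp_id, maf, beta = numeric(0),
                          pattern = c("custom", "null", "aligned", "antagonistic"),
                          cohort_multipliers = numeric(0)) {
  pattern <- match.arg(pattern)
  stopifnot(is.numeric(maf), length(maf) == 1L, maf > 0, maf <= 0.5)
  if (maf < 0.02)
    warning("maf < 0.02 is below the default study MAF filter", call. = FALSE)
  if (pattern == "null" && any(beta != 0))
    stop("pattern = 'null' requires all beta = 0")
  if (pattern == "aligned" && length(beta) >= 2 &&
      (any(beta == 0) || length(unique(sign(beta))) != 1L))
    stop("pattern = 'aligned' requires non-zero same-sign effects")
  if (pattern == "antagonistic" &&
      !(any(beta > 0) && any(beta < 0)))
    stop("pattern = 'antagonistic' requires effects of both signs")
  structure(list(snp_id = snp_id, maf = maf, beta = beta, pattern = pattern,
                 cohort_multipliers = cohort_multipliers),
            class = "effect_config")
}

#' The 20 default study phenotypes
#'
#' Twelve quantitative markers measured at repeated visits (six of them
#' log-transformed and scaled by 100 in analysis) plus seven diseases and
#' death, handled both as binary indicators and as age-at-onset outcomes.
#'
#' @param n_visits default number of visits for quantitative markers.
#' @return named list of [phenotype_spec()] objects.
#' @export
study_phenotypes <- function(n_visits = 3L) {
  logged <- c("BG", "BMI", "HDLC", "HR", "TC", "TG")
  markers <- c("BG", "BMI", "CRP", "creatinine", "DBP", "FVC",
               "HC", "HDLC", "HR", "SBP", "TC", "TG")
  outcomes <- c("AD", "AF", "cancer", "CHD", "DM", "death", "HF", "stroke")
  specs <- c(
    lapply(markers, function(m)
      phenotype_spec(m, "quantitative", "marker",
                     log_transform = m %in% logged, n_visits = n_visits)),
    lapply(outcomes, function(o)
      phenotype_spec(o, "time-to-event", "outcome"))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' The five default cohort specifications
#'
#' Five longitudinal cohorts totalling 33,431 subjects, with per-cohort
#' phenotype availability gaps (two cohorts miss some markers or outcomes),
#' emulating the structure of a multi-study consortium.
#'
#' @param scale optional factor in (0, 1] shrinking every cohort (minimum 50
#'   subjects each), for fast test runs.
#' @return named list of [cohort_spec()] objects.
#' @export
study_cohorts <- function(scale = 1) {
  ph <- names(study_phenotypes())
  specs <- list(
    cohort_spec("ARIC", 9612, setdiff(ph, "AD"), age_mean = 54.3, age_sd = 5.7),
    cohort_spec("CHS", 3182, ph, age_mean = 72.4, age_sd = 5.4),
    cohort_spec("FHS", 8628, ph, age_mean = 37.8, age_sd = 9.3),
    cohort_spec("MESA", 2527, setdiff(ph, c("cancer", "AD")),
                age_mean = 64.3, age_sd = 10.2),
    cohort_spec("HRS", 9482,
                setdiff(ph, c("creatinine", "FVC", "HC", "HR", "TG", "AF")),
                age_mean = 58.2, age_sd = 9.1)
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  if (scale != 1) {
    stopifnot(scale > 0, scale <= 1)
    for (nm in names(specs))
      specs[[nm]]$n_subjects <- max(50L, as.integer(round(specs[[nm]]$n_subjects * scale)))
  }
  specs
}

#' Default analysis thresholds
#'
#' @return list with: `p_gw` genome-wide significance cut-off (5e-8);
#'   `ratio_orders` the orders-of-magnitude gap between Fisher and omnibus
#'   p-values defining a strong heterogeneity impact (2, judged at
#'   `orders_resolution` = 0.1 decimal resolution, i.e. effective bound
#'   `ratio_orders - orders_resolution/2`); `validation_alpha` nominal level
#'   for the cross-cohort Bonferroni validation (0.05); `suggestive`
#'   suggestive-significance cut-off (0.1) and `replication_orders` minimum
#'   gap (0.2 orders) for per-cohort antagonism replication; `flat_prior_p`
#'   the flat p-value (0.4) substituted for phenotypes without prior
#'   evidence; `top_n` SNPs prioritized for stage 2 (1000); `permutations`
#'   dosage permutations for the effect-statistic correlation matrix (250).
#' @export
default_thresholds <- function() {
  list(p_gw = 5e-8, ratio_orders = 2, orders_resolution = 0.1,
       validation_alpha = 0.05, suggestive = 0.1, replication_orders = 0.2,
       flat_prior_p = 0.4, top_n = 1000L, permutations = 250L)
}

#' Default phenotype domains
#'
#' The three domains over which pleiotropy is tested: the 12 quantitative
#' markers, the 8 risk outcomes, and all 20 phenotypes.
#'
#' @param phenotypes named list of phenotype specs (defaults to
#'   [study_phenotypes()]).
#' @return named list of character vectors of phenotype names.
#' @export
default_domains <- function(phenotypes = study_phenotypes()) {
  tags <- vapply(phenotypes, `[[`, "", "domain_tag")
  nm <- names(phenotypes)
  list(markers12 = nm[tags == "marker"],
       outcomes = nm[tags == "outcome"],
       all20 = nm)
}
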