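# Tab-delimited interchange formats. Everything the pipeline writes is
# re-readable by the matching reader; p-values are serialized in scientific
# notation with >= 3 significant digits.

.stage1_cols <- c("snp_id", "phenotype", "cohort", "effect_allele",
                  "other_allele", "eaf", "beta", "se", "z", "p", "n")

#' Write stage-1 summary statistics
#'
#' Fixed-column TSV (snp_id, phenotype, cohort, effect_allele, other_allele,
#' eaf, beta, se, z, p, n), the pipeline's interchange format.
#'
#' @param stage1 stage-1 data.frame.
#' @param path output path.
#' @export
write_summary_stats <- function(stage1, path) {
  d <- stage1[, .stage1_cols]
  for (cc in c("eaf", "beta", "se", "z", "p"))
    d[[cc]] <- formatC(d[[cc]], digits = 10, format = "e")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read stage-1 summary statistics
#'
#' Validates the fixed header, types every column, recomputes exact log10
#' p-values from the z-scores, and collects malformed rows (non-positive
#' standard errors, p outside (0, 1], inconsistent z) into an error report
#' attached as the `"error_report"` attribute; the run continues without
#' those rows. A missing mandatory column or an empty file is a hard
#' failure.
#'
#' @param path TSV path.
#' @return typed data.frame with an extra `log10_p` column.
#' @export
read_summary_stats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("empty summary-statistics file: ", path)
  missing_cols <- setdiff(.stage1_cols, names(d))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  d <- d[, .stage1_cols]
  bad <- !is.finite(d$se) | d$se <= 0 | !is.finite(d$p) | d$p <= 0 |
    d$p > 1 | !is.finite(d$beta) |
    abs(d$z - d$beta / d$se) > 1e-6 * pmax(1, abs(d$z))
  report <- d[bad, , drop = FALSE]
  d <- d[!bad, , drop = FALSE]
  d$log10_p <- .log10p_z(d$z)
  rownames(d) <- NULL
  attr(d, "error_report") <- report
  d
}

#' Write a correlation matrix with its metadata side-car block
#'
#' Square TSV with phenotype ids as header row and first column, preceded
#' by `#`-prefixed metadata lines (kind, scope, permutations, repaired,
#' lambda).
#'
#' @param sigma a `sigma_matrix`.
#' @param path output path.
#' @export
write_sigma <- function(sigma, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(kind = attr(sigma, "kind"), scope = attr(sigma, "scope"),
            n_permutations = attr(sigma, "n_permutations"),
            repaired = attr(sigma, "repaired"),
            lambda = attr(sigma, "lambda"))
  writeLines(paste0("#", names(meta), "=", as.character(meta)), con)
  M <- as.data.frame(unclass(sigma))
  utils::write.table(cbind(phenotype = rownames(sigma), M), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a correlation matrix written by [write_sigma()]
#'
#' @param path TSV path.
#' @return `sigma_matrix` with restored metadata attributes.
#' @export
read_sigma <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", metal), "=")
  meta <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  d <- utils::read.delim(text = lines[!grepl("^#", lines)],
                         check.names = FALSE)
  M <- as.matrix(d[, -1L, drop = FALSE])
  rownames(M) <- d$phenotype
  .new_sigma(M, kind = meta[["kind"]], scope = meta[["scope"]],
             n_permutations = if (meta[["n_permutations"]] == "NA") NA_integer_
                              else as.integer(meta[["n_permutations"]]),
             repaired = as.logical(meta[["repaired"]]),
             lambda = as.numeric(meta[["lambda"]]))
}

#' Load the transcribed published worked example (115 classified SNPs)
#'
#' The package ships a transcription of the published table of 115 novel
#' pleiotropic SNPs: identifiers, genomic coordinates (GRCh38, metadata
#' only), domain, pathway, the battery p-values (the omnibus columns hold
#' MOp/MOb for pathway-1 rows and OpFc/ObFc for pathway-2 rows; the
#' dedicated MFp column is empty for pathway-2 rows, whose Fisher
#' comparator is FpFc), the printed heterogeneity group, and the prior-
#' evidence summary. Used as the regression fixture for the classification
#' rules.
#'
#' @param path fixture path (defaults to the installed copy).
#' @return data.frame of 115 rows with an added `p_fisher_comparator`
#'   column (MFp for pathway 1, FpFc for pathway 2).
#' @export
load_table2_fixture <- function(path = system.file("extdata",
                                                   "table2_fixture.tsv",
                                                   package = "pleiometa")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) != 115L)
    stop("fixture must have 115 rows, found ", nrow(d))
  stopifnot(all(d$pathway %in% c(1L, 2L)),
            all(d$group %in% c("HP", "HB", "HP/HB", "M")),
            all(is.finite(d$p_op)), all(is.finite(d$p_ob)),
            all(is.finite(d$p_fpfc)),
            all(is.finite(d$p_mfp[d$pathway == 1L])))
  d$p_fisher_comparator <- ifelse(d$pathway == 1L, d$p_mfp, d$p_fpfc)
  d
}

#' Write individual-level study data as tab-delimited tables
#'
#' One long-format phenotype table (subject_id, phenotype, visit, value,
#' age_at_visit), one outcome table (subject_id, outcome, event, age), one
#' dosage table (subject_id, snp_id, dosage), per cohort, plus a plain-text
#' study manifest.
#'
#' @param study a `pleio_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cd in study$cohorts) {
    pref <- file.path(dir, cd$name)
    qrows <- lapply(names(cd$quant), function(ph) {
      y <- cd$quant[[ph]]
      data.frame(subject_id = rep(seq_len(nrow(y)), ncol(y)),
                 phenotype = ph,
                 visit = rep(seq_len(ncol(y)), each = nrow(y)),
                 value = as.vector(y),
                 age_at_visit = rep(cd$covariates$age, ncol(y)))
    })
    q <- do.call(rbind, qrows)
    if (!is.null(q))
      utils::write.table(q[!is.na(q$value), ],
                         paste0(pref, "_phenotypes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    erows <- lapply(names(cd$events), function(ph)
      data.frame(subject_id = seq_len(nrow(cd$events[[ph]])), outcome = ph,
                 event = cd$events[[ph]]$event, age = cd$events[[ph]]$age))
    if (length(erows))
      utils::write.table(do.call(rbind, erows), paste0(pref, "_outcomes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    drows <- data.frame(subject_id = rep(seq_len(nrow(cd$dosage)),
                                         ncol(cd$dosage)),
                        snp_id = rep(colnames(cd$dosage),
                                     each = nrow(cd$dosage)),
                        dosage = as.vector(cd$dosage))
    utils::write.table(drows, paste0(pref, "_dosage.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  mf <- data.frame(
    cohort = vapply(study$cohorts, `[[`, "", "name"),
    n_subjects = vapply(study$cohorts, function(cd) nrow(cd$covariates), 0L),
    n_phenotypes = vapply(study$cohorts, function(cd)
      length(cd$phenotypes), 0L),
    n_snps = vapply(study$cohorts, function(cd) ncol(cd$dosage), 0L))
  utils::write.table(mf, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

#' Write the classification table
#'
#' TSV with one row per classified SNP; SNPs without any genome-wide
#' significant test (group `none`) are excluded.
#'
#' @param classified result of [classify_snps()].
#' @param path output path.
#' @export
write_classification <- function(classified, path) {
  utils::write.table(classified[classified$group != "none", ], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
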