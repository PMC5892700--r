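# Internal numerical helpers. All p-values in the pipeline are carried both on
# the probability scale (clipped at .p_floor so logs stay finite) and as exact
# log10 values, because genome-wide batteries routinely underflow double
# precision and the classification rules compare orders of magnitude.

.p_floor <- 1e-300

# two-sided normal tail of a z-score, as log10
.log10p_z <- function(z) {
  (log(2) + pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)) / log(10)
}

# upper chi-square tail, as log10
.log10p_chisq <- function(stat, df) {
  pchisq(stat, df = df, lower.tail = FALSE, log.p = TRUE) / log(10)
}

.p_from_log10 <- function(log10p) {
  pmax(10^pmax(log10p, log10(.p_floor)), .p_floor)
}

.clip_p <- function(p) {
  if (any(p <= 0, na.rm = TRUE)) {
    warning("p-value(s) of 0 clipped to ", .p_floor, call. = FALSE)
    p[!is.na(p) & p <= 0] <- .p_floor
  }
  p
}

# deterministic sub-seed derivation (kept well below .Machine$integer.max)
.derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + 97 * index) %% 2147483629)
}

.assert_prob <- function(p, what = "p") {
  ok <- p[!is.na(p)]
  if (any(!is.finite(ok)) || any(ok < 0) || any(ok > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
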