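# Tiny in-code fixture builders shared across the suite.

# SNP matrix from a character matrix of category calls (or a single vector,
# treated as one locus).
tiny_snp <- function(calls, call_rate = 1, reproducibility = 1) {
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = 1L,
                                         dimnames = list("L1", names(calls)))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("L%d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("S%d", seq_len(ncol(calls)))
  snp_matrix(calls, data.frame(
    locus_id = rownames(calls), ref_seq = "", alt_seq = "",
    call_rate = rep_len(call_rate, nrow(calls)),
    reproducibility = rep_len(reproducibility, nrow(calls)),
    stringsAsFactors = FALSE))
}

tiny_pa <- function(calls, call_rate = 1, reproducibility = 1) {
  if (!is.matrix(calls)) calls <- matrix(calls, nrow = 1L,
                                         dimnames = list("L1", names(calls)))
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("L%d", seq_len(nrow(calls)))
  if (is.null(colnames(calls)))
    colnames(calls) <- sprintf("S%d", seq_len(ncol(calls)))
  pa_matrix(calls, data.frame(
    locus_id = rownames(calls), sequence = "",
    call_rate = rep_len(call_rate, nrow(calls)),
    reproducibility = rep_len(reproducibility, nrow(calls)),
    stringsAsFactors = FALSE))
}

# Registry with n_m males, n_f females, n_u unknowns named S1, S2, ...
tiny_registry <- function(n_m, n_f, n_u = 0L, site = NA_character_) {
  n <- n_m + n_f + n_u
  sex_registry(sprintf("S%d", seq_len(n)),
               c(rep("M", n_m), rep("F", n_f), rep("U", n_u)), site)
}

male_ids <- function(reg) reg$sample_id[reg$sex == "M"]
female_ids <- function(reg) reg$sample_id[reg$sex == "F"]

# Random valid matrices for round-trip property tests.
random_snp <- function(n_loci, n_samples) {
  calls <- matrix(sample(c("HOM_REF", "HOM_ALT", "HET", "NULL_CALL"),
                         n_loci * n_samples, replace = TRUE),
                  n_loci, n_samples,
                  dimnames = list(sprintf("L%03d", seq_len(n_loci)),
                                  sprintf("S%02d", seq_len(n_samples))))
  snp_matrix(calls, data.frame(
    locus_id = rownames(calls),
    ref_seq = replicate(n_loci, paste(sample(c("A", "C", "G", "T"), 8,
                                             replace = TRUE), collapse = "")),
    alt_seq = "",
    call_rate = round(runif(n_loci), 6),
    reproducibility = round(runif(n_loci), 6), stringsAsFactors = FALSE))
}

random_pa <- function(n_loci, n_samples) {
  calls <- matrix(sample(c("PRESENT", "ABSENT", "NULL_CALL"),
                         n_loci * n_samples, replace = TRUE),
                  n_loci, n_samples,
                  dimnames = list(sprintf("L%03d", seq_len(n_loci)),
                                  sprintf("S%02d", seq_len(n_samples))))
  pa_matrix(calls, data.frame(
    locus_id = rownames(calls), sequence = "",
    call_rate = round(runif(n_loci), 6),
    reproducibility = round(runif(n_loci), 6), stringsAsFactors = FALSE))
}

# Hardy-Weinberg SNP calls at reference-allele frequency p (per-locus vector
# or scalar), used by the null-scan oracles.
hw_calls <- function(n_loci, n_samples, p) {
  p <- rep_len(p, n_loci)
  u <- matrix(runif(n_loci * n_samples), n_loci, n_samples)
  g <- matrix("HOM_ALT", n_loci, n_samples,
              dimnames = list(sprintf("L%05d", seq_len(n_loci)),
                              sprintf("S%02d", seq_len(n_samples))))
  g[u < p^2 + 2 * p * (1 - p)] <- "HET"
  g[u < p^2] <- "HOM_REF"
  g
}
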